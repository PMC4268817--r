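# Per-event sequence and positional features, and group-level statistics.

#' Flanking intron and exon lengths of a cassette event
#'
#' Upstream refers to the 5' side of the transcript, so on the minus strand
#' the genomically-right gap is the upstream intron. Events whose exons
#' abut or overlap (non-positive gap) are flagged invalid.
#'
#' @param events data frame with the exon-trio coordinate columns
#'   (`up_*`, `ca_*`, `dn_*`) in transcript order, plus `strand`.
#' @return the input with columns `up_intron_len`, `dn_intron_len`,
#'   `up_exon_len`, `ca_exon_len`, `dn_exon_len`, `valid`.
#' @export
flank_lengths <- function(events) {
  # transcript order: on "+" upstream exon lies genomically left of the
  # cassette; on "-" it lies right, so the gap arithmetic flips.
  plus <- events$strand == "+"
  up_gap <- ifelse(plus, events$ca_start - events$up_end,
                   events$up_start - events$ca_end)
  dn_gap <- ifelse(plus, events$dn_start - events$ca_end,
                   events$ca_start - events$dn_end)
  events$up_intron_len <- up_gap
  events$dn_intron_len <- dn_gap
  events$up_exon_len <- events$up_end - events$up_start
  events$ca_exon_len <- events$ca_end - events$ca_start
  events$dn_exon_len <- events$dn_end - events$dn_start
  events$valid <- up_gap > 0 & dn_gap > 0
  events
}

# Donor/acceptor window sequences for a junction, transcript orientation.
# 0-based half-open exon coordinates; the donor window spans the last 3 nt
# of the exon and the first 6 nt of the downstream intron, the acceptor the
# last 20 nt of the upstream intron and the first 3 nt of the exon.
donor_window_seq <- function(genome, chrom, strand, exon_start, exon_end) {
  if (strand == "+") {
    extract_seq(genome, chrom, exon_end - 3L, exon_end + 6L, strand)
  } else {
    extract_seq(genome, chrom, exon_start - 6L, exon_start + 3L, strand)
  }
}

acceptor_window_seq <- function(genome, chrom, strand, exon_start, exon_end) {
  if (strand == "+") {
    extract_seq(genome, chrom, exon_start - 20L, exon_start + 3L, strand)
  } else {
    extract_seq(genome, chrom, exon_end - 3L, exon_end + 20L, strand)
  }
}

#' Compute the per-event feature table
#'
#' For each event: flanking intron/exon lengths; donor and acceptor
#' splice-site scores of the cassette exon (its own acceptor and donor) and
#' of the flanking junctions; exonic motif frequencies over the cassette
#' exon and intronic frequencies over the full flanking introns; optional
#' permutation z-scores for the cassette exon.
#'
#' @param events exon-trio events (e.g. categorised events or control
#'   triplets).
#' @param genome a [Biostrings::DNAStringSet].
#' @param donor_model,acceptor_model `splice_site_model`s.
#' @param motif_sets named list of `motif_set`s (ESE/ESS over the exon,
#'   ISE/ISS over the introns).
#' @param zscore_sets names of motif sets for which a permutation z-score of
#'   the cassette exon is computed (`NULL` for none).
#' @param n_shuffles,seed z-score randomisation settings.
#' @return the events with feature columns appended; invalid events (non-
#'   positive intron gaps) carry NA features.
#' @export
compute_event_features <- function(events, genome, donor_model,
                                   acceptor_model, motif_sets = list(),
                                   zscore_sets = NULL, n_shuffles = 100,
                                   seed = 1) {
  ev <- flank_lengths(events)
  n <- nrow(ev)
  num <- function() rep(NA_real_, n)
  ev$ca_acceptor_score <- ev$ca_donor_score <- num()
  ev$up_donor_score <- ev$dn_acceptor_score <- num()
  for (ms_name in names(motif_sets)) {
    kind <- motif_sets[[ms_name]]$kind
    if (kind %in% c("ESE", "ESS")) {
      ev[[paste0("freq_", ms_name, "_ca")]] <- num()
    } else {
      ev[[paste0("freq_", ms_name, "_up_intron")]] <- num()
      ev[[paste0("freq_", ms_name, "_dn_intron")]] <- num()
    }
  }
  for (zs in zscore_sets) ev[[paste0("z_", zs, "_ca")]] <- num()
  for (i in seq_len(n)) {
    if (!ev$valid[i]) next
    chrom <- ev$chrom[i]; strand <- ev$strand[i]
    ca_seq <- extract_seq(genome, chrom, ev$ca_start[i], ev$ca_end[i], strand)
    # introns in transcript orientation
    if (strand == "+") {
      up_in <- extract_seq(genome, chrom, ev$up_end[i], ev$ca_start[i], strand)
      dn_in <- extract_seq(genome, chrom, ev$ca_end[i], ev$dn_start[i], strand)
    } else {
      up_in <- extract_seq(genome, chrom, ev$ca_end[i], ev$up_start[i], strand)
      dn_in <- extract_seq(genome, chrom, ev$dn_end[i], ev$ca_start[i], strand)
    }
    ev$ca_acceptor_score[i] <- score_site(
      acceptor_window_seq(genome, chrom, strand, ev$ca_start[i], ev$ca_end[i]),
      acceptor_model)
    ev$ca_donor_score[i] <- score_site(
      donor_window_seq(genome, chrom, strand, ev$ca_start[i], ev$ca_end[i]),
      donor_model)
    ev$up_donor_score[i] <- score_site(
      donor_window_seq(genome, chrom, strand, ev$up_start[i], ev$up_end[i]),
      donor_model)
    ev$dn_acceptor_score[i] <- score_site(
      acceptor_window_seq(genome, chrom, strand, ev$dn_start[i], ev$dn_end[i]),
      acceptor_model)
    for (ms_name in names(motif_sets)) {
      ms <- motif_sets[[ms_name]]
      if (ms$kind %in% c("ESE", "ESS")) {
        ev[[paste0("freq_", ms_name, "_ca")]][i] <- sre_frequency(ca_seq, ms)
      } else {
        ev[[paste0("freq_", ms_name, "_up_intron")]][i] <-
          sre_frequency(up_in, ms)
        ev[[paste0("freq_", ms_name, "_dn_intron")]][i] <-
          sre_frequency(dn_in, ms)
      }
    }
    for (zs in zscore_sets) {
      res <- motif_zscore(ca_seq, motif_sets[[zs]], n_shuffles = n_shuffles,
                          seed = seed + i)
      ev[[paste0("z_", zs, "_ca")]][i] <- res$z
    }
  }
  ev
}

#' Mann-Whitney-Wilcoxon comparison of two feature groups
#'
#' Two-sided rank-sum test; exact enumeration for small samples without
#' ties, normal approximation otherwise (the default behaviour of
#' [stats::wilcox.test()]).
#'
#' @param values_a,values_b numeric vectors (each non-empty).
#' @return list with `statistic` (the rank-sum U of group a), `p_value`,
#'   `n_a`, `n_b`.
#' @export
compare_groups <- function(values_a, values_b) {
  if (length(values_a) == 0 || length(values_b) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  wt <- suppressWarnings(wilcox.test(values_a, values_b,
                                     alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_a = length(values_a), n_b = length(values_b))
}

#' Rank correlation between intron length and expression change
#'
#' Spearman correlation with tie-corrected ranks between flanking intron
#' lengths and per-gene log fold changes. Constant input yields the
#' undefined sentinel (`NA` with `degenerate = TRUE`).
#'
#' @param intron_lengths,log_fold_changes paired numeric vectors, n >= 3.
#' @return list with `rho`, `p_value`, `n`, `degenerate`.
#' @export
length_expression_correlation <- function(intron_lengths, log_fold_changes) {
  ok <- is.finite(intron_lengths) & is.finite(log_fold_changes)
  x <- intron_lengths[ok]; y <- log_fold_changes[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    return(list(rho = NA_real_, p_value = NA_real_, n = length(x),
                degenerate = TRUE))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       degenerate = FALSE)
}

#' Group-wise feature comparisons with multiplicity adjustment
#'
#' Runs [compare_groups()] for each feature column between every test
#' category and a reference category, reporting raw and
#' Benjamini-Hochberg-adjusted p-values.
#'
#' @param features feature table with a `group` column.
#' @param feature_cols feature column names to test.
#' @param reference group label of the reference (control) category.
#' @return data frame `feature`, `group`, `statistic`, `p_value`, `p_adj`.
#' @export
feature_group_tests <- function(features, feature_cols,
                                reference = "Ctr") {
  groups <- setdiff(unique(features$group), reference)
  ref <- features[features$group == reference, , drop = FALSE]
  rows <- list()
  for (g in groups) {
    tst <- features[features$group == g, , drop = FALSE]
    for (fc in feature_cols) {
      a <- tst[[fc]]; b <- ref[[fc]]
      a <- a[is.finite(a)]; b <- b[is.finite(b)]
      if (length(a) == 0 || length(b) == 0) next
      res <- compare_groups(a, b)
      rows[[length(rows) + 1L]] <- data.frame(
        feature = fc, group = g, statistic = res$statistic,
        p_value = res$p_value, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(feature = character(), group = character(),
               statistic = numeric(), p_value = numeric(),
               stringsAsFactors = FALSE)
  out$p_adj <- p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}
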