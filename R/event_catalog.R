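# Differential-splicing event catalog: parsing, filtering, replicate
# intersection, cross-caller merging, direction/annotation classification,
# control-set construction, and the expression filter.
#
# Sign convention throughout: delta_psi = Psi_control - Psi_KD, so positive
# delta-Psi means increased skipping (lower inclusion) in the knockdown.

CASSETTE_COLS <- c("event_id", "gene_id", "chrom", "strand",
                   "up_start", "up_end", "ca_start", "ca_end",
                   "dn_start", "dn_end", "contrast",
                   "psi_control", "psi_kd", "delta_psi", "score",
                   "inc_reads", "skip_reads", "source")

event_key <- function(ev) {
  paste(ev$chrom, ev$strand, ev$ca_start, ev$ca_end, sep = "|")
}

intron_key <- function(ev) {
  paste(ev$chrom, ev$strand, ev$intron_start, ev$intron_end, sep = "|")
}

#' Parse a differential-splicing event table
#'
#' Reads a TSV in either caller dialect into the standard internal event
#' representation (0-based half-open coordinates, one row per event and
#' contrast). Rows violating the Psi range or the delta-Psi identity are
#' rejected with a line-number diagnostic.
#'
#' @param path TSV path.
#' @param dialect `"miso"` (per-replicate contrasts: columns `psi1`, `psi2`,
#'   `diff`, `bayes_factor`, `inc_reads`, `skip_reads`) or `"diffsplice"`
#'   (replicate-aware: `asm_id`, `psi_control`, `psi_kd`, `jsd`).
#' @param type `"cassette"` (exon trio coordinates) or `"intron"`
#'   (intron plus abutting flanking exons).
#' @return a data frame of standardised events; class `cassette_events` or
#'   `intron_events`.
#' @export
parse_event_table <- function(path, dialect = c("miso", "diffsplice"),
                              type = c("cassette", "intron")) {
  dialect <- match.arg(dialect)
  type <- match.arg(type)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0) {
    return(empty_events(type))
  }
  check_col <- function(cols) {
    miss <- setdiff(cols, names(tab))
    if (length(miss)) stop("missing column(s) in ", dialect, " table: ",
                           paste(miss, collapse = ", "), call. = FALSE)
  }
  coord_cols <- if (type == "cassette") {
    c("up_start", "up_end", "ca_start", "ca_end", "dn_start", "dn_end")
  } else {
    c("intron_start", "intron_end", "up_start", "up_end",
      "dn_start", "dn_end")
  }
  check_psi <- function(psi, what) {
    bad <- which(!is.na(psi) & (psi < 0 | psi > 1))
    if (length(bad)) {
      stop_with_line(bad[1] + 1L,  # +1 for the header line
                     sprintf("%s = %g outside [0, 1]", what, psi[bad[1]]))
    }
  }
  if (dialect == "miso") {
    check_col(c("event_id", "chrom", "strand", coord_cols, "contrast",
                "psi1", "psi2", "diff", "bayes_factor",
                "inc_reads", "skip_reads"))
    check_psi(tab$psi1, "psi1"); check_psi(tab$psi2, "psi2")
    bad <- which(!is.na(tab$diff) &
                   abs(tab$diff - (tab$psi1 - tab$psi2)) > 1e-9)
    if (length(bad)) {
      stop_with_line(bad[1] + 1L, "diff does not equal psi1 - psi2")
    }
    ev <- data.frame(
      event_id = tab$event_id,
      gene_id = tab$gene_id %||% NA_character_,
      tab[c("chrom", "strand", coord_cols, "contrast")],
      psi_control = tab$psi1, psi_kd = tab$psi2, delta_psi = tab$diff,
      score = tab$bayes_factor,
      inc_reads = tab$inc_reads, skip_reads = tab$skip_reads,
      source = "MISO", stringsAsFactors = FALSE)
  } else {
    check_col(c("asm_id", "chrom", "strand", coord_cols, "contrast",
                "psi_control", "psi_kd", "jsd"))
    check_psi(tab$psi_control, "psi_control")
    check_psi(tab$psi_kd, "psi_kd")
    ev <- data.frame(
      event_id = tab$asm_id,
      gene_id = tab$gene_id %||% NA_character_,
      tab[c("chrom", "strand", coord_cols, "contrast")],
      psi_control = tab$psi_control, psi_kd = tab$psi_kd,
      delta_psi = tab$psi_control - tab$psi_kd,
      score = tab$jsd,
      inc_reads = NA_real_, skip_reads = NA_real_,
      source = "DiffSplice", stringsAsFactors = FALSE)
  }
  if (type == "intron") {
    bad <- which(ev$up_end != ev$intron_start | ev$dn_start != ev$intron_end)
    if (length(bad)) {
      stop_with_line(bad[1] + 1L, "flanking exons do not abut the intron")
    }
    bad <- which(ev$intron_end - ev$intron_start < 1)
    if (length(bad)) stop_with_line(bad[1] + 1L, "intron length < 1 nt")
    class(ev) <- c("intron_events", "data.frame")
  } else {
    class(ev) <- c("cassette_events", "data.frame")
  }
  ev
}

empty_events <- function(type = "cassette") {
  coord_cols <- if (type == "cassette") {
    c("up_start", "up_end", "ca_start", "ca_end", "dn_start", "dn_end")
  } else {
    c("intron_start", "intron_end", "up_start", "up_end",
      "dn_start", "dn_end")
  }
  ev <- data.frame(event_id = character(), gene_id = character(),
                   chrom = character(), strand = character(),
                   stringsAsFactors = FALSE)
  for (cc in coord_cols) ev[[cc]] <- integer()
  ev$contrast <- character()
  ev$psi_control <- ev$psi_kd <- ev$delta_psi <- ev$score <- numeric()
  ev$inc_reads <- ev$skip_reads <- numeric()
  ev$source <- character()
  class(ev) <- c(if (type == "cassette") "cassette_events" else
    "intron_events", "data.frame")
  ev
}

#' Filter MISO-dialect events at the standard thresholds
#'
#' Retains an event iff all of: `|delta_psi| > 0.1`, evidence score
#' (Bayes factor) `> 5`, skipping reads `> 10`, inclusion reads `> 10`,
#' and inclusion + skipping reads `> 20` — all strict inequalities.
#'
#' @param events standardised events (MISO dialect; must carry counts).
#' @param delta_psi_min,score_min,min_inc,min_skip,min_total thresholds.
#' @return the retained subset.
#' @export
filter_miso_events <- function(events, delta_psi_min = 0.1, score_min = 5,
                               min_inc = 10, min_skip = 10, min_total = 20) {
  if (any(is.na(events$inc_reads)) || any(is.na(events$skip_reads))) {
    stop("events lack inclusion/skipping read counts", call. = FALSE)
  }
  keep <- !is.na(events$delta_psi) &
    abs(events$delta_psi) > delta_psi_min &
    events$score > score_min &
    events$skip_reads > min_skip &
    events$inc_reads > min_inc &
    (events$inc_reads + events$skip_reads) > min_total
  events[keep, , drop = FALSE]
}

#' Filter DiffSplice-dialect events
#'
#' DiffSplice calls are replicate-aware; only the inclusion-change threshold
#' `|delta_psi| > 0.1` (strict) is applied.
#'
#' @param events standardised events (DiffSplice dialect).
#' @param delta_psi_min threshold.
#' @export
filter_diffsplice_events <- function(events, delta_psi_min = 0.1) {
  keep <- !is.na(events$delta_psi) & abs(events$delta_psi) > delta_psi_min
  events[keep, , drop = FALSE]
}

#' Intersect filtered events across two replicates
#'
#' Keeps events (per contrast) present in both replicates at identical
#' cassette-exon coordinates with the same delta-Psi sign; reported Psi,
#' delta-Psi, score and counts are replicate means.
#'
#' @param rep1,rep2 filtered standardised events.
#' @return the intersected events.
#' @export
intersect_replicates <- function(rep1, rep2) {
  if (nrow(rep1) == 0 || nrow(rep2) == 0) return(empty_events())
  k1 <- paste(event_key(rep1), rep1$contrast)
  k2 <- paste(event_key(rep2), rep2$contrast)
  m <- match(k1, k2)
  keep <- !is.na(m) &
    sign(rep1$delta_psi) == sign(rep2$delta_psi[m])
  out <- rep1[keep, , drop = FALSE]
  m <- m[keep]
  for (cc in c("psi_control", "psi_kd", "delta_psi", "score",
               "inc_reads", "skip_reads")) {
    out[[cc]] <- (out[[cc]] + rep2[[cc]][m]) / 2
  }
  rownames(out) <- NULL
  out
}

#' Merge the MISO replicate intersection with DiffSplice calls
#'
#' Union of both catalogs, deduplicated per contrast by cassette-exon
#' coordinates (chromosome, strand, start, end). Events present in both are
#' marked `source = "both"` and keep the MISO Psi estimates (declared
#' precedence). Coordinate-equal events with opposite delta-Psi signs
#' across the two callers are discordant: excluded from the merged set and
#' returned in an audit table.
#'
#' @param miso_intersection,diffsplice_events filtered standardised events.
#' @return list with `events` (merged) and `discordant` (audit table).
#' @export
merge_catalogs <- function(miso_intersection, diffsplice_events) {
  a <- miso_intersection; b <- diffsplice_events
  if (nrow(b) == 0) {
    return(list(events = a, discordant = empty_events()))
  }
  if (nrow(a) == 0) {
    return(list(events = b, discordant = empty_events()))
  }
  ka <- paste(event_key(a), a$contrast)
  kb <- paste(event_key(b), b$contrast)
  m <- match(ka, kb)
  shared <- !is.na(m)
  concordant <- shared & sign(a$delta_psi) == sign(b$delta_psi[m])
  discordant_a <- shared & !concordant
  out <- a
  out$source[concordant] <- "both"
  out <- out[!discordant_a, , drop = FALSE]
  b_only <- b[!(kb %in% ka), , drop = FALSE]
  merged <- rbind(out, b_only)
  rownames(merged) <- NULL
  disc <- rbind(a[discordant_a, , drop = FALSE],
                b[kb %in% ka[discordant_a], , drop = FALSE])
  rownames(disc) <- NULL
  list(events = merged, discordant = disc)
}

#' Classify merged events by direction and annotation status
#'
#' Aggregates the per-contrast rows of each event and assigns:
#' direction `"+"` (increased skipping) if `delta_psi > delta_psi_min` in at
#' least one EJC contrast, `"-"` if `delta_psi < -delta_psi_min`; events
#' significant in no EJC contrast get direction `"none"` and are excluded
#' from the categorised set. Annotation class is `ALT` if the cassette exon
#' is annotated alternative, `CON` if it is an annotated exon with no
#' alternative annotation. Excluded with an audit record: events whose
#' cassette exon is absent from the annotation, events not flanked by
#' constitutive annotated exons on both sides, events whose cassette exon
#' overlaps another event's cassette exon (complex splicing patterns), and
#' events with conflicting directions across EJC contrasts.
#'
#' @param merged merged standardised events (per-contrast rows).
#' @param annotation a `genome_annotation`.
#' @param delta_psi_min direction threshold (strict).
#' @return list with `events` (one row per categorised event, with
#'   `direction`, `anno_class`, `category`, `significant_contrasts`,
#'   `delta_psi` = the largest-magnitude significant EJC delta) and `audit`
#'   (excluded events with a `reason` column).
#' @export
classify_events <- function(merged, annotation, delta_psi_min = 0.1) {
  ex <- annotation$exons
  exon_id <- paste(ex$chrom, ex$strand, ex$start, ex$end, sep = "|")
  audit <- list()
  rows <- list()
  for (grp in split(merged, event_key(merged))) {
    base <- grp[1, , drop = FALSE]
    ejc <- grp[grp$contrast %in% EJC_CONTRASTS, , drop = FALSE]
    up <- ejc$contrast[!is.na(ejc$delta_psi) & ejc$delta_psi > delta_psi_min]
    dn <- ejc$contrast[!is.na(ejc$delta_psi) & ejc$delta_psi < -delta_psi_min]
    if (length(up) && length(dn)) {
      base$reason <- "direction_conflict"
      audit[[length(audit) + 1L]] <- base
      next
    }
    direction <- if (length(up)) "+" else if (length(dn)) "-" else "none"
    if (direction == "none") next
    sig <- ejc[ejc$contrast %in% c(up, dn), , drop = FALSE]
    base$delta_psi <- sig$delta_psi[which.max(abs(sig$delta_psi))]
    base$significant_contrasts <- paste(sort(c(up, dn)), collapse = ",")
    base$source <- paste(sort(unique(grp$source)), collapse = ",")
    # annotation lookups
    ca <- match(paste(base$chrom, base$strand, base$ca_start, base$ca_end,
                      sep = "|"), exon_id)
    if (is.na(ca)) {
      base$reason <- "cassette_not_in_annotation"
      audit[[length(audit) + 1L]] <- base[setdiff(names(base),
                                                  c("significant_contrasts"))]
      next
    }
    flank_ids <- paste(base$chrom, base$strand,
                       c(base$up_start, base$dn_start),
                       c(base$up_end, base$dn_end), sep = "|")
    fl <- match(flank_ids, exon_id)
    if (any(is.na(fl))) {
      base$reason <- "flank_not_in_annotation"
      audit[[length(audit) + 1L]] <- base[setdiff(names(base),
                                                  c("significant_contrasts"))]
      next
    }
    if (any(ex$alternative[fl])) {
      base$reason <- "alternative_flank"
      audit[[length(audit) + 1L]] <- base[setdiff(names(base),
                                                  c("significant_contrasts"))]
      next
    }
    base$direction <- direction
    base$anno_class <- if (ex$alternative[ca]) "ALT" else "CON"
    rows[[length(rows) + 1L]] <- base
  }
  if (length(rows) == 0) {
    out <- empty_events()
    out$direction <- out$anno_class <- out$category <- character()
    out$significant_contrasts <- character()
  } else {
    out <- do.call(rbind, rows)
    # complex patterns: cassette exon overlapping another event's cassette
    gr <- GenomicRanges::GRanges(out$chrom,
                                 IRanges::IRanges(out$ca_start + 1L,
                                                  out$ca_end),
                                 strand = out$strand)
    hits <- GenomicRanges::findOverlaps(gr, gr)
    ovl <- unique(S4Vectors::queryHits(hits)[
      S4Vectors::queryHits(hits) != S4Vectors::subjectHits(hits)])
    if (length(ovl)) {
      bad <- out[ovl, , drop = FALSE]
      bad$reason <- "overlapping_event"
      bad$direction <- bad$anno_class <- NULL
      audit[[length(audit) + 1L]] <- bad
      out <- out[-ovl, , drop = FALSE]
    }
    out$category <- paste0(out$direction, out$anno_class)
    rownames(out) <- NULL
  }
  audit_df <- if (length(audit)) {
    common <- Reduce(intersect, lapply(audit, names))
    do.call(rbind, lapply(audit, `[`, common))
  } else {
    data.frame(event_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  }
  rownames(audit_df) <- NULL
  list(events = out, audit = audit_df)
}

#' Classify intron-retention events by direction of change
#'
#' Direction `"+"` (decreased intron level in knockdown, i.e. retention
#' down) if `delta_psi > delta_psi_min` in at least one EJC contrast;
#' `"-"` (increased retention) if `delta_psi < -delta_psi_min`; conflicting
#' events are excluded to the audit table. Psi here is the intron inclusion
#' (retention) level.
#'
#' @param events standardised intron events (per-contrast rows).
#' @param delta_psi_min direction threshold (strict).
#' @return list with `events` (one row per classified event) and `audit`.
#' @export
classify_intron_events <- function(events, delta_psi_min = 0.1) {
  rows <- list(); audit <- list()
  for (grp in split(events, intron_key(events))) {
    base <- grp[1, , drop = FALSE]
    ejc <- grp[grp$contrast %in% EJC_CONTRASTS, , drop = FALSE]
    up <- any(!is.na(ejc$delta_psi) & ejc$delta_psi > delta_psi_min)
    dn <- any(!is.na(ejc$delta_psi) & ejc$delta_psi < -delta_psi_min)
    if (up && dn) {
      base$reason <- "direction_conflict"
      audit[[length(audit) + 1L]] <- base
      next
    }
    if (!up && !dn) next
    sig <- ejc[!is.na(ejc$delta_psi) &
                 abs(ejc$delta_psi) > delta_psi_min, , drop = FALSE]
    base$delta_psi <- sig$delta_psi[which.max(abs(sig$delta_psi))]
    base$direction <- if (up) "+" else "-"
    base$category <- if (up) "retention-down" else "retention-up"
    rows[[length(rows) + 1L]] <- base
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    e <- empty_events("intron"); e$direction <- e$category <- character(); e
  }
  audit_df <- if (length(audit)) do.call(rbind, audit) else
    data.frame(event_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  rownames(out) <- rownames(audit_df) <- NULL
  list(events = out, audit = audit_df)
}

#' Build the two control exon sets
#'
#' `Ctr`: alternative (cassette) events unaffected in every EJC contrast —
#' `|delta_psi| < 0.03` throughout and all Psi estimates inside the open
#' interval (0.1, 0.9) — sampled without replacement to `n_ctr`.
#' `CtrCON`: triplets of three successive constitutive exons, excluding the
#' first and last exon of each transcript and allowing at most one triplet
#' per gene, sampled to `n_ctr_con`. Both sets are restricted to expressed
#' genes when `expressed_genes` is given. If a requested size exceeds the
#' eligible pool the full pool is returned with a warning.
#'
#' @param all_miso_events unfiltered standardised MISO events (per-contrast
#'   rows) from which Ctr candidates are drawn.
#' @param annotation a `genome_annotation`.
#' @param n_ctr,n_ctr_con requested control-set sizes.
#' @param seed sampling seed.
#' @param max_delta,psi_range Ctr eligibility: maximum absolute splicing
#'   change and open Psi interval.
#' @param expressed_genes optional character vector of expressed gene ids.
#' @return list with data frames `ctr` (events) and `ctr_con` (exon
#'   triplets: `up_*`, `ca_*`, `dn_*` coordinate columns in transcript
#'   order).
#' @export
build_controls <- function(all_miso_events, annotation,
                           n_ctr = 100, n_ctr_con = 100, seed = 1,
                           max_delta = 0.03, psi_range = c(0.1, 0.9),
                           expressed_genes = NULL) {
  ev <- all_miso_events
  ex <- annotation$exons
  exon_id <- paste(ex$chrom, ex$strand, ex$start, ex$end, sep = "|")
  # Ctr: per event, every EJC-contrast row must satisfy the predicates
  ejc <- ev[ev$contrast %in% EJC_CONTRASTS, , drop = FALSE]
  ok_row <- !is.na(ejc$delta_psi) & abs(ejc$delta_psi) < max_delta &
    ejc$psi_control > psi_range[1] & ejc$psi_control < psi_range[2] &
    ejc$psi_kd > psi_range[1] & ejc$psi_kd < psi_range[2]
  keys <- event_key(ejc)
  eligible_keys <- names(which(tapply(ok_row, keys, all)))
  cand <- ejc[!duplicated(keys) & keys %in% eligible_keys, , drop = FALSE]
  # must correspond to an annotated alternative exon
  ca <- match(paste(cand$chrom, cand$strand, cand$ca_start, cand$ca_end,
                    sep = "|"), exon_id)
  cand <- cand[!is.na(ca) & ex$alternative[ca], , drop = FALSE]
  if (!is.null(expressed_genes)) {
    cand <- cand[cand$gene_id %in% expressed_genes, , drop = FALSE]
  }
  # CtrCON: one triplet of successive internal constitutive exons per gene
  con_pool <- list()
  for (tx in split(ex, ex$transcript_id)) {
    if (!is.null(expressed_genes) && !(tx$gene_id[1] %in% expressed_genes)) {
      next
    }
    tx <- tx[order(tx$exon_rank), ]
    n_ex <- nrow(tx)
    if (n_ex < 5L) next  # need 3 successive internal exons
    internal <- 2:(n_ex - 1L)
    con <- internal[!tx$alternative[internal]]
    runs <- split(con, cumsum(c(1, diff(con) != 1)))
    starts <- unlist(lapply(runs, function(r) {
      if (length(r) >= 3) r[seq_len(length(r) - 2L)] else integer(0)
    }), use.names = FALSE)
    if (length(starts) == 0) next
    con_pool[[tx$gene_id[1]]] <- lapply(starts, function(s) {
      idx <- s:(s + 2L)
      data.frame(gene_id = tx$gene_id[1], chrom = tx$chrom[1],
                 strand = tx$strand[1],
                 up_start = tx$start[idx[1]], up_end = tx$end[idx[1]],
                 ca_start = tx$start[idx[2]], ca_end = tx$end[idx[2]],
                 dn_start = tx$start[idx[3]], dn_end = tx$end[idx[3]],
                 stringsAsFactors = FALSE)
    })
  }
  with_seed(seed, {
    ctr <- sample_pool(cand, n_ctr, "Ctr")
    per_gene <- lapply(con_pool, function(triplets) {
      triplets[[sample.int(length(triplets), 1L)]]
    })
    con_df <- if (length(per_gene)) {
      do.call(rbind, per_gene)
    } else {
      data.frame(gene_id = character(), chrom = character(),
                 strand = character(), up_start = integer(),
                 up_end = integer(), ca_start = integer(),
                 ca_end = integer(), dn_start = integer(),
                 dn_end = integer(), stringsAsFactors = FALSE)
    }
    rownames(con_df) <- NULL
    ctr_con <- sample_pool(con_df, n_ctr_con, "CtrCON")
    list(ctr = ctr, ctr_con = ctr_con)
  })
}

sample_pool <- function(pool, n, what) {
  if (nrow(pool) <= n) {
    if (nrow(pool) < n) {
      warning(sprintf("%s pool (%d) smaller than requested n = %d; %s",
                      what, nrow(pool), n, "returning the full pool"),
              call. = FALSE)
    }
    rownames(pool) <- NULL
    return(pool)
  }
  out <- pool[sort(sample.int(nrow(pool), n)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Expression (coverage) filter
#'
#' Per-gene coverage is `C = read_length * reads / tx_length`. A gene is
#' retained iff `C >= threshold` in the control condition and in at least
#' one knockdown condition (threshold inclusive, so the worked value
#' C = 51*200/1020 = 10 passes).
#'
#' @param records long-format data frame with columns `gene_id`,
#'   `condition`, `reads`, `tx_length` (and optionally `read_length`).
#' @param threshold coverage cutoff (default 10).
#' @param read_length default read length in nt when the column is absent.
#' @return character vector of retained gene ids, with the full per-gene
#'   coverage table in attribute `"coverage"` (adds `coverage` and `rpkm`
#'   columns).
#' @export
expression_filter <- function(records, threshold = 10, read_length = 51) {
  req <- c("gene_id", "condition", "reads", "tx_length")
  miss <- setdiff(req, names(records))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (any(records$tx_length <= 0)) {
    stop("tx_length must be positive", call. = FALSE)
  }
  R <- records$read_length %||% read_length
  records$coverage <- R * records$reads / records$tx_length
  totals <- tapply(records$reads, records$condition, sum)
  records$rpkm <- records$reads /
    (records$tx_length / 1e3 * totals[records$condition] / 1e6)
  ctrl_ok <- with(records, tapply(
    coverage >= threshold & condition == CONTROL_CONDITION, gene_id, any))
  kd_ok <- with(records, tapply(
    coverage >= threshold & condition != CONTROL_CONDITION, gene_id, any))
  genes <- names(which(ctrl_ok & kd_ok[names(ctrl_ok)]))
  structure(genes, coverage = records)
}

#' Per-gene expression fold changes
#'
#' Fold change of library-size-normalised counts, knockdown over control,
#' per contrast.
#'
#' @param records long-format expression records as in
#'   [expression_filter()].
#' @return data frame `gene_id`, `contrast`, `fc`.
#' @export
fold_changes <- function(records) {
  totals <- tapply(records$reads, records$condition, sum)
  ctrl <- records[records$condition == CONTROL_CONDITION, ]
  ctrl_norm <- setNames(ctrl$reads / totals[[CONTROL_CONDITION]],
                        ctrl$gene_id)
  kd <- records[records$condition != CONTROL_CONDITION, ]
  data.frame(
    gene_id = kd$gene_id,
    contrast = kd$condition,
    fc = (kd$reads / totals[kd$condition]) / ctrl_norm[kd$gene_id],
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Simulate per-gene read counts
#'
#' Counts consistent with the coverage definition: `reads ~ Poisson(level *
#' tx_length / read_length)`, where `level` is the gene's mean per-base
#' exonic coverage. Genes in `upregulated_genes` get their knockdown
#' expectation multiplied by `up_fc` in the EJC contrasts (emulating
#' stabilised NMD targets).
#'
#' @param annotation a `genome_annotation`.
#' @param config a [sim_config()].
#' @param expression optional per-gene levels (`gene_id`, `level`) as
#'   returned by [simulate_coverage()]; drawn afresh when `NULL`.
#' @param upregulated_genes,up_fc see description.
#' @return long-format records usable by [expression_filter()].
#' @export
simulate_expression_counts <- function(annotation, config, expression = NULL,
                                       upregulated_genes = character(0),
                                       up_fc = 2) {
  validate_sim_config(config)
  with_seed(config$seed + 3L, {
    genes <- annotation$genes
    if (is.null(expression)) {
      expression <- data.frame(
        gene_id = genes$gene_id,
        level = rlnorm(nrow(genes), config$expression_meanlog,
                       config$expression_sdlog),
        stringsAsFactors = FALSE)
    }
    tx_len <- tapply(annotation$exons$end - annotation$exons$start,
                     annotation$exons$gene_id, sum)
    lam <- expression$level * tx_len[expression$gene_id] / config$read_length
    rows <- list()
    for (cond in c(CONTROL_CONDITION, ALL_CONTRASTS)) {
      mult <- rep(1, nrow(genes))
      if (cond %in% EJC_CONTRASTS) {
        mult[expression$gene_id %in% upregulated_genes] <- up_fc
      }
      rows[[cond]] <- data.frame(
        gene_id = expression$gene_id, condition = cond,
        reads = rpois(nrow(genes), lam * mult),
        tx_length = as.numeric(tx_len[expression$gene_id]),
        read_length = config$read_length,
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
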