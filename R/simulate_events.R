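# Simulated differential-splicing event tables in two caller dialects.
#
# For each cassette event, condition and replicate, informative reads are
# drawn as total ~ Poisson(read_depth) and inclusion ~ Binomial(total, Psi),
# so the observed Psi-hat = inc/(inc+skip) is an unbiased binomial
# estimator of the true inclusion level.

#' Simulate per-replicate event tables in two dialects
#'
#' Produces per-replicate MISO-like contrast tables (control vs each
#' knockdown, one table per replicate) and a single replicate-aware
#' DiffSplice-like table. The MISO-like evidence score standing in for the
#' Bayes factor is `2 * |delta-Psi-hat| * sqrt(total informative reads)`, a
#' monotone function of effect size and depth under which the conventional
#' threshold of 5 separates planted changes (|delta-Psi| = 0.3 at depth
#' 100x2) from null events. The DiffSplice-like score is the Jensen-Shannon
#' divergence between the two estimated inclusion distributions.
#'
#' @param annotation a `genome_annotation` whose `events` carry true Psi
#'   columns (from [generate_annotation()]).
#' @param config a [sim_config()].
#' @return a list with `miso` (list of data frames, one per replicate) and
#'   `diffsplice` (one data frame).
#' @export
simulate_event_tables <- function(annotation, config) {
  validate_sim_config(config)
  ev <- annotation$events
  if (nrow(ev) == 0) {
    stop("annotation has no cassette events", call. = FALSE)
  }
  psi_cols <- paste0("psi_", c(CONTROL_CONDITION, ALL_CONTRASTS))
  if (!all(psi_cols %in% names(ev))) {
    stop("every event needs a true Psi per condition (columns ",
         paste(psi_cols, collapse = ", "), ")", call. = FALSE)
  }
  with_seed(config$seed + 1L, simulate_event_tables_impl(ev, config))
}

simulate_event_tables_impl <- function(ev, config) {
  n <- nrow(ev)
  depth <- config$read_depth
  draw <- function(psi) {
    total <- rpois(n, depth)
    inc <- rbinom(n, total, psi)
    list(inc = inc, skip = total - inc)
  }
  coord_cols <- c("event_id", "gene_id", "chrom", "strand",
                  "up_start", "up_end", "ca_start", "ca_end",
                  "dn_start", "dn_end")
  miso <- vector("list", config$n_replicates)
  ds_rows <- list()
  for (rep_i in seq_len(config$n_replicates)) {
    rows <- list()
    for (cc in ALL_CONTRASTS) {
      ctrl <- draw(ev$psi_control)
      kd <- draw(ev[[paste0("psi_", cc)]])
      psi1 <- ifelse(ctrl$inc + ctrl$skip > 0,
                     ctrl$inc / (ctrl$inc + ctrl$skip), NA_real_)
      psi2 <- ifelse(kd$inc + kd$skip > 0,
                     kd$inc / (kd$inc + kd$skip), NA_real_)
      diff <- psi1 - psi2
      total <- ctrl$inc + ctrl$skip + kd$inc + kd$skip
      rows[[cc]] <- cbind(
        ev[coord_cols],
        data.frame(contrast = cc, psi1 = psi1, psi2 = psi2, diff = diff,
                   bayes_factor = 2 * abs(diff) * sqrt(total),
                   inc_reads = ctrl$inc + kd$inc,
                   skip_reads = ctrl$skip + kd$skip,
                   stringsAsFactors = FALSE))
      ds_rows[[paste(rep_i, cc)]] <- data.frame(
        contrast = cc, rep = rep_i, psi1 = psi1, psi2 = psi2,
        stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    miso[[rep_i]] <- tab
  }
  # DiffSplice-like: replicate-aware, one row per event x contrast with
  # group-mean Psi and a JSD score.
  ds <- list()
  for (cc in ALL_CONTRASTS) {
    reps <- ds_rows[grepl(paste0(" ", cc, "$"), names(ds_rows))]
    p1 <- rowMeans(do.call(cbind, lapply(reps, `[[`, "psi1")), na.rm = TRUE)
    p2 <- rowMeans(do.call(cbind, lapply(reps, `[[`, "psi2")), na.rm = TRUE)
    ds[[cc]] <- cbind(
      ev[coord_cols],
      data.frame(asm_id = paste0("ASM_", ev$event_id), contrast = cc,
                 psi_control = p1, psi_kd = p2,
                 jsd = mapply(bernoulli_jsd, p1, p2),
                 stringsAsFactors = FALSE))
  }
  ds <- do.call(rbind, ds)
  rownames(ds) <- NULL
  list(miso = miso, diffsplice = ds)
}

# Jensen-Shannon divergence between Bernoulli(p) and Bernoulli(q), bits.
bernoulli_jsd <- function(p, q) {
  if (is.na(p) || is.na(q)) return(NA_real_)
  m <- (p + q) / 2
  h <- function(x) {
    x <- c(x, 1 - x)
    x <- x[x > 0]
    -sum(x * log2(x))
  }
  h(m) - (h(p) + h(q)) / 2
}

#' Write a simulated event table to TSV
#'
#' @param tab a MISO-like or DiffSplice-like data frame from
#'   [simulate_event_tables()].
#' @param path output path.
#' @export
write_event_table <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
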