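# End-to-end orchestration: simulate -> catalog -> features -> splicing
# maps -> NMD flags -> summary report, with deterministic outputs.

#' Pipeline configuration
#'
#' Bundles the simulation block and every analysis threshold. All printed
#' thresholds have the conventional defaults: delta-Psi 0.1, evidence score
#' 5, read filters 10/10/20, expression coverage 10, fold change 1.5, 100
#' randomisations for z-scores, 100-nt border windows.
#'
#' @param sim a [sim_config()] simulation block.
#' @param delta_psi_min,score_min,min_inc,min_skip,min_total event filters.
#' @param coverage_min expression-filter threshold.
#' @param fc_min AS-NMD fold-change threshold.
#' @param n_shuffles z-score randomisations.
#' @param map_width splicing-map border window (nt).
#' @param n_ctr,n_ctr_con control-set sizes.
#' @param compute_zscores whether per-event motif z-scores are computed
#'   (the slowest step; off by default).
#' @param out_dir output directory (`NULL` for no file output).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            delta_psi_min = 0.1, score_min = 5,
                            min_inc = 10, min_skip = 10, min_total = 20,
                            coverage_min = 10, fc_min = 1.5,
                            n_shuffles = 100, map_width = 100L,
                            n_ctr = 100, n_ctr_con = 100,
                            compute_zscores = FALSE,
                            out_dir = NULL) {
  cfg <- as.list(environment())
  validate_sim_config(cfg$sim)
  thr <- c("delta_psi_min", "score_min", "min_inc", "min_skip", "min_total",
           "coverage_min", "fc_min", "n_shuffles", "map_width")
  if (any(unlist(cfg[thr]) <= 0)) {
    stop("all thresholds must be positive", call. = FALSE)
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline on simulated data
#'
#' Simulates annotation, genome, event tables, coverage tracks and gene
#' counts from the configured generator, then applies the whole analysis:
#' MISO-dialect filtering and replicate intersection, union with the
#' DiffSplice-dialect calls, direction/annotation classification, control
#' sets, the expression filter, per-event sequence features with group
#' comparisons, exon and intron RNA splicing maps, PTC/AS-NMD flags, and a
#' category summary. A log records every filter predicate applied and the
#' seed. When `out_dir` is set, result tables are written as TSV; on
#' failure partial outputs are removed.
#'
#' @param config a [pipeline_config()].
#' @return a report bundle (list): `classified`, `audit`, `controls`,
#'   `expressed_genes`, `features`, `group_tests`, `exon_map`,
#'   `intron_map`, `nmd`, `summary`, `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    started <- list.files(config$out_dir, full.names = TRUE)
    on.exit({
      if (!isTRUE(get0(".pipeline_done", envir = environment()))) {
        new_files <- setdiff(list.files(config$out_dir, full.names = TRUE),
                             started)
        unlink(new_files)
      }
    })
  }
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))
  say("seed = %d", config$sim$seed)

  sim <- generate_annotation(config$sim)
  ann <- sim$annotation; genome <- sim$genome
  tabs <- simulate_event_tables(ann, config$sim)
  cov <- simulate_coverage(ann, config$sim)
  counts <- simulate_expression_counts(ann, config$sim,
                                       expression = cov$expression)

  say("MISO filter: |delta_psi| > %g AND score > %g AND skip_reads > %g AND inc_reads > %g AND inc+skip > %g (all strict)",
      config$delta_psi_min, config$score_min, config$min_skip,
      config$min_inc, config$min_total)
  miso_filt <- lapply(tabs$miso, function(tab) {
    ev <- standardize_miso(tab)
    filter_miso_events(ev, config$delta_psi_min, config$score_min,
                       config$min_inc, config$min_skip, config$min_total)
  })
  miso_int <- Reduce(intersect_replicates, miso_filt)
  say("MISO replicate intersection: %d rows", nrow(miso_int))
  ds <- filter_diffsplice_events(standardize_diffsplice(tabs$diffsplice),
                                 config$delta_psi_min)
  say("DiffSplice filter: |delta_psi| > %g (strict): %d rows",
      config$delta_psi_min, nrow(ds))
  merged <- merge_catalogs(miso_int, ds)
  say("merged catalog: %d rows, %d discordant",
      nrow(merged$events), nrow(merged$discordant))
  cls <- classify_events(merged$events, ann, config$delta_psi_min)
  say("classified: %d events categorised, %d audited",
      nrow(cls$events), nrow(cls$audit))

  say("expression filter: coverage = read_length * reads / tx_length >= %g (inclusive) in control and >= 1 KD",
      config$coverage_min)
  expressed <- expression_filter(counts, config$coverage_min)
  all_miso <- standardize_miso(tabs$miso[[1]])
  controls <- build_controls(all_miso, ann, n_ctr = config$n_ctr,
                             n_ctr_con = config$n_ctr_con,
                             seed = config$sim$seed,
                             expressed_genes = as.character(expressed))
  say("controls: Ctr = %d, CtrCON = %d", nrow(controls$ctr),
      nrow(controls$ctr_con))

  # features over categorised events + controls
  motif_sets <- bundled_motif_sets()
  donor <- train_site_model(sample_training_sites(donor_pwm(), 2000,
                                                  config$sim$seed),
                            "donor")
  acceptor <- train_site_model(sample_training_sites(acceptor_pwm(), 2000,
                                                     config$sim$seed),
                               "acceptor")
  groups <- list()
  if (nrow(cls$events)) {
    for (d in unique(cls$events$direction)) {
      groups[[d]] <- cls$events[cls$events$direction == d, , drop = FALSE]
    }
  }
  groups[["Ctr"]] <- controls$ctr
  groups[["CtrCON"]] <- controls$ctr_con
  groups <- groups[vapply(groups, nrow, 0L) > 0]
  feats <- lapply(names(groups), function(g) {
    f <- compute_event_features(
      groups[[g]], genome, donor, acceptor, motif_sets,
      zscore_sets = if (config$compute_zscores) "ESE" else NULL,
      n_shuffles = config$n_shuffles, seed = config$sim$seed)
    f$group <- g
    f
  })
  common <- Reduce(intersect, lapply(feats, names))
  features <- do.call(rbind, lapply(feats, `[`, common))
  feature_cols <- intersect(
    c("up_intron_len", "dn_intron_len", "ca_exon_len",
      "ca_acceptor_score", "ca_donor_score",
      paste0("freq_", names(motif_sets), "_ca"),
      paste0("freq_", names(motif_sets), "_up_intron"),
      paste0("freq_", names(motif_sets), "_dn_intron")),
    names(features))
  group_tests <- feature_group_tests(features, feature_cols,
                                     reference = "Ctr")

  say("splicing maps: %d-nt border windows, mRNA-masked normalisation",
      config$map_width)
  exon_map <- suppressWarnings(
    build_map(groups, cov$clip, cov$mrna, width = config$map_width))
  intron_map <- suppressWarnings(
    build_intron_map(groups, cov$clip, cov$mrna, width = config$map_width))

  # NMD: PTC status of both isoforms of each categorised event
  nmd <- NULL
  if (nrow(cls$events)) {
    ptc <- do.call(rbind, lapply(seq_len(nrow(cls$events)), function(i) {
      orfs <- derive_isoform_orfs(cls$events[i, ], ann, genome)
      if (is.null(orfs)) {
        return(data.frame(event_id = cls$events$event_id[i],
                          ptc_inclusion = NA, ptc_skipping = NA))
      }
      data.frame(event_id = cls$events$event_id[i],
                 ptc_inclusion = find_ptc(orfs$inclusion)$is_ptc,
                 ptc_skipping = find_ptc(orfs$skipping)$is_ptc)
    }))
    ptc$ptc_inclusion[is.na(ptc$ptc_inclusion)] <- FALSE
    ptc$ptc_skipping[is.na(ptc$ptc_skipping)] <- FALSE
    say("AS-NMD flag: PTC-bearing AND fold change > %g (strict) in >= 1 EJC contrast",
        config$fc_min)
    nmd <- asnmd_candidates(cls$events, ptc, fold_changes(counts),
                            config$fc_min)
  }

  summary <- summarize_categories(cls$events)
  report <- list(classified = cls$events, audit = cls$audit,
                 discordant = merged$discordant, controls = controls,
                 expressed_genes = as.character(expressed),
                 features = features, group_tests = group_tests,
                 exon_map = exon_map, intron_map = intron_map,
                 nmd = nmd, summary = summary, log = log)
  if (!is.null(config$out_dir)) {
    write_report(report, config$out_dir)
  }
  assign(".pipeline_done", TRUE, envir = environment())
  report
}

sample_training_sites <- function(pwm, n, seed) {
  with_seed(seed + 4L, sample_sites(pwm, n))
}

# Map the raw simulated dialect tables onto the standardised event columns.
standardize_miso <- function(tab) {
  ev <- data.frame(
    event_id = tab$event_id, gene_id = tab$gene_id,
    tab[c("chrom", "strand", "up_start", "up_end", "ca_start", "ca_end",
          "dn_start", "dn_end", "contrast")],
    psi_control = tab$psi1, psi_kd = tab$psi2, delta_psi = tab$diff,
    score = tab$bayes_factor, inc_reads = tab$inc_reads,
    skip_reads = tab$skip_reads, source = "MISO",
    stringsAsFactors = FALSE)
  class(ev) <- c("cassette_events", "data.frame")
  ev
}

standardize_diffsplice <- function(tab) {
  ev <- data.frame(
    event_id = tab$asm_id, gene_id = tab$gene_id,
    tab[c("chrom", "strand", "up_start", "up_end", "ca_start", "ca_end",
          "dn_start", "dn_end", "contrast")],
    psi_control = tab$psi_control, psi_kd = tab$psi_kd,
    delta_psi = tab$psi_control - tab$psi_kd, score = tab$jsd,
    inc_reads = NA_real_, skip_reads = NA_real_, source = "DiffSplice",
    stringsAsFactors = FALSE)
  class(ev) <- c("cassette_events", "data.frame")
  ev
}

write_report <- function(report, out_dir) {
  wt <- function(x, name) {
    if (is.null(x) || (is.data.frame(x) && nrow(x) == 0)) return(invisible())
    write.table(x, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  wt(report$classified, "classified_events.tsv")
  wt(report$audit, "audit.tsv")
  wt(report$discordant, "discordant.tsv")
  wt(report$controls$ctr, "controls_ctr.tsv")
  wt(report$controls$ctr_con, "controls_ctr_con.tsv")
  wt(report$features, "features.tsv")
  wt(report$group_tests, "group_tests.tsv")
  wt(report$exon_map, "splicing_map_exon.tsv")
  wt(report$intron_map, "splicing_map_intron.tsv")
  wt(report$nmd, "nmd_flags.tsv")
  wt(report$summary, "summary.tsv")
  writeLines(report$log, file.path(out_dir, "pipeline.log"))
  writeLines(report$expressed_genes, file.path(out_dir,
                                               "expressed_genes.txt"))
  invisible(out_dir)
}

#' Summarise categorised events
#'
#' Counts and percentages per direction and per direction-by-annotation
#' category; percentages over direction classes sum to 100.
#'
#' @param classified categorised events (with `direction`, `anno_class`).
#' @return data frame `direction`, `anno_class`, `count`, `pct` (of all
#'   categorised events; `NaN` sentinel when the input is empty).
#' @export
summarize_categories <- function(classified) {
  if (is.null(classified) || nrow(classified) == 0) {
    return(data.frame(direction = character(), anno_class = character(),
                      count = integer(), pct = numeric(),
                      stringsAsFactors = FALSE))
  }
  tab <- as.data.frame(table(direction = classified$direction,
                             anno_class = classified$anno_class),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "count"
  tab$pct <- 100 * tab$count / nrow(classified)
  tab[order(tab$direction, tab$anno_class), ]
}
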