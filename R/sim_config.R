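#' Simulation configuration
#'
#' Builds the configuration object driving the synthetic-data generator.
#' Defaults emulate the statistical structure of a HeLa knockdown
#' mRNA-seq splicing study: multi-exon genes with cassette exons, binomially
#' sampled inclusion/skipping reads at a set true inclusion level (Psi) per
#' condition, CLIP coverage with a canonical peak 24 nt upstream of each
#' exon's 3' end, and sequences carrying donor/acceptor splice-site motifs.
#'
#' @param n_genes number of genes to simulate.
#' @param exon_len_meanlog,exon_len_sdlog lognormal parameters for exon
#'   length (nt); lengths are rounded and floored at `exon_len_min`.
#' @param intron_len_meanlog,intron_len_sdlog,intron_len_min as above, for
#'   intron length (nt). The default median of 1.5 kb is typical of human
#'   introns.
#' @param n_exons_lambda exon count per gene is `3 + rpois(n_exons_lambda)`,
#'   so every gene has at least three exons.
#' @param cassette_fraction probability that an internal exon is flagged as
#'   an alternative (cassette) exon.
#' @param psi_control true inclusion level (Psi) of cassette exons in the
#'   control condition.
#' @param affected_fraction fraction of cassette events that truly change
#'   upon EJC knockdown.
#' @param skipping_bias among affected events, fraction with increased
#'   skipping in the knockdown (positive delta-Psi); default 0.65 matches
#'   the skew observed for EJC-dependent exons.
#' @param delta_psi magnitude of the planted true change in Psi.
#' @param read_depth expected informative reads per event, per condition and
#'   replicate.
#' @param n_replicates replicates per condition.
#' @param read_length read length in nt used by the expression filter.
#' @param expression_meanlog,expression_sdlog lognormal parameters of mean
#'   per-base mRNA coverage per gene.
#' @param intron_expression_fraction intron (pre-mRNA) coverage relative to
#'   the gene's exonic level; keeps intron positions normalisable.
#' @param clip_peak_offset signed position of the planted CLIP peak relative
#'   to each exon's 3' border (default -24 nt, the canonical EJC site).
#' @param clip_peak_height,clip_background CLIP peak height and flat
#'   background, in coverage units.
#' @param clip_peak_sd Gaussian width (nt) of the planted CLIP peak.
#' @param clip_intron_peak_offset optional signed offset of an additional
#'   intronic CLIP peak relative to each intron's 5' end; `NULL` for none.
#' @param motif_plant_density motifs planted per nt when sequences are
#'   seeded with regulatory elements (0 disables planting).
#' @param seed integer seed; a fixed seed yields byte-identical outputs.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 100,
                       exon_len_meanlog = log(150), exon_len_sdlog = 0.4,
                       exon_len_min = 30,
                       intron_len_meanlog = log(1500), intron_len_sdlog = 1.0,
                       intron_len_min = 60,
                       n_exons_lambda = 5,
                       cassette_fraction = 0.2,
                       psi_control = 0.85,
                       affected_fraction = 0.3,
                       skipping_bias = 0.65,
                       delta_psi = 0.3,
                       read_depth = 100,
                       n_replicates = 2,
                       read_length = 51,
                       expression_meanlog = log(20), expression_sdlog = 0.7,
                       intron_expression_fraction = 0.1,
                       clip_peak_offset = -24,
                       clip_peak_height = 20,
                       clip_background = 1,
                       clip_peak_sd = 1,
                       clip_intron_peak_offset = NULL,
                       motif_plant_density = 0,
                       seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_genes < 1) stop("n_genes must be >= 1", call. = FALSE)
  for (f in c("exon_len_sdlog", "intron_len_sdlog")) {
    if (cfg[[f]] < 0) stop(f, " must be non-negative", call. = FALSE)
  }
  if (cfg$exon_len_min < 1 || cfg$intron_len_min < 1) {
    stop("minimum exon/intron lengths must be >= 1 nt", call. = FALSE)
  }
  psis <- c(cfg$psi_control,
            cfg$psi_control - cfg$delta_psi,
            cfg$psi_control + cfg$delta_psi * 0)
  if (any(c(cfg$psi_control, cfg$cassette_fraction, cfg$affected_fraction,
            cfg$skipping_bias) < 0) ||
      any(c(cfg$psi_control, cfg$cassette_fraction, cfg$affected_fraction,
            cfg$skipping_bias) > 1)) {
    stop("fractions and Psi values must lie in [0, 1]", call. = FALSE)
  }
  if (any(psis < 0 | psis > 1)) {
    stop("psi_control and delta_psi imply a true Psi outside [0, 1]",
         call. = FALSE)
  }
  if (cfg$motif_plant_density < 0) stop("motif_plant_density must be >= 0",
                                        call. = FALSE)
  if (cfg$read_depth <= 0) stop("read_depth must be positive", call. = FALSE)
  invisible(cfg)
}

#' Read or write a simulation configuration as YAML
#'
#' @param path file path.
#' @param cfg a `sim_config` object.
#' @return `read_sim_config()` returns a validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$clip_intron_peak_offset) &&
      length(raw$clip_intron_peak_offset) == 0) {
    raw$clip_intron_peak_offset <- NULL
  }
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(cfg, path) {
  validate_sim_config(cfg)
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
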