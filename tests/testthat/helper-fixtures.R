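# Shared fixtures: compact simulation configs (short introns keep the test
# genomes small) and a hand-built three-exon annotation used by the
# coordinate-level checks.

small_sim_config <- function(...) {
  args <- list(...)
  defaults <- list(n_genes = 20, intron_len_meanlog = log(300),
                   intron_len_sdlog = 0.5, seed = 42)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# One plus-strand and one minus-strand gene, three exons each, with a
# 30-nt cassette exon; coordinates chosen by hand so every expected
# position can be computed on paper.
toy_annotation <- function() {
  genes <- data.frame(
    gene_id = c("GP", "GM"), chrom = "chrT", strand = c("+", "-"),
    start = c(100L, 2000L), end = c(1000L, 2900L), n_exons = 3L,
    stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = rep(c("GP", "GM"), each = 3),
    transcript_id = rep(c("GP.T1", "GM.T1"), each = 3),
    chrom = "chrT",
    strand = rep(c("+", "-"), each = 3),
    start = c(100L, 400L, 700L, 2000L, 2400L, 2700L),
    end = c(250L, 430L, 1000L, 2250L, 2430L, 2900L),
    exon_rank = c(1L, 2L, 3L, 3L, 2L, 1L),
    alternative = c(FALSE, TRUE, FALSE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  events <- data.frame(
    event_id = c("EVP", "EVM"), gene_id = c("GP", "GM"), chrom = "chrT",
    strand = c("+", "-"),
    up_start = c(100L, 2700L), up_end = c(250L, 2900L),
    ca_start = c(400L, 2400L), ca_end = c(430L, 2430L),
    dn_start = c(700L, 2000L), dn_end = c(1000L, 2250L),
    psi_control = 0.8, psi_eIF4A3 = 0.5, psi_Y14 = 0.5, psi_MLN51 = 0.5,
    psi_Upf1 = 0.8, true_affected = TRUE, true_direction = "+",
    stringsAsFactors = FALSE)
  structure(list(genes = genes, exons = exons, events = events,
                 seqlengths = c(chrT = 3500)),
            class = "genome_annotation")
}

# Build a standardised cassette-event row block programmatically.
make_events <- function(n, contrast = "eIF4A3", delta = 0.3, psi0 = 0.8,
                        score = 10, inc = 50, skip = 50, chrom = "chrS1",
                        strand = "+", start0 = 1000L, source = "MISO") {
  starts <- start0 + (seq_len(n) - 1L) * 1000L
  ev <- data.frame(
    event_id = sprintf("T%04d", seq_len(n)), gene_id = sprintf("G%04d", seq_len(n)),
    chrom = chrom, strand = strand,
    up_start = starts - 300L, up_end = starts - 200L,
    ca_start = starts, ca_end = starts + 100L,
    dn_start = starts + 300L, dn_end = starts + 400L,
    contrast = contrast, psi_control = psi0, psi_kd = psi0 - delta,
    delta_psi = delta, score = score, inc_reads = inc, skip_reads = skip,
    source = source, stringsAsFactors = FALSE)
  class(ev) <- c("cassette_events", "data.frame")
  ev
}
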