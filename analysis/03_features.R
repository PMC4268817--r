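#!/usr/bin/env Rscript
# Sequence features of categorised events vs controls: flanking intron
# lengths, donor/acceptor splice-site strengths, and SRE frequencies, with
# Mann-Whitney group comparisons (raw and BH-adjusted p-values), plus the
# intron-length vs expression-change correlation.

suppressPackageStartupMessages(library(ejcsplice))

sim_dir <- "results/sim"; cat_dir <- "results/catalog"
out <- "results/features"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

genome <- read_genome_fasta(file.path(sim_dir, "genome.fa"))
classified <- read.delim(file.path(cat_dir, "classified_events.tsv"))
ctr <- read.delim(file.path(cat_dir, "controls_ctr.tsv"))
ctr_con <- read.delim(file.path(cat_dir, "controls_ctr_con.tsv"))

# trainable position models stand in the scoring role of published
# maximum-entropy tables; trained on sites sampled from the reference models
donor <- train_site_model(
  ejcsplice:::with_seed(11, ejcsplice:::sample_sites(donor_pwm(), 5000)),
  "donor")
acceptor <- train_site_model(
  ejcsplice:::with_seed(11, ejcsplice:::sample_sites(acceptor_pwm(), 5000)),
  "acceptor")
motifs <- bundled_motif_sets()

groups <- list()
for (d in unique(classified$direction)) {
  groups[[d]] <- classified[classified$direction == d, ]
}
groups[["Ctr"]] <- ctr
groups[["CtrCON"]] <- ctr_con
groups <- groups[vapply(groups, nrow, 0L) > 0]

feats <- lapply(names(groups), function(g) {
  message("features for group ", g, " (", nrow(groups[[g]]), " events)")
  f <- compute_event_features(groups[[g]], genome, donor, acceptor, motifs)
  f$group <- g
  f
})
common <- Reduce(intersect, lapply(feats, names))
features <- do.call(rbind, lapply(feats, `[`, common))

feature_cols <- intersect(
  c("up_intron_len", "dn_intron_len", "ca_exon_len",
    "ca_acceptor_score", "ca_donor_score",
    "freq_ESE_ca", "freq_ESS_ca",
    "freq_ISE_up_intron", "freq_ISE_dn_intron",
    "freq_ISS_up_intron", "freq_ISS_dn_intron"),
  names(features))
tests <- feature_group_tests(features, feature_cols, reference = "Ctr")
print(tests[order(tests$p_value), ][1:10, ])

# intron length vs differential expression, genome-wide: mean intron length
# per gene against its log2 fold change
counts <- read.delim(file.path(sim_dir, "gene_counts.tsv"))
fc <- fold_changes(counts)
fc <- fc[fc$contrast == "eIF4A3" & is.finite(log2(fc$fc)), ]
ann <- read_annotation_gtf(file.path(sim_dir, "annotation.gtf"))
mean_intron <- vapply(split(ann$exons, ann$exons$gene_id), function(ex) {
  ex <- ex[order(ex$start), ]
  mean(ex$start[-1] - ex$end[-nrow(ex)])
}, numeric(1))
m <- match(names(mean_intron), fc$gene_id)
ok <- !is.na(m)
corr <- length_expression_correlation(mean_intron[ok], log2(fc$fc[m[ok]]))
message(sprintf(
  "intron length vs log2 FC (eIF4A3): rho = %.3f, p = %.3f (n = %d)",
  corr$rho, corr$p_value, corr$n))

wt <- function(x, name) write.table(x, file.path(out, name), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
wt(features, "features.tsv")
wt(tests, "group_tests.tsv")
wt(data.frame(rho = corr$rho, p_value = corr$p_value, n = corr$n),
   "length_expression_correlation.tsv")
message("wrote ", out)
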