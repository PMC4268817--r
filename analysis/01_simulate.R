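#!/usr/bin/env Rscript
# Simulate the study inputs: annotation (GTF), genome (FASTA), per-replicate
# MISO-dialect and replicate-aware DiffSplice-dialect event tables (TSV),
# mRNA and CLIP coverage (bedGraph, one file per strand), and per-gene read
# counts (TSV). Everything is seeded; re-running reproduces identical bytes.

suppressPackageStartupMessages(library(ejcsplice))

out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(n_genes = 120, seed = 1)
write_sim_config(cfg, file.path(out, "sim_config.yaml"))

message("generating annotation + genome (", cfg$n_genes, " genes) ...")
sim <- generate_annotation(cfg)
write_annotation_gtf(sim$annotation, file.path(out, "annotation.gtf"))
write_genome_fasta(sim$genome, file.path(out, "genome.fa"))
# ground truth, kept separate from the GTF
write.table(sim$annotation$events, file.path(out, "true_events.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message("simulating event tables ...")
tabs <- simulate_event_tables(sim$annotation, cfg)
for (r in seq_along(tabs$miso)) {
  write_event_table(tabs$miso[[r]],
                    file.path(out, sprintf("miso_rep%d.tsv", r)))
}
write_event_table(tabs$diffsplice, file.path(out, "diffsplice.tsv"))

message("simulating coverage tracks ...")
cov <- simulate_coverage(sim$annotation, cfg)
write_bedgraph(cov$mrna, file.path(out, "mrna"))
write_bedgraph(cov$clip, file.path(out, "clip"))
write.table(cov$expression, file.path(out, "expression_levels.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message("simulating gene counts ...")
counts <- simulate_expression_counts(sim$annotation, cfg,
                                     expression = cov$expression)
write.table(counts, file.path(out, "gene_counts.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

n_ev <- nrow(sim$annotation$events)
message(sprintf(
  "done: %d genes, %d cassette events (%d truly affected, %.0f%% skipping-up)",
  cfg$n_genes, n_ev, sum(sim$annotation$events$true_affected),
  100 * mean(sim$annotation$events$true_direction[
    sim$annotation$events$true_affected] == "+")))
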