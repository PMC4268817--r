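#!/usr/bin/env Rscript
# NMD analysis: classify the inclusion and skipping isoform of every
# categorised event for premature termination codons (50-nt rule) and flag
# AS-NMD candidates (PTC-bearing and upregulated > 1.5-fold in an EJC
# knockdown).

suppressPackageStartupMessages(library(ejcsplice))

sim_dir <- "results/sim"; cat_dir <- "results/catalog"
out <- "results/nmd"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ann <- read_annotation_gtf(file.path(sim_dir, "annotation.gtf"))
genome <- read_genome_fasta(file.path(sim_dir, "genome.fa"))
classified <- read.delim(file.path(cat_dir, "classified_events.tsv"))
counts <- read.delim(file.path(sim_dir, "gene_counts.tsv"))

ptc <- do.call(rbind, lapply(seq_len(nrow(classified)), function(i) {
  orfs <- derive_isoform_orfs(classified[i, ], ann, genome)
  if (is.null(orfs)) {
    return(data.frame(event_id = classified$event_id[i],
                      ptc_inclusion = FALSE, ptc_skipping = FALSE,
                      stringsAsFactors = FALSE))
  }
  data.frame(event_id = classified$event_id[i],
             ptc_inclusion = find_ptc(orfs$inclusion)$is_ptc,
             ptc_skipping = find_ptc(orfs$skipping)$is_ptc,
             stringsAsFactors = FALSE)
}))

flags <- asnmd_candidates(classified, ptc, fold_changes(counts))
n_ptc <- sum(flags$ptc_bearing)
n_cand <- sum(flags$asnmd_status == "candidate")
message(sprintf(
  "%d / %d events PTC-bearing (%.1f%%); %d AS-NMD candidates (%.1f%% of PTC+)",
  n_ptc, nrow(flags), 100 * n_ptc / nrow(flags), n_cand,
  if (n_ptc > 0) 100 * n_cand / n_ptc else 0))

write.table(flags, file.path(out, "nmd_flags.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("wrote ", out)
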