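#!/usr/bin/env Rscript
# Build the event catalog from the simulated tables: apply the five-predicate
# MISO filter per replicate, intersect replicates, take the union with the
# DiffSplice calls, classify by direction and annotation status, build the
# Ctr / CtrCON control sets, and apply the expression filter.

suppressPackageStartupMessages(library(ejcsplice))

sim_dir <- "results/sim"
out <- "results/catalog"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
stopifnot(file.exists(file.path(sim_dir, "annotation.gtf")))

ann <- read_annotation_gtf(file.path(sim_dir, "annotation.gtf"))
miso <- lapply(1:2, function(r) {
  parse_event_table(file.path(sim_dir, sprintf("miso_rep%d.tsv", r)), "miso")
})
ds_raw <- parse_event_table(file.path(sim_dir, "diffsplice.tsv"),
                            "diffsplice")

miso_filt <- lapply(miso, filter_miso_events)
message(sprintf("MISO filter: %d / %d and %d / %d rows retained",
                nrow(miso_filt[[1]]), nrow(miso[[1]]),
                nrow(miso_filt[[2]]), nrow(miso[[2]])))
miso_int <- Reduce(intersect_replicates, miso_filt)
message(sprintf("replicate intersection: %d rows", nrow(miso_int)))

ds <- filter_diffsplice_events(ds_raw)
merged <- merge_catalogs(miso_int, ds)
message(sprintf("merged catalog: %d rows (union), %d discordant",
                nrow(merged$events), nrow(merged$discordant)))

cls <- classify_events(merged$events, ann)
smry <- summarize_categories(cls$events)
print(smry)
message(sprintf("%d events categorised (%0.f%% skipping-up); %d audited",
                nrow(cls$events),
                100 * mean(cls$events$direction == "+"), nrow(cls$audit)))

counts <- read.delim(file.path(sim_dir, "gene_counts.tsv"))
expressed <- expression_filter(counts, threshold = 10)
message(sprintf("expression filter: %d / %d genes at coverage >= 10",
                length(expressed), length(unique(counts$gene_id))))

controls <- build_controls(miso[[1]], ann, n_ctr = 100, n_ctr_con = 100,
                           seed = 1, expressed_genes = as.character(expressed))
message(sprintf("controls: Ctr = %d, CtrCON = %d",
                nrow(controls$ctr), nrow(controls$ctr_con)))

wt <- function(x, name) write.table(x, file.path(out, name), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
wt(cls$events, "classified_events.tsv")
wt(cls$audit, "audit.tsv")
wt(merged$discordant, "discordant.tsv")
wt(smry, "summary.tsv")
wt(controls$ctr, "controls_ctr.tsv")
wt(controls$ctr_con, "controls_ctr_con.tsv")
writeLines(as.character(expressed), file.path(out, "expressed_genes.txt"))
message("wrote ", out)
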