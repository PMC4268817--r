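#!/usr/bin/env Rscript
# Final report: recount every emitted table and print the headline numbers
# of the analysis, verifying that the written TSVs agree with themselves.

suppressPackageStartupMessages(library(ejcsplice))

cat_dir <- "results/catalog"
classified <- read.delim(file.path(cat_dir, "classified_events.tsv"))
smry <- read.delim(file.path(cat_dir, "summary.tsv"))

# internal/external consistency: summary must recount from the event table
stopifnot(sum(smry$count) == nrow(classified))
recount <- summarize_categories(classified)
stopifnot(all(recount$count == smry[order(smry$direction, smry$anno_class),
                                    "count"]))

cat("=== categorised cassette events ===\n")
print(smry)
cat(sprintf("\n%d events; %.0f%% increased skipping, %.0f%% increased inclusion\n",
            nrow(classified), 100 * mean(classified$direction == "+"),
            100 * mean(classified$direction == "-")))

tests <- read.delim("results/features/group_tests.tsv")
sig <- tests[tests$p_adj < 0.05, ]
cat(sprintf("\n=== feature comparisons vs Ctr: %d of %d significant (BH < 0.05) ===\n",
            nrow(sig), nrow(tests)))
if (nrow(sig)) print(sig[order(sig$p_value), c("feature", "group", "p_value",
                                               "p_adj")])

emap <- read.delim("results/splicemap/splicing_map_exon.tsv")
cat("\n=== splicing-map peaks (relative position of profile maximum) ===\n")
for (g in unique(emap$category)) {
  sub <- emap[emap$category == g, ]
  cat(sprintf("  %-6s: %+d nt (max height %.2f, %d positions)\n",
              g, sub$rel_pos[which.max(sub$height)], max(sub$height),
              nrow(sub)))
}

flags <- read.delim("results/nmd/nmd_flags.tsv")
cat(sprintf("\n=== NMD: %d / %d PTC-bearing; %d AS-NMD candidates ===\n",
            sum(flags$ptc_bearing), nrow(flags),
            sum(flags$asnmd_status == "candidate")))
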