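#!/usr/bin/env Rscript
# RNA splicing maps: positional CLIP-binding profiles over 100-nt windows at
# the borders of the upstream, cassette and downstream exons (and the
# flanking introns), per event category, with the expression-masked
# normalisation and global max scaling.

suppressPackageStartupMessages(library(ejcsplice))

sim_dir <- "results/sim"; cat_dir <- "results/catalog"
out <- "results/splicemap"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ann <- read_annotation_gtf(file.path(sim_dir, "annotation.gtf"))
clip <- read_bedgraph(file.path(sim_dir, "clip"), ann$seqlengths)
mrna <- read_bedgraph(file.path(sim_dir, "mrna"), ann$seqlengths)
classified <- read.delim(file.path(cat_dir, "classified_events.tsv"))
ctr <- read.delim(file.path(cat_dir, "controls_ctr.tsv"))
ctr_con <- read.delim(file.path(cat_dir, "controls_ctr_con.tsv"))

groups <- list()
for (d in unique(classified$direction)) {
  groups[[d]] <- classified[classified$direction == d, ]
}
groups[["Ctr"]] <- ctr
groups[["CtrCON"]] <- ctr_con
groups <- groups[vapply(groups, nrow, 0L) > 0]

exon_map <- suppressWarnings(build_map(groups, clip, mrna, width = 100L))
intron_map <- suppressWarnings(build_intron_map(groups, clip, mrna,
                                                width = 100L))
write_profile(exon_map, file.path(out, "splicing_map_exon.tsv"))
write_profile(intron_map, file.path(out, "splicing_map_intron.tsv"))

for (g in unique(exon_map$category)) {
  message(sprintf("category %-6s: profile max %.3f at rel. position %+d nt",
                  g, max(exon_map$height[exon_map$category == g]),
                  profile_argmax(exon_map, g)))
}
message("wrote ", out)
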