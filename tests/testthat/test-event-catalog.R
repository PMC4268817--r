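# Event catalog: parsing, the five-predicate filter, replicate
# intersection, cross-caller merging, classification and control sets.

write_miso_tsv <- function(ev, path) {
  tab <- data.frame(event_id = ev$event_id, gene_id = ev$gene_id,
                    ev[c("chrom", "strand", "up_start", "up_end", "ca_start",
                         "ca_end", "dn_start", "dn_end", "contrast")],
                    psi1 = ev$psi_control, psi2 = ev$psi_kd,
                    diff = ev$delta_psi, bayes_factor = ev$score,
                    inc_reads = ev$inc_reads, skip_reads = ev$skip_reads,
                    stringsAsFactors = FALSE)
  write_event_table(tab, path)
}

test_that("parsing rejects out-of-range Psi with a line diagnostic", {
  ev <- make_events(3)
  ev$psi_control[2] <- 1.2
  ev$delta_psi <- ev$psi_control - ev$psi_kd
  path <- tempfile(fileext = ".tsv")
  write_miso_tsv(ev, path)
  expect_error(parse_event_table(path, "miso"), "line 3.*outside")
})

test_that("an empty table parses to an empty event list", {
  path <- tempfile(fileext = ".tsv")
  writeLines("event_id\tchrom", path)
  expect_equal(nrow(parse_event_table(path, "miso")), 0)
})

test_that("write -> parse round trip preserves the event set", {
  ev <- make_events(8, delta = 0.25)
  path <- tempfile(fileext = ".tsv")
  write_miso_tsv(ev, path)
  back <- parse_event_table(path, "miso")
  expect_equal(back[names(ev)], as.data.frame(ev),
               ignore_attr = TRUE)
})

test_that("the MISO filter equals row-by-row predicate evaluation", {
  # 12 events straddling every threshold, including exact boundaries
  ev <- make_events(12)
  ev$delta_psi <- c(0.3, 0.10, 0.101, -0.3, 0.05, 0.3, 0.3, 0.3, 0.3,
                    -0.15, 0.2, 0.11)
  ev$score <- c(10, 10, 10, 10, 10, 5, 5.01, 10, 10, 6, 4.9, 10)
  ev$inc_reads <- c(50, 50, 50, 50, 50, 50, 50, 10, 11, 50, 50, 50)
  ev$skip_reads <- c(50, 50, 50, 50, 50, 50, 50, 50, 9, 50, 10, 50)
  ev$psi_control <- 0.8; ev$psi_kd <- ev$psi_control - ev$delta_psi
  got <- filter_miso_events(ev)
  # brute-force oracle, evaluated independently per row
  keep <- vapply(seq_len(nrow(ev)), function(i) {
    abs(ev$delta_psi[i]) > 0.1 && ev$score[i] > 5 &&
      ev$skip_reads[i] > 10 && ev$inc_reads[i] > 10 &&
      (ev$inc_reads[i] + ev$skip_reads[i]) > 20
  }, logical(1))
  expect_identical(got$event_id, ev$event_id[keep])
  # boundary semantics are strict
  expect_false("T0002" %in% got$event_id)  # |delta| = 0.10 exactly
  expect_false("T0006" %in% got$event_id)  # score = 5 exactly
  expect_false("T0008" %in% got$event_id)  # inc = 10 exactly
})

test_that("filtering without count columns errors", {
  ev <- make_events(2)
  ev$inc_reads <- NA_real_
  expect_error(filter_miso_events(ev), "counts")
})

test_that("replicate intersection keeps coordinate- and sign-matched events", {
  a <- make_events(6, delta = 0.3)
  b <- make_events(6, delta = 0.3)
  b <- b[c(1, 2, 3), ]                       # drop three from rep2
  b$delta_psi[2] <- -0.3                     # opposite sign
  b$psi_kd[2] <- b$psi_control[2] + 0.3
  got <- intersect_replicates(a, b)
  expect_identical(got$event_id, c("T0001", "T0003"))
  # reported delta is the replicate mean
  a2 <- make_events(1, delta = 0.2); b2 <- make_events(1, delta = 0.4)
  expect_equal(intersect_replicates(a2, b2)$delta_psi, 0.3)
  # disjoint coordinate sets intersect to nothing
  c2 <- make_events(2, start0 = 99000L)
  expect_equal(nrow(intersect_replicates(a, c2)), 0)
  # oracle: set intersection keyed by coordinates + sign
  key <- function(e) paste(e$chrom, e$strand, e$ca_start, e$ca_end,
                           e$contrast, sign(e$delta_psi))
  expect_setequal(key(got), intersect(key(a), key(b)))
})

test_that("merging is a deduplicated union with MISO precedence", {
  miso <- make_events(3, delta = 0.3)
  ds <- make_events(3, delta = 0.2, source = "DiffSplice",
                    start0 = 3000L)          # overlaps T0003 of miso only
  merged <- merge_catalogs(miso, ds)
  expect_equal(nrow(merged$events), 5)       # 3 + 3 - 1 shared
  shared <- merged$events[merged$events$ca_start == 3000L, ]
  expect_equal(shared$source, "both")
  expect_equal(shared$delta_psi, 0.3)        # MISO value kept
  # empty DiffSplice input returns the MISO intersection unchanged
  e <- merge_catalogs(miso, miso[0, ])
  expect_equal(e$events$event_id, miso$event_id)
  # union size bound and commutativity up to source labels
  key <- function(x) paste(x$chrom, x$strand, x$ca_start, x$ca_end)
  m2 <- merge_catalogs(ds, miso)
  expect_setequal(key(merged$events), key(m2$events))
  expect_lte(nrow(merged$events), nrow(miso) + nrow(ds))
})

test_that("coordinate-equal events with opposite signs are discordant", {
  miso <- make_events(2, delta = 0.3)
  ds <- make_events(2, delta = -0.3, source = "DiffSplice")
  ds$psi_kd <- ds$psi_control + 0.3
  merged <- merge_catalogs(miso, ds)
  expect_equal(nrow(merged$events), 0)
  expect_equal(nrow(merged$discordant), 4)
})

test_that("classification matches exhaustive enumeration on a known annotation", {
  sim <- generate_annotation(small_sim_config(n_genes = 30, seed = 21))
  ann <- sim$annotation
  ev_truth <- ann$events
  # build per-contrast rows straight from the ground truth
  rows <- list()
  for (cc in c("eIF4A3", "Y14", "MLN51")) {
    e <- ev_truth
    e$contrast <- cc
    e$psi_kd <- e[[paste0("psi_", cc)]]
    e$delta_psi <- e$psi_control - e$psi_kd
    e$score <- 10; e$inc_reads <- e$skip_reads <- 50; e$source <- "MISO"
    rows[[cc]] <- e[c("event_id", "gene_id", "chrom", "strand", "up_start",
                      "up_end", "ca_start", "ca_end", "dn_start", "dn_end",
                      "contrast", "psi_control", "psi_kd", "delta_psi",
                      "score", "inc_reads", "skip_reads", "source")]
  }
  merged <- do.call(rbind, rows)
  cls <- classify_events(merged, ann)
  # enumeration oracle: per event, direction from the true Psi change and
  # eligibility from the annotation flags
  ex <- ann$exons
  exid <- paste(ex$chrom, ex$strand, ex$start, ex$end)
  expected <- list()
  for (i in seq_len(nrow(ev_truth))) {
    e <- ev_truth[i, ]
    d <- e$psi_control - e$psi_eIF4A3
    dir <- if (d > 0.1) "+" else if (d < -0.1) "-" else "none"
    if (dir == "none") next
    fl <- match(paste(e$chrom, e$strand, c(e$up_start, e$dn_start),
                      c(e$up_end, e$dn_end)), exid)
    if (any(ex$alternative[fl])) next
    ca <- match(paste(e$chrom, e$strand, e$ca_start, e$ca_end), exid)
    expected[[length(expected) + 1L]] <-
      paste(e$event_id, dir, if (ex$alternative[ca]) "ALT" else "CON")
  }
  got <- paste(cls$events$event_id, cls$events$direction,
               cls$events$anno_class)
  expect_setequal(got, unlist(expected))
})

test_that("direction thresholds are strict and ALT/CON follow the annotation", {
  ann <- toy_annotation()
  ev <- ann$events
  ev$contrast <- "eIF4A3"; ev$psi_kd <- 0.55
  ev$delta_psi <- c(0.25, 0.10)  # second sits exactly at the threshold
  ev$psi_control <- c(0.8, 0.65)
  ev$score <- 10; ev$inc_reads <- ev$skip_reads <- 50; ev$source <- "MISO"
  cls <- classify_events(ev, ann)
  expect_equal(nrow(cls$events), 1)
  expect_equal(cls$events$direction, "+")
  expect_equal(cls$events$anno_class, "ALT")  # cassette annotated alternative
})

test_that("events absent from the annotation are excluded with an audit record", {
  ann <- toy_annotation()
  ev <- ann$events[1, ]
  ev$ca_start <- 401L  # no such exon
  ev$contrast <- "eIF4A3"; ev$psi_control <- 0.8; ev$psi_kd <- 0.5
  ev$delta_psi <- 0.3; ev$score <- 10
  ev$inc_reads <- ev$skip_reads <- 50; ev$source <- "MISO"
  cls <- classify_events(ev, ann)
  expect_equal(nrow(cls$events), 0)
  expect_equal(cls$audit$reason, "cassette_not_in_annotation")
})

test_that("control sets satisfy their defining predicates", {
  sim <- generate_annotation(small_sim_config(n_genes = 40, seed = 30,
                                              affected_fraction = 0))
  ann <- sim$annotation
  ev <- ann$events
  rows <- lapply(c("eIF4A3", "Y14", "MLN51"), function(cc) {
    e <- ev
    e$contrast <- cc
    e$psi_control <- 0.5; e$psi_kd <- 0.51
    e$delta_psi <- -0.01
    e$score <- 1; e$inc_reads <- e$skip_reads <- 50; e$source <- "MISO"
    e[c("event_id", "gene_id", "chrom", "strand", "up_start", "up_end",
        "ca_start", "ca_end", "dn_start", "dn_end", "contrast",
        "psi_control", "psi_kd", "delta_psi", "score", "inc_reads",
        "skip_reads", "source")]
  })
  all_ev <- do.call(rbind, rows)
  # a Psi = 0.95 event is outside the open interval and ineligible
  all_ev$psi_control[all_ev$event_id == all_ev$event_id[1]] <- 0.95
  ctrl <- build_controls(all_ev, ann, n_ctr = 10, n_ctr_con = 10, seed = 5)
  expect_false(all_ev$event_id[1] %in% ctrl$ctr$event_id)
  expect_lte(nrow(ctrl$ctr), 10)
  expect_true(all(abs(ctrl$ctr$delta_psi) < 0.03))
  expect_true(all(ctrl$ctr$psi_control > 0.1 & ctrl$ctr$psi_control < 0.9))
  # reproducible under a fixed seed
  ctrl2 <- build_controls(all_ev, ann, n_ctr = 10, n_ctr_con = 10, seed = 5)
  expect_identical(ctrl$ctr$event_id, ctrl2$ctr$event_id)
  expect_identical(ctrl$ctr_con, ctrl2$ctr_con)
  # CtrCON triplets: internal, constitutive, at most one per gene
  expect_lte(max(table(ctrl$ctr_con$gene_id)), 1)
  ex <- ann$exons
  exid <- paste(ex$chrom, ex$strand, ex$start, ex$end)
  for (i in seq_len(nrow(ctrl$ctr_con))) {
    t <- ctrl$ctr_con[i, ]
    idx <- match(paste(t$chrom, t$strand,
                       c(t$up_start, t$ca_start, t$dn_start),
                       c(t$up_end, t$ca_end, t$dn_end)), exid)
    expect_false(any(ex$alternative[idx]))
    ranks <- sort(ex$exon_rank[idx])
    expect_equal(diff(ranks), c(1L, 1L))           # successive
    n_ex <- max(ex$exon_rank[ex$gene_id == t$gene_id])
    expect_true(min(ranks) >= 2 && max(ranks) <= n_ex - 1)  # internal
  }
})

test_that("a five-exon gene yields exactly the middle triplet", {
  genes <- data.frame(gene_id = "G5", chrom = "c", strand = "+",
                      start = 0L, end = 900L, n_exons = 5L,
                      stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = "G5", transcript_id = "G5.T1", chrom = "c",
                      strand = "+", start = seq(0L, 800L, 200L),
                      end = seq(0L, 800L, 200L) + 100L, exon_rank = 1:5,
                      alternative = FALSE, stringsAsFactors = FALSE)
  ann <- structure(list(genes = genes, exons = exons,
                        events = NULL, seqlengths = c(c = 1000)),
                   class = "genome_annotation")
  empty <- make_events(1)[0, ]
  ctrl <- suppressWarnings(
    build_controls(empty, ann, n_ctr = 0, n_ctr_con = 5, seed = 1))
  expect_equal(nrow(ctrl$ctr_con), 1)
  expect_equal(ctrl$ctr_con$ca_start, 400L)  # exon 3 is the middle slot
  expect_equal(ctrl$ctr_con$up_start, 200L)
  expect_equal(ctrl$ctr_con$dn_start, 600L)
})

test_that("the expression filter implements coverage = R*N/L inclusively", {
  rec <- data.frame(
    gene_id = rep(c("A", "B", "C"), each = 2),
    condition = rep(c("control", "eIF4A3"), 3),
    reads = c(200, 200,   0, 0,   200, 5),
    tx_length = 1020, stringsAsFactors = FALSE)
  genes <- expression_filter(rec, threshold = 10, read_length = 51)
  cov <- attr(genes, "coverage")
  # worked arithmetic: 51 * 200 / 1020 = 10.0 exactly, retained inclusively
  expect_equal(cov$coverage[cov$gene_id == "A"][1], 10.0)
  expect_true("A" %in% genes)
  expect_false("B" %in% genes)  # zero reads, coverage 0
  expect_false("C" %in% genes)  # expressed in control only
  bad <- rec; bad$tx_length <- 0
  expect_error(expression_filter(bad), "positive")
})

test_that("fold changes are normalised-count ratios", {
  rec <- data.frame(
    gene_id = rep(c("A", "B"), each = 3),
    condition = rep(c("control", "eIF4A3", "Upf1"), 2),
    reads = c(100, 300, 100, 100, 100, 100),
    tx_length = 1000, stringsAsFactors = FALSE)
  fc <- fold_changes(rec)
  # totals: control 200, eIF4A3 400, Upf1 200
  expect_equal(fc$fc[fc$gene_id == "A" & fc$contrast == "eIF4A3"],
               (300 / 400) / (100 / 200))
  expect_equal(fc$fc[fc$gene_id == "B" & fc$contrast == "Upf1"], 1)
})

test_that("intron-retention events parse, validate and classify by direction", {
  ir <- data.frame(
    event_id = c("IR1", "IR2", "IR3"), gene_id = "G", chrom = "c",
    strand = "+", intron_start = 100L, intron_end = 300L,
    up_start = 0L, up_end = 100L, dn_start = 300L, dn_end = 400L,
    contrast = "eIF4A3", psi1 = c(0.5, 0.2, 0.4),
    psi2 = c(0.2, 0.5, 0.45), diff = c(0.3, -0.3, -0.05),
    bayes_factor = 10, inc_reads = 50, skip_reads = 50,
    stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".tsv")
  write_event_table(ir, path)
  ev <- parse_event_table(path, "miso", type = "intron")
  expect_s3_class(ev, "intron_events")
  # IR1/IR2/IR3 share coordinates, so classification sees one event with
  # conflicting directions -> audit; separate the coordinates instead
  ev$intron_start <- c(100L, 1100L, 2100L)
  ev$intron_end <- c(300L, 1300L, 2300L)
  ev$up_start <- ev$intron_start - 100L; ev$up_end <- ev$intron_start
  ev$dn_start <- ev$intron_end; ev$dn_end <- ev$intron_end + 100L
  cls <- classify_intron_events(ev)
  got <- setNames(cls$events$category, cls$events$event_id)
  expect_equal(got[["IR1"]], "retention-down")   # intron level drops in KD
  expect_equal(got[["IR2"]], "retention-up")
  expect_false("IR3" %in% names(got))            # |delta| below threshold
  # flanks must abut the intron
  bad <- ir; bad$up_end <- 99L
  write_event_table(bad, path)
  expect_error(parse_event_table(path, "miso", type = "intron"), "abut")
})
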