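# Sequence features: flank lengths, splice-site models and scoring, SRE
# frequencies and permutation z-scores, and the group statistics.

test_that("flanking intron lengths are strand-aware coordinate gaps", {
  ev <- data.frame(chrom = "c", strand = c("+", "-"),
                   up_start = c(100L, 500L), up_end = c(200L, 600L),
                   ca_start = c(500L, 100L), ca_end = c(600L, 200L),
                   dn_start = c(800L, 0L), dn_end = c(900L, 50L),
                   stringsAsFactors = FALSE)
  got <- flank_lengths(ev)
  # plus strand: exons at [100,200) and [500,600) leave a 300-nt intron
  expect_equal(got$up_intron_len[1], 300)
  expect_equal(got$dn_intron_len[1], 200)
  # same coordinates seen from the minus strand flip the labels
  expect_equal(got$up_intron_len[2], 300)
  expect_equal(got$dn_intron_len[2], 50)
  expect_true(all(got$valid))
  # abutting exons are invalid
  ab <- ev[1, ]; ab$up_end <- 500L
  expect_false(flank_lengths(ab)$valid)
})

test_that("site-model training recovers per-position probabilities", {
  # all-identical training set with zero pseudocount gives probability 1
  m <- train_site_model(rep("CAGGTAAGT", 5), "donor", pseudocount = 0)
  expect_equal(unname(m$probs["G", 4]), 1)
  expect_equal(unname(m$probs["A", 4]), 0)
  # sampling-recovery oracle: 10,000 draws from a known model
  pwm <- donor_pwm()
  seqs <- ejcsplice:::with_seed(99, ejcsplice:::sample_sites(pwm, 10000))
  fit <- train_site_model(seqs, "donor", pseudocount = 0.5)
  expect_lt(max(abs(fit$probs - pwm)), 0.02)
  # contract violations
  expect_error(train_site_model(character(0), "donor"), "no training")
  expect_error(train_site_model("CAGGTAAG", "donor"), "9 nt")
  expect_error(train_site_model(rep("CAGGTAANT", 3), "donor"), "non-ACGT")
})

test_that("scoring is log2 odds against the background", {
  # model equal to its background scores 0 for any sequence
  bg <- ejcsplice:::background_site_model("donor")
  expect_equal(score_site("ACGTACGTA", bg), 0, tolerance = 1e-12)
  expect_equal(score_site("GGGGGGGGG", bg), 0, tolerance = 1e-12)
  # toy model with two informative positions: 2 * log2(0.8 / 0.25)
  probs <- matrix(0.25, 4, 9, dimnames = list(c("A", "C", "G", "T"), NULL))
  probs[, 1] <- c(0.8, 0.2 / 3, 0.2 / 3, 0.2 / 3)
  probs[, 2] <- c(0.8, 0.2 / 3, 0.2 / 3, 0.2 / 3)
  m <- structure(list(site_type = "donor", length = 9L, probs = probs,
                      background = setNames(rep(0.25, 4),
                                            c("A", "C", "G", "T")),
                      kind = "position"),
                 class = "splice_site_model")
  expect_equal(score_site("AACGTACGT", m), 2 * log2(0.8 / 0.25),
               tolerance = 1e-9)
  # a 9-mer model rejects an 8-nt input
  expect_error(score_site("ACGTACGT", m), "9-mer")
})

test_that("position scores are additive and column-permutation invariant", {
  pwm <- donor_pwm()
  m <- structure(list(site_type = "donor", length = 9L, probs = pwm,
                      background = setNames(rep(0.25, 4),
                                            c("A", "C", "G", "T")),
                      kind = "position"),
                 class = "splice_site_model")
  s <- "CAGGTAAGT"
  per_pos <- vapply(1:9, function(j) {
    b <- substr(s, j, j)
    log2(pwm[b, j] / 0.25)
  }, numeric(1))
  expect_equal(score_site(s, m), sum(per_pos), tolerance = 1e-9)
  # swapping two identical-probability columns leaves all scores unchanged
  m2 <- m; m2$probs[, c(1, 9)] <- m2$probs[, c(9, 1)]
  s2 <- paste0(substr(s, 9, 9), substr(s, 2, 8), substr(s, 1, 1))
  expect_equal(score_site(s2, m2), score_site(s, m), tolerance = 1e-9)
})

test_that("score tables load into an exact lookup model", {
  path <- tempfile()
  writeLines(c("CAGGTAAGT\t8.21", "AAAAAAAAA\t-12.5"), path)
  m <- load_maxent_tables(path, "donor")
  expect_equal(score_site("CAGGTAAGT", m), 8.21)
  m2 <- load_maxent_tables(path, "donor")
  expect_equal(score_site("AAAAAAAAA", m2), score_site("AAAAAAAAA", m))
  expect_error(load_maxent_tables(tempfile(), "donor"), "train_site_model")
  writeLines("CAGG\t1.0", path)
  expect_error(load_maxent_tables(path, "donor"), "malformed")
})

test_that("train -> sample -> train round trip converges in total variation", {
  pwm <- acceptor_pwm()
  seqs <- ejcsplice:::with_seed(7, ejcsplice:::sample_sites(pwm, 10000))
  fit <- train_site_model(seqs, "acceptor", pseudocount = 0.5)
  tv_per_pos <- colSums(abs(fit$probs - pwm)) / 2
  expect_lt(max(tv_per_pos), 0.02)
})

test_that("SRE frequency counts overlapping windows per nt", {
  ms <- motif_set("GAAGAA", "ESE")
  # matches at positions 1 and 4 of GAAGAAGAA -> 2/9
  expect_equal(as.numeric(sre_frequency("GAAGAAGAA", ms)), 2 / 9)
  expect_equal(as.numeric(sre_frequency("CCCCCCCCC", ms)), 0)
  # doubling length at identical counts halves the frequency
  expect_equal(as.numeric(sre_frequency(paste0("GAAGAAGAA", strrep("C", 9)),
                                        ms)),
               (2 / 9) / 2)
  # sequence shorter than the motif: zero with a flag
  short <- sre_frequency("GAA", ms)
  expect_equal(as.numeric(short), 0)
  expect_true(attr(short, "too_short"))
})

test_that("reverse-complement invariance holds only for closed motif sets", {
  seqc <- "GAAGAAGAACCC"
  rc <- ejcsplice:::reverse_complement(seqc)
  open_set <- motif_set("GAAGAA", "ESE")
  closed_set <- motif_set(c("GAAGAA", "TTCTTC"), "ESE")
  expect_false(isTRUE(all.equal(as.numeric(sre_frequency(seqc, open_set)),
                                as.numeric(sre_frequency(rc, open_set)))))
  expect_equal(as.numeric(sre_frequency(seqc, closed_set)),
               as.numeric(sre_frequency(rc, closed_set)))
})

test_that("the permutation z-score matches an independent reimplementation", {
  set.seed(50)
  seqc <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  ms <- motif_set("GAAGAA", "ESE")
  got <- motif_zscore(seqc, ms, n_shuffles = 100, seed = 17)
  # independent oracle: same seeded permutations, naive counting
  count6 <- function(s) {
    hits <- 0
    for (i in 1:(nchar(s) - 5)) {
      if (substr(s, i, i + 5) == "GAAGAA") hits <- hits + 1
    }
    hits / nchar(s)
  }
  bases <- strsplit(seqc, "")[[1]]
  f_null <- ejcsplice:::with_seed(17, vapply(1:100, function(i) {
    count6(paste(bases[sample.int(200)], collapse = ""))
  }, numeric(1)))
  z_oracle <- (count6(seqc) - mean(f_null)) / sd(f_null)
  if (sd(f_null) == 0) {
    expect_true(got$degenerate)
  } else {
    expect_equal(got$z, z_oracle, tolerance = 1e-12)
  }
})

test_that("degenerate shuffles return the documented sentinel", {
  got <- motif_zscore(strrep("A", 60), motif_set("AAAAAA", "ESE"),
                      n_shuffles = 10, seed = 1)
  expect_true(got$degenerate)
  expect_true(is.na(got$z))
  expect_error(motif_zscore("ACGT", motif_set("ACGTAA", "ESE"),
                            n_shuffles = 1), "n_shuffles")
})

test_that("dinucleotide shuffling preserves composition and seeds", {
  seqc <- strrep("ACGT", 30)
  a <- motif_zscore(seqc, motif_set("ACGTAC", "ESE"), n_shuffles = 20,
                    seed = 3, dinucleotide = TRUE)
  b <- motif_zscore(seqc, motif_set("ACGTAC", "ESE"), n_shuffles = 20,
                    seed = 3, dinucleotide = TRUE)
  expect_equal(a$z, b$z)
})

test_that("group comparison reproduces the exact rank-sum distribution", {
  # exhaustive oracle: C(6,3) = 20 arrangements, U = 0 is one-sided 1/20
  res <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.1)
  # identical groups are indistinguishable
  expect_gt(compare_groups(1:10, 1:10)$p_value, 0.9)
  # p decreases monotonically with a location shift
  set.seed(2)
  x <- rnorm(200)
  ps <- vapply(c(0.2, 0.5, 1), function(d) {
    compare_groups(x, x + d)$p_value
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_error(compare_groups(numeric(0), 1:3), "non-empty")
})

test_that("length-expression correlation is Spearman with sentinels", {
  expect_equal(length_expression_correlation(1:10, (1:10)^2)$rho, 1)
  got <- length_expression_correlation(c(1, 2, 3), c(5, 5, 5))
  expect_true(got$degenerate)
  expect_true(is.na(got$rho))
  # null-distribution oracle: independent draws stay near zero
  set.seed(8)
  rhos <- vapply(1:20, function(i) {
    length_expression_correlation(rnorm(1000), rnorm(1000))$rho
  }, numeric(1))
  expect_gte(mean(abs(rhos) < 0.08), 0.95)
  expect_error(length_expression_correlation(1:2, 1:2), "3")
})

test_that("z-scores under the null are calibrated", {
  # composition-matched null: the observed sequence is itself a fresh
  # random string, so z should be mean ~0, sd ~1 over many sequences
  ms <- bundled_motif_sets()$ESE
  set.seed(60)
  zs <- vapply(1:150, function(i) {
    s <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
    motif_zscore(s, ms, n_shuffles = 50, seed = i)$z
  }, numeric(1))
  zs <- zs[!is.na(zs)]
  expect_lt(abs(mean(zs)), 0.15)
  expect_gt(sd(zs), 0.75)
  expect_lt(sd(zs), 1.25)
})

test_that("event feature extraction scores real windows from the genome", {
  sim <- generate_annotation(small_sim_config(n_genes = 8, seed = 33))
  ann <- sim$annotation
  donor <- train_site_model(
    ejcsplice:::with_seed(1, ejcsplice:::sample_sites(donor_pwm(), 2000)),
    "donor")
  acceptor <- train_site_model(
    ejcsplice:::with_seed(1, ejcsplice:::sample_sites(acceptor_pwm(), 2000)),
    "acceptor")
  ms <- bundled_motif_sets()
  feats <- compute_event_features(ann$events, sim$genome, donor, acceptor,
                                  ms, zscore_sets = "ESE", n_shuffles = 20)
  expect_true(all(feats$valid))
  # planted sites should score clearly above background on average
  expect_gt(mean(feats$ca_donor_score), 2)
  expect_gt(mean(feats$ca_acceptor_score), 2)
  expect_true(all(feats$freq_ESE_ca >= 0 & feats$freq_ESE_ca <= 1))
  expect_true(all(c("freq_ISS_up_intron", "z_ESE_ca") %in% names(feats)))
})

test_that("bundled synthetic motif fixtures are intact and regenerable", {
  sets <- bundled_motif_sets()
  sizes <- vapply(sets, function(s) length(s$motifs), integer(1))
  expect_identical(unname(sizes[c("ESE", "ESS", "ISE", "ISS")]),
                   c(238L, 176L, 199L, 102L))
  for (s in sets) {
    expect_false(anyDuplicated(s$motifs) > 0)
    expect_true(all(nchar(s$motifs) == s$k))
  }
  # files are the frozen output of the deterministic generator
  regen <- synthetic_motif_sets()
  for (k in names(sets)) {
    expect_identical(sets[[k]]$motifs, regen[[k]]$motifs)
  }
})
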