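# Splice-site strength scoring.
#
# The donor (5'ss) window is a 9-mer: the last 3 nt of the exon and the first
# 6 nt of the downstream intron. The acceptor (3'ss) window is a 23-mer: the
# last 20 nt of the upstream intron and the first 3 nt of the exon. Scores
# are log2 odds (bits) of a per-position nucleotide model against a
# background composition, so that a sequence scored under a model equal to
# its background scores exactly 0.

DONOR_LEN <- 9L
ACCEPTOR_LEN <- 23L

site_length <- function(site_type) {
  switch(site_type, donor = DONOR_LEN, acceptor = ACCEPTOR_LEN,
         stop("site_type must be 'donor' or 'acceptor'", call. = FALSE))
}

#' Reference position models for simulated splice sites
#'
#' Per-position nucleotide probability matrices (rows A, C, G, T) used by the
#' synthetic-data generator to embed realistic donor and acceptor contexts,
#' and by tests as a known ground-truth model. The donor matrix encodes the
#' (C/A)AG|GTAAGT consensus; the acceptor matrix a pyrimidine-rich tract
#' followed by the invariant AG and a weak exonic G.
#'
#' @return a 4 x 9 (donor) or 4 x 23 (acceptor) column-stochastic matrix.
#' @export
donor_pwm <- function() {
  p <- matrix(0.25, nrow = 4, ncol = DONOR_LEN,
              dimnames = list(DNA_BASES, NULL))
  #              exon -3 -2 -1 | intron +1..+6
  p[, 1] <- c(0.35, 0.35, 0.20, 0.10)  # C/A
  p[, 2] <- c(0.60, 0.10, 0.15, 0.15)  # A
  p[, 3] <- c(0.10, 0.05, 0.80, 0.05)  # G
  p[, 4] <- c(0.01, 0.01, 0.97, 0.01)  # G (near-invariant)
  p[, 5] <- c(0.01, 0.01, 0.01, 0.97)  # T (near-invariant)
  p[, 6] <- c(0.60, 0.10, 0.20, 0.10)  # A
  p[, 7] <- c(0.70, 0.05, 0.15, 0.10)  # A
  p[, 8] <- c(0.10, 0.05, 0.75, 0.10)  # G
  p[, 9] <- c(0.15, 0.15, 0.15, 0.55)  # T
  p
}

#' @rdname donor_pwm
#' @export
acceptor_pwm <- function() {
  p <- matrix(0.25, nrow = 4, ncol = ACCEPTOR_LEN,
              dimnames = list(DNA_BASES, NULL))
  for (j in 1:18) p[, j] <- c(0.10, 0.35, 0.10, 0.45)  # polypyrimidine tract
  p[, 19] <- c(0.97, 0.01, 0.01, 0.01)                 # A (near-invariant)
  p[, 20] <- c(0.01, 0.01, 0.97, 0.01)                 # G (near-invariant)
  p[, 21] <- c(0.25, 0.15, 0.50, 0.10)                 # exonic G-rich
  p[, 22] <- c(0.30, 0.20, 0.25, 0.25)
  p[, 23] <- c(0.25, 0.25, 0.25, 0.25)
  p
}

# Sample n site sequences from a position model (columns independent).
sample_sites <- function(pwm, n) {
  L <- ncol(pwm)
  mat <- vapply(seq_len(L), function(j) {
    sample(DNA_BASES, n, replace = TRUE, prob = pwm[, j])
  }, character(n))
  if (n == 1L) mat <- matrix(mat, nrow = 1)
  apply(mat, 1, paste, collapse = "")
}

#' Train a per-position splice-site model
#'
#' Fits an independent per-position nucleotide probability model with an
#' additive pseudocount, plus a background model taken as the global base
#' composition of the training set (overridable). This trainable model
#' stands in the same scoring role as published maximum-entropy splice-site
#' score tables, which can be loaded instead via [load_maxent_tables()].
#'
#' @param sequences character vector of training sites, all of the length
#'   required by `site_type` (9 for donor, 23 for acceptor), uppercase ACGT.
#' @param site_type `"donor"` or `"acceptor"`.
#' @param pseudocount additive pseudocount per cell (default 0.5 keeps all
#'   scores finite).
#' @param background optional length-4 named probability vector (A,C,G,T)
#'   overriding the training-set composition.
#' @return an object of class `splice_site_model`.
#' @export
train_site_model <- function(sequences, site_type = c("donor", "acceptor"),
                             pseudocount = 0.5, background = NULL) {
  site_type <- match.arg(site_type)
  L <- site_length(site_type)
  if (length(sequences) == 0) stop("no training sequences", call. = FALSE)
  if (any(nchar(sequences) != L)) {
    stop(sprintf("all %s training sequences must be %d nt", site_type, L),
         call. = FALSE)
  }
  chars <- strsplit(toupper(sequences), "", fixed = TRUE)
  mat <- matrix(unlist(chars), ncol = L, byrow = TRUE)
  if (!all(mat %in% DNA_BASES)) {
    stop("training sequences contain non-ACGT symbols", call. = FALSE)
  }
  probs <- vapply(seq_len(L), function(j) {
    counts <- table(factor(mat[, j], levels = DNA_BASES)) + pseudocount
    as.numeric(counts / sum(counts))
  }, numeric(4))
  rownames(probs) <- DNA_BASES
  if (is.null(background)) {
    counts <- table(factor(mat, levels = DNA_BASES)) + pseudocount
    background <- as.numeric(counts / sum(counts))
    names(background) <- DNA_BASES
  } else {
    background <- background[DNA_BASES]
    if (abs(sum(background) - 1) > 1e-9) {
      stop("background probabilities must sum to 1", call. = FALSE)
    }
  }
  structure(list(site_type = site_type, length = L, probs = probs,
                 background = background, kind = "position"),
            class = "splice_site_model")
}

# A model identical to its background; scores 0 for every sequence.
background_site_model <- function(site_type = c("donor", "acceptor"),
                                  background = NULL) {
  site_type <- match.arg(site_type)
  L <- site_length(site_type)
  bg <- background %||% setNames(rep(0.25, 4), DNA_BASES)
  probs <- matrix(bg, nrow = 4, ncol = L, dimnames = list(DNA_BASES, NULL))
  structure(list(site_type = site_type, length = L, probs = probs,
                 background = bg, kind = "position"),
            class = "splice_site_model")
}

#' Score a splice site in bits
#'
#' Log2 odds of the site model against its background, summed over
#' positions for position models, or a direct table lookup for models
#' loaded from score tables.
#'
#' @param sequence a single site sequence of the model's length.
#' @param model a `splice_site_model`.
#' @return score in bits.
#' @export
score_site <- function(sequence, model) {
  stopifnot(inherits(model, "splice_site_model"))
  sequence <- toupper(sequence)
  if (nchar(sequence) != model$length) {
    stop(sprintf("%s model requires a %d-mer, got %d nt",
                 model$site_type, model$length, nchar(sequence)),
         call. = FALSE)
  }
  if (model$kind == "table") {
    sc <- model$scores[[sequence]]
    if (is.null(sc)) stop("sequence absent from score table: ", sequence,
                          call. = FALSE)
    return(sc)
  }
  bases <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (!all(bases %in% DNA_BASES)) {
    stop("sequence contains non-ACGT symbols", call. = FALSE)
  }
  idx <- match(bases, DNA_BASES)
  sum(log2(model$probs[cbind(idx, seq_along(idx))] / model$background[idx]))
}

#' Load a published splice-site score table
#'
#' Reads a precomputed k-mer score table (two whitespace-separated columns:
#' site sequence, score in bits — the layout in which maximum-entropy
#' splice-site scores are commonly redistributed) into a lookup model whose
#' [score_site()] reproduces the published scores exactly. When no table is
#' available, train a position model from site sequences with
#' [train_site_model()] instead.
#'
#' @param path path to the score-table file.
#' @param site_type `"donor"` or `"acceptor"`.
#' @return a `splice_site_model` of kind `"table"`.
#' @export
load_maxent_tables <- function(path, site_type = c("donor", "acceptor")) {
  site_type <- match.arg(site_type)
  if (!file.exists(path)) {
    stop("score table not found: ", path,
         "; no published tables are bundled — train a position model with ",
         "train_site_model() instead", call. = FALSE)
  }
  tab <- read.delim(path, header = FALSE, sep = "", comment.char = "#",
                    col.names = c("kmer", "score"),
                    colClasses = c("character", "numeric"))
  L <- site_length(site_type)
  if (nrow(tab) == 0 || any(nchar(tab$kmer) != L)) {
    stop("malformed score table: expected ", L, "-mers", call. = FALSE)
  }
  if (anyDuplicated(tab$kmer)) {
    stop("malformed score table: duplicate k-mers", call. = FALSE)
  }
  scores <- as.list(tab$score)
  names(scores) <- toupper(tab$kmer)
  structure(list(site_type = site_type, length = L, scores = scores,
                 kind = "table"),
            class = "splice_site_model")
}

#' @export
print.splice_site_model <- function(x, ...) {
  cat(sprintf("<splice_site_model: %s, %d-mer, %s>\n",
              x$site_type, x$length, x$kind))
  invisible(x)
}
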