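# Splicing-regulatory-element (SRE) motif sets and counting.
#
# Four motif families are used: exonic splicing enhancers and silencers
# (ESE, ESS; hexamers), intronic splicing enhancers (ISE; hexamers) and
# intronic splicing silencers (ISS; decamers). Frequencies are sliding-
# window counts (overlaps included) normalised by sequence length.

MOTIF_KINDS <- c(ESE = 6L, ESS = 6L, ISE = 6L, ISS = 10L)

#' Construct a splicing-regulatory motif set
#'
#' @param motifs character vector of motif strings over A,C,G,T; all of the
#'   length fixed by `kind` (6 nt for ESE/ESS/ISE, 10 nt for ISS).
#' @param kind one of `"ESE"`, `"ESS"`, `"ISE"`, `"ISS"`.
#' @param name optional label.
#' @return an object of class `motif_set`.
#' @export
motif_set <- function(motifs, kind = c("ESE", "ESS", "ISE", "ISS"),
                      name = kind) {
  kind <- match.arg(kind)
  k <- MOTIF_KINDS[[kind]]
  motifs <- toupper(motifs)
  if (any(nchar(motifs) != k)) {
    stop(kind, " motifs must all be ", k, " nt", call. = FALSE)
  }
  if (!all(strsplit(paste(motifs, collapse = ""), "")[[1]] %in% DNA_BASES)) {
    stop("motifs must be over the A,C,G,T alphabet", call. = FALSE)
  }
  motifs <- unique(motifs)
  structure(list(name = name, kind = kind, k = k, motifs = motifs),
            class = "motif_set")
}

#' @export
print.motif_set <- function(x, ...) {
  cat(sprintf("<motif_set %s (%s): %d motifs of %d nt>\n",
              x$name, x$kind, length(x$motifs), x$k))
  invisible(x)
}

#' Read or write a motif set as a one-motif-per-line text file
#'
#' @param path file path.
#' @param kind motif family, fixing the motif length.
#' @param name optional label (defaults to the file base name).
#' @export
read_motif_set <- function(path, kind, name = NULL) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  motif_set(lines, kind = kind,
            name = name %||% sub("\\.[^.]*$", "", basename(path)))
}

#' @rdname read_motif_set
#' @param ms a `motif_set`.
#' @export
write_motif_set <- function(ms, path) {
  writeLines(ms$motifs, path)
  invisible(path)
}

#' Deterministic synthetic stand-ins for the published SRE motif sets
#'
#' Generates four motif sets with the cardinalities of the published
#' catalogues (238 ESE hexamers, 176 ESS hexamers, 199 ISE hexamers,
#' 102 ISS decamers). The motif *content* is synthetic — drawn
#' deterministically and disjointly from the k-mer space, with ESE biased
#' purine-rich and ESS/ISS pyrimidine-rich as a coarse compositional
#' caricature of the real catalogues. The published screens themselves are
#' not redistributed; use [read_motif_set()] to load the real lists if you
#' have them. Copies bundled with the package live under
#' `inst/extdata/` with a `_synthetic` filename suffix.
#'
#' @param seed generation seed (fixed default: the bundled files are this
#'   function's frozen output).
#' @return named list of four `motif_set`s.
#' @export
synthetic_motif_sets <- function(seed = 20140901) {
  with_seed(seed, {
    sample_kmers <- function(n, k, probs, exclude = character(0)) {
      out <- character(0)
      while (length(out) < n) {
        cand <- vapply(seq_len(n * 2L), function(i) {
          paste(sample(DNA_BASES, k, replace = TRUE, prob = probs),
                collapse = "")
        }, character(1))
        out <- setdiff(unique(c(out, setdiff(cand, exclude))), exclude)
      }
      out[seq_len(n)]
    }
    purine <- c(0.40, 0.10, 0.40, 0.10)      # A,C,G,T
    pyrimidine <- c(0.10, 0.35, 0.10, 0.45)
    uniform <- rep(0.25, 4)
    ese <- sample_kmers(238, 6, purine)
    ess <- sample_kmers(176, 6, pyrimidine, exclude = ese)
    ise <- sample_kmers(199, 6, uniform, exclude = c(ese, ess))
    iss <- sample_kmers(102, 10, pyrimidine)
    list(ESE = motif_set(ese, "ESE", "ESE_synthetic"),
         ESS = motif_set(ess, "ESS", "ESS_synthetic"),
         ISE = motif_set(ise, "ISE", "ISE_synthetic"),
         ISS = motif_set(iss, "ISS", "ISS_synthetic"))
  })
}

#' Load the bundled synthetic motif sets
#'
#' Reads the four synthetic SRE motif files shipped under `inst/extdata/`.
#' @return named list of four `motif_set`s.
#' @export
bundled_motif_sets <- function() {
  dir <- system.file("extdata", package = "ejcsplice")
  kinds <- names(MOTIF_KINDS)
  out <- lapply(kinds, function(kind) {
    read_motif_set(file.path(dir, sprintf("%s_synthetic.txt", tolower(kind))),
                   kind = kind, name = paste0(kind, "_synthetic"))
  })
  names(out) <- kinds
  out
}

#' Plant motif occurrences into a sequence
#'
#' Overwrites non-overlapping windows of the sequence with motifs drawn from
#' the set, at an expected rate of `density` occurrences per nt. Original
#' sequence length is preserved.
#'
#' @param sequence nucleotide string.
#' @param motifs a `motif_set`.
#' @param density planted occurrences per nt (>= 0).
#' @param seed integer seed.
#' @return list with `sequence` (modified string) and `positions`
#'   (1-based start positions of planted occurrences).
#' @export
plant_motifs <- function(sequence, motifs, density, seed = 1) {
  stopifnot(inherits(motifs, "motif_set"))
  if (density < 0) stop("density must be >= 0", call. = FALSE)
  n <- nchar(sequence)
  k <- motifs$k
  if (k > n) stop("motif length exceeds sequence length", call. = FALSE)
  if (density == 0) return(list(sequence = sequence, positions = integer(0)))
  with_seed(seed, {
    n_target <- rpois(1, density * n)
    starts <- sample.int(n - k + 1L, min(n_target, n - k + 1L))
    planted <- integer(0)
    occupied <- logical(n)
    bases <- strsplit(sequence, "", fixed = TRUE)[[1]]
    for (s in starts) {
      win <- s:(s + k - 1L)
      if (any(occupied[win])) next
      m <- sample(motifs$motifs, 1L)
      bases[win] <- strsplit(m, "", fixed = TRUE)[[1]]
      occupied[win] <- TRUE
      planted <- c(planted, s)
      if (length(planted) >= n_target) break
    }
    list(sequence = paste(bases, collapse = ""), positions = sort(planted))
  })
}

#' SRE frequency of a sequence
#'
#' Counts sliding-window positions (overlaps counted) whose k-mer belongs to
#' the motif set, normalised by the sequence length — occurrences per nt.
#'
#' @param sequence nucleotide string.
#' @param motifs a `motif_set`.
#' @return frequency in `[0, 1]`; 0 (with attribute `too_short = TRUE`)
#'   when the sequence is shorter than the motif length.
#' @export
sre_frequency <- function(sequence, motifs) {
  stopifnot(inherits(motifs, "motif_set"))
  n <- nchar(sequence)
  if (n < motifs$k) {
    return(structure(0, too_short = TRUE))
  }
  count_motif_hits(toupper(sequence), motifs) / n
}

count_motif_hits <- function(sequence, motifs) {
  n <- nchar(sequence)
  k <- motifs$k
  wins <- substring(sequence, 1:(n - k + 1L), k:n)
  sum(wins %in% motifs$motifs)
}

#' Permutation z-score of SRE frequency
#'
#' Compares the observed motif frequency of a sequence with its frequency in
#' `n_shuffles` seeded randomisations of the same sequence:
#' `z = (f_obs - mean(f_shuffled)) / sd(f_shuffled)`. The default shuffle is
#' a uniform permutation of the nucleotides (mononucleotide composition
#' preserved); `dinucleotide = TRUE` shuffles non-overlapping dinucleotide
#' blocks instead. When every shuffle gives the same frequency (sd = 0,
#' e.g. a homopolymer) the z-score is the undefined sentinel `NA` with
#' `degenerate = TRUE`; such values are excluded from downstream enrichment
#' summaries rather than imputed.
#'
#' @param sequence nucleotide string.
#' @param motifs a `motif_set` (or a single motif string plus `kind`).
#' @param n_shuffles number of randomisations (>= 2; conventionally 100).
#' @param seed integer seed.
#' @param dinucleotide preserve dinucleotide blocks when shuffling.
#' @return list with `z`, `f_obs`, `f_null_mean`, `f_null_sd`,
#'   `degenerate`.
#' @export
motif_zscore <- function(sequence, motifs, n_shuffles = 100, seed = 1,
                         dinucleotide = FALSE) {
  if (is.character(motifs)) {
    k <- unique(nchar(motifs))
    kind <- names(MOTIF_KINDS)[match(k, MOTIF_KINDS)]
    if (is.na(kind)) stop("cannot infer motif kind from length ", k,
                          call. = FALSE)
    motifs <- motif_set(motifs, kind)
  }
  stopifnot(inherits(motifs, "motif_set"))
  if (n_shuffles < 2) stop("n_shuffles must be >= 2", call. = FALSE)
  sequence <- toupper(sequence)
  f_obs <- as.numeric(sre_frequency(sequence, motifs))
  n <- nchar(sequence)
  bases <- strsplit(sequence, "", fixed = TRUE)[[1]]
  f_null <- with_seed(seed, vapply(seq_len(n_shuffles), function(i) {
    shuf <- if (dinucleotide) {
      n_pairs <- n %/% 2L
      pair_starts <- seq(1L, by = 2L, length.out = n_pairs)
      ord <- sample.int(n_pairs)
      idx <- as.vector(rbind(pair_starts[ord], pair_starts[ord] + 1L))
      if (n %% 2L == 1L) idx <- c(idx, n)
      bases[idx]
    } else {
      bases[sample.int(n)]
    }
    as.numeric(sre_frequency(paste(shuf, collapse = ""), motifs))
  }, numeric(1)))
  mu <- mean(f_null)
  sdv <- sd(f_null)
  if (sdv == 0) {
    return(list(z = NA_real_, f_obs = f_obs, f_null_mean = mu,
                f_null_sd = 0, degenerate = TRUE))
  }
  list(z = (f_obs - mu) / sdv, f_obs = f_obs, f_null_mean = mu,
       f_null_sd = sdv, degenerate = FALSE)
}
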