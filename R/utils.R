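#' @keywords internal
"_PACKAGE"

#' @importFrom stats rbinom rpois rlnorm runif sd wilcox.test cor.test p.adjust setNames
#' @importFrom utils read.delim write.table
NULL

# Contrast names used throughout: the three EJC-component knockdowns and the
# NMD-factor knockdown, against a common control.
EJC_CONTRASTS <- c("eIF4A3", "Y14", "MLN51")
ALL_CONTRASTS <- c("eIF4A3", "Y14", "MLN51", "Upf1")
CONTROL_CONDITION <- "control"

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` with the RNG seeded at `seed`, restoring the caller's RNG state.
# All generator entry points use this so a fixed seed gives byte-identical
# output regardless of surrounding RNG use.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

DNA_BASES <- c("A", "C", "G", "T")

# Random DNA as a character scalar; `n` in nt.
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Extract a transcript-orientation sequence from a genome (DNAStringSet),
# 0-based half-open genomic coordinates.
extract_seq <- function(genome, chrom, start, end, strand) {
  stopifnot(end > start)
  s <- Biostrings::subseq(genome[[chrom]], start = start + 1L, end = end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

stop_with_line <- function(line, msg) {
  stop(sprintf("line %d: %s", line, msg), call. = FALSE)
}
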