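# Per-base coverage tracks, keyed by (chromosome, strand).
#
# A coverage_track stores one numeric vector per "chrom:strand" key; queries
# outside covered regions return 0. Values are non-negative. bedGraph is the
# interchange format, one file per strand (bedGraph itself is unstranded).

track_key <- function(chrom, strand) paste0(chrom, ":", strand)

#' Construct an empty coverage track
#'
#' @param seqlengths named numeric vector of chromosome lengths.
#' @param strands strands to allocate (default both).
#' @return an object of class `coverage_track`.
#' @export
coverage_track <- function(seqlengths, strands = c("+", "-")) {
  values <- list()
  for (chrom in names(seqlengths)) {
    for (s in strands) {
      values[[track_key(chrom, s)]] <- numeric(seqlengths[[chrom]])
    }
  }
  structure(list(values = values, seqlengths = seqlengths),
            class = "coverage_track")
}

#' Query per-base values from a coverage track
#'
#' @param track a `coverage_track`.
#' @param chrom,strand location.
#' @param pos 0-based positions (vector); positions outside covered
#'   regions return 0.
#' @return numeric vector of values, all >= 0.
#' @export
track_values <- function(track, chrom, strand, pos) {
  v <- track$values[[track_key(chrom, strand)]]
  out <- numeric(length(pos))
  if (is.null(v)) return(out)
  ok <- pos >= 0 & pos < length(v)
  out[ok] <- v[pos[ok] + 1L]
  out
}

track_add <- function(track, chrom, strand, pos, values) {
  key <- track_key(chrom, strand)
  v <- track$values[[key]]
  v[pos + 1L] <- v[pos + 1L] + values
  track$values[[key]] <- v
  track
}

#' Scale a coverage track by a constant
#' @param track a `coverage_track`.
#' @param factor non-negative multiplier.
#' @export
track_scale <- function(track, factor) {
  stopifnot(factor >= 0)
  track$values <- lapply(track$values, `*`, factor)
  track
}

#' @export
print.coverage_track <- function(x, ...) {
  tot <- sum(vapply(x$values, sum, numeric(1)))
  cat(sprintf("<coverage_track: %d chrom:strand keys, total signal %.1f>\n",
              length(x$values), tot))
  invisible(x)
}

#' Simulate mRNA and CLIP coverage tracks
#'
#' mRNA coverage is uniform over each gene's exons at a per-gene expression
#' level (lognormal across genes) plus Poisson noise, with a low pre-mRNA
#' level over introns (`intron_expression_fraction` of the exonic level).
#' CLIP coverage is a flat Poisson background over expressed gene bodies
#' plus a Gaussian-shaped peak of height `clip_peak_height` centred at
#' `clip_peak_offset` from each exon's 3' border (transcript orientation;
#' the canonical deposition site is -24 nt). Both tracks live on the gene's
#' strand. A peak whose offset falls outside the exon is truncated with a
#' warning.
#'
#' @param annotation a `genome_annotation`.
#' @param config a [sim_config()].
#' @return list with `mrna` and `clip` `coverage_track`s and `expression`
#'   (per-gene data frame of mean exonic coverage levels).
#' @export
simulate_coverage <- function(annotation, config) {
  validate_sim_config(config)
  with_seed(config$seed + 2L, simulate_coverage_impl(annotation, config))
}

simulate_coverage_impl <- function(ann, config) {
  mrna <- coverage_track(ann$seqlengths)
  clip <- coverage_track(ann$seqlengths)
  mv <- mrna$values
  cv <- clip$values
  level <- rlnorm(nrow(ann$genes), config$expression_meanlog,
                  config$expression_sdlog)
  expression <- data.frame(gene_id = ann$genes$gene_id, level = level,
                           stringsAsFactors = FALSE)
  truncated <- 0L
  for (i in seq_len(nrow(ann$genes))) {
    g <- ann$genes[i, ]
    ex <- ann$exons[ann$exons$gene_id == g$gene_id, ]
    ex <- ex[order(ex$start), ]
    key <- track_key(g$chrom, g$strand)
    # mRNA: exons at gene level, introns at the pre-mRNA fraction
    gene_pos <- g$start:(g$end - 1L)
    in_exon <- rep(FALSE, length(gene_pos))
    for (k in seq_len(nrow(ex))) {
      in_exon[(ex$start[k] - g$start + 1L):(ex$end[k] - g$start)] <- TRUE
    }
    lam <- ifelse(in_exon, level[i], level[i] * config$intron_expression_fraction)
    mv[[key]][gene_pos + 1L] <- rpois(length(gene_pos), lam)
    # CLIP: background everywhere on the gene body
    clip_vals <- rpois(length(gene_pos), config$clip_background)
    # plus a peak at clip_peak_offset from each exon's 3' border
    for (k in seq_len(nrow(ex))) {
      len <- ex$end[k] - ex$start[k]
      # transcript-orientation position of the peak centre within the exon,
      # 0-based from the exon 5' end: offset -24 => len - 24
      centre <- len + config$clip_peak_offset
      if (centre < 0L || centre >= len) {
        truncated <- truncated + 1L
        next
      }
      rel <- 0:(len - 1L)
      shape <- config$clip_peak_height *
        exp(-0.5 * ((rel - centre) / config$clip_peak_sd)^2)
      gpos <- if (g$strand == "+") ex$start[k] + rel else ex$end[k] - 1L - rel
      idx <- gpos - g$start + 1L
      clip_vals[idx] <- clip_vals[idx] + round(shape)
    }
    if (!is.null(config$clip_intron_peak_offset) && nrow(ex) > 1L) {
      for (k in seq_len(nrow(ex) - 1L)) {
        istart <- ex$end[k]; iend <- ex$start[k + 1L]
        ilen <- iend - istart
        centre <- config$clip_intron_peak_offset
        if (centre < 0L) centre <- ilen + centre
        if (centre < 0L || centre >= ilen) next
        rel <- 0:(ilen - 1L)
        shape <- config$clip_peak_height *
          exp(-0.5 * ((rel - centre) / config$clip_peak_sd)^2)
        gpos <- if (g$strand == "+") istart + rel else iend - 1L - rel
        idx <- gpos - g$start + 1L
        clip_vals[idx] <- clip_vals[idx] + round(shape)
      }
    }
    cv[[key]][gene_pos + 1L] <- cv[[key]][gene_pos + 1L] + clip_vals
  }
  if (truncated > 0L) {
    warning(truncated, " exon(s) shorter than the CLIP peak offset; ",
            "peak truncated", call. = FALSE)
  }
  mrna$values <- mv
  clip$values <- cv
  list(mrna = mrna, clip = clip, expression = expression)
}

#' Write a coverage track as bedGraph, one file per strand
#'
#' @param track a `coverage_track`.
#' @param prefix output path prefix; files `<prefix>_plus.bedGraph` and
#'   `<prefix>_minus.bedGraph` are written via rtracklayer.
#' @return the written paths, invisibly.
#' @export
write_bedgraph <- function(track, prefix) {
  paths <- character(0)
  for (s in c("+", "-")) {
    gr_list <- list()
    for (chrom in names(track$seqlengths)) {
      v <- track$values[[track_key(chrom, s)]]
      if (is.null(v)) next
      r <- rle(v)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths
      keep <- r$values != 0
      if (!any(keep)) next
      gr_list[[chrom]] <- GenomicRanges::GRanges(
        seqnames = chrom,
        ranges = IRanges::IRanges(start = starts[keep] + 1L, end = ends[keep]),
        score = r$values[keep])
    }
    path <- sprintf("%s_%s.bedGraph", prefix,
                    if (s == "+") "plus" else "minus")
    gr <- if (length(gr_list)) {
      suppressWarnings(do.call(c, unname(gr_list)))
    } else GenomicRanges::GRanges()
    rtracklayer::export(gr, path, format = "bedGraph")
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read strand-split bedGraph files into a coverage track
#'
#' @param prefix path prefix as in [write_bedgraph()].
#' @param seqlengths named chromosome lengths.
#' @export
read_bedgraph <- function(prefix, seqlengths) {
  track <- coverage_track(seqlengths)
  for (s in c("+", "-")) {
    path <- sprintf("%s_%s.bedGraph", prefix,
                    if (s == "+") "plus" else "minus")
    if (!file.exists(path)) next
    gr <- rtracklayer::import(path, format = "bedGraph")
    chroms <- as.character(GenomicRanges::seqnames(gr))
    for (chrom in unique(chroms)) {
      sel <- chroms == chrom
      starts <- GenomicRanges::start(gr)[sel] - 1L
      widths <- GenomicRanges::width(gr)[sel]
      pos <- sequence(widths, from = starts + 1L)  # 1-based indices
      key <- track_key(chrom, s)
      v <- track$values[[key]]
      v[pos] <- rep(gr$score[sel], widths)
      track$values[[key]] <- v
    }
  }
  track
}
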