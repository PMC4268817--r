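# RNA splicing maps: category-wise positional CLIP-binding profiles over
# 100-nt windows anchored at exon-intron borders.
#
# Relative-position convention (transcript orientation): at an exon's 5'
# border, exonic positions are +1, +2, ... counting into the exon; at the
# 3' border, exonic positions are ..., -2, -1 with -1 the last exon base.
# The canonical EJC deposition site is therefore -24. Intronic windows use
# the same scheme anchored at the intron's own borders.

#' Border-anchored coordinate frames of an exon
#'
#' Returns, for one exon, the genomic positions of its 5'-border frame
#' (relative positions 1..width) and 3'-border frame (relative positions
#' -width..-1), strand-aware. Exons shorter than `width` contribute only
#' their existing positions, and the two frames of a short exon overlap by
#' construction.
#'
#' @param start,end 0-based half-open exon coordinates.
#' @param strand `"+"` or `"-"`.
#' @param width frame width in nt (default 100).
#' @return data frame with `frame` (`"5p"`/`"3p"`), `rel_pos`, `gpos`
#'   (0-based genomic position).
#' @export
extract_border_windows <- function(start, end, strand, width = 100L) {
  len <- end - start
  stopifnot(len >= 1)
  m <- min(len, width)
  rel5 <- seq_len(m)                  # 1..m from the 5' border
  rel3 <- -(m:1)                      # -m..-1 into the 3' border
  if (strand == "+") {
    g5 <- start + rel5 - 1L
    g3 <- end + rel3
  } else {
    g5 <- end - rel5
    g3 <- start - rel3 - 1L
  }
  data.frame(frame = rep(c("5p", "3p"), each = m),
             rel_pos = c(rel5, rel3),
             gpos = c(g5, g3),
             stringsAsFactors = FALSE)
}

#' Expression-normalised CLIP values over a coordinate frame
#'
#' Per-position ratio `c'(p) = CLIP(p) / mRNA(p)`; positions with zero mRNA
#' coverage are masked (`NA`) and excluded both from sums and from the
#' exon-count normalisation downstream, rather than producing unbounded
#' ratios. A pseudocount can be supplied instead of masking.
#'
#' @param clip,mrna `coverage_track`s.
#' @param chrom,strand location of the exon the frame belongs to.
#' @param frames data frame from [extract_border_windows()].
#' @param pseudocount added to the mRNA denominator; 0 (default) masks
#'   zero-expression positions.
#' @return `frames` with columns `clip`, `mrna`, `value` (masked positions
#'   `NA`). Warns when every position is masked.
#' @export
normalize_clip <- function(clip, mrna, chrom, strand, frames,
                           pseudocount = 0) {
  cv <- track_values(clip, chrom, strand, frames$gpos)
  mv <- track_values(mrna, chrom, strand, frames$gpos) + pseudocount
  val <- ifelse(mv > 0, cv / mv, NA_real_)
  if (all(is.na(val))) {
    warning("all positions masked (no mRNA coverage) for ", chrom, ":",
            strand, call. = FALSE)
  }
  frames$clip <- cv
  frames$mrna <- mv
  frames$value <- val
  frames
}

# Accumulate one region's exons into per-position sums and counts.
accumulate_region <- function(events, region, clip, mrna, width,
                              pseudocount) {
  scol <- paste0(region, "_start"); ecol <- paste0(region, "_end")
  acc <- list()
  for (i in seq_len(nrow(events))) {
    fr <- extract_border_windows(events[[scol]][i], events[[ecol]][i],
                                 events$strand[i], width)
    fr <- suppressWarnings(
      normalize_clip(clip, mrna, events$chrom[i], events$strand[i], fr,
                     pseudocount))
    ok <- !is.na(fr$value)
    if (!any(ok)) next
    key <- paste(fr$frame[ok], fr$rel_pos[ok])
    for (j in which(ok)) {
      k <- paste(fr$frame[j], fr$rel_pos[j])
      if (is.null(acc[[k]])) acc[[k]] <- c(0, 0)
      acc[[k]] <- acc[[k]] + c(fr$value[j], 1)
    }
  }
  if (length(acc) == 0) return(NULL)
  parts <- strsplit(names(acc), " ", fixed = TRUE)
  data.frame(
    region = region,
    frame = vapply(parts, `[`, "", 1),
    rel_pos = as.integer(vapply(parts, `[`, "", 2)),
    sum_value = vapply(acc, `[`, 0, 1),
    n = as.integer(vapply(acc, `[`, 0, 2)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Build RNA splicing maps over exon-border windows
#'
#' For each event category and each region of the exon trio (upstream,
#' cassette, downstream exon), accumulates the expression-normalised CLIP
#' signal `c'(p)` of every exon over its two border frames, averages per
#' position by the number of contributing exons `n(p)`, and scales the
#' whole category profile by its maximum over the analysed region, so the
#' profile height lies in [0, 1] with max exactly 1 whenever any signal is
#' present. This order (per-exon ratio, per-position mean, global max
#' scaling) makes profiles invariant to global CLIP scaling, to per-gene
#' expression level, and to category size.
#'
#' @param events_by_category named list of exon-trio event data frames
#'   (e.g. categories `+`, `-`, `Ctr`, `CON`, `CtrCON`).
#' @param clip,mrna `coverage_track`s (mRNA from the control condition).
#' @param width border window width in nt (default 100).
#' @param pseudocount passed to [normalize_clip()].
#' @return a `splicing_map_profile` data frame: `category`, `region`,
#'   `frame`, `rel_pos`, `height`, `n`. Empty categories are omitted with
#'   a warning.
#' @export
build_map <- function(events_by_category, clip, mrna, width = 100L,
                      pseudocount = 0) {
  build_map_over_regions(events_by_category, clip, mrna,
                         regions = c("up", "ca", "dn"), width = width,
                         pseudocount = pseudocount)
}

#' Build RNA splicing maps over flanking-intron windows
#'
#' As [build_map()], with the coordinate frames anchored on the intronic
#' sides of the cassette exon's borders: both ends of the upstream and the
#' downstream intron. Introns shorter than `width` contribute truncated
#' frames.
#'
#' @inheritParams build_map
#' @export
build_intron_map <- function(events_by_category, clip, mrna, width = 100L,
                             pseudocount = 0) {
  with_introns <- lapply(events_by_category, function(ev) {
    plus <- ev$strand == "+"
    ev$upin_start <- ifelse(plus, ev$up_end, ev$ca_end)
    ev$upin_end <- ifelse(plus, ev$ca_start, ev$up_start)
    ev$dnin_start <- ifelse(plus, ev$ca_end, ev$dn_end)
    ev$dnin_end <- ifelse(plus, ev$dn_start, ev$ca_start)
    ev[ev$upin_end > ev$upin_start & ev$dnin_end > ev$dnin_start, ,
       drop = FALSE]
  })
  build_map_over_regions(with_introns, clip, mrna,
                         regions = c("upin", "dnin"), width = width,
                         pseudocount = pseudocount)
}

build_map_over_regions <- function(events_by_category, clip, mrna, regions,
                                   width, pseudocount) {
  out <- list()
  for (cat in names(events_by_category)) {
    ev <- events_by_category[[cat]]
    if (is.null(ev) || nrow(ev) == 0) {
      warning("category ", cat, " is empty; omitted", call. = FALSE)
      next
    }
    parts <- list()
    for (region in regions) {
      part <- accumulate_region(ev, region, clip, mrna, width, pseudocount)
      if (!is.null(part)) parts[[region]] <- part
    }
    if (length(parts) == 0) {
      warning("category ", cat, " has no normalisable positions; omitted",
              call. = FALSE)
      next
    }
    prof <- do.call(rbind, parts)
    prof$height <- prof$sum_value / prof$n
    mx <- max(prof$height)
    if (mx > 0) prof$height <- prof$height / mx
    prof$category <- cat
    prof <- prof[order(match(prof$region, regions),
                       match(prof$frame, c("5p", "3p")), prof$rel_pos),
                 c("category", "region", "frame", "rel_pos", "height", "n")]
    rownames(prof) <- NULL
    out[[cat]] <- prof
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(category = character(), region = character(),
               frame = character(), rel_pos = integer(),
               height = numeric(), n = integer(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("splicing_map_profile", "data.frame")
  res
}

#' Position of the maximum of a splicing-map profile
#'
#' @param profile a `splicing_map_profile`.
#' @param category,region,frame optional filters.
#' @return the `rel_pos` of the highest point of the (filtered) profile.
#' @export
profile_argmax <- function(profile, category = NULL, region = NULL,
                           frame = NULL) {
  p <- profile
  if (!is.null(category)) p <- p[p$category == category, ]
  if (!is.null(region)) p <- p[p$region == region, ]
  if (!is.null(frame)) p <- p[p$frame == frame, ]
  if (nrow(p) == 0) stop("no profile rows after filtering", call. = FALSE)
  p$rel_pos[which.max(p$height)]
}

#' Write a splicing-map profile as TSV
#' @param profile a `splicing_map_profile`.
#' @param path output path.
#' @export
write_profile <- function(profile, path) {
  write.table(profile, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
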