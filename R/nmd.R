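# Premature termination codons by the 50-nt rule, and AS-NMD candidates.
#
# A stop codon is premature when it lies more than 50 nt upstream of an
# exon-exon junction; since the last junction is the 3'-most, scanning the
# last junction is equivalent to scanning all of them. Distances are in
# spliced-transcript coordinates.

#' Construct an isoform ORF description
#'
#' @param exon_lengths exon lengths (nt) in transcript order.
#' @param stop_pos transcript coordinate (1-based nt from the 5' end) of the
#'   last nt of the stop codon; `NA` when no stop was found.
#' @return an `isoform_orf`: `junctions` (transcript coordinates of the last
#'   nt of each exon except the final one, strictly increasing), `stop_pos`,
#'   `tx_length`.
#' @export
isoform_orf <- function(exon_lengths, stop_pos) {
  stopifnot(all(exon_lengths >= 1))
  tx_length <- sum(exon_lengths)
  junctions <- cumsum(exon_lengths)
  junctions <- junctions[-length(junctions)]
  if (!is.na(stop_pos) && (stop_pos < 1 || stop_pos > tx_length)) {
    stop("stop codon position outside the transcript", call. = FALSE)
  }
  structure(list(junctions = junctions, stop_pos = stop_pos,
                 tx_length = tx_length),
            class = "isoform_orf")
}

#' Classify a stop codon as premature by the 50-nt rule
#'
#' `is_ptc` is true iff the stop codon lies strictly more than 50 nt
#' upstream of the last exon-exon junction (distance 50 is not premature).
#' Single-exon transcripts have no junction and are never PTC-positive.
#'
#' @param isoform an [isoform_orf()].
#' @param min_distance the rule's distance threshold in nt (default 50).
#' @return list with `is_ptc` and `distance_to_last_junction` (signed,
#'   positive when the stop is upstream of the junction; `NA` with no
#'   junction or no stop).
#' @export
find_ptc <- function(isoform, min_distance = 50) {
  stopifnot(inherits(isoform, "isoform_orf"))
  if (length(isoform$junctions) == 0 || is.na(isoform$stop_pos)) {
    return(list(is_ptc = FALSE, distance_to_last_junction = NA_real_))
  }
  d <- max(isoform$junctions) - isoform$stop_pos
  list(is_ptc = d > min_distance, distance_to_last_junction = d)
}

#' Derive inclusion- and skipping-isoform ORFs for a cassette event
#'
#' Builds the inclusion isoform from the transcript's full exon chain and
#' the skipping isoform by removing the cassette exon, then scans each
#' spliced sequence for the first ATG and the first in-frame stop codon
#' downstream of it.
#'
#' @param event one exon-trio event row (needs `chrom`, `strand`,
#'   `ca_start`, `ca_end`, and a `gene_id` resolvable in the annotation).
#' @param annotation a `genome_annotation`.
#' @param genome a [Biostrings::DNAStringSet].
#' @return list with `inclusion` and `skipping` [isoform_orf()]s, or `NULL`
#'   when the cassette exon cannot be matched to the transcript.
#' @export
derive_isoform_orfs <- function(event, annotation, genome) {
  ex <- annotation$exons[annotation$exons$gene_id == event$gene_id, ,
                         drop = FALSE]
  if (nrow(ex) == 0) return(NULL)
  ex <- ex[order(ex$exon_rank), ]
  ca <- which(ex$start == event$ca_start & ex$end == event$ca_end)
  if (length(ca) != 1) return(NULL)
  orf_from_exons <- function(keep) {
    lens <- ex$end[keep] - ex$start[keep]
    seqs <- vapply(which(keep), function(k) {
      extract_seq(genome, ex$chrom[k], ex$start[k], ex$end[k], ex$strand[k])
    }, character(1))
    # minus-strand transcripts read exons in transcript order already
    tx_seq <- paste(seqs, collapse = "")
    isoform_orf(lens, first_stop_after_atg(tx_seq))
  }
  keep_all <- rep(TRUE, nrow(ex))
  keep_skip <- keep_all; keep_skip[ca] <- FALSE
  list(inclusion = orf_from_exons(keep_all),
       skipping = orf_from_exons(keep_skip))
}

# 1-based transcript coordinate of the last nt of the first in-frame stop
# codon downstream of the first ATG; NA when absent.
first_stop_after_atg <- function(tx_seq) {
  atg <- regexpr("ATG", tx_seq, fixed = TRUE)
  if (atg < 0) return(NA_real_)
  n <- nchar(tx_seq)
  pos <- as.integer(atg)
  while (pos + 2L <= n) {
    codon <- substr(tx_seq, pos, pos + 2L)
    if (codon %in% c("TAA", "TAG", "TGA")) return(pos + 2L)
    pos <- pos + 3L
  }
  NA_real_
}

#' Flag premature-termination and AS-NMD candidate events
#'
#' An event is PTC-bearing if either of its two isoforms carries a
#' premature stop; it is an AS-NMD candidate if it is additionally
#' upregulated (fold change strictly greater than `fc_min`, default 1.5) in
#' at least one EJC contrast. Events without fold-change information are
#' flagged `"undetermined"` rather than dropped.
#'
#' @param events categorised events (needs `event_id`, `gene_id`).
#' @param ptc_status data frame `event_id`, `ptc_inclusion`, `ptc_skipping`
#'   (logicals).
#' @param gene_fc data frame `gene_id`, `contrast`, `fc` (from
#'   [fold_changes()]).
#' @param fc_min fold-change threshold (strict).
#' @return `events` with columns `ptc_bearing`, `max_ejc_fc`,
#'   `asnmd_status` in `{"candidate", "not_candidate", "undetermined"}`.
#' @export
asnmd_candidates <- function(events, ptc_status, gene_fc, fc_min = 1.5) {
  m <- match(events$event_id, ptc_status$event_id)
  if (any(is.na(m))) {
    stop("PTC status missing for event(s): ",
         paste(events$event_id[is.na(m)][1:min(3, sum(is.na(m)))],
               collapse = ", "), call. = FALSE)
  }
  events$ptc_bearing <- ptc_status$ptc_inclusion[m] |
    ptc_status$ptc_skipping[m]
  ejc_fc <- gene_fc[gene_fc$contrast %in% EJC_CONTRASTS, , drop = FALSE]
  max_fc <- tapply(ejc_fc$fc, ejc_fc$gene_id, max, na.rm = TRUE)
  events$max_ejc_fc <- as.numeric(max_fc[events$gene_id])
  events$asnmd_status <- ifelse(
    !events$ptc_bearing, "not_candidate",
    ifelse(is.na(events$max_ejc_fc), "undetermined",
           ifelse(events$max_ejc_fc > fc_min, "candidate",
                  "not_candidate")))
  events
}
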