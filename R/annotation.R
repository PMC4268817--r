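# Synthetic genome annotation and sequence.
#
# Internal coordinate convention is 0-based half-open [start, end); GTF is
# emitted 1-based inclusive at the boundary. Each simulated gene has one
# reference (inclusion) transcript; cassette exons are internal exons
# flagged alternative, and the skipping isoform is derived on demand by
# dropping the cassette exon.

GENES_PER_CHROM <- 50L
INTERGENIC_GAP <- 500L

#' Generate a synthetic annotation and genome
#'
#' Simulates multi-exon genes (>= 3 exons each) laid out on synthetic
#' chromosomes, flags a configured fraction of internal exons as cassette
#' (alternative) exons, assigns each cassette event a true inclusion level
#' per condition, and builds a genome sequence with donor/acceptor
#' splice-site contexts embedded at every exon border from the reference
#' position models ([donor_pwm()], [acceptor_pwm()]).
#'
#' True Psi assignment: a fraction `affected_fraction` of cassette events
#' change in all three EJC knockdowns (and not in the Upf1 knockdown);
#' with probability `skipping_bias` the change is increased skipping
#' (Psi drops by `delta_psi` from `psi_control`), otherwise increased
#' inclusion (baseline `psi_control - delta_psi` rising to `psi_control`).
#'
#' @param config a [sim_config()] object.
#' @return a list with elements `annotation` (class `genome_annotation`:
#'   data frames `genes`, `exons`, `events`, plus `seqlengths`) and
#'   `genome` (a [Biostrings::DNAStringSet]).
#' @export
generate_annotation <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, generate_annotation_impl(config))
}

generate_annotation_impl <- function(config) {
  n <- config$n_genes
  gene_ids <- sprintf("G%05d", seq_len(n))
  chroms <- sprintf("chrS%d", ((seq_len(n) - 1L) %/% GENES_PER_CHROM) + 1L)
  strands <- sample(c("+", "-"), n, replace = TRUE)

  genes_list <- vector("list", n)
  exons_list <- vector("list", n)
  offset <- setNames(rep(200L, length(unique(chroms))), unique(chroms))

  for (i in seq_len(n)) {
    n_ex <- 3L + stats::rpois(1, config$n_exons_lambda)
    ex_len <- pmax(config$exon_len_min,
                   round(rlnorm(n_ex, config$exon_len_meanlog,
                                config$exon_len_sdlog)))
    in_len <- pmax(config$intron_len_min,
                   round(rlnorm(n_ex - 1L, config$intron_len_meanlog,
                                config$intron_len_sdlog)))
    chrom <- chroms[i]
    gstart <- offset[[chrom]]
    starts <- gstart + c(0L, cumsum(ex_len[-n_ex] + in_len))
    ends <- starts + ex_len
    offset[[chrom]] <- ends[n_ex] + INTERGENIC_GAP

    alternative <- rep(FALSE, n_ex)
    if (n_ex >= 3L && config$cassette_fraction > 0) {
      internal <- 2:(n_ex - 1L)
      alternative[internal] <-
        runif(length(internal)) < config$cassette_fraction
    }
    # transcript order: genomic order on +, reversed on -
    rank <- if (strands[i] == "+") seq_len(n_ex) else rev(seq_len(n_ex))
    genes_list[[i]] <- data.frame(
      gene_id = gene_ids[i], chrom = chrom, strand = strands[i],
      start = starts[1], end = ends[n_ex], n_exons = n_ex,
      stringsAsFactors = FALSE)
    exons_list[[i]] <- data.frame(
      gene_id = gene_ids[i],
      transcript_id = paste0(gene_ids[i], ".T1"),
      chrom = chrom, strand = strands[i],
      start = starts, end = ends, exon_rank = rank,
      alternative = alternative, stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, genes_list)
  exons <- do.call(rbind, exons_list)
  events <- assign_true_psi(build_cassette_events(exons), config)
  seqlengths <- vapply(split(exons$end, exons$chrom), max, numeric(1)) +
    INTERGENIC_GAP
  ann <- structure(list(genes = genes, exons = exons, events = events,
                        seqlengths = seqlengths),
                   class = "genome_annotation")
  genome <- build_genome_sequence(ann, config)
  list(annotation = ann, genome = genome)
}

# One event per alternative exon, with flanking exons taken in transcript
# order (upstream = 5' side of the transcript).
build_cassette_events <- function(exons) {
  rows <- list()
  for (tx in split(exons, exons$transcript_id)) {
    tx <- tx[order(tx$exon_rank), ]
    n_ex <- nrow(tx)
    for (k in seq_len(n_ex)) {
      if (!tx$alternative[k] || k == 1L || k == n_ex) next
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = tx$gene_id[1], chrom = tx$chrom[1], strand = tx$strand[1],
        up_start = tx$start[k - 1L], up_end = tx$end[k - 1L],
        ca_start = tx$start[k], ca_end = tx$end[k],
        dn_start = tx$start[k + 1L], dn_end = tx$end[k + 1L],
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(event_id = character(), gene_id = character(),
                      chrom = character(), strand = character(),
                      up_start = integer(), up_end = integer(),
                      ca_start = integer(), ca_end = integer(),
                      dn_start = integer(), dn_end = integer(),
                      stringsAsFactors = FALSE))
  }
  ev <- do.call(rbind, rows)
  cbind(event_id = sprintf("EV%05d", seq_len(nrow(ev))), ev,
        stringsAsFactors = FALSE)
}

assign_true_psi <- function(events, config) {
  n <- nrow(events)
  affected <- runif(n) < config$affected_fraction
  skipping_up <- runif(n) < config$skipping_bias
  psi_ctrl <- ifelse(affected & !skipping_up,
                     config$psi_control - config$delta_psi,
                     config$psi_control)
  psi_kd <- ifelse(affected,
                   ifelse(skipping_up,
                          config$psi_control - config$delta_psi,
                          config$psi_control),
                   psi_ctrl)
  events$psi_control <- psi_ctrl
  for (cc in EJC_CONTRASTS) events[[paste0("psi_", cc)]] <- psi_kd
  events$psi_Upf1 <- psi_ctrl   # EJC-dependent changes are Upf1-independent
  events$true_affected <- affected
  events$true_direction <- ifelse(!affected, "none",
                                  ifelse(skipping_up, "+", "-"))
  events
}

# Random chromosome sequences with splice-site contexts (and a start codon)
# planted at the appropriate genomic windows, strand-aware.
build_genome_sequence <- function(ann, config) {
  dpwm <- donor_pwm(); apwm <- acceptor_pwm()
  seqs <- lapply(names(ann$seqlengths), function(chrom) {
    L <- as.integer(ann$seqlengths[[chrom]])
    bases <- sample(DNA_BASES, L, replace = TRUE)
    ex <- ann$exons[ann$exons$chrom == chrom, ]
    for (tx in split(ex, ex$transcript_id)) {
      tx <- tx[order(tx$exon_rank), ]
      n_ex <- nrow(tx)
      plus <- tx$strand[1] == "+"
      for (k in seq_len(n_ex)) {
        if (k < n_ex) {  # donor at this exon's 3' border
          site <- sample_sites(dpwm, 1L)
          if (plus) {
            w <- (tx$end[k] - 3L):(tx$end[k] + 5L) + 1L
            bases[w] <- strsplit(site, "")[[1]]
          } else {
            w <- (tx$start[k] - 6L):(tx$start[k] + 2L) + 1L
            bases[w] <- strsplit(reverse_complement(site), "")[[1]]
          }
        }
        if (k > 1L) {    # acceptor at this exon's 5' border
          site <- sample_sites(apwm, 1L)
          if (plus) {
            w <- (tx$start[k] - 20L):(tx$start[k] + 2L) + 1L
            bases[w] <- strsplit(site, "")[[1]]
          } else {
            w <- (tx$end[k] - 3L):(tx$end[k] + 19L) + 1L
            bases[w] <- strsplit(reverse_complement(site), "")[[1]]
          }
        }
      }
      # start codon near the transcript 5' end (position 9-11 of exon 1)
      if (plus) {
        w <- tx$start[1] + 8:10 + 1L
        bases[w] <- c("A", "T", "G")
      } else {
        w <- tx$end[1] - 11:9
        bases[w] <- c("C", "A", "T")
      }
    }
    paste(bases, collapse = "")
  })
  genome <- Biostrings::DNAStringSet(unlist(seqs))
  names(genome) <- names(ann$seqlengths)
  genome
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation: %d genes, %d exons (%d alternative), %d cassette events>\n",
              nrow(x$genes), nrow(x$exons), sum(x$exons$alternative),
              nrow(x$events)))
  invisible(x)
}

#' Write and read the annotation as GTF
#'
#' Emits gene, transcript and exon features, 1-based inclusive, with an
#' `exon_class` attribute recording the alternative/constitutive flag.
#' `read_annotation_gtf()` parses such a file (via rtracklayer) back into a
#' `genome_annotation`; ground-truth Psi columns are not part of the GTF and
#' are absent after a round trip.
#'
#' @param ann a `genome_annotation`.
#' @param path output file path.
#' @export
write_annotation_gtf <- function(ann, path) {
  fmt_attr <- function(...) paste0(..., collapse = "")
  lines <- character(0)
  for (i in seq_len(nrow(ann$genes))) {
    g <- ann$genes[i, ]
    lines <- c(lines, sprintf(
      "%s\tejcsplice_sim\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
      g$chrom, g$start + 1L, g$end, g$strand, g$gene_id))
    ex <- ann$exons[ann$exons$gene_id == g$gene_id, ]
    ex <- ex[order(ex$exon_rank), ]
    lines <- c(lines, sprintf(
      "%s\tejcsplice_sim\ttranscript\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
      g$chrom, g$start + 1L, g$end, g$strand, g$gene_id, ex$transcript_id[1]))
    lines <- c(lines, sprintf(
      "%s\tejcsplice_sim\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\"; exon_number \"%d\"; exon_class \"%s\";",
      ex$chrom, ex$start + 1L, ex$end, ex$strand, ex$gene_id,
      ex$transcript_id, ex$exon_rank,
      ifelse(ex$alternative, "alternative", "constitutive")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_annotation_gtf
#' @export
read_annotation_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  exons <- data.frame(
    gene_id = ex$gene_id,
    transcript_id = ex$transcript_id,
    chrom = as.character(GenomicRanges::seqnames(ex)),
    strand = as.character(GenomicRanges::strand(ex)),
    start = GenomicRanges::start(ex) - 1L,
    end = GenomicRanges::end(ex),
    exon_rank = as.integer(ex$exon_number),
    alternative = ex$exon_class == "alternative",
    stringsAsFactors = FALSE)
  exons <- exons[order(exons$gene_id, exons$start), ]
  rownames(exons) <- NULL
  gn <- gr[gr$type == "gene"]
  genes <- data.frame(
    gene_id = gn$gene_id,
    chrom = as.character(GenomicRanges::seqnames(gn)),
    strand = as.character(GenomicRanges::strand(gn)),
    start = GenomicRanges::start(gn) - 1L,
    end = GenomicRanges::end(gn),
    n_exons = as.integer(table(exons$gene_id)[gn$gene_id]),
    stringsAsFactors = FALSE)
  rownames(genes) <- NULL
  seqlengths <- vapply(split(exons$end, exons$chrom), max, numeric(1)) +
    INTERGENIC_GAP
  structure(list(genes = genes, exons = exons,
                 events = build_cassette_events(exons),
                 seqlengths = seqlengths),
            class = "genome_annotation")
}

#' Write the genome as FASTA
#' @param genome a [Biostrings::DNAStringSet].
#' @param path output path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read a genome FASTA
#' @param path FASTA path.
#' @export
read_genome_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}
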