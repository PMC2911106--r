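#' Regulatory-region length metrics
#'
#' Length definitions used throughout the package. All distances are counts
#' of bases strictly between two coding nucleotides, in the gene's own
#' orientation:
#'
#' * 5' IGR: from a gene's 5'-most coding base to the closest coding base of
#'   a *different* gene in the gene's 5' direction, on either strand.
#' * 3' IGR: the mirror image, from the 3'-most coding base in the 3'
#'   direction.
#' * first intron: per transcript, the intron closest 3' of the translation
#'   start; the gene-level value is the maximum across isoforms, and a
#'   second measure takes the largest continuous segment of that intron not
#'   covered by any gene's coding interval.
#' * UTR lengths: the maximum total UTR length across isoforms, after
#'   discarding 3' UTRs shorter than 5 bp and 5' UTRs shorter than 3 bp as
#'   annotation artifacts; 3' UTRs spanning more than one exon are excluded
#'   from the maximum unless explicitly allowed.
#'
#' Genes with no coding neighbour in the required direction are censored
#' (`NA` with a reason) rather than assigned a distance to the chromosome
#' end.
#'
#' @name region_metrics
NULL

chrom_index <- function(annotation) {
  split(annotation$coding, annotation$coding$chrom)
}

# nearest other-gene coding base at position <= s; bases strictly between
dist_to_coding_left <- function(idx, s, gene_id) {
  cand <- idx$gene_id != gene_id & idx$start <= s
  if (!any(cand)) return(NA_integer_)
  p <- max(pmin(idx$end[cand] - 1L, s))
  max(0L, s - p - 1L)
}

# nearest other-gene coding base at position >= t
dist_to_coding_right <- function(idx, t, gene_id) {
  cand <- idx$gene_id != gene_id & idx$end > t
  if (!any(cand)) return(NA_integer_)
  p <- min(pmax(idx$start[cand], t))
  max(0L, p - t - 1L)
}

gene_coding_extent <- function(annotation, gene_id) {
  seg <- annotation$coding[annotation$coding$gene_id == gene_id, , drop = FALSE]
  if (nrow(seg) == 0L) abort(sprintf("gene not in annotation: %s", gene_id))
  c(min(seg$start), max(seg$end))
}

#' 5' intergenic region length of one gene
#'
#' @param gene_id a gene identifier present in `annotation`.
#' @param annotation a [genome_annotation()].
#' @return Integer number of bases strictly between the gene's 5'-most coding
#'   base and the nearest coding base of a different gene in the 5'
#'   direction (0 when they abut or overlap); `NA` when no other coding gene
#'   lies in that direction on the chromosome (censored).
#' @export
five_prime_igr <- function(gene_id, annotation) {
  info <- gene_row(annotation, gene_id)
  idx <- annotation$coding[annotation$coding$chrom == info$chrom, , drop = FALSE]
  ext <- gene_coding_extent(annotation, gene_id)
  if (info$strand == "+") {
    dist_to_coding_left(idx, ext[1], gene_id)
  } else {
    dist_to_coding_right(idx, ext[2] - 1L, gene_id)
  }
}

#' 3' intergenic region length of one gene
#'
#' Mirror of [five_prime_igr()], measured from the gene's 3'-most coding base
#' in the 3' direction.
#' @inheritParams five_prime_igr
#' @return Integer bp, or `NA` when censored.
#' @export
three_prime_igr <- function(gene_id, annotation) {
  info <- gene_row(annotation, gene_id)
  idx <- annotation$coding[annotation$coding$chrom == info$chrom, , drop = FALSE]
  ext <- gene_coding_extent(annotation, gene_id)
  if (info$strand == "+") {
    dist_to_coding_right(idx, ext[2] - 1L, gene_id)
  } else {
    dist_to_coding_left(idx, ext[1], gene_id)
  }
}

gene_row <- function(annotation, gene_id) {
  i <- match(gene_id, annotation$genes$gene_id)
  if (is.na(i)) abort(sprintf("gene not in annotation: %s", gene_id))
  annotation$genes[i, , drop = FALSE]
}

# per-transcript first intron (nearest 3' of the translation start), as a
# [start, end) window or NULL
first_intron_window <- function(ex, cds_start, cds_end, strand) {
  k <- nrow(ex)
  if (k < 2L) return(NULL)
  istart <- ex$end[-k]
  iend <- ex$start[-1L]
  if (strand == "+") {
    ok <- istart >= cds_start
    if (!any(ok)) return(NULL)
    j <- which(ok)[which.min(istart[ok])]
  } else {
    ok <- iend <= cds_end
    if (!any(ok)) return(NULL)
    j <- which(ok)[which.max(iend[ok])]
  }
  c(istart[j], iend[j])
}

#' First-intron length measures of one gene
#'
#' @inheritParams five_prime_igr
#' @return A list with `intron1_max` (largest first-intron length across
#'   isoforms) and `intron1_noncoding` (largest continuous run of bases in
#'   that intron not covered by any gene's coding interval); both 0 for
#'   intronless genes.
#' @export
first_intron_lengths <- function(gene_id, annotation) {
  info <- gene_row(annotation, gene_id)
  tx <- annotation$transcripts[annotation$transcripts$gene_id == gene_id, ,
                               drop = FALSE]
  best <- NULL
  best_len <- 0L
  for (i in seq_len(nrow(tx))) {
    ex <- annotation$exons[annotation$exons$transcript_id == tx$transcript_id[i], ,
                           drop = FALSE]
    w <- first_intron_window(ex, tx$cds_start[i], tx$cds_end[i], info$strand)
    if (!is.null(w)) {
      len <- w[2] - w[1]
      if (len > best_len) {
        best_len <- as.integer(len)
        best <- w
      }
    }
  }
  if (is.null(best)) {
    return(list(intron1_max = 0L, intron1_noncoding = 0L))
  }
  idx <- annotation$coding[annotation$coding$chrom == info$chrom, , drop = FALSE]
  nc <- max_uncovered_run(idx$start, idx$end, best[1], best[2])
  list(intron1_max = best_len, intron1_noncoding = nc)
}

tx_utr_lengths <- function(ex, cds_start, cds_end, strand) {
  left <- sum(pmax(0L, pmin(ex$end, cds_start) - ex$start))
  n_left <- sum(pmin(ex$end, cds_start) - ex$start > 0L)
  right <- sum(pmax(0L, ex$end - pmax(ex$start, cds_end)))
  n_right <- sum(ex$end - pmax(ex$start, cds_end) > 0L)
  if (strand == "+") {
    list(utr5 = left, utr3 = right, n_utr3_exons = n_right)
  } else {
    list(utr5 = right, utr3 = left, n_utr3_exons = n_left)
  }
}

#' UTR lengths of one gene
#'
#' Per-gene UTR length is the maximum of per-transcript total UTR lengths.
#' Transcripts whose 3' UTR spans more than one exon are excluded from the
#' 3' UTR maximum unless `allow_multiexon_utr3` is `TRUE`. After taking the
#' maximum, 3' UTRs shorter than `utr3_min` (5 bp) and 5' UTRs shorter than
#' `utr5_min` (3 bp) are reported absent (`NA`), treating them as annotation
#' artifacts.
#'
#' @inheritParams five_prime_igr
#' @param allow_multiexon_utr3 keep multi-exon 3' UTRs in the maximum?
#' @param utr3_min,utr5_min minimum retained UTR lengths (bp).
#' @return A list with `utr3`, `utr5` (integer bp or `NA`) and
#'   `utr3_multiexon` (`TRUE` when any isoform's 3' UTR spans > 1 exon).
#' @export
utr_lengths <- function(gene_id, annotation, allow_multiexon_utr3 = FALSE,
                        utr3_min = 5L, utr5_min = 3L) {
  info <- gene_row(annotation, gene_id)
  tx <- annotation$transcripts[annotation$transcripts$gene_id == gene_id, ,
                               drop = FALSE]
  u3 <- integer(0)
  u5 <- integer(0)
  multi <- FALSE
  for (i in seq_len(nrow(tx))) {
    ex <- annotation$exons[annotation$exons$transcript_id == tx$transcript_id[i], ,
                           drop = FALSE]
    u <- tx_utr_lengths(ex, tx$cds_start[i], tx$cds_end[i], info$strand)
    u5 <- c(u5, u$utr5)
    if (u$n_utr3_exons > 1L) {
      multi <- TRUE
      if (allow_multiexon_utr3) u3 <- c(u3, u$utr3)
    } else {
      u3 <- c(u3, u$utr3)
    }
  }
  utr3 <- if (length(u3) > 0L) max(u3) else NA_integer_
  utr5 <- if (length(u5) > 0L) max(u5) else NA_integer_
  if (!is.na(utr3) && utr3 < utr3_min) utr3 <- NA_integer_
  if (!is.na(utr5) && utr5 < utr5_min) utr5 <- NA_integer_
  list(utr3 = utr3, utr5 = utr5, utr3_multiexon = multi)
}

#' Per-gene regulatory-region length table
#'
#' Computes every region-length metric for every coding gene: the 5'/3'
#' intergenic regions (censored genes carry a `censored_reason`), the
#' first-intron measures, the filtered UTR lengths and the combined
#' variants. For genes transcribed as part of an operon, only the 5'-most
#' member is flagged for inclusion in 5' IGR analyses
#' (`included_in_igr5_set`). In trans-spliced ("worm mode") genomes the
#' `utr5_plus_utr3` combined variant is omitted.
#'
#' @param annotation a [genome_annotation()].
#' @param operons optional tibble (`gene_id`, `operon_id`, `position`).
#' @param species_flags list; recognised entries `trans_spliced` (logical).
#' @param allow_multiexon_utr3,utr3_min,utr5_min see [utr_lengths()].
#' @param utr3_allow_list optional character vector of gene ids; genes not
#'   listed have their 3' UTR set to `NA` (dataset-restriction rule).
#' @return A tibble with one row per coding gene.
#' @export
compute_region_table <- function(annotation, operons = NULL,
                                 species_flags = list(trans_spliced = FALSE),
                                 allow_multiexon_utr3 = FALSE,
                                 utr3_min = 5L, utr5_min = 3L,
                                 utr3_allow_list = NULL) {
  stopifnot(inherits(annotation, "genome_annotation"))
  if (!is.null(operons)) annotation <- add_operons(annotation, operons)
  genes <- annotation$genes
  idx_by_chrom <- chrom_index(annotation)

  # per-gene coding extents, vectorised
  ext <- annotation$coding |>
    group_by(.data$gene_id) |>
    summarise(cmin = min(.data$start), cmax = max(.data$end))
  cmin <- setNames(ext$cmin, ext$gene_id)
  cmax <- setNames(ext$cmax, ext$gene_id)

  n <- nrow(genes)
  igr5 <- igr3 <- i1max <- i1nc <- utr3 <- utr5 <- rep(NA_integer_, n)
  multi3 <- logical(n)
  for (i in seq_len(n)) {
    gid <- genes$gene_id[i]
    idx <- idx_by_chrom[[genes$chrom[i]]]
    lo <- cmin[[gid]]
    hi <- cmax[[gid]] - 1L
    if (genes$strand[i] == "+") {
      igr5[i] <- dist_to_coding_left(idx, lo, gid)
      igr3[i] <- dist_to_coding_right(idx, hi, gid)
    } else {
      igr5[i] <- dist_to_coding_right(idx, hi, gid)
      igr3[i] <- dist_to_coding_left(idx, lo, gid)
    }
    fi <- first_intron_lengths(gid, annotation)
    i1max[i] <- fi$intron1_max
    i1nc[i] <- fi$intron1_noncoding
    u <- utr_lengths(gid, annotation, allow_multiexon_utr3, utr3_min, utr5_min)
    utr3[i] <- u$utr3
    utr5[i] <- u$utr5
    multi3[i] <- u$utr3_multiexon
  }
  if (!is.null(utr3_allow_list)) {
    utr3[!(genes$gene_id %in% utr3_allow_list)] <- NA_integer_
  }
  censored_reason <- dplyr::case_when(
    is.na(igr5) & is.na(igr3) ~ "no 5' or 3' coding neighbor",
    is.na(igr5) ~ "no coding neighbor in 5' direction",
    is.na(igr3) ~ "no coding neighbor in 3' direction",
    TRUE ~ NA_character_
  )
  out <- tibble(
    gene_id = genes$gene_id, chrom = genes$chrom, strand = genes$strand,
    igr5 = igr5, igr3 = igr3,
    intron1_max = i1max, intron1_noncoding = i1nc,
    utr5 = utr5, utr3 = utr3, utr3_multiexon = multi3,
    igr5_plus_intron1 = igr5 + i1max,
    igr5_plus_igr3 = igr5 + igr3,
    igr5_plus_intron1_plus_igr3 = igr5 + i1max + igr3,
    utr5_plus_utr3 = utr5 + utr3,
    included_in_igr5_set = is.na(genes$operon_position) | genes$operon_position == 1L,
    censored_reason = censored_reason
  )
  if (isTRUE(species_flags$trans_spliced)) {
    out$utr5_plus_utr3 <- NULL
  }
  out
}
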