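# Brute-force per-base oracles, independent of the package's interval engine.
# Everything here enumerates individual base positions (0-based) from the raw
# exon/CDS tables, so it shares no code with the IRanges-backed index.

# list: gene_id -> sorted vector of 0-based coding base positions
oracle_coding_positions <- function(annotation) {
  tx <- annotation$transcripts
  out <- list()
  for (i in seq_len(nrow(tx))) {
    tid <- tx$transcript_id[i]
    gid <- tx$gene_id[i]
    cds <- annotation$cds[annotation$cds$transcript_id == tid, , drop = FALSE]
    pos <- integer(0)
    for (j in seq_len(nrow(cds))) {
      pos <- c(pos, seq.int(cds$start[j], cds$end[j] - 1L))
    }
    out[[gid]] <- sort(unique(c(out[[gid]], pos)))
  }
  out
}

oracle_gene_info <- function(annotation, gene_id) {
  i <- match(gene_id, annotation$genes$gene_id)
  list(chrom = annotation$genes$chrom[i], strand = annotation$genes$strand[i])
}

# per chromosome: sorted unique coding positions and, in parallel, the
# number of distinct genes covering each (for "coding by a different gene")
oracle_chrom_pools <- function(annotation, coding_pos) {
  pools <- list()
  for (ch in unique(annotation$genes$chrom)) {
    genes <- annotation$genes$gene_id[annotation$genes$chrom == ch]
    all_pos <- unlist(coding_pos[genes], use.names = FALSE)
    tab <- table(all_pos)
    pos <- as.integer(names(tab))
    o <- order(pos)
    pools[[ch]] <- list(pos = pos[o], n_genes = as.integer(tab)[o])
  }
  pools
}

# distance strictly between the 5'-most coding base and the nearest
# other-gene coding base in the 5' direction; NA when no neighbour
oracle_igr <- function(annotation, coding_pos, gene_id, side = c("5", "3"),
                       chrom_pools = NULL) {
  side <- match.arg(side)
  info <- oracle_gene_info(annotation, gene_id)
  own <- coding_pos[[gene_id]]
  if (is.null(chrom_pools)) {
    chrom_pools <- oracle_chrom_pools(annotation, coding_pos)
  }
  pool <- chrom_pools[[info$chrom]]
  # a position is coding-by-another-gene when it is outside this gene's
  # positions, or covered by two or more genes
  other <- pool$pos[pool$n_genes >= 2L | !(pool$pos %in% own)]
  leftward <- (info$strand == "+") == (side == "5")
  if (leftward) {
    anchor <- min(own)
    cand <- other[other <= anchor]
    if (length(cand) == 0L) return(NA_integer_)
    max(0L, anchor - max(cand) - 1L)
  } else {
    anchor <- max(own)
    cand <- other[other >= anchor]
    if (length(cand) == 0L) return(NA_integer_)
    max(0L, min(cand) - anchor - 1L)
  }
}

# first intron per transcript by base enumeration; returns gene-level maxima
oracle_first_intron <- function(annotation, coding_pos, gene_id,
                                chrom_pools = NULL) {
  info <- oracle_gene_info(annotation, gene_id)
  tx <- annotation$transcripts[annotation$transcripts$gene_id == gene_id, ,
                               drop = FALSE]
  if (is.null(chrom_pools)) {
    chrom_pools <- oracle_chrom_pools(annotation, coding_pos)
  }
  all_coding <- chrom_pools[[info$chrom]]$pos
  best_len <- 0L
  best_window <- NULL
  for (i in seq_len(nrow(tx))) {
    ex <- annotation$exons[annotation$exons$transcript_id == tx$transcript_id[i], ,
                           drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) < 2L) next
    cds_s <- tx$cds_start[i]
    cds_e <- tx$cds_end[i]
    introns <- cbind(ex$end[-nrow(ex)], ex$start[-1L])
    if (info$strand == "+") {
      ok <- introns[, 1] >= cds_s
      if (!any(ok)) next
      w <- introns[ok, , drop = FALSE][which.min(introns[ok, 1]), ]
    } else {
      ok <- introns[, 2] <= cds_e
      if (!any(ok)) next
      w <- introns[ok, , drop = FALSE][which.max(introns[ok, 2]), ]
    }
    len <- w[2] - w[1]
    if (len > best_len) {
      best_len <- as.integer(len)
      best_window <- w
    }
  }
  if (is.null(best_window)) return(list(intron1_max = 0L, intron1_noncoding = 0L))
  bases <- seq.int(best_window[1], best_window[2] - 1L)
  noncoding <- !(bases %in% all_coding)
  runs <- rle(noncoding)
  nc <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  list(intron1_max = best_len, intron1_noncoding = as.integer(nc))
}

# per-gene UTR lengths by per-transcript base counting
oracle_utrs <- function(annotation, gene_id, allow_multiexon_utr3 = FALSE,
                        utr3_min = 5L, utr5_min = 3L) {
  info <- oracle_gene_info(annotation, gene_id)
  tx <- annotation$transcripts[annotation$transcripts$gene_id == gene_id, ,
                               drop = FALSE]
  u3s <- integer(0)
  u5s <- integer(0)
  multi <- FALSE
  for (i in seq_len(nrow(tx))) {
    ex <- annotation$exons[annotation$exons$transcript_id == tx$transcript_id[i], ,
                           drop = FALSE]
    exonic <- unlist(lapply(seq_len(nrow(ex)),
                            function(j) seq.int(ex$start[j], ex$end[j] - 1L)))
    cds_s <- tx$cds_start[i]
    cds_e <- tx$cds_end[i]
    left <- exonic[exonic < cds_s]
    right <- exonic[exonic >= cds_e]
    u3_bases <- if (info$strand == "+") right else left
    u5_bases <- if (info$strand == "+") left else right
    n_exons_u3 <- sum(vapply(seq_len(nrow(ex)), function(j) {
      any(u3_bases >= ex$start[j] & u3_bases < ex$end[j])
    }, logical(1)))
    if (n_exons_u3 > 1L) {
      multi <- TRUE
      if (allow_multiexon_utr3) u3s <- c(u3s, length(u3_bases))
    } else {
      u3s <- c(u3s, length(u3_bases))
    }
    u5s <- c(u5s, length(u5_bases))
  }
  u3 <- if (length(u3s)) max(u3s) else NA_integer_
  u5 <- if (length(u5s)) max(u5s) else NA_integer_
  if (!is.na(u3) && u3 < utr3_min) u3 <- NA_integer_
  if (!is.na(u5) && u5 < utr5_min) u5 <- NA_integer_
  list(utr3 = u3, utr5 = u5, utr3_multiexon = multi)
}

# maximal runs of the per-base coding mask of one chromosome (any gene)
oracle_coding_runs <- function(annotation, coding_pos, chrom) {
  genes <- annotation$genes$gene_id[annotation$genes$chrom == chrom]
  pos <- sort(unique(unlist(coding_pos[genes], use.names = FALSE)))
  if (length(pos) == 0L) return(data.frame(start = integer(), end = integer()))
  breaks <- c(0L, which(diff(pos) > 1L), length(pos))
  data.frame(start = pos[head(breaks, -1L) + 1L],
             end = pos[breaks[-1L]] + 1L)
}

# full oracle metric table for a small genome
oracle_region_table <- function(annotation, allow_multiexon_utr3 = FALSE) {
  coding_pos <- oracle_coding_positions(annotation)
  pools <- oracle_chrom_pools(annotation, coding_pos)
  rows <- lapply(annotation$genes$gene_id, function(g) {
    fi <- oracle_first_intron(annotation, coding_pos, g, pools)
    u <- oracle_utrs(annotation, g, allow_multiexon_utr3)
    data.frame(gene_id = g,
               igr5 = oracle_igr(annotation, coding_pos, g, "5", pools),
               igr3 = oracle_igr(annotation, coding_pos, g, "3", pools),
               intron1_max = fi$intron1_max,
               intron1_noncoding = fi$intron1_noncoding,
               utr5 = u$utr5, utr3 = u$utr3,
               utr3_multiexon = u$utr3_multiexon)
  })
  do.call(rbind, rows)
}
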