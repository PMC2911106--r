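#' Genome annotation as an internal gene-model table set
#'
#' A `genome_annotation` bundles the tables the region-length metrics need:
#' one row per gene, per transcript, per exon and per CDS segment, all in the
#' internal 0-based half-open coordinate convention, plus a per-chromosome
#' index of coding intervals (the union, over a gene's transcripts, of exon
#' segments overlapped by that transcript's CDS span). Non-coding genes are
#' excluded from the tables and recorded in `skipped` with a reason.
#'
#' @param genes tibble with columns `gene_id`, `chrom`, `strand` ("+"/"-"),
#'   and optionally `operon_id`, `operon_position` (1 = 5'-most member).
#' @param transcripts tibble with columns `transcript_id`, `gene_id`.
#' @param exons tibble with columns `transcript_id`, `start`, `end`
#'   (0-based half-open).
#' @param cds tibble with columns `transcript_id`, `start`, `end`
#'   (0-based half-open CDS segments; may be empty for a transcript).
#' @return A `genome_annotation` object (a classed list of tibbles:
#'   `genes`, `transcripts`, `exons`, `cds`, `coding`, `skipped`).
#' @export
genome_annotation <- function(genes, transcripts, exons, cds) {
  genes <- as_tibble(genes)
  transcripts <- as_tibble(transcripts)
  exons <- as_tibble(exons)
  cds <- as_tibble(cds)
  assert_cols(genes, c("gene_id", "chrom", "strand"), "genes")
  assert_cols(transcripts, c("transcript_id", "gene_id"), "transcripts")
  assert_cols(exons, c("transcript_id", "start", "end"), "exons")
  assert_cols(cds, c("transcript_id", "start", "end"), "cds")
  if (!all(genes$strand %in% c("+", "-"))) {
    abort("gene strand must be '+' or '-'")
  }
  if (anyDuplicated(genes$gene_id)) abort("duplicated gene_id in genes")
  if (anyDuplicated(transcripts$transcript_id)) {
    abort("duplicated transcript_id in transcripts")
  }
  orphan <- setdiff(transcripts$gene_id, genes$gene_id)
  if (length(orphan) > 0L) {
    abort(sprintf("transcript(s) reference unknown parent gene(s): %s",
                  paste(head(orphan, 5), collapse = ", ")))
  }
  if (!("operon_id" %in% names(genes))) genes$operon_id <- NA_character_
  if (!("operon_position" %in% names(genes))) genes$operon_position <- NA_integer_
  bad_op <- xor(is.na(genes$operon_id), is.na(genes$operon_position))
  if (any(bad_op)) {
    abort("operon_position must be present exactly when operon_id is")
  }

  exons <- arrange(exons, .data$transcript_id, .data$start)
  cds <- arrange(cds, .data$transcript_id, .data$start)
  validate_transcript_structure(transcripts, exons, cds)

  # CDS genomic span per transcript (NA when the transcript has no CDS)
  span <- cds |>
    group_by(.data$transcript_id) |>
    summarise(cds_start = min(.data$start), cds_end = max(.data$end))
  transcripts <- left_join(transcripts, span, by = "transcript_id")

  coding_tx <- transcripts$transcript_id[!is.na(transcripts$cds_start)]
  gene_has_cds <- transcripts |>
    group_by(.data$gene_id) |>
    summarise(has_cds = any(!is.na(.data$cds_start)))
  skipped_ids <- gene_has_cds$gene_id[!gene_has_cds$has_cds]
  skipped_ids <- c(skipped_ids, setdiff(genes$gene_id, transcripts$gene_id))
  skipped <- tibble(gene_id = skipped_ids,
                    reason = rep("no CDS-bearing transcript", length(skipped_ids)))

  keep <- !(genes$gene_id %in% skipped$gene_id)
  genes_kept <- genes[keep, , drop = FALSE]
  transcripts <- transcripts[transcripts$gene_id %in% genes_kept$gene_id &
                               transcripts$transcript_id %in% coding_tx, ,
                             drop = FALSE]
  exons <- exons[exons$transcript_id %in% transcripts$transcript_id, , drop = FALSE]
  cds <- cds[cds$transcript_id %in% transcripts$transcript_id, , drop = FALSE]

  coding <- build_coding_index(genes_kept, transcripts, exons)

  structure(
    list(genes = arrange(genes_kept, .data$chrom, .data$gene_id),
         transcripts = arrange(transcripts, .data$gene_id, .data$transcript_id),
         exons = exons, cds = cds, coding = coding,
         skipped = as_tibble(skipped)),
    class = "genome_annotation"
  )
}

# exon sorting/overlap and CDS-within-exon invariants; errors name transcripts
validate_transcript_structure <- function(transcripts, exons, cds) {
  ex_by_tx <- split(exons, exons$transcript_id)
  for (tx in names(ex_by_tx)) {
    e <- ex_by_tx[[tx]]
    if (any(e$end <= e$start)) abort(sprintf("empty exon in transcript %s", tx))
    if (nrow(e) > 1L && any(e$start[-1L] < e$end[-nrow(e)])) {
      abort(sprintf("overlapping exons in transcript %s", tx))
    }
  }
  cds_by_tx <- split(cds, cds$transcript_id)
  for (tx in names(cds_by_tx)) {
    cc <- cds_by_tx[[tx]]
    e <- ex_by_tx[[tx]]
    if (is.null(e)) abort(sprintf("CDS for transcript %s has no exons", tx))
    inside <- vapply(seq_len(nrow(cc)), function(i) {
      any(e$start <= cc$start[i] & cc$end[i] <= e$end)
    }, logical(1))
    if (!all(inside)) {
      abort(sprintf("CDS outside exons in transcript %s", tx))
    }
  }
  invisible(NULL)
}

# Per-gene union of CDS-overlapping exon segments, one sorted table.
build_coding_index <- function(genes, transcripts, exons) {
  tx_info <- transcripts[!is.na(transcripts$cds_start),
                         c("transcript_id", "gene_id", "cds_start", "cds_end")]
  ex <- inner_join(exons, tx_info, by = "transcript_id")
  seg_s <- pmax(ex$start, ex$cds_start)
  seg_e <- pmin(ex$end, ex$cds_end)
  keep <- seg_s < seg_e
  segs <- tibble(gene_id = ex$gene_id[keep], start = seg_s[keep], end = seg_e[keep])
  segs <- left_join(segs, genes[, c("gene_id", "chrom")], by = "gene_id")
  out <- segs |>
    group_by(.data$chrom, .data$gene_id) |>
    summarise(merged = list(merge_intervals(.data$start, .data$end)),
              .groups = "drop") |>
    mutate(start = purrr::map(.data$merged, "start"),
           end = purrr::map(.data$merged, "end")) |>
    select(-"merged") |>
    tidyr::unnest(c("start", "end")) |>
    arrange(.data$chrom, .data$start, .data$end)
  out[, c("chrom", "start", "end", "gene_id")]
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %d coding genes, %d transcripts, %d chromosomes",
              nrow(x$genes), nrow(x$transcripts), length(unique(x$genes$chrom))))
  if (nrow(x$skipped) > 0L) {
    cat(sprintf(" (%d genes skipped)", nrow(x$skipped)))
  }
  cat("\n")
  invisible(x)
}

#' Parse a GFF3 or GTF annotation into a genome_annotation
#'
#' Reads gene/transcript/exon/CDS features via rtracklayer and converts the
#' 1-based inclusive file coordinates to the internal 0-based half-open
#' convention. Genes without any CDS-bearing transcript are skipped with a
#' reason; structural inconsistencies (transcript without a parent gene, CDS
#' falling outside its transcript's exons) are errors.
#'
#' @param path path to an annotation file.
#' @param dialect `"gff3"` or `"gtf"`.
#' @return A [genome_annotation()].
#' @export
parse_annotation <- function(path, dialect = c("gff3", "gtf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("annotation file not found: %s", path))
  check_annotation_lines(path)
  gr <- rtracklayer::import(path, format = if (dialect == "gff3") "gff3" else "gtf")
  if (dialect == "gff3") parse_gff3_granges(gr) else parse_gtf_granges(gr)
}

# cheap structural scan so malformed rows fail with a line number
check_annotation_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- which(body)[nfield != 9L]
  if (length(bad) > 0L) {
    abort(sprintf("malformed annotation line %d in %s (expected 9 tab-separated fields)",
                  bad[1L], path))
  }
  invisible(NULL)
}

parse_gff3_granges <- function(gr) {
  type <- as.character(gr$type)
  id <- if (!is.null(gr$ID)) as.character(gr$ID) else rep(NA_character_, length(gr))
  parent <- if (!is.null(gr$Parent)) {
    vapply(gr$Parent, function(p) if (length(p)) as.character(p[1]) else NA_character_,
           character(1))
  } else rep(NA_character_, length(gr))

  is_gene <- type == "gene"
  is_tx <- type %in% c("mRNA", "transcript")
  genes <- tibble(gene_id = id[is_gene],
                  chrom = as.character(GenomicRanges::seqnames(gr))[is_gene],
                  strand = as.character(GenomicRanges::strand(gr))[is_gene])
  tx <- tibble(transcript_id = id[is_tx], gene_id = parent[is_tx])
  if (any(is.na(tx$gene_id))) {
    abort(sprintf("transcript without parent gene: %s",
                  paste(head(tx$transcript_id[is.na(tx$gene_id)], 5), collapse = ", ")))
  }
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  exons <- tibble(transcript_id = parent[type == "exon"],
                  start = start0[type == "exon"], end = end0[type == "exon"])
  cds <- tibble(transcript_id = parent[type == "CDS"],
                start = start0[type == "CDS"], end = end0[type == "CDS"])
  genome_annotation(genes, tx, exons, cds)
}

parse_gtf_granges <- function(gr) {
  type <- as.character(gr$type)
  if (is.null(gr$gene_id) || is.null(gr$transcript_id)) {
    abort("GTF input lacks gene_id/transcript_id attributes")
  }
  is_feat <- type %in% c("exon", "CDS")
  tx_ids <- as.character(gr$transcript_id)
  gene_ids <- as.character(gr$gene_id)
  if (any(is_feat & (is.na(tx_ids) | is.na(gene_ids)))) {
    abort("GTF exon/CDS feature without gene_id or transcript_id")
  }
  feat <- tibble(type = type[is_feat],
                 transcript_id = tx_ids[is_feat],
                 gene_id = gene_ids[is_feat],
                 chrom = as.character(GenomicRanges::seqnames(gr))[is_feat],
                 strand = as.character(GenomicRanges::strand(gr))[is_feat],
                 start = GenomicRanges::start(gr)[is_feat] - 1L,
                 end = GenomicRanges::end(gr)[is_feat])
  genes <- feat |>
    distinct(.data$gene_id, .data$chrom, .data$strand) |>
    rename(gene_id = "gene_id")
  if (anyDuplicated(genes$gene_id)) {
    abort("GTF gene with inconsistent chrom/strand across features")
  }
  tx <- distinct(feat, .data$transcript_id, .data$gene_id)
  exons <- feat[feat$type == "exon", c("transcript_id", "start", "end")]
  cds <- feat[feat$type == "CDS", c("transcript_id", "start", "end")]
  genome_annotation(genes, tx, exons, cds)
}

#' Write a genome_annotation back to GFF3
#'
#' Emits gene, mRNA, exon and CDS features (1-based inclusive coordinates)
#' such that [parse_annotation()] on the output reproduces the object.
#'
#' @param annotation a [genome_annotation()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "genome_annotation"))
  g <- annotation$genes
  tx <- annotation$transcripts
  ex <- left_join(annotation$exons,
                  tx[, c("transcript_id", "gene_id")], by = "transcript_id")
  cc <- left_join(annotation$cds,
                  tx[, c("transcript_id", "gene_id")], by = "transcript_id")
  gene_of <- setNames(g$chrom, g$gene_id)
  strand_of <- setNames(g$strand, g$gene_id)

  # gene spans = hull of exons of their transcripts
  tx_span <- ex |>
    group_by(.data$transcript_id, .data$gene_id) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  g_span <- tx_span |>
    group_by(.data$gene_id) |>
    summarise(start = min(.data$start), end = max(.data$end))

  fmt <- function(chrom, type, s0, e0, strand, attr) {
    sprintf("%s\tmztarch\t%s\t%d\t%d\t.\t%s\t%s\t%s",
            chrom, type, s0 + 1L, e0, strand,
            if (type == "CDS") "0" else ".", attr)
  }
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(g_span))) {
    gid <- g_span$gene_id[i]
    lines <- c(lines, fmt(gene_of[[gid]], "gene", g_span$start[i], g_span$end[i],
                          strand_of[[gid]], sprintf("ID=%s", gid)))
    txs <- tx_span[tx_span$gene_id == gid, , drop = FALSE]
    for (j in seq_len(nrow(txs))) {
      tid <- txs$transcript_id[j]
      lines <- c(lines, fmt(gene_of[[gid]], "mRNA", txs$start[j], txs$end[j],
                            strand_of[[gid]], sprintf("ID=%s;Parent=%s", tid, gid)))
      exj <- ex[ex$transcript_id == tid, , drop = FALSE]
      lines <- c(lines, fmt(gene_of[[gid]], "exon", exj$start, exj$end,
                            strand_of[[gid]], sprintf("Parent=%s", tid)))
      ccj <- cc[cc$transcript_id == tid, , drop = FALSE]
      if (nrow(ccj) > 0L) {
        lines <- c(lines, fmt(gene_of[[gid]], "CDS", ccj$start, ccj$end,
                              strand_of[[gid]], sprintf("Parent=%s", tid)))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Coding intervals of one chromosome
#'
#' Returns the coordinate-sorted list of coding intervals (the union over all
#' transcripts of CDS-overlapping exon segments, merged within each gene) on
#' one chromosome, both strands together, each tagged with its owning gene.
#'
#' @param annotation a [genome_annotation()].
#' @param chrom chromosome name.
#' @return tibble with columns `start`, `end` (0-based half-open), `gene_id`.
#' @export
coding_intervals <- function(annotation, chrom) {
  stopifnot(inherits(annotation, "genome_annotation"))
  if (!(chrom %in% annotation$genes$chrom)) {
    abort(sprintf("unknown chromosome: %s", chrom))
  }
  out <- annotation$coding[annotation$coding$chrom == chrom,
                           c("start", "end", "gene_id")]
  arrange(out, .data$start, .data$end)
}

#' Attach operon membership to an annotation
#'
#' @param annotation a [genome_annotation()].
#' @param operons tibble with columns `gene_id`, `operon_id`, `position`
#'   (1 = 5'-most gene of the operon).
#' @return The annotation with operon columns filled in on `genes`.
#' @export
add_operons <- function(annotation, operons) {
  stopifnot(inherits(annotation, "genome_annotation"))
  operons <- as_tibble(operons)
  assert_cols(operons, c("gene_id", "operon_id", "position"), "operon table")
  unknown <- setdiff(operons$gene_id, annotation$genes$gene_id)
  if (length(unknown) > 0L) {
    abort(sprintf("operon table references unknown gene(s): %s",
                  paste(head(unknown, 5), collapse = ", ")))
  }
  idx <- match(annotation$genes$gene_id, operons$gene_id)
  annotation$genes$operon_id <- operons$operon_id[idx]
  annotation$genes$operon_position <- as.integer(operons$position[idx])
  annotation
}
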