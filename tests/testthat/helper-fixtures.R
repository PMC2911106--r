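# Hand-built fixtures. Coordinates in comments are 0-based half-open.

# one gene with arbitrary transcripts; exons/cds are lists of c(start, end)
make_tx <- function(transcript_id, exons, cds) {
  list(transcript_id = transcript_id,
       exons = do.call(rbind, exons), cds = do.call(rbind, cds))
}

build_ann <- function(genes) {
  g_rows <- list()
  t_rows <- list()
  e_rows <- list()
  c_rows <- list()
  for (g in genes) {
    g_rows[[length(g_rows) + 1L]] <-
      tibble::tibble(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand)
    for (tx in g$transcripts) {
      t_rows[[length(t_rows) + 1L]] <-
        tibble::tibble(transcript_id = tx$transcript_id, gene_id = g$gene_id)
      e_rows[[length(e_rows) + 1L]] <-
        tibble::tibble(transcript_id = tx$transcript_id,
                       start = tx$exons[, 1], end = tx$exons[, 2])
      if (!is.null(tx$cds) && nrow(tx$cds) > 0L) {
        c_rows[[length(c_rows) + 1L]] <-
          tibble::tibble(transcript_id = tx$transcript_id,
                         start = tx$cds[, 1], end = tx$cds[, 2])
      }
    }
  }
  genome_annotation(dplyr::bind_rows(g_rows), dplyr::bind_rows(t_rows),
                    dplyr::bind_rows(e_rows),
                    if (length(c_rows)) dplyr::bind_rows(c_rows) else
                      tibble::tibble(transcript_id = character(),
                                     start = integer(), end = integer()))
}

simple_gene <- function(gene_id, chrom, strand, exons, cds,
                        transcript_id = paste0(gene_id, ".t1")) {
  list(gene_id = gene_id, chrom = chrom, strand = strand,
       transcripts = list(make_tx(transcript_id, exons, cds)))
}

# two-gene fixture: gA on +, two exons with 5'/3' UTRs; gB on -, single exon
fixture_gff3_lines <- function() {
  f <- function(...) paste(..., sep = "\t")
  c("##gff-version 3",
    f("chr1", "test", "gene", 101, 400, ".", "+", ".", "ID=gA"),
    f("chr1", "test", "mRNA", 101, 400, ".", "+", ".", "ID=gA.t1;Parent=gA"),
    f("chr1", "test", "exon", 101, 200, ".", "+", ".", "Parent=gA.t1"),
    f("chr1", "test", "exon", 301, 400, ".", "+", ".", "Parent=gA.t1"),
    f("chr1", "test", "CDS", 151, 200, ".", "+", "0", "Parent=gA.t1"),
    f("chr1", "test", "CDS", 301, 350, ".", "+", "0", "Parent=gA.t1"),
    f("chr1", "test", "gene", 601, 900, ".", "-", ".", "ID=gB"),
    f("chr1", "test", "mRNA", 601, 900, ".", "-", ".", "ID=gB.t1;Parent=gB"),
    f("chr1", "test", "exon", 601, 900, ".", "-", ".", "Parent=gB.t1"),
    f("chr1", "test", "CDS", 651, 850, ".", "-", "0", "Parent=gB.t1"))
}

fixture_gtf_lines <- function() {
  f <- function(...) paste(..., sep = "\t")
  at <- function(g, t) sprintf('gene_id "%s"; transcript_id "%s";', g, t)
  c(f("chr1", "test", "transcript", 101, 400, ".", "+", ".", at("gA", "gA.t1")),
    f("chr1", "test", "exon", 101, 200, ".", "+", ".", at("gA", "gA.t1")),
    f("chr1", "test", "exon", 301, 400, ".", "+", ".", at("gA", "gA.t1")),
    f("chr1", "test", "CDS", 151, 200, ".", "+", "0", at("gA", "gA.t1")),
    f("chr1", "test", "CDS", 301, 350, ".", "+", "0", at("gA", "gA.t1")),
    f("chr1", "test", "transcript", 601, 900, ".", "-", ".", at("gB", "gB.t1")),
    f("chr1", "test", "exon", 601, 900, ".", "-", ".", at("gB", "gB.t1")),
    f("chr1", "test", "CDS", 651, 850, ".", "-", "0", at("gB", "gB.t1")))
}

write_fixture <- function(lines, ext) {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# compare two genome_annotation objects on content (row order normalised);
# operon membership travels in the operon TSV, not in GFF3, so the operon
# columns are compared only when both objects carry them
expect_same_annotation <- function(a, b) {
  strip_op <- function(g) g[, setdiff(names(g), c("operon_id", "operon_position"))]
  norm <- function(x) {
    list(genes = dplyr::arrange(strip_op(x$genes), gene_id),
         transcripts = dplyr::arrange(x$transcripts, transcript_id),
         exons = dplyr::arrange(x$exons, transcript_id, start),
         cds = dplyr::arrange(x$cds, transcript_id, start),
         coding = dplyr::arrange(x$coding, chrom, start, gene_id))
  }
  na <- norm(a)
  nb <- norm(b)
  for (nm in names(na)) {
    expect_equal(as.data.frame(na[[nm]]), as.data.frame(nb[[nm]]),
                 ignore_attr = TRUE, label = nm)
  }
}
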