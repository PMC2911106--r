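test_that("a minimal two-gene GFF3 fixture parses with correct structure", {
  path <- write_fixture(fixture_gff3_lines(), ".gff3")
  ann <- parse_annotation(path, "gff3")
  expect_s3_class(ann, "genome_annotation")
  expect_equal(nrow(ann$genes), 2L)
  expect_equal(ann$genes$strand[match(c("gA", "gB"), ann$genes$gene_id)],
               c("+", "-"))
  # internal coordinates are 0-based half-open
  gA_cds <- ann$cds[ann$cds$transcript_id == "gA.t1", ]
  expect_equal(gA_cds$start, c(150, 300))
  expect_equal(gA_cds$end, c(200, 350))
})

test_that("two transcripts sharing a CDS start but differing 3' UTR ends live under one gene", {
  g <- list(gene_id = "gA", chrom = "chr1", strand = "+",
            transcripts = list(
              make_tx("gA.t1", list(c(100, 400)), list(c(150, 300))),
              make_tx("gA.t2", list(c(100, 500)), list(c(150, 300)))))
  ann <- build_ann(list(g, simple_gene("gB", "chr1", "+", list(c(700, 800)),
                                       list(c(700, 800)))))
  expect_equal(nrow(ann$genes), 2L)
  expect_equal(sum(ann$transcripts$gene_id == "gA"), 2L)
  u <- utr_lengths("gA", ann)
  expect_equal(u$utr3, 200L) # max over isoforms: 400->500 vs 300->400
})

test_that("the GTF dialect of the same models parses to an identical annotation", {
  p1 <- write_fixture(fixture_gff3_lines(), ".gff3")
  p2 <- write_fixture(fixture_gtf_lines(), ".gtf")
  expect_same_annotation(parse_annotation(p1, "gff3"),
                         parse_annotation(p2, "gtf"))
})

test_that("writing to GFF3 and re-parsing round-trips the annotation", {
  sim <- simulate_genome(sim_config(seed = 11, n_genes = 40,
                                    operon_fraction = 0.2))
  path <- withr::local_tempfile(fileext = ".gff3")
  write_annotation(sim$annotation, path)
  reparsed <- parse_annotation(path, "gff3")
  expect_same_annotation(sim$annotation, reparsed)
  # operon membership is carried by the operon table, re-attached after parse
  reparsed_op <- add_operons(reparsed, sim$operons)
  expect_equal(
    reparsed_op$genes$operon_id[match(sim$annotation$genes$gene_id,
                                      reparsed_op$genes$gene_id)],
    sim$annotation$genes$operon_id)
})

test_that("structural errors are rejected with informative messages", {
  bad <- fixture_gff3_lines()
  bad[4] <- "chr1\ttest\texon\t101"
  expect_error(parse_annotation(write_fixture(bad, ".gff3")), "line 4")

  orphan <- c("##gff-version 3",
              "chr1\ttest\tmRNA\t101\t400\t.\t+\t.\tID=t1",
              "chr1\ttest\texon\t101\t400\t.\t+\t.\tParent=t1",
              "chr1\ttest\tCDS\t101\t400\t.\t+\t0\tParent=t1")
  expect_error(parse_annotation(write_fixture(orphan, ".gff3")),
               "without parent gene")

  expect_error(
    build_ann(list(simple_gene("gX", "chr1", "+",
                               exons = list(c(100, 200)),
                               cds = list(c(150, 250))))),
    "CDS outside exons.*gX")
})

test_that("genes without CDS are skipped with a reason, not dropped silently", {
  genes <- list(
    simple_gene("coding", "chr1", "+", list(c(100, 200)), list(c(100, 200))),
    list(gene_id = "ncrna", chrom = "chr1", strand = "+",
         transcripts = list(make_tx("ncrna.t1", list(c(300, 400)), list())))
  )
  ann <- build_ann(genes)
  expect_equal(ann$genes$gene_id, "coding")
  expect_equal(ann$skipped$gene_id, "ncrna")
  expect_match(ann$skipped$reason, "no CDS")
})

test_that("coding_intervals merges isoforms and excludes UTR-only exons", {
  # single-exon gene: one interval equal to its CDS
  ann1 <- build_ann(list(simple_gene("g1", "chr1", "+",
                                     list(c(100, 200)), list(c(100, 200)))))
  ci <- coding_intervals(ann1, "chr1")
  expect_equal(as.data.frame(ci),
               data.frame(start = 100, end = 200, gene_id = "g1"))
  expect_error(coding_intervals(ann1, "chrX"), "unknown chromosome")

  # opposite strands interleave into one sorted list
  ann2 <- build_ann(list(
    simple_gene("g1", "chr1", "+", list(c(100, 200)), list(c(100, 200))),
    simple_gene("g2", "chr1", "-", list(c(300, 400)), list(c(300, 400)))))
  ci2 <- coding_intervals(ann2, "chr1")
  expect_equal(ci2$gene_id, c("g1", "g2"))
  expect_true(!is.unsorted(ci2$start))

  # multi-exon gene whose first exon is pure 5' UTR
  g <- simple_gene("g3", "chr1", "+",
                   exons = list(c(100, 150), c(200, 300)),
                   cds = list(c(220, 280)))
  ann3 <- build_ann(list(g))
  ci3 <- coding_intervals(ann3, "chr1")
  expect_equal(as.data.frame(ci3),
               data.frame(start = 220, end = 280, gene_id = "g3"))
})

test_that("coding intervals equal maximal runs of the brute-force coding mask", {
  for (seed in c(3, 17)) {
    sim <- simulate_genome(sim_config(seed = seed, n_genes = 50,
                                      operon_fraction = 0.1))
    coding_pos <- oracle_coding_positions(sim$annotation)
    for (ch in unique(sim$annotation$genes$chrom)) {
      runs <- oracle_coding_runs(sim$annotation, coding_pos, ch)
      ci <- coding_intervals(sim$annotation, ch)
      # merge per-gene intervals across genes before comparing to the mask
      merged <- IRanges::reduce(IRanges::IRanges(ci$start + 1L, ci$end))
      expect_equal(IRanges::start(merged) - 1L, runs$start)
      expect_equal(IRanges::end(merged), runs$end)
    }
  }
})
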