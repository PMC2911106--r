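# gene gU with coding ending at 200 (half-open), gene gV starting at 300:
# the 100 bases in between are gV's 5' IGR and gU's 3' IGR
tandem_ann <- function() {
  build_ann(list(
    simple_gene("gU", "chr1", "+", list(c(100, 200)), list(c(100, 200))),
    simple_gene("gV", "chr1", "+", list(c(300, 450)), list(c(300, 450)))))
}

test_that("5' IGR is the strand-aware distance to the nearest other-gene coding base", {
  ann <- tandem_ann()
  expect_equal(five_prime_igr("gV", ann), 100L)
  expect_equal(three_prime_igr("gU", ann), 100L)
  # gap symmetry of mutual neighbours
  expect_equal(three_prime_igr("gU", ann), five_prime_igr("gV", ann))

  # overlapping CDS at the 5' end gives 0
  ann_ov <- build_ann(list(
    simple_gene("gU", "chr1", "+", list(c(100, 320)), list(c(100, 320))),
    simple_gene("gV", "chr1", "+", list(c(300, 450)), list(c(300, 450)))))
  expect_equal(five_prime_igr("gV", ann_ov), 0L)

  # only gene on its chromosome: censored in both directions
  solo <- build_ann(list(simple_gene("gS", "chr9", "-",
                                     list(c(100, 200)), list(c(100, 200)))))
  expect_true(is.na(five_prime_igr("gS", solo)))
  expect_true(is.na(three_prime_igr("gS", solo)))
  expect_error(five_prime_igr("nope", solo), "not in annotation")
})

test_that("minus-strand genes measure the 3' IGR leftward in genomic coordinates", {
  ann <- build_ann(list(
    simple_gene("gL", "chr1", "+", list(c(100, 200)), list(c(100, 200))),
    simple_gene("gM", "chr1", "-", list(c(260, 400)), list(c(260, 400)))))
  # gM 3' end is its genomic start (260); nearest other coding base is 199
  expect_equal(three_prime_igr("gM", ann), 60L)
  # and its 5' direction (rightward) has no neighbour
  expect_true(is.na(five_prime_igr("gM", ann)))
})

test_that("first-intron measures follow the max-over-isoforms and non-coding-run rules", {
  intronless <- build_ann(list(simple_gene("g1", "chr1", "+",
                                           list(c(100, 400)), list(c(150, 350)))))
  fi <- first_intron_lengths("g1", intronless)
  expect_equal(fi, list(intron1_max = 0L, intron1_noncoding = 0L))

  # two isoforms with first introns of 80 and 120 bp
  g <- list(gene_id = "g2", chrom = "chr1", strand = "+", transcripts = list(
    make_tx("g2.t1", list(c(100, 200), c(280, 400)),
            list(c(150, 200), c(280, 350))),
    make_tx("g2.t2", list(c(100, 200), c(320, 440)),
            list(c(150, 200), c(320, 390)))))
  ann2 <- build_ann(list(g))
  expect_equal(first_intron_lengths("g2", ann2)$intron1_max, 120L)

  # a nested gene's 30 bp CDS inside the 120 bp intron splits it into runs
  # of 40 and 50; the non-coding measure takes the larger flank
  nested <- build_ann(list(
    simple_gene("host", "chr1", "+", list(c(100, 200), c(320, 440)),
                list(c(150, 200), c(320, 390))),
    simple_gene("guest", "chr1", "+", list(c(240, 270)), list(c(240, 270)))))
  fi2 <- first_intron_lengths("host", nested)
  expect_equal(fi2$intron1_max, 120L)
  expect_equal(fi2$intron1_noncoding, 50L)
})

test_that("UTRs shorter than the artifact thresholds are reported absent", {
  # 4 bp 3' UTR and 2 bp 5' UTR both fall below the thresholds
  ann <- build_ann(list(simple_gene("g1", "chr1", "+",
                                    list(c(100, 306)), list(c(102, 302)))))
  u <- utr_lengths("g1", ann)
  expect_true(is.na(u$utr3))
  expect_true(is.na(u$utr5))
  # the same regions survive when the thresholds are lowered
  u_loose <- utr_lengths("g1", ann, utr3_min = 0L, utr5_min = 0L)
  expect_equal(u_loose$utr3, 4L)
  expect_equal(u_loose$utr5, 2L)
})

test_that("multi-exon 3' UTR isoforms are excluded from the maximum unless allowed", {
  g <- list(gene_id = "g1", chrom = "chr1", strand = "+", transcripts = list(
    make_tx("t.a", list(c(100, 450)), list(c(100, 300))),   # 150 bp, 1 exon
    make_tx("t.b", list(c(100, 600)), list(c(100, 300))),   # 300 bp, 1 exon
    make_tx("t.c", list(c(100, 400), c(500, 900)),          # 500 bp over 2 exons
            list(c(100, 300)))))
  ann <- build_ann(list(g))
  u <- utr_lengths("g1", ann, allow_multiexon_utr3 = FALSE)
  expect_equal(u$utr3, 300L)
  expect_true(u$utr3_multiexon)
  u2 <- utr_lengths("g1", ann, allow_multiexon_utr3 = TRUE)
  expect_equal(u2$utr3, 500L)

  # when every isoform is multi-exon the 3' UTR is absent under the exclusion
  g_only <- list(gene_id = "g2", chrom = "chr1", strand = "+", transcripts =
                   list(make_tx("t.d", list(c(100, 400), c(500, 900)),
                                list(c(100, 300)))))
  ann2 <- build_ann(list(g_only))
  expect_true(is.na(utr_lengths("g2", ann2)$utr3))
})

test_that("operon genes beyond the first are excluded from 5' IGR analyses", {
  genes <- list(
    simple_gene("a", "chr1", "+", list(c(1000, 1500)), list(c(1000, 1500))),
    simple_gene("b", "chr1", "+", list(c(1600, 2100)), list(c(1600, 2100))),
    simple_gene("c", "chr1", "+", list(c(2200, 2700)), list(c(2200, 2700))))
  ann <- build_ann(genes)
  operons <- tibble::tibble(gene_id = c("a", "b", "c"),
                            operon_id = "op1", position = 1:3)
  tab <- compute_region_table(ann, operons = operons)
  expect_equal(tab$included_in_igr5_set[match(c("a", "b", "c"), tab$gene_id)],
               c(TRUE, FALSE, FALSE))
  expect_error(
    compute_region_table(ann, operons = tibble::tibble(
      gene_id = "zz", operon_id = "op1", position = 1)),
    "unknown gene")
})

test_that("trans-spliced (worm mode) genomes omit the summed-UTR variant", {
  sim <- simulate_genome(sim_config(seed = 5, n_genes = 30))
  tab_worm <- compute_region_table(sim$annotation,
                                   species_flags = list(trans_spliced = TRUE))
  tab_std <- compute_region_table(sim$annotation)
  expect_false("utr5_plus_utr3" %in% names(tab_worm))
  expect_true("utr5_plus_utr3" %in% names(tab_std))
  # combined variants are the sums of their components where all are present
  ok <- !is.na(tab_std$igr5) & !is.na(tab_std$igr3)
  expect_equal(tab_std$igr5_plus_igr3[ok], (tab_std$igr5 + tab_std$igr3)[ok])
  expect_equal(tab_std$igr5_plus_intron1_plus_igr3[ok],
               (tab_std$igr5 + tab_std$intron1_max + tab_std$igr3)[ok])
})

test_that("every metric matches the per-base brute-force oracle on synthetic genomes", {
  for (seed in c(2, 23, 101)) {
    sim <- simulate_genome(sim_config(seed = seed, n_genes = 50,
                                      operon_fraction = 0.15,
                                      alt_splice_prob = 0.3))
    got <- compute_region_table(sim$annotation)
    want <- oracle_region_table(sim$annotation)
    got <- got[match(want$gene_id, got$gene_id), ]
    for (col in c("igr5", "igr3", "intron1_max", "intron1_noncoding",
                  "utr5", "utr3", "utr3_multiexon")) {
      expect_equal(got[[col]], want[[col]], ignore_attr = TRUE,
                   label = sprintf("%s (seed %d)", col, seed))
    }
  }
})

test_that("combined transcriptional variants correlate strongly with the 5' IGR", {
  sim <- simulate_genome(sim_config(seed = 42, n_genes = 300))
  tab <- compute_region_table(sim$annotation)
  for (v in c("igr5_plus_intron1", "igr5_plus_igr3",
              "igr5_plus_intron1_plus_igr3")) {
    ok <- !is.na(tab$igr5) & !is.na(tab[[v]])
    ct <- suppressWarnings(
      cor.test(tab$igr5[ok], tab[[v]][ok], method = "spearman"))
    expect_gt(ct$estimate, 0)
    expect_lt(ct$p.value, 0.01)
  }
})

test_that("lowering the UTR thresholds never decreases the count of present UTRs", {
  sim <- simulate_genome(sim_config(seed = 8, n_genes = 80))
  counts <- sapply(c(10L, 5L, 1L, 0L), function(th) {
    tab <- compute_region_table(sim$annotation, utr3_min = th, utr5_min = th)
    c(sum(!is.na(tab$utr3)), sum(!is.na(tab$utr5)))
  })
  expect_true(all(diff(counts[1, ]) >= 0))
  expect_true(all(diff(counts[2, ]) >= 0))
})
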