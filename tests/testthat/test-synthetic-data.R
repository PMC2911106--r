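test_that("the generator is deterministic, down to the written GFF3 bytes", {
  cfg <- sim_config(seed = 19, n_genes = 50, operon_fraction = 0.1)
  s1 <- simulate_genome(cfg)
  s2 <- simulate_genome(cfg)
  expect_identical(s1, s2)
  p1 <- withr::local_tempfile(fileext = ".gff3")
  p2 <- withr::local_tempfile(fileext = ".gff3")
  write_annotation(s1$annotation, p1)
  write_annotation(s2$annotation, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(simulate_expression(s1$truth, cfg),
                   simulate_expression(s2$truth, cfg))
})

test_that("with no planted effects, class lengths are indistinguishable from the genome", {
  rejections <- 0L
  for (seed in 1:15) {
    sim <- simulate_genome(sim_config(seed = 300 + seed, n_genes = 250))
    tab <- compute_region_table(sim$annotation)
    maternal <- sim$truth$gene_id[sim$truth$all_maternal]
    a <- tab$igr5[tab$gene_id %in% maternal & !is.na(tab$igr5)]
    b <- tab$igr5[!is.na(tab$igr5)]
    if (ks_one_sided(a, b)$p < 0.05) rejections <- rejections + 1L
  }
  # ~ Binomial(15, 0.05) under the null construction
  expect_lte(rejections, 4L)
})

test_that("a planted maternal 3' UTR truncation is recovered by the sweep", {
  eff <- list(strict_maternal = list(utr3_left_truncation_percentile = 20),
              mostly_maternal = list(utr3_left_truncation_percentile = 20),
              maternal_zygotic = list(utr3_left_truncation_percentile = 20))
  sim <- simulate_genome(sim_config(seed = 77, n_genes = 1500,
                                    class_effects = eff))
  tab <- compute_region_table(sim$annotation)
  maternal <- sim$truth$gene_id[sim$truth$all_maternal]
  a <- tab$utr3[tab$gene_id %in% maternal & !is.na(tab$utr3)]
  b <- tab$utr3[!(tab$gene_id %in% maternal) & !is.na(tab$utr3)]
  sw <- percentile_sweep(a, b)
  expect_lt(sw$p_min, 1e-4)
  expect_equal(sw$q_top_significant, 100)
  # the under-representation of short 3' UTRs is already visible in the
  # lowest percentile subsets
  low_q <- sw$per_q$p[sw$per_q$q <= 30]
  expect_true(any(low_q < 0.05))
})

test_that("simulated expression matches the class-conditional construction", {
  cfg <- sim_config(seed = 23, n_genes = 300)
  sim <- simulate_genome(cfg)
  expr <- simulate_expression(sim$truth, cfg)
  sz <- expr[expr$gene_id %in%
               sim$truth$gene_id[sim$truth$origin_class == "strict_zygotic"], ]
  # strict-zygotic genes sit below the presence threshold before the MZT
  pre_cols <- attr(expr, "timepoints")[seq_len(attr(expr, "mzt_index"))]
  expect_true(all(sz[, pre_cols] < cfg$presence_call))
  expect_true(all(sz$maternal == 0))
})

test_that("phylogenetic profiles reproduce the true conservation classes exactly", {
  cfg <- sim_config(seed = 29, n_genes = 300)
  sim <- simulate_genome(cfg)
  prof <- simulate_phylo_profiles(sim$truth, cfg)
  cls <- classify_conservation(prof$profiles, prof$taxon_kinds)
  expect_equal(cls$conservation_class, sim$truth$conservation_class)
})

test_that("zero-noise orthologs preserve ranks exactly; planted shifts are pair-specific", {
  cfg <- sim_config(seed = 37, n_genes = 400)
  sim <- simulate_genome(cfg)
  tab <- compute_region_table(sim$annotation)
  ortho <- simulate_orthologs(tab, sim$truth, cfg)
  ranks_a <- percentile_ranks(tab[tab$included_in_igr5_set, ])
  fc <- rank_fold_changes(ortho$pairs_b, ranks_a,
                          percentile_ranks(ortho$lengths_b))
  expect_true(all(fc$log2_fc == 0))

  cfg2 <- cfg
  cfg2$ortholog_rank_noise <- 0.05
  cfg2$maternal_rank_shift <- 0.2
  ortho2 <- simulate_orthologs(tab, sim$truth, cfg2)
  fc_b <- rank_fold_changes(ortho2$pairs_b, ranks_a,
                            percentile_ranks(ortho2$lengths_b))
  fc_c <- rank_fold_changes(ortho2$pairs_c, ranks_a,
                            percentile_ranks(ortho2$lengths_c))
  ks_b <- compare_maternal_vs_all(fc_b, ortho2$maternal_pairs_b)
  ks_c <- compare_maternal_vs_all(fc_c, ortho2$maternal_pairs_c)
  expect_lt(ks_b$p, 0.01)   # shifted ("chicken-like") pair
  expect_gt(ks_c$p, 0.05)   # untouched pair

  # with zero maternal overlap the downstream comparison errors cleanly
  cfg3 <- cfg
  cfg3$maternal_overlap <- 0
  ortho3 <- simulate_orthologs(tab, sim$truth, cfg3)
  expect_error(compare_maternal_vs_all(fc, ortho3$maternal_pairs_b), "empty")
})

test_that("operon genes are consecutive, plus-strand and tightly packed", {
  sim <- simulate_genome(sim_config(seed = 41, n_genes = 200,
                                    operon_fraction = 0.3))
  expect_gt(nrow(sim$operons), 0L)
  g <- sim$annotation$genes
  op_strand <- g$strand[match(sim$operons$gene_id, g$gene_id)]
  expect_true(all(op_strand == "+"))
  # within every operon, positions run 1..k
  by_op <- split(sim$operons$position, sim$operons$operon_id)
  for (pos in by_op) expect_equal(sort(pos), seq_along(pos))
})
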