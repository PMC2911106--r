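panel_kinds <- function() {
  tibble::tibble(
    taxon = c("yeast", "pombe", "arabidopsis", "rice", "fly", "worm", "fish",
              "mouse"),
    kind = c("unicellular", "unicellular", "plant", "plant", "animal",
             "animal", "animal", "animal"))
}

profile_row <- function(gene_id, present) {
  k <- panel_kinds()
  row <- as.list(setNames(as.integer(k$taxon %in% present), k$taxon))
  tibble::as_tibble(c(list(gene_id = gene_id), row))
}

test_that("conservation classes follow the phylogenetic profiling rules", {
  profiles <- dplyr::bind_rows(
    profile_row("unicell_only", "yeast"),
    profile_row("animals3", c("fly", "worm", "fish")),
    profile_row("animals_plus_plant", c("fly", "worm", "arabidopsis")),
    profile_row("one_animal", "fly"),
    profile_row("nothing", character()))
  cls <- classify_conservation(profiles, panel_kinds())
  expect_equal(setNames(cls$conservation_class, cls$gene_id),
               c(unicell_only = "core", animals3 = "metazoan",
                 animals_plus_plant = "other", one_animal = "other",
                 nothing = "other"))
  # classes are exhaustive and mutually exclusive by construction
  expect_true(all(cls$conservation_class %in% c("core", "metazoan", "other")))

  bad_kinds <- panel_kinds()[panel_kinds()$kind != "plant", ]
  expect_error(
    classify_conservation(profiles[, c("gene_id", bad_kinds$taxon)], bad_kinds),
    ">=1 plant")
})

test_that("decoupled maternal/zygotic components classify per the stated rules", {
  tp <- c("t1", "t2", "t3")
  data <- tibble::tribble(
    ~gene_id, ~maternal, ~zygotic, ~t1, ~t2, ~t3,
    "sm", 100, 0, 100, 25, 25,      # 4-fold decrease, no zygotic part
    "mm", 80, 20, 100, 25, 25,      # decrease with 20% zygotic fraction
    "mz", 100, 10, 100, 95, 105,    # flat profile
    "sz", 0, 100, 0, 100, 100,      # post-MZT only, no maternal
    "moz", 0.5, 100, 0, 100, 100,   # post-MZT with small maternal fraction
    "off", 0, 0, 0, 0, 0)
  cls <- classify_origin_decoupled(data, tp)
  expect_equal(as.character(cls$origin_class),
               c("strict_maternal", "mostly_maternal", "maternal_zygotic",
                 "strict_zygotic", "mostly_zygotic", "unclassified"))
  # every maternal-detected gene is in the all-maternal set
  expect_equal(cls$all_maternal, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  # each gene gets exactly one class
  expect_equal(nrow(cls), nrow(data))
  expect_true(!anyNA(cls$origin_class))
  expect_error(classify_origin_decoupled(
    dplyr::mutate(data, maternal = -1), tp), "non-negative")
})

test_that("time-course classification needs presence before and reduction after the MZT", {
  tp <- c("t1", "t2", "t3")
  data <- tibble::tribble(
    ~gene_id, ~t1, ~t2, ~t3,
    "mat", 90, 20, 15,     # present, then >= 3-fold reduced at every point
    "zyg", 0, 50, 60,      # absent pre, present post
    "flat", 80, 75, 90,    # present, never reduced
    "mixed", 90, 20, 80,   # reduced at one point only
    "zero", 0, 0, 0)
  cls <- classify_origin_timecourse(data, tp, mzt_index = 1)
  expect_equal(as.character(cls$origin_class),
               c("strict_maternal", "strict_zygotic", "maternal_zygotic",
                 "unclassified", "unclassified"))
  expect_error(classify_origin_timecourse(data, tp, mzt_index = 3),
               "mzt_index")
})

test_that("rank classification keeps ties at the cutoff and nests across thresholds", {
  data <- tibble::tibble(gene_id = sprintf("g%03d", 1:100),
                         abundance = 100:1)
  expect_length(classify_origin_rank(data, 0.5), 50L)

  # a tie spanning the cutoff rank keeps both tied genes
  tied <- tibble::tibble(gene_id = c("a", "b", "c", "d"),
                         abundance = c(10, 5, 5, 1))
  expect_setequal(classify_origin_rank(tied, 0.5), c("a", "b", "c"))

  withr::with_seed(99, {
    tab <- tibble::tibble(gene_id = sprintf("g%04d", 1:400),
                          abundance = rlnorm(400, 3, 1))
  })
  sets <- lapply(seq(0.05, 0.5, by = 0.05),
                 function(f) classify_origin_rank(tab, f))
  for (i in seq_along(sets)[-1]) {
    expect_true(all(sets[[i - 1]] %in% sets[[i]]))
  }
  expect_error(classify_origin_rank(
    tibble::tibble(gene_id = "g", abundance = 0), 0.5), "presence")
})

test_that("classifiers recover simulated class labels at >= 95% under noise", {
  cfg <- sim_config(seed = 31, n_genes = 400, noise_sd_log2 = 0.2)
  sim <- simulate_genome(cfg)
  expr <- simulate_expression(sim$truth, cfg)
  tp <- attr(expr, "timepoints")

  dec <- classify_origin_decoupled(expr, tp)
  acc_dec <- mean(as.character(dec$origin_class) ==
                    as.character(sim$truth$origin_class))
  expect_gte(acc_dec, 0.95)

  tc <- classify_origin_timecourse(expr, tp, attr(expr, "mzt_index"))
  acc_tc <- mean(as.character(tc$origin_class) ==
                   as.character(sim$truth$timecourse_class))
  expect_gte(acc_tc, 0.95)

  # and exactly, without noise
  cfg0 <- sim_config(seed = 31, n_genes = 400, noise_sd_log2 = 0)
  expr0 <- simulate_expression(sim$truth, cfg0)
  tc0 <- classify_origin_timecourse(expr0, tp, attr(expr0, "mzt_index"))
  expect_equal(as.character(tc0$origin_class),
               as.character(sim$truth$timecourse_class))
})

test_that("label tables read from TSV are validated and completed", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    gene_id = c("a", "b"), origin_class = c("strict_maternal", "unclassified")),
    path)
  lab <- read_origin_labels(path)
  expect_equal(lab$all_maternal, c(TRUE, FALSE))
  readr::write_tsv(tibble::tibble(gene_id = "a", origin_class = "bogus"), path)
  expect_error(read_origin_labels(path), "unknown origin class")
})
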