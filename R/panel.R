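#' Generate the packaged six-species synthetic panel
#'
#' Builds a panel of six synthetic species emulating the comparative study
#' design: three high-nutrition species (fly-, worm- and fish-like) with
#' maternal 5' IGRs planted shorter than the genome average and zygotic 5'
#' IGRs planted longer, one medium-nutrition species (chick-like) with a
#' mild maternal shortening, and two low-nutrition species (mouse- and
#' human-like) with maternal 5' IGRs planted *longer* than the genome
#' average — so the maternal-to-genome ratio decreases with the amount of
#' maternal nutritional contribution. The fish-like species additionally
#' carries a left-truncated maternal 3' UTR distribution
#' (under-representation of short 3' UTRs); the worm-like species has
#' operons, trans-splicing and an RNAi phenotype table whose phenotype
#' calls are associated with 5' IGR length (the 3' UTR is untouched); the
#' human-like species anchors a 1:1:1 ortholog analysis with a planted
#' maternal rank shift in the chick-like pair only.
#'
#' Origin labels are derived by running the package's own classifiers on
#' simulated expression (decoupled components for the fly-like species,
#' time courses for worm/fish/mouse, abundance ranks for chick/human);
#' conservation classes come from simulated phylogenetic profiles. All
#' inputs are written as plain-text files (GFF3 + TSV) under
#' `file.path(dir, "inputs")` so the returned configuration exercises the
#' parsers end to end.
#'
#' @param dir directory for inputs and results.
#' @param seed integer master seed; all per-species seeds derive from it.
#' @param n_genes genes per species.
#' @param stat a [stat_config()] stored in the returned config.
#' @return A run configuration list for [run_full()].
#' @export
synthetic_panel <- function(dir, seed = 1L, n_genes = 1000L,
                            stat = stat_config()) {
  in_dir <- file.path(dir, "inputs")
  dir.create(in_dir, showWarnings = FALSE, recursive = TRUE)
  maternal_classes <- c("strict_maternal", "mostly_maternal", "maternal_zygotic")

  effects <- function(m_scale, z_scale = NULL, utr3_trunc = NULL) {
    eff <- lapply(maternal_classes, function(cl) {
      e <- list(igr5_scale = m_scale)
      if (!is.null(utr3_trunc)) e$utr3_left_truncation_percentile <- utr3_trunc
      e
    })
    names(eff) <- maternal_classes
    if (!is.null(z_scale)) eff$strict_zygotic <- list(igr5_scale = z_scale)
    eff
  }

  panel <- list(
    list(name = "sp_fly", nutrition = "high", labels = "decoupled",
         maternal_set = "strict_maternal", class_effects = effects(0.5, 2.0)),
    list(name = "sp_worm", nutrition = "high", labels = "timecourse",
         maternal_set = "strict_maternal", class_effects = effects(0.5, 2.0),
         operon_fraction = 0.15, trans_spliced = TRUE, rnai = TRUE),
    list(name = "sp_fish", nutrition = "high", labels = "timecourse",
         maternal_set = "strict_maternal",
         class_effects = effects(0.5, 2.0, utr3_trunc = 20)),
    list(name = "sp_chick", nutrition = "medium", labels = "rank",
         maternal_set = "all_maternal", class_effects = effects(0.9)),
    list(name = "sp_mouse", nutrition = "low", labels = "timecourse",
         maternal_set = "strict_maternal", class_effects = effects(1.6, 0.7)),
    list(name = "sp_human", nutrition = "low", labels = "rank",
         maternal_set = "all_maternal", class_effects = effects(1.6))
  )

  species_cfgs <- list()
  human_state <- NULL
  for (i in seq_along(panel)) {
    sp <- panel[[i]]
    cfg <- sim_config(seed = as.integer(seed + 10L * i),
                      n_genes = as.integer(n_genes),
                      class_effects = sp$class_effects,
                      conservation_igr5_scale = c(core = 0.75, metazoan = 1.2,
                                                  other = 1),
                      operon_fraction = sp$operon_fraction %||% 0,
                      rnai_effect = 3)
    sim <- simulate_genome(cfg)
    prof <- simulate_phylo_profiles(sim$truth, cfg)
    expr <- simulate_expression(sim$truth, cfg)

    ann_path <- file.path(in_dir, sprintf("%s.gff3", sp$name))
    write_annotation(sim$annotation, ann_path)
    prof_path <- file.path(in_dir, sprintf("%s_profiles.tsv", sp$name))
    write_tsv_strict(prof$profiles, prof_path)
    kinds_path <- file.path(in_dir, sprintf("%s_taxa.tsv", sp$name))
    write_tsv_strict(prof$taxon_kinds, kinds_path)
    expr_path <- file.path(in_dir, sprintf("%s_expression.tsv", sp$name))
    write_tsv_strict(expr, expr_path)

    tp <- attr(expr, "timepoints")
    labels <- switch(sp$labels,
      decoupled = classify_origin_decoupled(expr, tp),
      timecourse = classify_origin_timecourse(expr, tp, attr(expr, "mzt_index")),
      rank = {
        stage <- tibble(gene_id = expr$gene_id, abundance = expr$maternal)
        sel <- classify_origin_rank(stage, top_fraction = 0.5)
        tibble(gene_id = expr$gene_id,
               origin_class = factor("unclassified", levels = origin_levels),
               all_maternal = expr$gene_id %in% sel)
      })
    labels_path <- file.path(in_dir, sprintf("%s_labels.tsv", sp$name))
    write_tsv_strict(labels, labels_path)

    entry <- list(name = sp$name, annotation = ann_path, dialect = "gff3",
                  labels = labels_path, profiles = prof_path,
                  taxon_kinds = kinds_path,
                  flags = list(trans_spliced = isTRUE(sp$trans_spliced)),
                  nutrition_class = sp$nutrition,
                  maternal_set = sp$maternal_set)
    if (sp$labels == "rank") {
      # no zygotic data: only the all-maternal comparisons are meaningful
      entry$comparisons <- bind_rows(
        tibble(metric = "utr3", class_a = "all_maternal",
               stratum = c("core", "metazoan"), pool = "all_other"),
        tibble(metric = "igr5", class_a = "all_maternal",
               stratum = c("core", "metazoan"), pool = "all"),
        tibble(metric = "igr5", class_a = "metazoan", class_b = "core",
               stratum = NA_character_, pool = NA_character_)
      )
    }
    if (nrow(sim$operons) > 0L) {
      op_path <- file.path(in_dir, sprintf("%s_operons.tsv", sp$name))
      write_tsv_strict(sim$operons, op_path)
      entry$operons <- op_path
    }
    metrics <- NULL
    if (isTRUE(sp$rnai)) {
      metrics <- compute_region_table(sim$annotation, operons = sim$operons)
      rnai <- simulate_rnai(metrics, sim$truth, cfg)
      rnai_path <- file.path(in_dir, sprintf("%s_rnai.tsv", sp$name))
      write_tsv_strict(rnai, rnai_path)
      entry$rnai <- rnai_path
    }
    if (sp$name == "sp_human") {
      human_state <- list(truth = sim$truth,
                          metrics = compute_region_table(sim$annotation),
                          cfg = cfg)
    }
    species_cfgs[[length(species_cfgs) + 1L]] <- entry
  }

  # 1:1:1 orthologs anchored on the human-like species; the chick-like pair
  # carries a planted maternal rank shift, the mouse-like pair is null
  ocfg <- human_state$cfg
  ocfg$ortholog_rank_noise <- 0.05
  ocfg$maternal_rank_shift <- 0.15
  ortho <- simulate_orthologs(human_state$metrics, human_state$truth, ocfg)
  opaths <- list(
    pairs_b = file.path(in_dir, "ortholog_pairs_chick.tsv"),
    pairs_c = file.path(in_dir, "ortholog_pairs_mouse.tsv"),
    lengths_b = file.path(in_dir, "ortholog_lengths_chick.tsv"),
    lengths_c = file.path(in_dir, "ortholog_lengths_mouse.tsv"),
    maternal_b = file.path(in_dir, "ortholog_maternal_chick.tsv"),
    maternal_c = file.path(in_dir, "ortholog_maternal_mouse.tsv")
  )
  write_tsv_strict(ortho$pairs_b, opaths$pairs_b)
  write_tsv_strict(ortho$pairs_c, opaths$pairs_c)
  write_tsv_strict(ortho$lengths_b, opaths$lengths_b)
  write_tsv_strict(ortho$lengths_c, opaths$lengths_c)
  write_tsv_strict(tibble(gene_a = ortho$maternal_pairs_b), opaths$maternal_b)
  write_tsv_strict(tibble(gene_a = ortho$maternal_pairs_c), opaths$maternal_c)

  list(
    seed = seed,
    species = species_cfgs,
    ortholog = list(anchor = "sp_human",
                    partners = c("chick_like", "mouse_like"),
                    pairs = list(opaths$pairs_b, opaths$pairs_c),
                    lengths = list(opaths$lengths_b, opaths$lengths_c),
                    maternal_pairs = list(opaths$maternal_b, opaths$maternal_c)),
    stat = stat,
    output_dir = file.path(dir, "results")
  )
}
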