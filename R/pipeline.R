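#' Default comparison design
#'
#' One row per comparison run for each species: 3' UTRs of all-maternal
#' genes against all *other* genes of the same conservation stratum, and 5'
#' IGRs of the strict classes against the genome-wide stratum set. The
#' `pool` column selects the reference definition (`"all_other"` excludes
#' the class under evaluation from the reference; `"all"` keeps it).
#'
#' A `class_b` column (default `NA`) turns a row into a direct class-vs-class
#' comparison (e.g. metazoan against core genes) instead of class-vs-pool.
#'
#' @return tibble with columns `metric`, `class_a`, `class_b`, `stratum`,
#'   `pool`.
#' @export
default_comparisons <- function() {
  out <- bind_rows(
    tidyr::expand_grid(metric = "utr3", class_a = "all_maternal",
                       stratum = c("core", "metazoan"), pool = "all_other"),
    tidyr::expand_grid(metric = "igr5",
                       class_a = c("strict_maternal", "strict_zygotic"),
                       stratum = c("core", "metazoan"), pool = "all"),
    tibble(metric = "igr5", class_a = "metazoan", class_b = "core",
           stratum = NA_character_, pool = NA_character_)
  )
  out
}

metric_values <- function(metrics, metric, gene_ids = NULL) {
  x <- metrics
  if (!is.null(gene_ids)) x <- x[x$gene_id %in% gene_ids, , drop = FALSE]
  if (grepl("igr5", metric)) x <- x[x$included_in_igr5_set, , drop = FALSE]
  v <- x[[metric]]
  v[!is.na(v)]
}

class_gene_ids <- function(classes, class_a) {
  if (class_a == "all_maternal") {
    classes$gene_id[classes$all_maternal]
  } else if (class_a %in% c("core", "metazoan", "other")) {
    classes$gene_id[classes$conservation_class == class_a]
  } else {
    classes$gene_id[as.character(classes$origin_class) == class_a]
  }
}

#' Run the sweep comparisons for one species
#'
#' For every configured comparison, truncation-sweep KS test of the class's
#' length distribution against the genome-wide reference of the same
#' conservation stratum, with the metric's filters (operon censoring, UTR
#' thresholds) applied before pooling. Comparisons whose class or reference
#' is empty are skipped with a warning.
#'
#' @param metrics table from [compute_region_table()].
#' @param classes tibble with `gene_id`, `origin_class`, `all_maternal`,
#'   `conservation_class`.
#' @param comparisons design tibble, see [default_comparisons()].
#' @param stat a [stat_config()].
#' @param species species label for the output tables.
#' @return list with `per_q` (long tibble of every grid point) and
#'   `summary` (one row per comparison).
#' @export
run_sweep_comparisons <- function(metrics, classes,
                                  comparisons = default_comparisons(),
                                  stat = stat_config(),
                                  species = NA_character_) {
  per_q <- list()
  summary <- list()
  if (!("class_b" %in% names(comparisons))) comparisons$class_b <- NA_character_
  for (i in seq_len(nrow(comparisons))) {
    cmp <- comparisons[i, , drop = FALSE]
    stratum_ids <- if (is.na(cmp$stratum)) classes$gene_id else {
      classes$gene_id[classes$conservation_class == cmp$stratum]
    }
    a_ids <- intersect(class_gene_ids(classes, cmp$class_a), stratum_ids)
    b_ids <- if (!is.na(cmp$class_b)) {
      intersect(class_gene_ids(classes, cmp$class_b), stratum_ids)
    } else if (identical(cmp$pool, "all_other")) {
      setdiff(stratum_ids, a_ids)
    } else {
      stratum_ids
    }
    a <- metric_values(metrics, cmp$metric, a_ids)
    b <- metric_values(metrics, cmp$metric, b_ids)
    if (length(a) == 0L || length(b) == 0L) {
      warn(sprintf("skipping %s %s vs %s (%s): empty sample after filtering",
                   cmp$metric, cmp$class_a,
                   if (!is.na(cmp$class_b)) cmp$class_b else cmp$pool,
                   cmp$stratum))
      next
    }
    sw <- percentile_sweep(a, b, stat)
    tag <- tibble(species = species, metric = cmp$metric, class_a = cmp$class_a,
                  class_b = cmp$class_b, stratum = cmp$stratum, pool = cmp$pool)
    per_q[[length(per_q) + 1L]] <- bind_cols(tag[rep(1L, nrow(sw$per_q)), ],
                                             sw$per_q)
    summary[[length(summary) + 1L]] <-
      bind_cols(tag, tibble(p_min = sw$p_min, q_at_p_min = sw$q_at_p_min,
                            q_top_significant = sw$q_top_significant,
                            n_a = length(a), n_b = length(b)))
  }
  list(per_q = bind_rows(per_q), summary = bind_rows(summary))
}

load_species_inputs <- function(sp) {
  ann <- if (inherits(sp$annotation, "genome_annotation")) sp$annotation else {
    parse_annotation(sp$annotation, dialect = sp$dialect %||% "gff3")
  }
  operons <- sp$operons
  if (is.character(operons)) {
    operons <- readr::read_tsv(operons, show_col_types = FALSE, progress = FALSE)
  }
  labels <- sp$labels
  if (is.character(labels)) labels <- read_origin_labels(labels)
  cons <- sp$conservation
  if (is.null(cons) && !is.null(sp$profiles)) {
    profiles <- if (is.character(sp$profiles)) {
      readr::read_tsv(sp$profiles, show_col_types = FALSE, progress = FALSE)
    } else sp$profiles
    kinds <- if (is.character(sp$taxon_kinds)) {
      readr::read_tsv(sp$taxon_kinds, show_col_types = FALSE, progress = FALSE)
    } else sp$taxon_kinds
    cons <- classify_conservation(profiles, kinds)
  }
  rnai <- sp$rnai
  if (is.character(rnai)) {
    rnai <- readr::read_tsv(rnai, show_col_types = FALSE, progress = FALSE)
  }
  list(annotation = ann, operons = operons, labels = labels,
       conservation = cons, rnai = rnai)
}

#' Run the full analysis for one species
#'
#' Parses the annotation, computes the region-length table, assembles class
#' assignments (origin labels plus conservation classes from phylogenetic
#' profiles) and runs the configured sweep comparisons.
#'
#' @param sp species entry: a list with `name`, `annotation` (path or
#'   [genome_annotation()]), optional `dialect`, `operons`, `labels` (path
#'   or tibble), `profiles`/`taxon_kinds` or a precomputed `conservation`
#'   table, optional `rnai` table, `flags`
#'   (`trans_spliced`, `allow_multiexon_utr3`), `nutrition_class`,
#'   `maternal_set`, optional `comparisons`.
#' @param stat a [stat_config()].
#' @return list with `name`, `metrics`, `classes`, `sweeps` (per_q +
#'   summary), `rnai` (sweep pair or NULL), `inputs`.
#' @export
run_species <- function(sp, stat = stat_config()) {
  inp <- load_species_inputs(sp)
  flags <- sp$flags %||% list()
  metrics <- compute_region_table(
    inp$annotation, operons = inp$operons,
    species_flags = list(trans_spliced = isTRUE(flags$trans_spliced)),
    allow_multiexon_utr3 = isTRUE(flags$allow_multiexon_utr3)
  )
  classes <- inp$labels
  if (!is.null(inp$conservation)) {
    classes <- left_join(classes, inp$conservation, by = "gene_id")
  }
  if (!("conservation_class" %in% names(classes))) {
    abort(sprintf("species %s: no conservation classes available", sp$name))
  }
  comparisons <- sp$comparisons %||% default_comparisons()
  if (!is.data.frame(comparisons)) comparisons <- as_tibble(comparisons)
  sweeps <- run_sweep_comparisons(metrics, classes, comparisons, stat,
                                  species = sp$name)
  rnai_res <- NULL
  if (!is.null(inp$rnai)) {
    maternal_ids <- classes$gene_id[classes$all_maternal]
    rnai_res <- rnai_phenotype_compare(
      metrics[metrics$gene_id %in% maternal_ids, , drop = FALSE],
      inp$rnai, stat)
  }
  list(name = sp$name, metrics = metrics, classes = classes, sweeps = sweeps,
       rnai = rnai_res, inputs = inp,
       nutrition_class = sp$nutrition_class %||% NA_character_,
       maternal_set = sp$maternal_set %||% "strict_maternal")
}

read_pairs <- function(x) {
  if (is.character(x)) {
    readr::read_tsv(x, show_col_types = FALSE, progress = FALSE)
  } else as_tibble(x)
}

run_ortholog_analysis <- function(ortho, species_results, stat) {
  anchor <- species_results[[ortho$anchor]]
  ranks_a <- percentile_ranks(
    anchor$metrics[anchor$metrics$included_in_igr5_set, , drop = FALSE])
  out_fc <- list()
  out_test <- list()
  for (j in seq_along(ortho$partners)) {
    pname <- ortho$partners[j]
    pairs <- read_pairs(ortho$pairs[[j]])
    lengths <- read_pairs(ortho$lengths[[j]])
    ranks_b <- percentile_ranks(lengths)
    fcs <- rank_fold_changes(pairs, ranks_a, ranks_b)
    maternal <- ortho$maternal_pairs[[j]]
    if (is.character(maternal) && length(maternal) == 1L && file.exists(maternal)) {
      maternal <- readr::read_tsv(maternal, show_col_types = FALSE,
                                  progress = FALSE)$gene_a
    }
    ks <- compare_maternal_vs_all(fcs, maternal, stat)
    out_fc[[j]] <- mutate(as_tibble(fcs), pair = sprintf("%s-%s", ortho$anchor, pname),
                          maternal_pair = .data$gene_a %in% maternal)
    out_test[[j]] <- tibble(pair = sprintf("%s-%s", ortho$anchor, pname),
                            d = ks$d, p = ks$p, n_maternal = ks$n_a,
                            n_all = ks$n_b)
  }
  list(fc = bind_rows(out_fc), tests = bind_rows(out_test))
}

#' Run the full multi-species analysis
#'
#' Orchestrates the pipeline over every configured species: per-species
#' metrics, classes and sweep comparisons; the ortholog rank fold-change
#' analysis; the maternal-to-genome ratio summary across nutrition classes;
#' and the RNAi phenotype comparison where a phenotype table is supplied.
#' All results are written as TSVs under `config$output_dir`, together with
#' a manifest recording the package version and input digests. A species
#' that fails is recorded and the rest proceed; the run errors only if all
#' species fail.
#'
#' @param config run configuration: list with `species` (list of entries,
#'   see [run_species()]), optional `ortholog` (list with `anchor`,
#'   `partners`, `pairs`, `lengths`, `maternal_pairs`), `stat`
#'   (a [stat_config()] or list of its arguments), `output_dir`.
#' @return Invisibly, a list with `species` results, `ortholog`, `ratio`,
#'   `failures`, and the output paths.
#' @export
run_full <- function(config) {
  stat <- config$stat %||% stat_config()
  if (!inherits(stat, "stat_config")) stat <- do.call(stat_config, stat)
  out_dir <- config$output_dir
  if (is.null(out_dir)) abort("config$output_dir is required")
  check_config_paths(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  results <- list()
  failures <- list()
  for (sp in config$species) {
    res <- tryCatch(run_species(sp, stat), error = function(e) e)
    if (inherits(res, "error")) {
      failures[[sp$name]] <- conditionMessage(res)
      inform(sprintf("species %s failed: %s", sp$name, conditionMessage(res)))
    } else {
      results[[sp$name]] <- res
    }
  }
  if (length(results) == 0L) abort("all species failed")

  all_per_q <- bind_rows(purrr::map(results, ~ .x$sweeps$per_q))
  all_summary <- bind_rows(purrr::map(results, ~ .x$sweeps$summary))
  for (nm in names(results)) {
    write_tsv_strict(results[[nm]]$metrics,
                     file.path(out_dir, sprintf("%s_metrics.tsv", nm)))
    write_tsv_strict(results[[nm]]$classes,
                     file.path(out_dir, sprintf("%s_classes.tsv", nm)))
  }
  write_tsv_strict(all_per_q, file.path(out_dir, "sweeps.tsv"))
  write_tsv_strict(all_summary, file.path(out_dir, "sweeps_summary.tsv"))

  ortho_res <- NULL
  if (!is.null(config$ortholog)) {
    ortho_res <- run_ortholog_analysis(config$ortholog, results, stat)
    write_tsv_strict(ortho_res$fc, file.path(out_dir, "ortholog_fc.tsv"))
    write_tsv_strict(ortho_res$tests, file.path(out_dir, "ortholog_tests.tsv"))
  }

  ratio <- ratio_summary_table(results)
  if (nrow(ratio) > 0L) {
    write_tsv_strict(ratio, file.path(out_dir, "ratio_summary.tsv"))
  }

  rnai_rows <- list()
  for (nm in names(results)) {
    rr <- results[[nm]]$rnai
    if (!is.null(rr)) {
      rnai_rows[[nm]] <- tibble(
        species = nm, metric = c("igr5", "utr3"),
        p_min = c(rr$igr5$p_min, rr$utr3$p_min),
        q_at_p_min = c(rr$igr5$q_at_p_min, rr$utr3$q_at_p_min),
        q_top_significant = c(rr$igr5$q_top_significant,
                              rr$utr3$q_top_significant),
        n_observed = rr$n_observed, n_none = rr$n_none)
    }
  }
  if (length(rnai_rows) > 0L) {
    write_tsv_strict(bind_rows(rnai_rows), file.path(out_dir, "rnai_comparison.tsv"))
  }

  write_manifest(config, results, out_dir)
  invisible(list(species = results, ortholog = ortho_res, ratio = ratio,
                 failures = failures, output_dir = out_dir))
}

# every referenced input path must exist before any computation starts
check_config_paths <- function(config) {
  paths <- character()
  for (sp in config$species) {
    for (f in c("annotation", "operons", "labels", "profiles", "taxon_kinds",
                "rnai")) {
      if (is.character(sp[[f]])) paths <- c(paths, sp[[f]])
    }
  }
  if (!is.null(config$ortholog)) {
    for (f in c("pairs", "lengths")) {
      v <- config$ortholog[[f]]
      if (!is.null(v)) {
        if (!is.list(v)) v <- list(v)
        paths <- c(paths, unlist(purrr::keep(v, is.character)))
      }
    }
  }
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L) {
    abort(sprintf("input file not found: %s", missing[1L]))
  }
  invisible(config)
}

# maternal/genome 5' IGR ratio per species, metazoan stratum, three measures
ratio_summary_table <- function(results) {
  rows <- list()
  for (nm in names(results)) {
    res <- results[[nm]]
    nut <- res$nutrition_class %||% NA_character_
    maternal_set <- res$maternal_set %||% "strict_maternal"
    cls <- res$classes
    metazoan <- cls$gene_id[cls$conservation_class == "metazoan"]
    m_ids <- intersect(class_gene_ids(cls, maternal_set), metazoan)
    m_len <- metric_values(res$metrics, "igr5", m_ids)
    g_len <- metric_values(res$metrics, "igr5", metazoan)
    if (length(m_len) == 0L || length(g_len) == 0L) next
    rows[[nm]] <- maternal_genome_ratio(m_len, g_len, species = nm,
                                        nutrition_class = nut)
  }
  bind_rows(rows)
}

write_manifest <- function(config, results, out_dir) {
  inputs <- character()
  for (sp in config$species) {
    for (f in c("annotation", "operons", "labels", "profiles", "taxon_kinds",
                "rnai")) {
      if (is.character(sp[[f]]) && file.exists(sp[[f]])) {
        inputs[sp[[f]]] <- unname(tools::md5sum(sp[[f]]))
      }
    }
  }
  manifest <- list(
    package = "mztarch",
    version = as.character(utils::packageVersion("mztarch")),
    seed = config$seed %||% NA,
    species = purrr::map_chr(config$species, "name"),
    input_md5 = as.list(inputs)
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(NULL)
}

#' Read a YAML run configuration
#'
#' @param path YAML file with the structure accepted by [run_full()];
#'   relative input paths are resolved against the YAML file's directory.
#' @return config list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  fix <- function(p) {
    if (is.character(p) && !file.exists(p) && file.exists(file.path(base, p))) {
      file.path(base, p)
    } else p
  }
  cfg$species <- purrr::map(cfg$species, function(sp) {
    for (f in c("annotation", "operons", "labels", "profiles", "taxon_kinds",
                "rnai")) {
      sp[[f]] <- fix(sp[[f]])
    }
    sp
  })
  if (!is.null(cfg$ortholog)) {
    for (f in c("pairs", "lengths", "maternal_pairs")) {
      cfg$ortholog[[f]] <- purrr::map(cfg$ortholog[[f]], fix)
    }
  }
  cfg
}
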