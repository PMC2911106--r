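#' Classifier configuration
#'
#' Numeric thresholds shared by the origin-of-synthesis classifiers.
#'
#' @param fold_change_min minimum fold change for a "significant decrease"
#'   (default 3).
#' @param p_max p-value ceiling applied when per-gene p-values are supplied
#'   (default 0.001); without replicate-level data the fold-change rule alone
#'   decides.
#' @param zygotic_fraction_max upper bound on the minority-origin fraction
#'   for the "mostly" classes (default 0.33).
#' @param maternal_rank_top top abundance-rank fraction called maternal in
#'   rank mode (default 0.50, the laid-egg convention).
#' @param zygotic_rank_top top abundance-rank fraction called zygotic in
#'   gastrulation rank mode (default 0.25).
#' @param presence_call abundance at or above which a gene is called
#'   expressed (default 1).
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(fold_change_min = 3, p_max = 0.001,
                              zygotic_fraction_max = 0.33,
                              maternal_rank_top = 0.50,
                              zygotic_rank_top = 0.25,
                              presence_call = 1) {
  stopifnot(fold_change_min > 1, p_max > 0, p_max < 1,
            zygotic_fraction_max > 0, zygotic_fraction_max <= 1,
            maternal_rank_top > 0, maternal_rank_top <= 1,
            zygotic_rank_top > 0, zygotic_rank_top <= 1)
  structure(list(fold_change_min = fold_change_min, p_max = p_max,
                 zygotic_fraction_max = zygotic_fraction_max,
                 maternal_rank_top = maternal_rank_top,
                 zygotic_rank_top = zygotic_rank_top,
                 presence_call = presence_call),
            class = "classifier_config")
}

origin_levels <- c("strict_maternal", "mostly_maternal", "maternal_zygotic",
                   "mostly_zygotic", "strict_zygotic", "unclassified")

#' Conservation class from phylogenetic presence/absence profiles
#'
#' A gene is `core` when present in at least one unicellular taxon;
#' otherwise `metazoan` when present in at least two animal taxa and absent
#' from all plants; otherwise `other`.
#'
#' @param profiles tibble with a `gene_id` column plus one 0/1 (or logical)
#'   column per taxon.
#' @param taxon_kinds tibble with columns `taxon` and `kind`
#'   (`"unicellular"`, `"plant"` or `"animal"`).
#' @return tibble with columns `gene_id`, `conservation_class`.
#' @export
classify_conservation <- function(profiles, taxon_kinds) {
  profiles <- as_tibble(profiles)
  taxon_kinds <- as_tibble(taxon_kinds)
  assert_cols(profiles, "gene_id", "profiles")
  assert_cols(taxon_kinds, c("taxon", "kind"), "taxon_kinds")
  taxa <- setdiff(names(profiles), "gene_id")
  unknown <- setdiff(taxa, taxon_kinds$taxon)
  if (length(unknown) > 0L) {
    abort(sprintf("taxa without a declared kind: %s",
                  paste(head(unknown, 5), collapse = ", ")))
  }
  kind <- setNames(taxon_kinds$kind, taxon_kinds$taxon)[taxa]
  if (!all(kind %in% c("unicellular", "plant", "animal"))) {
    abort("taxon kind must be unicellular, plant or animal")
  }
  if (sum(kind == "unicellular") < 1L || sum(kind == "plant") < 1L ||
      sum(kind == "animal") < 2L) {
    abort("panel needs >=1 unicellular, >=1 plant and >=2 animal taxa")
  }
  m <- as.matrix(profiles[, taxa, drop = FALSE])
  storage.mode(m) <- "logical"
  in_unicell <- rowSums(m[, kind == "unicellular", drop = FALSE]) >= 1L
  in_plant <- rowSums(m[, kind == "plant", drop = FALSE]) >= 1L
  n_animal <- rowSums(m[, kind == "animal", drop = FALSE])
  cls <- dplyr::case_when(
    in_unicell ~ "core",
    n_animal >= 2L & !in_plant ~ "metazoan",
    TRUE ~ "other"
  )
  tibble(gene_id = profiles$gene_id, conservation_class = cls)
}

#' Origin class from decoupled maternal/zygotic components
#'
#' Classifies genes using separately quantified maternal and zygotic
#' contributions to early-embryo mRNA abundance, together with an abundance
#' time course. Genes detected before the maternal-to-zygotic transition
#' belong to the all-maternal set; among these, a significant decrease over
#' the time course (fold change at least `fold_change_min`, and p at most
#' `p_max` when a `p_decrease` column is supplied) with zero zygotic
#' component is `strict_maternal`, a decrease with a small zygotic fraction
#' (below `zygotic_fraction_max`) is `mostly_maternal`, and a stable
#' maternal abundance is `maternal_zygotic`. Genes expressed only after the
#' transition are `strict_zygotic` (no maternal component) or
#' `mostly_zygotic` (small maternal fraction).
#'
#' @param data tibble with columns `gene_id`, `maternal`, `zygotic`
#'   (non-negative component abundances), time-course columns named in
#'   `timepoints`, and optionally `p_decrease`.
#' @param timepoints character vector of time-course column names, ordered
#'   from earliest (pre-MZT) to latest.
#' @param config a [classifier_config()].
#' @return tibble with columns `gene_id`, `origin_class`, `all_maternal`
#'   (logical membership of the all-maternal set).
#' @export
classify_origin_decoupled <- function(data, timepoints,
                                      config = classifier_config()) {
  data <- as_tibble(data)
  assert_cols(data, c("gene_id", "maternal", "zygotic", timepoints), "data")
  if (any(data$maternal < 0 | data$zygotic < 0, na.rm = TRUE)) {
    abort("component abundances must be non-negative")
  }
  tc <- as.matrix(data[, timepoints, drop = FALSE])
  if (any(tc < 0, na.rm = TRUE)) abort("time-course abundances must be non-negative")
  first <- tc[, 1L]
  last_min <- apply(tc[, -1L, drop = FALSE], 1L, min)
  fc_ok <- first >= config$fold_change_min * last_min
  if ("p_decrease" %in% names(data)) {
    fc_ok <- fc_ok & data$p_decrease <= config$p_max
  }
  total <- data$maternal + data$zygotic
  zf <- ifelse(total > 0, data$zygotic / total, NA_real_)
  mf <- ifelse(total > 0, data$maternal / total, NA_real_)
  pre_present <- data$maternal >= config$presence_call
  post_present <- apply(tc[, -1L, drop = FALSE], 1L, max) >= config$presence_call |
    data$zygotic >= config$presence_call
  zmax <- config$zygotic_fraction_max
  cls <- dplyr::case_when(
    pre_present & fc_ok & data$zygotic == 0 ~ "strict_maternal",
    pre_present & fc_ok & zf > 0 & zf < zmax ~ "mostly_maternal",
    pre_present & !fc_ok ~ "maternal_zygotic",
    !pre_present & post_present & data$maternal == 0 ~ "strict_zygotic",
    !pre_present & post_present & mf > 0 & mf < zmax ~ "mostly_zygotic",
    TRUE ~ "unclassified"
  )
  tibble(gene_id = data$gene_id,
         origin_class = factor(cls, levels = origin_levels),
         all_maternal = pre_present)
}

#' Origin class from an expression time course
#'
#' Profile-based classification for species without decoupled component
#' measurements. `mzt_index` is the index (into `timepoints`) of the last
#' pre-transition time point; at least one time point must lie on each side.
#' Genes present before the transition and reduced by at least the
#' configured fold change at *every* later point are `strict_maternal`;
#' genes absent before and present at every later point are
#' `strict_zygotic`; genes present before and reduced at no later point are
#' `maternal_zygotic`; everything else (including all-zero genes) is
#' `unclassified`.
#'
#' @param data tibble with `gene_id` plus time-course columns.
#' @param timepoints ordered time-course column names.
#' @param mzt_index index of the last pre-MZT time point.
#' @param config a [classifier_config()].
#' @return tibble with columns `gene_id`, `origin_class`, `all_maternal`.
#' @export
classify_origin_timecourse <- function(data, timepoints, mzt_index,
                                       config = classifier_config()) {
  data <- as_tibble(data)
  assert_cols(data, c("gene_id", timepoints), "data")
  k <- length(timepoints)
  if (mzt_index < 1L || mzt_index >= k) {
    abort("mzt_index must leave >=1 time point before and after the transition")
  }
  tc <- as.matrix(data[, timepoints, drop = FALSE])
  pre <- tc[, seq_len(mzt_index), drop = FALSE]
  post <- tc[, (mzt_index + 1L):k, drop = FALSE]
  pre_max <- apply(pre, 1L, max)
  pre_present <- pre_max >= config$presence_call
  post_present_all <- apply(post >= config$presence_call, 1L, all)
  reduced <- pre_max >= config$fold_change_min * post
  reduced_all <- apply(reduced, 1L, all)
  reduced_any <- apply(reduced, 1L, any)
  cls <- dplyr::case_when(
    pre_present & reduced_all ~ "strict_maternal",
    !pre_present & post_present_all ~ "strict_zygotic",
    pre_present & !reduced_any ~ "maternal_zygotic",
    TRUE ~ "unclassified"
  )
  tibble(gene_id = data$gene_id,
         origin_class = factor(cls, levels = origin_levels),
         all_maternal = pre_present)
}

#' Gene set from abundance ranks at a single stage
#'
#' Selects the genes whose abundance rank (descending) falls within the top
#' `top_fraction` of genes called expressed; all genes tied with the cutoff
#' abundance are included, so the set can exceed the nominal count.
#'
#' @param data tibble with columns `gene_id` and `abundance`.
#' @param top_fraction fraction of expressed genes to select, in (0, 1].
#' @param presence_call abundance threshold for calling a gene expressed.
#' @return Character vector of selected gene ids.
#' @export
classify_origin_rank <- function(data, top_fraction, presence_call = 1) {
  data <- as_tibble(data)
  assert_cols(data, c("gene_id", "abundance"), "data")
  stopifnot(top_fraction > 0, top_fraction <= 1)
  expressed <- data[data$abundance >= presence_call, , drop = FALSE]
  if (nrow(expressed) == 0L) abort("no genes pass the presence call")
  k <- max(1L, floor(nrow(expressed) * top_fraction))
  cutoff <- sort(expressed$abundance, decreasing = TRUE)[k]
  expressed$gene_id[expressed$abundance >= cutoff]
}

#' Read a precomputed origin-class label table
#'
#' Classes can be supplied directly (published dataset tables) instead of
#' being derived by a classifier.
#'
#' @param path TSV with columns `gene_id`, `origin_class`, and optionally
#'   `all_maternal`.
#' @return tibble with columns `gene_id`, `origin_class`, `all_maternal`.
#' @export
read_origin_labels <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_cols(tab, c("gene_id", "origin_class"), "label table")
  bad <- setdiff(unique(tab$origin_class), origin_levels)
  if (length(bad) > 0L) {
    abort(sprintf("unknown origin class label(s): %s", paste(bad, collapse = ", ")))
  }
  if (!("all_maternal" %in% names(tab))) {
    tab$all_maternal <- tab$origin_class %in%
      c("strict_maternal", "mostly_maternal", "maternal_zygotic")
  }
  tab$origin_class <- factor(tab$origin_class, levels = origin_levels)
  tab[, c("gene_id", "origin_class", "all_maternal")]
}
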