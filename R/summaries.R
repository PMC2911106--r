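#' Maternal-to-genome length ratio
#'
#' Estimates the relative transcriptional regulatory complexity of maternal
#' genes as the ratio of a location measure of maternal metazoan gene 5' IGR
#' lengths to the same measure over all metazoan genes. Three measures are
#' supported: the median, the 75th percentile, and a 5% trimmed mean
#' (by default 5% removed from each tail; `trim_per_tail = 0.025` gives the
#' 5%-total convention).
#'
#' @param maternal_lengths lengths (bp) of the maternal gene class.
#' @param genome_lengths genome-wide lengths (bp) of the same metric.
#' @param measure one or more of `"median"`, `"p75"`, `"trimmed_mean_5"`.
#' @param trim_per_tail trim fraction per tail for the trimmed mean.
#' @param species,nutrition_class optional labels carried into the output.
#' @return tibble with one row per measure: `species`, `nutrition_class`,
#'   `measure`, `maternal_value`, `genome_value`, `ratio`.
#' @export
maternal_genome_ratio <- function(maternal_lengths, genome_lengths,
                                  measure = c("median", "p75", "trimmed_mean_5"),
                                  trim_per_tail = 0.05,
                                  species = NA_character_,
                                  nutrition_class = NA_character_) {
  measure <- match.arg(measure, several.ok = TRUE)
  maternal_lengths <- maternal_lengths[!is.na(maternal_lengths)]
  genome_lengths <- genome_lengths[!is.na(genome_lengths)]
  if (length(maternal_lengths) == 0L || length(genome_lengths) == 0L) {
    abort("both length vectors must be non-empty")
  }
  loc <- function(x, m) {
    switch(m,
           median = median(x),
           p75 = quantile(x, 0.75, names = FALSE),
           trimmed_mean_5 = mean(x, trim = trim_per_tail))
  }
  rows <- purrr::map(measure, function(m) {
    mv <- loc(maternal_lengths, m)
    gv <- loc(genome_lengths, m)
    if (gv == 0) abort(sprintf("genome-wide %s is zero; ratio undefined", m))
    tibble(species = species, nutrition_class = nutrition_class, measure = m,
           maternal_value = mv, genome_value = gv, ratio = mv / gv)
  })
  bind_rows(rows)
}

#' RNAi phenotype vs. no-phenotype regulatory-region comparison
#'
#' Splits maternal genes by whether an RNAi knockdown phenotype was
#' observed, and runs the percentile KS sweep (phenotype group as the class
#' under evaluation, no-phenotype group as the reference) separately for 5'
#' IGR and 3' UTR lengths. Maternal genes without a phenotype entry are
#' excluded.
#'
#' @param maternal_metrics region-length table rows
#'   (from [compute_region_table()]) for the maternal gene set.
#' @param phenotype_table tibble with columns `gene_id`, `phenotype`
#'   (`"observed"` or `"none"`).
#' @param config a [stat_config()].
#' @return list with elements `igr5` and `utr3`, each an `mzt_sweep`, plus
#'   `n_observed` and `n_none` group sizes.
#' @export
rnai_phenotype_compare <- function(maternal_metrics, phenotype_table,
                                   config = stat_config()) {
  maternal_metrics <- as_tibble(maternal_metrics)
  phenotype_table <- as_tibble(phenotype_table)
  assert_cols(maternal_metrics, c("gene_id", "igr5", "utr3"), "maternal_metrics")
  assert_cols(phenotype_table, c("gene_id", "phenotype"), "phenotype_table")
  if (!all(phenotype_table$phenotype %in% c("observed", "none"))) {
    abort("phenotype must be 'observed' or 'none'")
  }
  joined <- inner_join(maternal_metrics, phenotype_table, by = "gene_id")
  obs <- joined[joined$phenotype == "observed", , drop = FALSE]
  none <- joined[joined$phenotype == "none", , drop = FALSE]
  if (nrow(obs) == 0L || nrow(none) == 0L) {
    abort("both phenotype groups must be non-empty")
  }
  run_metric <- function(col, include_flag = NULL) {
    a <- obs[[col]]
    b <- none[[col]]
    if (!is.null(include_flag) && include_flag %in% names(obs)) {
      a <- a[obs[[include_flag]]]
      b <- b[none[[include_flag]]]
    }
    percentile_sweep(a[!is.na(a)], b[!is.na(b)], config)
  }
  list(igr5 = run_metric("igr5", "included_in_igr5_set"),
       utr3 = run_metric("utr3"),
       n_observed = nrow(obs), n_none = nrow(none))
}
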