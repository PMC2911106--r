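#' Within-genome percentile ranks of 5' IGR length
#'
#' Normalises lengths for genome size and gene number by replacing each
#' gene's 5' IGR length with its percentile rank within the genome: the
#' average rank of the sorted lengths divided by the number of usable genes,
#' so ranks lie in (0, 1], tied lengths share a rank, and any strictly
#' monotone transform of the lengths leaves the table unchanged. Censored
#' genes (`NA` length) are excluded.
#'
#' @param data tibble with columns `gene_id` and the length column.
#' @param value name of the length column (default `"igr5"`).
#' @param species optional species label carried as an attribute.
#' @return tibble with columns `gene_id`, `rank` (in (0, 1]).
#' @export
percentile_ranks <- function(data, value = "igr5", species = NULL) {
  data <- as_tibble(data)
  assert_cols(data, c("gene_id", value), "data")
  usable <- data[!is.na(data[[value]]), , drop = FALSE]
  if (nrow(usable) < 2L) abort("need >= 2 genes with a non-censored length")
  if (anyDuplicated(usable$gene_id)) abort("duplicated gene_id in length table")
  r <- rank(usable[[value]], ties.method = "average") / nrow(usable)
  out <- tibble(gene_id = usable$gene_id, rank = r)
  attr(out, "species") <- species
  out
}

#' Rank fold changes across 1:1 ortholog pairs
#'
#' For each 1:1 ortholog pair, the log2 ratio of the two genes'
#' within-genome percentile ranks of 5' IGR length. A fold change of zero
#' means the gene and its ortholog rank identically within their respective
#' genomes. Pairs with a censored member (absent from a rank table) are
#' dropped, with the count recorded in the `n_dropped` attribute.
#'
#' @param pairs tibble with columns `gene_a`, `gene_b` (1:1: no gene may
#'   appear twice).
#' @param ranks_a,ranks_b rank tables from [percentile_ranks()].
#' @return tibble with columns `gene_a`, `gene_b`, `rank_a`, `rank_b`,
#'   `log2_fc`.
#' @export
rank_fold_changes <- function(pairs, ranks_a, ranks_b) {
  pairs <- as_tibble(pairs)
  assert_cols(pairs, c("gene_a", "gene_b"), "pairs")
  if (anyDuplicated(pairs$gene_a) || anyDuplicated(pairs$gene_b)) {
    abort("pairs table violates the 1:1 constraint (duplicated gene)")
  }
  ra <- setNames(ranks_a$rank, ranks_a$gene_id)[pairs$gene_a]
  rb <- setNames(ranks_b$rank, ranks_b$gene_id)[pairs$gene_b]
  keep <- !is.na(ra) & !is.na(rb)
  out <- tibble(gene_a = pairs$gene_a[keep], gene_b = pairs$gene_b[keep],
                rank_a = unname(ra[keep]), rank_b = unname(rb[keep]),
                log2_fc = log2(unname(ra[keep]) / unname(rb[keep])))
  attr(out, "n_dropped") <- sum(!keep)
  class(out) <- c("mzt_rank_fc", class(out))
  out
}

#' Compare maternal ortholog rank fold changes against all orthologs
#'
#' One-sided KS test of the maternal pairs' log2 rank fold changes against
#' the full set of pairs, direction "maternal shifted towards larger fold
#' changes". The maternal subset should contain pairs maternal in both
#' species.
#'
#' @param fcs a fold-change table from [rank_fold_changes()].
#' @param maternal_pairs character vector of `gene_a` identifiers defining
#'   the maternal pair subset.
#' @param config a [stat_config()].
#' @return An `mzt_ks` object.
#' @export
compare_maternal_vs_all <- function(fcs, maternal_pairs, config = stat_config()) {
  fcs <- as_tibble(fcs)
  assert_cols(fcs, c("gene_a", "log2_fc"), "fcs")
  sub <- fcs$log2_fc[fcs$gene_a %in% maternal_pairs]
  if (length(sub) == 0L) abort("maternal pair subset is empty")
  ks_one_sided(sub, fcs$log2_fc, config)
}

#' Intersect two pairwise 1:1 tables into a 1:1:1 set
#'
#' Restricts two pairwise ortholog tables sharing an anchor species to the
#' genes present in both, yielding the three-way single-ortholog set.
#'
#' @param pairs_ab,pairs_ac tibbles with columns `gene_a`, `gene_b` where
#'   `gene_a` is the anchor species in both.
#' @return list of the two tables restricted to the common anchor genes.
#' @export
restrict_one_to_one_to_one <- function(pairs_ab, pairs_ac) {
  common <- intersect(pairs_ab$gene_a, pairs_ac$gene_a)
  list(ab = pairs_ab[pairs_ab$gene_a %in% common, , drop = FALSE],
       ac = pairs_ac[pairs_ac$gene_a %in% common, , drop = FALSE])
}
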