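#' Statistical configuration for the KS sweep
#'
#' @param alpha significance level (default 0.05).
#' @param q_start first percentile of the sweep grid (default 15).
#' @param q_step grid increment in percent (default 5).
#' @param p_method `"asymptotic"` (one-sided large-sample formula) or
#'   `"permutation"` (label permutation; exhaustive when the number of
#'   splits is small).
#' @param n_permutations Monte Carlo permutation count (default 2000).
#' @param exact_limit enumerate all splits exactly when
#'   `choose(n_a + n_b, n_a)` does not exceed this (default 50000).
#' @param subset_anchor whose percentile defines the sweep truncation:
#'   `"reference"` (sample b, the default), `"pooled"`, or `"each"`.
#' @param seed optional integer seed scoping the permutation draws.
#' @return A list of class `stat_config`.
#' @export
stat_config <- function(alpha = 0.05, q_start = 15, q_step = 5,
                        p_method = c("asymptotic", "permutation"),
                        n_permutations = 2000, exact_limit = 50000,
                        subset_anchor = c("reference", "pooled", "each"),
                        seed = NULL) {
  p_method <- match.arg(p_method)
  subset_anchor <- match.arg(subset_anchor)
  stopifnot(alpha > 0, alpha < 1, q_start > 0, q_start <= 100, q_step > 0)
  structure(list(alpha = alpha, q_start = q_start, q_step = q_step,
                 p_method = p_method, n_permutations = n_permutations,
                 exact_limit = exact_limit, subset_anchor = subset_anchor,
                 seed = seed),
            class = "stat_config")
}

# signed sup of ECDF_b - ECDF_a over observed points (>= 0 by the limit at -Inf)
ks_statistic_right <- function(a, b) {
  x <- sort(unique(c(a, b)))
  fa <- stats::ecdf(a)(x)
  fb <- stats::ecdf(b)(x)
  max(0, max(fb - fa))
}

#' One-sided two-sample Kolmogorov-Smirnov test
#'
#' Tests whether `sample_a` is shifted to the right of `sample_b` (fewer
#' short values): the statistic is the supremum of the signed difference
#' between the empirical CDF of `sample_b` and that of `sample_a`. The
#' asymptotic p-value is `exp(-2 d^2 n_a n_b / (n_a + n_b))`; because region
#' lengths are integers with many ties, a permutation p-value (exhaustive
#' for small samples) is available as the exact alternative.
#'
#' @param sample_a,sample_b numeric length vectors (bp); `sample_a` is the
#'   class under evaluation, `sample_b` the reference.
#' @param config a [stat_config()].
#' @return An object of class `mzt_ks`: list with `d`, `p`, `n_a`, `n_b`,
#'   `direction`, `method`, `alpha`.
#' @export
ks_one_sided <- function(sample_a, sample_b, config = stat_config()) {
  if (length(sample_a) == 0L || length(sample_b) == 0L) {
    abort("both samples must be non-empty")
  }
  if (!all(is.finite(sample_a)) || !all(is.finite(sample_b))) {
    abort("samples must be finite")
  }
  d <- ks_statistic_right(sample_a, sample_b)
  na <- length(sample_a)
  nb <- length(sample_b)
  if (config$p_method == "asymptotic") {
    p <- exp(-2 * d^2 * na * nb / (na + nb))
    p <- min(max(p, .Machine$double.xmin), 1)
  } else {
    p <- ks_permutation_p(sample_a, sample_b, d, config)
  }
  structure(list(d = d, p = p, n_a = na, n_b = nb,
                 direction = "a shifted right of b",
                 method = config$p_method, alpha = config$alpha),
            class = "mzt_ks")
}

ks_permutation_p <- function(sample_a, sample_b, d_obs, config) {
  pooled <- c(sample_a, sample_b)
  n <- length(pooled)
  na <- length(sample_a)
  n_splits <- choose(n, na)
  eps <- 1e-12
  if (n_splits <= config$exact_limit) {
    idx <- combn(n, na)
    count <- 0L
    for (j in seq_len(ncol(idx))) {
      d <- ks_statistic_right(pooled[idx[, j]], pooled[-idx[, j]])
      if (d >= d_obs - eps) count <- count + 1L
    }
    count / ncol(idx)
  } else {
    with_seed_if(config$seed, {
      count <- 0L
      for (j in seq_len(config$n_permutations)) {
        take <- sample.int(n, na)
        d <- ks_statistic_right(pooled[take], pooled[-take])
        if (d >= d_obs - eps) count <- count + 1L
      }
      (count + 1) / (config$n_permutations + 1)
    })
  }
}

#' @export
print.mzt_ks <- function(x, ...) {
  cat(sprintf("One-sided two-sample KS (%s): D = %.4f, p = %.3g (n_a = %d, n_b = %d)\n",
              x$method, x$d, x$p, x$n_a, x$n_b))
  invisible(x)
}

#' Iterative percentile-subset KS sweep
#'
#' Quantifies where in the length distribution two samples differ, by
#' truncating both samples at increasing percentile cutoffs and re-running
#' the one-sided KS test on each truncation. The grid starts at the 15th
#' percentile and increments by 5% up to 100% (the untruncated test). By
#' default the cutoff at each grid point is the percentile of the reference
#' sample (`sample_b`), so the subsets are comparable across gene classes;
#' `subset_anchor` switches to pooled-sample or per-sample percentiles.
#' Reported are the minimum p-value over the grid with the percentile
#' attaining it, and the top-most percentile whose p-value is below `alpha`.
#' Raw per-percentile p-values are reported uncorrected (a Bonferroni
#' column is included for information only).
#'
#' @inheritParams ks_one_sided
#' @return An object of class `mzt_sweep`: list with `per_q` (tibble of
#'   `q`, `d`, `p`, `p_bonferroni`, `n_a`, `n_b`), `p_min`, `q_at_p_min`,
#'   `q_top_significant` (`NA` when no grid point is significant), `alpha`,
#'   `anchor`.
#' @export
percentile_sweep <- function(sample_a, sample_b, config = stat_config()) {
  if (length(sample_a) == 0L || length(sample_b) == 0L) {
    abort("both samples must be non-empty")
  }
  grid <- seq(config$q_start, 100, by = config$q_step)
  if (max(grid) < 100) grid <- c(grid, 100)
  rows <- purrr::map(grid, function(q) {
    if (q >= 100) {
      a <- sample_a
      b <- sample_b
    } else {
      a <- sample_a
      b <- sample_b
      if (config$subset_anchor == "each") {
        a <- a[a <= quantile(a, q / 100, names = FALSE)]
        b <- b[b <= quantile(b, q / 100, names = FALSE)]
      } else {
        ref <- if (config$subset_anchor == "pooled") c(sample_a, sample_b) else sample_b
        cut <- quantile(ref, q / 100, names = FALSE)
        a <- a[a <= cut]
        b <- b[b <= cut]
      }
    }
    if (length(a) == 0L || length(b) == 0L) return(NULL)
    ks <- ks_one_sided(a, b, config)
    tibble(q = q, d = ks$d, p = ks$p, n_a = ks$n_a, n_b = ks$n_b)
  })
  per_q <- bind_rows(rows)
  if (nrow(per_q) == 0L) abort("every percentile truncation left an empty sample")
  per_q$p_bonferroni <- pmin(1, per_q$p * nrow(per_q))
  per_q <- per_q[, c("q", "d", "p", "p_bonferroni", "n_a", "n_b")]
  i_min <- which.min(per_q$p)
  sig <- per_q$q[per_q$p < config$alpha]
  structure(list(per_q = per_q,
                 p_min = per_q$p[i_min],
                 q_at_p_min = per_q$q[i_min],
                 q_top_significant = if (length(sig) > 0L) max(sig) else NA_real_,
                 alpha = config$alpha,
                 anchor = config$subset_anchor),
            class = "mzt_sweep")
}

#' @export
print.mzt_sweep <- function(x, ...) {
  cat(sprintf("Percentile KS sweep (%d grid points, anchor = %s)\n",
              nrow(x$per_q), x$anchor))
  cat(sprintf("  min p = %.3g at the %gth percentile; top significant percentile: %s\n",
              x$p_min, x$q_at_p_min,
              if (is.na(x$q_top_significant)) "none" else
                sprintf("%g", x$q_top_significant)))
  invisible(x)
}
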