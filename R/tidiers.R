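#' Tidy a one-sided KS result
#'
#' @param x an `mzt_ks` object.
#' @param ... unused.
#' @return One-row tibble with `d`, `p`, `n_a`, `n_b`, `direction`, `method`.
#' @export
tidy.mzt_ks <- function(x, ...) {
  tibble(d = x$d, p = x$p, n_a = x$n_a, n_b = x$n_b,
         direction = x$direction, method = x$method)
}

#' @rdname tidy.mzt_ks
#' @export
glance.mzt_ks <- function(x, ...) tidy(x)

#' Tidy a percentile sweep
#'
#' @param x an `mzt_sweep` object.
#' @param ... unused.
#' @return The per-percentile tibble (`q`, `d`, `p`, `p_bonferroni`,
#'   `n_a`, `n_b`).
#' @export
tidy.mzt_sweep <- function(x, ...) x$per_q

#' One-row summary of a percentile sweep
#'
#' @param x an `mzt_sweep` object.
#' @param ... unused.
#' @return tibble with `p_min`, `q_at_p_min`, `q_top_significant`, `alpha`,
#'   `anchor`.
#' @export
glance.mzt_sweep <- function(x, ...) {
  tibble(p_min = x$p_min, q_at_p_min = x$q_at_p_min,
         q_top_significant = x$q_top_significant,
         alpha = x$alpha, anchor = x$anchor)
}

#' Plot a percentile sweep
#'
#' Shows -log10(p) along the percentile grid with the significance level
#' as a dashed line and the minimum-p percentile highlighted.
#'
#' @param object an `mzt_sweep` object.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.mzt_sweep <- function(object, ...) {
  df <- object$per_q
  ggplot2::ggplot(df, ggplot2::aes(x = .data$q, y = -log10(.data$p))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(object$alpha), linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$q_at_p_min, colour = "red",
                        linetype = "dotted") +
    ggplot2::labs(x = "percentile cutoff (%)", y = expression(-log[10](p)),
                  title = "Iterative percentile KS sweep") +
    ggplot2::theme_minimal()
}

#' Plot ortholog rank fold changes
#'
#' Empirical CDFs of log2 rank fold changes for all pairs and for the
#' maternal-pair subset (when a `maternal_pair` column is present).
#'
#' @param object a fold-change table from [rank_fold_changes()], optionally
#'   with a logical `maternal_pair` column.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.mzt_rank_fc <- function(object, ...) {
  df <- as_tibble(object)
  df$set <- "all pairs"
  if ("maternal_pair" %in% names(df)) {
    df <- bind_rows(df,
                    mutate(df[df$maternal_pair, , drop = FALSE],
                           set = "maternal pairs"))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_fc, colour = .data$set)) +
    ggplot2::stat_ecdf() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = expression(log[2] ~ "rank fold change"),
                  y = "cumulative fraction", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the maternal-to-genome ratio summary
#'
#' @param ratio a ratio table from [maternal_genome_ratio()] rows (several
#'   species), with `nutrition_class` filled in.
#' @return A ggplot object.
#' @export
plot_ratio_summary <- function(ratio) {
  ratio$nutrition_class <- factor(ratio$nutrition_class,
                                  levels = c("low", "medium", "high"))
  ggplot2::ggplot(ratio, ggplot2::aes(x = .data$nutrition_class,
                                      y = .data$ratio,
                                      colour = .data$measure,
                                      group = .data$measure)) +
    ggplot2::geom_point() +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "maternal nutritional contribution",
                  y = "maternal / genome 5' IGR ratio") +
    ggplot2::theme_minimal()
}
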