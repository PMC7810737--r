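#' QC RSD distribution before and after preprocessing
#'
#' @param before,after tibbles from [compute_rsd()].
#' @return a ggplot of the two empirical RSD distributions.
#' @export
plot_rsd_audit <- function(before, after) {
  df <- dplyr::bind_rows(
    dplyr::mutate(before, stage = "raw"),
    dplyr::mutate(after, stage = "preprocessed")
  ) |>
    dplyr::filter(is.finite(.data$rsd_pct))
  ggplot2::ggplot(df, ggplot2::aes(.data$rsd_pct,
                                   colour = factor(.data$stage, c("raw", "preprocessed")))) +
    ggplot2::stat_ecdf() +
    ggplot2::geom_vline(xintercept = c(5, 10), linetype = 3) +
    ggplot2::coord_cartesian(xlim = c(0, 50)) +
    ggplot2::labs(x = "pooled-QC RSD (%)", y = "fraction of metabolites",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Consensus significance against fold change
#'
#' Volcano-style view of a univariate table: biweight log2 fold change
#' against the average passing p-value, consensus calls highlighted.
#'
#' @param table a [univariate_table()] tibble.
#' @return a ggplot.
#' @export
plot_univariate <- function(table) {
  df <- dplyr::mutate(table,
                      best_p = pmin(.data$p_t, .data$p_wilcoxon,
                                    .data$p_binomial, na.rm = TRUE))
  ggplot2::ggplot(df, ggplot2::aes(.data$b_log2, -log10(.data$best_p),
                                   colour = .data$consensus)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "biweight log2 fold change (DEL/CNT)",
                  y = "-log10 best p", colour = "consensus") +
    ggplot2::theme_minimal()
}
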