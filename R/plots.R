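#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point geom_line
#'   geom_tile coord_flip labs scale_fill_gradient2 theme_minimal
NULL

#' Plot methods for ranking results
#'
#' `autoplot()` on a `topsis_result` or `saw_result` draws the per-drug
#' score as a sorted bar chart; on a `ranking_report` it draws a bump-style
#' comparison of the TOPSIS and SAW ranks (crossing lines mark drugs the
#' two methods order differently).
#'
#' @param object A `topsis_result`, `saw_result` or `ranking_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-adrank
NULL

score_barplot <- function(scores, value, title, xlab) {
  df <- scores[order(scores[[value]]), ]
  df$alternative <- factor(df$alternative, levels = df$alternative)
  ggplot(df, aes(x = .data$alternative, y = .data[[value]])) +
    geom_col(fill = "steelblue") +
    coord_flip() +
    labs(title = title, x = NULL, y = xlab) +
    theme_minimal()
}

#' @rdname autoplot-adrank
#' @method autoplot topsis_result
#' @export
autoplot.topsis_result <- function(object, ...) {
  score_barplot(object$scores, "closeness",
                "TOPSIS relative closeness to the ideal solution",
                "closeness coefficient")
}

#' @rdname autoplot-adrank
#' @method autoplot saw_result
#' @export
autoplot.saw_result <- function(object, ...) {
  score_barplot(object$scores, "total_score",
                "SAW weighted total scores", "total score")
}

#' @rdname autoplot-adrank
#' @method autoplot ranking_report
#' @export
autoplot.ranking_report <- function(object, ...) {
  rep <- object$report
  long <- tidyr::pivot_longer(
    rep[, c("alternative", "topsis_rank", "saw_rank")],
    cols = c("topsis_rank", "saw_rank"),
    names_to = "method", values_to = "rank"
  )
  long$method <- factor(ifelse(long$method == "topsis_rank", "TOPSIS", "SAW"),
                        levels = c("TOPSIS", "SAW"))
  ggplot(long, aes(x = .data$method, y = .data$rank,
                   group = .data$alternative)) +
    geom_line(colour = "grey60") +
    geom_point() +
    ggplot2::geom_text(
      data = long[long$method == "TOPSIS", ],
      aes(label = .data$alternative), hjust = 1.1, size = 3
    ) +
    ggplot2::scale_y_reverse(breaks = seq_len(nrow(rep))) +
    labs(title = "Rank agreement between TOPSIS and SAW",
         x = NULL, y = "rank (1 = best)") +
    theme_minimal()
}

#' Heatmap of the index-property correlation grid
#'
#' @param corr Long correlation grid from [correlate_indices()].
#' @return A ggplot object (tiles coloured by Pearson r).
#' @export
plot_correlation_grid <- function(corr) {
  corr <- tibble::as_tibble(corr)
  ggplot(corr, aes(x = .data$property, y = .data$index, fill = .data$r)) +
    geom_tile() +
    ggplot2::geom_text(aes(label = sprintf("%.2f", .data$r)), size = 3) +
    scale_fill_gradient2(limits = c(-1, 1), low = "steelblue",
                         mid = "white", high = "firebrick") +
    labs(title = "Index-property correlations", x = NULL, y = NULL) +
    theme_minimal()
}
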