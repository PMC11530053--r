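#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom rlang .data
NULL

#' Broom-style tidiers for adrank result objects
#'
#' `tidy()` returns the per-alternative score table (sorted by rank) of a
#' `topsis_result`, `saw_result` or `ranking_report`, or the coefficient
#' table of a `qspr_fit`.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy-adrank
NULL

#' One-row summaries for adrank result objects
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @name glance-adrank
NULL
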