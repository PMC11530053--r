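#' Linear normalization for simple additive weighting
#'
#' Converts every criterion to a maximizing scale in `(0, 1]`: a benefit
#' column is divided by its maximum (`x / max`), a cost column is inverted
#' through its minimum (`min / x`). Each column attains 1 at its best
#' alternative. A `scheme = "vector"` switch applies the Euclidean
#' normalization of [vector_normalize()] instead (direction handled by
#' reciprocal inversion first), for sensitivity analysis.
#'
#' @param D A decision matrix (see [as_decision_matrix()]).
#' @param directions See [as_directions()]; default all-benefit.
#' @param scheme `"max"` (default, the textbook SAW scale) or `"vector"`.
#' @return A tibble of the same shape as `D`.
#' @export
saw_normalize <- function(D, directions = "benefit", scheme = c("max", "vector")) {
  scheme <- match.arg(scheme)
  D <- as_decision_matrix(D)
  m <- table_to_matrix(D)
  dir <- as_directions(directions, colnames(m))
  cost <- dir == "cost"
  if (scheme == "max") {
    for (j in seq_len(ncol(m))) {
      m[, j] <- if (cost[j]) min(m[, j]) / m[, j] else m[, j] / max(m[, j])
    }
  } else {
    if (any(cost)) m[, cost] <- 1 / m[, cost, drop = FALSE]
    m <- sweep(m, 2, sqrt(colSums(m^2)), "/")
  }
  matrix_to_table(m)
}

#' Weighted total scores
#'
#' `TS_i = sum_j w_j * n_ij` over a normalized grid.
#'
#' @param N A normalized grid (first column labels).
#' @param w Weights (see [weight_matrix()]).
#' @return A tibble with columns `alternative`, `total_score`.
#' @export
saw_total_scores <- function(N, w) {
  N <- tibble::as_tibble(N)
  m <- table_to_matrix(N)
  w <- as_weight_vector(w, colnames(m))
  tibble::tibble(alternative = rownames(m),
                 total_score = as.numeric(m %*% w))
}

#' Rank alternatives by simple additive weighting (SAW)
#'
#' Normalizes the decision matrix to a maximizing scale, weights each
#' criterion, and sums to a total score per alternative; rank 1 is the
#' highest total score. With weights summing to 1 and max-normalization,
#' total scores lie in `(0, 1]` and a dominant alternative scores exactly 1.
#' Ties are handled as in [topsis_rank()].
#'
#' @inheritParams topsis_rank
#' @param scheme Normalization scheme, see [saw_normalize()].
#' @return An object of class `saw_result` with the audit trail:
#'   `normalized`, `weighted` grids and a `scores` tibble
#'   (`alternative`, `total_score`, `rank`), plus `ties`.
#' @export
#' @examples
#' D <- data.frame(drug = c("a", "b", "c"),
#'                 C1 = c(3, 4, 5), C2 = c(6, 5, 7))
#' saw_rank(D, weights = c(C1 = 0.5, C2 = 0.5))
saw_rank <- function(D, weights, directions = "benefit",
                     scheme = c("max", "vector"), tie_tol = 1e-12) {
  scheme <- match.arg(scheme)
  D <- as_decision_matrix(D)
  criteria <- names(D)[-1]
  w <- as_weight_vector(weights, criteria)
  dir <- as_directions(directions, criteria)
  N <- saw_normalize(D, dir, scheme)
  W <- weight_matrix(N, w)
  ts <- saw_total_scores(N, w)
  scores <- dplyr::mutate(ts, rank = rank_with_ties(.data$total_score, tie_tol))
  structure(
    list(decision = D, weights = w, directions = dir, scheme = scheme,
         normalized = N, weighted = W, scores = scores,
         ties = tie_groups(scores$alternative, scores$rank)),
    class = "saw_result"
  )
}

#' @export
print.saw_result <- function(x, ...) {
  cat(sprintf("<saw_result: %d alternatives x %d criteria, %s normalization>\n",
              nrow(x$scores), length(x$weights), x$scheme))
  print(dplyr::arrange(x$scores, .data$rank), ...)
  invisible(x)
}

#' @rdname tidy-adrank
#' @method tidy saw_result
#' @export
tidy.saw_result <- function(x, ...) {
  dplyr::arrange(x$scores, .data$rank)
}

#' @rdname glance-adrank
#' @method glance saw_result
#' @export
glance.saw_result <- function(x, ...) {
  tibble::tibble(
    n_alternatives = nrow(x$scores),
    n_criteria = length(x$weights),
    n_tie_groups = length(x$ties),
    best = x$scores$alternative[which.max(x$scores$total_score)],
    best_score = max(x$scores$total_score)
  )
}
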