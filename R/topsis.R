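#' Benefit/cost direction of each criterion
#'
#' A benefit criterion is one where larger values are preferable (its ideal
#' is the column maximum); a cost criterion prefers smaller values. The
#' direction decides which extreme is "ideal" in TOPSIS and which
#' normalization SAW applies.
#'
#' @param dir One of: a single string `"benefit"` or `"cost"` (recycled to
#'   all criteria); a named character vector; or a data frame with columns
#'   `criterion` and `direction`. Criteria without an entry default to
#'   benefit with a warning.
#' @param criteria Character vector of criterion names to cover.
#' @return A named character vector over `criteria` with values
#'   `"benefit"` or `"cost"`.
#' @export
as_directions <- function(dir, criteria) {
  if (is.data.frame(dir)) {
    if (!all(c("criterion", "direction") %in% names(dir))) {
      rlang::abort("direction table needs columns `criterion` and `direction`",
                   class = "adrank_format_error")
    }
    dir <- stats::setNames(dir$direction, dir$criterion)
  }
  if (!is.character(dir)) {
    rlang::abort("directions must be character", class = "adrank_format_error")
  }
  if (is.null(names(dir))) {
    if (length(dir) == 1L) dir <- stats::setNames(rep(dir, length(criteria)), criteria)
    else if (length(dir) == length(criteria)) names(dir) <- criteria
    else rlang::abort("unnamed directions must be length 1 or match the criteria",
                      class = "adrank_dimension_error")
  }
  missing <- setdiff(criteria, names(dir))
  if (length(missing)) {
    rlang::warn(sprintf("no direction given for %s; defaulting to benefit",
                        paste(missing, collapse = ", ")))
    dir[missing] <- "benefit"
  }
  dir <- dir[criteria]
  if (!all(dir %in% c("benefit", "cost"))) {
    rlang::abort("directions must be 'benefit' or 'cost'",
                 class = "adrank_format_error")
  }
  dir
}

#' Euclidean (vector) normalization of a decision matrix
#'
#' `r_ij = x_ij / sqrt(sum_i x_ij^2)`: each criterion column is scaled to
#' unit Euclidean norm. This is the TOPSIS normalization.
#'
#' @param D A decision matrix (see [as_decision_matrix()]).
#' @return A tibble of the same shape; every column has norm 1.
#' @export
vector_normalize <- function(D) {
  D <- as_decision_matrix(D)
  m <- table_to_matrix(D)
  matrix_to_table(sweep(m, 2, sqrt(colSums(m^2)), "/"))
}

#' Apply criterion weights to a normalized grid
#'
#' `v_ij = w_j * r_ij`, column by column.
#'
#' @param R A normalized grid (first column labels).
#' @param w Weights as accepted by [entropy_weights()] output, a named
#'   numeric vector, or a bare numeric vector in column order.
#' @return A tibble of the same shape as `R`.
#' @export
weight_matrix <- function(R, w) {
  R <- tibble::as_tibble(R)
  m <- table_to_matrix(R)
  w <- as_weight_vector(w, colnames(m))
  matrix_to_table(sweep(m, 2, w, "*"))
}

#' Ideal and anti-ideal points of a weighted grid
#'
#' For a benefit criterion the ideal is the column maximum and the
#' anti-ideal the column minimum; for a cost criterion the roles reverse.
#'
#' @param V A weighted normalized grid (first column labels).
#' @param directions See [as_directions()]; default all-benefit.
#' @return A list with named numeric vectors `ideal` and `anti_ideal`.
#' @export
ideal_points <- function(V, directions = "benefit") {
  m <- table_to_matrix(tibble::as_tibble(V))
  dir <- as_directions(directions, colnames(m))
  hi <- apply(m, 2, max)
  lo <- apply(m, 2, min)
  cost <- dir == "cost"
  ideal <- ifelse(cost, lo, hi)
  anti <- ifelse(cost, hi, lo)
  list(ideal = stats::setNames(ideal, colnames(m)),
       anti_ideal = stats::setNames(anti, colnames(m)))
}

#' Separation of each alternative from the ideal and anti-ideal points
#'
#' Euclidean distances of each alternative's weighted row to the ideal
#' (`p_plus`) and anti-ideal (`p_minus`) points.
#'
#' @param V A weighted normalized grid (first column labels).
#' @param ideal,anti_ideal Named numeric vectors as from [ideal_points()].
#' @return A tibble with columns `alternative`, `p_plus`, `p_minus`.
#' @export
separation_measures <- function(V, ideal, anti_ideal) {
  m <- table_to_matrix(tibble::as_tibble(V))
  if (length(ideal) != ncol(m) || length(anti_ideal) != ncol(m)) {
    rlang::abort("ideal point length must match the number of criteria",
                 class = "adrank_dimension_error")
  }
  tibble::tibble(
    alternative = rownames(m),
    p_plus = unname(sqrt(rowSums(sweep(m, 2, ideal)^2))),
    p_minus = unname(sqrt(rowSums(sweep(m, 2, anti_ideal)^2)))
  )
}

#' Relative closeness to the ideal solution
#'
#' `C_i = p_minus_i / (p_plus_i + p_minus_i)`, in `[0, 1]`; 1 means the
#' alternative sits at the ideal point, 0 at the anti-ideal.
#'
#' @param p_plus,p_minus Non-negative separation measures.
#' @return Numeric vector of closeness coefficients.
#' @export
closeness_coefficient <- function(p_plus, p_minus) {
  stopifnot(length(p_plus) == length(p_minus))
  if (any(p_plus < 0 | p_minus < 0)) {
    rlang::abort("separation measures must be non-negative",
                 class = "adrank_format_error")
  }
  denom <- p_plus + p_minus
  if (any(denom == 0)) {
    rlang::abort(
      "degenerate instance: an alternative is simultaneously ideal and anti-ideal (all criteria constant)",
      class = "adrank_degenerate_error"
    )
  }
  p_minus / denom
}

#' Rank alternatives by TOPSIS
#'
#' Runs the full Technique for Order of Preference by Similarity to Ideal
#' Solution: vector normalization, weighting, ideal/anti-ideal points,
#' Euclidean separation measures, and the relative closeness coefficient.
#' Rank 1 is the largest closeness; alternatives whose closeness values
#' agree within `tie_tol` share the minimum rank and subsequent ranks are
#' skipped (competition ranking).
#'
#' @param D A decision matrix (see [as_decision_matrix()]).
#' @param weights See [weight_matrix()].
#' @param directions See [as_directions()]; default all-benefit.
#' @param tie_tol Absolute tolerance within which closeness values tie.
#' @return An object of class `topsis_result` holding the full audit trail:
#'   `normalized`, `weighted`, `ideal`, `anti_ideal`, and a `scores` tibble
#'   with `alternative`, `p_plus`, `p_minus`, `closeness`, `rank`, plus
#'   `ties` (list of tied groups). Use [tidy()] to extract the score table.
#' @export
#' @examples
#' D <- data.frame(drug = c("a", "b", "c"),
#'                 C1 = c(3, 4, 5), C2 = c(6, 5, 7))
#' topsis_rank(D, weights = c(C1 = 0.5, C2 = 0.5))
topsis_rank <- function(D, weights, directions = "benefit", tie_tol = 1e-12) {
  D <- as_decision_matrix(D)
  criteria <- names(D)[-1]
  w <- as_weight_vector(weights, criteria)
  dir <- as_directions(directions, criteria)
  R <- vector_normalize(D)
  V <- weight_matrix(R, w)
  pts <- ideal_points(V, dir)
  sep <- separation_measures(V, pts$ideal, pts$anti_ideal)
  cc <- closeness_coefficient(sep$p_plus, sep$p_minus)
  scores <- dplyr::mutate(sep, closeness = cc,
                          rank = rank_with_ties(cc, tie_tol))
  structure(
    list(decision = D, weights = w, directions = dir,
         normalized = R, weighted = V,
         ideal = pts$ideal, anti_ideal = pts$anti_ideal,
         scores = scores,
         ties = tie_groups(scores$alternative, scores$rank)),
    class = "topsis_result"
  )
}

#' @export
print.topsis_result <- function(x, ...) {
  cat(sprintf("<topsis_result: %d alternatives x %d criteria>\n",
              nrow(x$scores), length(x$weights)))
  print(dplyr::arrange(x$scores, .data$rank), ...)
  if (length(x$ties)) {
    cat("ties:", paste(vapply(x$ties, paste, "", collapse = " = "),
                       collapse = "; "), "\n")
  }
  invisible(x)
}

#' @rdname tidy-adrank
#' @method tidy topsis_result
#' @export
tidy.topsis_result <- function(x, ...) {
  dplyr::arrange(x$scores, .data$rank)
}

#' @rdname glance-adrank
#' @method glance topsis_result
#' @export
glance.topsis_result <- function(x, ...) {
  tibble::tibble(
    n_alternatives = nrow(x$scores),
    n_criteria = length(x$weights),
    n_tie_groups = length(x$ties),
    best = x$scores$alternative[which.max(x$scores$closeness)],
    best_closeness = max(x$scores$closeness)
  )
}
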