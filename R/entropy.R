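#' Validate a decision matrix
#'
#' A decision matrix holds the performance of `m >= 2` alternatives (rows)
#' on `n >= 1` criteria (columns) as strictly positive reals. The first
#' column carries the alternative labels; every other column must be
#' numeric. Strict positivity is required by the entropy weighting stage
#' (logarithms) and by the ratio normalizations of TOPSIS and SAW.
#'
#' @param x A data frame whose first column is the alternative label (any
#'   name; it is renamed to `alternative`) and whose remaining columns are
#'   the criteria.
#' @param shift_zeros If `TRUE`, entries equal to zero are shifted up by
#'   `1e-6 * max(column)` before validation, a conventional preprocessing
#'   step for data with structural zeros. Off by default; negative entries
#'   are always rejected.
#' @return A tibble: `alternative` followed by the criterion columns.
#' @export
as_decision_matrix <- function(x, shift_zeros = FALSE) {
  x <- tibble::as_tibble(x)
  if (ncol(x) < 2L) {
    rlang::abort("need a label column plus at least one criterion column",
                 class = "adrank_format_error")
  }
  names(x)[1] <- "alternative"
  x$alternative <- as.character(x$alternative)
  if (anyDuplicated(x$alternative)) {
    rlang::abort("duplicate alternative labels", class = "adrank_format_error")
  }
  if (anyDuplicated(names(x))) {
    rlang::abort("duplicate criterion labels", class = "adrank_format_error")
  }
  if (nrow(x) < 2L) {
    rlang::abort("a decision matrix needs at least 2 alternatives",
                 class = "adrank_format_error")
  }
  vals <- x[, -1, drop = FALSE]
  if (!all(vapply(vals, is.numeric, logical(1)))) {
    rlang::abort("criterion columns must be numeric",
                 class = "adrank_format_error")
  }
  if (anyNA(vals)) {
    rlang::abort("decision matrix entries must not be missing",
                 class = "adrank_format_error")
  }
  if (shift_zeros) {
    x[, -1] <- lapply(vals, function(col) {
      if (any(col == 0)) col + 1e-6 * max(col) else col
    })
    vals <- x[, -1, drop = FALSE]
  }
  if (any(as.matrix(vals) <= 0)) {
    rlang::abort("decision matrix entries must be strictly positive",
                 class = "adrank_positivity_error")
  }
  x
}

#' Column-wise proportional normalization
#'
#' Rescales each criterion column to proportions over the alternatives,
#' `r_ij = x_ij / sum_i x_ij`, so every column sums to 1. This is the
#' normalization the entropy weighting uses.
#'
#' @param D A decision matrix (see [as_decision_matrix()]).
#' @return A tibble of the same shape with all columns summing to 1.
#' @export
column_normalize <- function(D) {
  D <- as_decision_matrix(D)
  m <- table_to_matrix(D)
  matrix_to_table(sweep(m, 2, colSums(m), "/"))
}

#' Shannon entropy of each criterion column
#'
#' For a column of proportions `r_ij` over `m` alternatives, the entropy is
#' `E_j = -(1 / ln m) * sum_i r_ij ln r_ij`, with the convention
#' `0 * ln 0 = 0`. `E_j = 1` for a uniform column (no discriminating
#' information) and `E_j = 0` for a one-hot column.
#'
#' @param R A normalized grid as returned by [column_normalize()]: first
#'   column labels, criterion columns summing to 1 with entries in `[0, 1]`.
#' @return A tibble with columns `criterion` and `entropy`.
#' @export
criterion_entropy <- function(R) {
  R <- tibble::as_tibble(R)
  m <- table_to_matrix(R)
  if (nrow(m) < 2L) {
    rlang::abort("entropy is undefined for fewer than 2 alternatives (ln m = 0)",
                 class = "adrank_degenerate_error")
  }
  if (any(m < 0) || any(abs(colSums(m) - 1) > 1e-8)) {
    rlang::abort("columns must be proportions summing to 1; run column_normalize() first",
                 class = "adrank_format_error")
  }
  plogp <- ifelse(m > 0, m * log(m), 0)
  tibble::tibble(
    criterion = colnames(m),
    entropy = unname(-colSums(plogp) / log(nrow(m)))
  )
}

#' Objective criterion weights by the entropy method
#'
#' Converts per-criterion entropies into weights
#' `w_j = (1 - E_j) / sum_j (1 - E_j)`: the less uniform (more dispersed) a
#' criterion's column, the lower its entropy and the higher its weight.
#' Weights are non-negative and sum to 1, and are invariant to positive
#' rescaling of any criterion column.
#'
#' @param x Either a decision matrix (the full chain
#'   normalize -> entropy -> weights is run) or a numeric vector of
#'   entropies in `[0, 1]`, optionally named by criterion.
#' @param equal_fallback When every criterion is perfectly uniform
#'   (`E_j = 1` for all `j`) the weights are undefined; with
#'   `equal_fallback = TRUE` equal weights `1/n` are returned with a
#'   warning instead of an error.
#' @return A tibble with columns `criterion`, `entropy`, `weight`.
#' @export
#' @examples
#' D <- data.frame(drug = c("a", "b", "c"),
#'                 C1 = c(1, 1, 2), C2 = c(5, 5, 5))
#' entropy_weights(D)  # uniform C2 gets weight 0
entropy_weights <- function(x, equal_fallback = FALSE) {
  if (is.data.frame(x)) {
    E <- criterion_entropy(column_normalize(x))
  } else if (is.numeric(x)) {
    if (any(x < -1e-9 | x > 1 + 1e-9)) {
      rlang::abort("entropies must lie in [0, 1]", class = "adrank_format_error")
    }
    E <- tibble::tibble(
      criterion = names(x) %||% paste0("C", seq_along(x)),
      entropy = pmin(pmax(as.numeric(x), 0), 1)
    )
  } else {
    rlang::abort("`x` must be a decision matrix or a numeric entropy vector",
                 class = "adrank_format_error")
  }
  d <- 1 - E$entropy
  if (sum(d) <= 1e-12) {
    if (!equal_fallback) {
      rlang::abort(
        "all criteria are uniform (entropy 1 everywhere): weights undefined; set equal_fallback = TRUE for equal weights",
        class = "adrank_degenerate_weights"
      )
    }
    rlang::warn("all criteria uniform; falling back to equal weights")
    d <- rep(1, nrow(E))
  }
  tibble::tibble(criterion = E$criterion, entropy = E$entropy,
                 weight = d / sum(d))
}

# Coerce weights to a named numeric vector over `criteria`, validating
# non-negativity and sum-to-one.
as_weight_vector <- function(w, criteria) {
  if (is.data.frame(w)) {
    if (!all(c("criterion", "weight") %in% names(w))) {
      rlang::abort("weight table needs columns `criterion` and `weight`",
                   class = "adrank_format_error")
    }
    w <- stats::setNames(w$weight, w$criterion)
  }
  if (!is.numeric(w)) {
    rlang::abort("weights must be numeric", class = "adrank_format_error")
  }
  if (is.null(names(w))) {
    if (length(w) != length(criteria)) {
      rlang::abort("unnamed weights must match the number of criteria",
                   class = "adrank_dimension_error")
    }
    names(w) <- criteria
  }
  if (!all(criteria %in% names(w))) {
    rlang::abort(sprintf("missing weights for criteria: %s",
                         paste(setdiff(criteria, names(w)), collapse = ", ")),
                 class = "adrank_dimension_error")
  }
  w <- w[criteria]
  if (any(w < 0)) {
    rlang::abort("weights must be non-negative", class = "adrank_format_error")
  }
  if (abs(sum(w) - 1) > 1e-6) {
    rlang::abort("weights must sum to 1", class = "adrank_format_error")
  }
  w
}
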