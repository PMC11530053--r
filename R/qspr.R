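#' Physicochemical property vocabulary and preferred directions
#'
#' The QSPR stage works with six standard physicochemical properties.
#' `property_vocabulary()` gives their canonical order (also the tie-break
#' order in [allocate_property_to_index()]); `property_directions()` gives
#' the fixed pharmacological preference for each: higher boiling point
#' (less volatile), higher molecular weight (better absorption) and higher
#' flash point (less flammable) are benefits, while lower melting point
#' (better absorption), lower density (less resistance to absorption) and
#' lower complexity (fewer administration risks) are preferred, making
#' those three cost criteria.
#'
#' @return `property_vocabulary()`: a character vector.
#'   `property_directions()`: a tibble with columns `property`, `direction`.
#' @export
property_vocabulary <- function() {
  c("melting_point", "boiling_point", "molecular_weight",
    "density", "flash_point", "complexity")
}

#' @rdname property_vocabulary
#' @export
property_directions <- function() {
  tibble::tibble(
    property = property_vocabulary(),
    direction = c("cost", "benefit", "benefit", "cost", "benefit", "cost")
  )
}

#' Validate a physicochemical property table
#'
#' @param x A data frame: first column alternative labels, remaining
#'   columns named from [property_vocabulary()] (units: melting, boiling
#'   and flash points in degrees Celsius, molecular weight in g/mol,
#'   density in g/cm^3, complexity dimensionless). Missing entries are
#'   allowed and handled pairwise downstream.
#' @return A tibble with first column `alternative`; the per-property
#'   missingness count is attached as attribute `n_missing`.
#' @export
as_property_table <- function(x) {
  x <- tibble::as_tibble(x)
  if (ncol(x) < 2L) {
    rlang::abort("need a label column plus at least one property column",
                 class = "adrank_format_error")
  }
  names(x)[1] <- "alternative"
  x$alternative <- as.character(x$alternative)
  unknown <- setdiff(names(x)[-1], property_vocabulary())
  if (length(unknown)) {
    rlang::abort(sprintf("unknown properties: %s (vocabulary: %s)",
                         paste(unknown, collapse = ", "),
                         paste(property_vocabulary(), collapse = ", ")),
                 class = "adrank_format_error")
  }
  if (!all(vapply(x[-1], is.numeric, logical(1)))) {
    rlang::abort("property columns must be numeric",
                 class = "adrank_format_error")
  }
  attr(x, "n_missing") <- vapply(x[-1], function(col) sum(is.na(col)), 0L)
  x
}

#' Correlate topological indices with physicochemical properties
#'
#' Pearson (or Spearman) correlation between every index column and every
#' property column over the alternatives shared by the two tables, using
#' pairwise-complete observations. A property (or index) that is constant
#' over the shared alternatives has no defined correlation; the cell is
#' returned as `NA`, never coerced to 0.
#'
#' @param indices Output of [compute_indices()] (or any table whose first
#'   column labels the alternatives and whose other columns are indices).
#' @param properties A property table (see [as_property_table()]).
#' @param method `"pearson"` (default, the standard QSPR choice) or
#'   `"spearman"` for a rank-based sensitivity check.
#' @return A long tibble with columns `index`, `property`, `r`, `n_used`.
#' @export
correlate_indices <- function(indices, properties,
                              method = c("pearson", "spearman")) {
  method <- match.arg(method)
  indices <- tibble::as_tibble(indices)
  names(indices)[1] <- "alternative"
  properties <- as_property_table(properties)
  shared <- intersect(indices$alternative, properties$alternative)
  if (length(shared) < 3L) {
    rlang::abort("need at least 3 shared alternatives to correlate",
                 class = "adrank_format_error")
  }
  xi <- indices[match(shared, indices$alternative), -1, drop = FALSE]
  yp <- properties[match(shared, properties$alternative), -1, drop = FALSE]
  grid <- tidyr::expand_grid(index = names(xi), property = names(yp))
  purrr::pmap_dfr(grid, function(index, property) {
    x <- xi[[index]]
    y <- yp[[property]]
    ok <- stats::complete.cases(x, y)
    n <- sum(ok)
    r <- if (n >= 3L && stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0) {
      stats::cor(x[ok], y[ok], method = method)
    } else {
      NA_real_
    }
    tibble::tibble(index = index, property = property, r = r, n_used = n)
  })
}

#' Fit a simple linear QSPR regression
#'
#' Ordinary least squares of a property on a single index,
#' `y = slope * x + intercept`, the one-descriptor linear model
#' conventional in QSPR screening.
#'
#' @param x Index values (numeric).
#' @param y Property values (numeric, same length; `NA` pairs dropped).
#' @param index_name,property_name Labels carried into the result.
#' @return An object of class `qspr_fit` with fields `index_name`,
#'   `property_name`, `slope`, `intercept`, `se_slope`, `pearson_r`,
#'   `r_squared`, `n_used`, and the underlying `lm` fit as `model`.
#' @export
#' @examples
#' f <- fit_simple_regression(c(0, 1, 2), c(0, 2, 4))
#' f$slope      # 2
#' f$r_squared  # 1
fit_simple_regression <- function(x, y, index_name = "index",
                                  property_name = "property") {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) {
    rlang::abort("need at least 3 complete observations",
                 class = "adrank_format_error")
  }
  if (stats::sd(x) == 0) {
    rlang::abort("index values are constant: singular fit",
                 class = "adrank_singular_fit")
  }
  fit <- stats::lm(y ~ x)
  # summary() warns on an exactly collinear (zero-residual) fit; such fits
  # are legitimate here (noise-free synthetic panels)
  co <- stats::coef(suppressWarnings(summary(fit)))
  r <- if (stats::sd(y) == 0) 0 else stats::cor(x, y)
  structure(
    list(index_name = index_name, property_name = property_name,
         slope = unname(co["x", "Estimate"]),
         intercept = unname(co["(Intercept)", "Estimate"]),
         se_slope = unname(co["x", "Std. Error"]),
         pearson_r = r, r_squared = r^2, n_used = length(x),
         model = fit),
    class = "qspr_fit"
  )
}

#' @export
print.qspr_fit <- function(x, ...) {
  cat(sprintf("<qspr_fit: %s ~ %s, slope %.4g (SE %.3g), R^2 %.3f, n = %d>\n",
              x$property_name, x$index_name, x$slope, x$se_slope,
              x$r_squared, x$n_used))
  invisible(x)
}

#' @rdname tidy-adrank
#' @method tidy qspr_fit
#' @export
tidy.qspr_fit <- function(x, ...) {
  tibble::tibble(
    index = x$index_name, property = x$property_name,
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = c(unname(stats::coef(suppressWarnings(summary(x$model)))["(Intercept)", "Std. Error"]),
                  x$se_slope)
  )
}

#' @rdname glance-adrank
#' @method glance qspr_fit
#' @export
glance.qspr_fit <- function(x, ...) {
  tibble::tibble(index = x$index_name, property = x$property_name,
                 pearson_r = x$pearson_r, r.squared = x$r_squared,
                 n_used = x$n_used)
}

#' Allocate each index its best-correlated property
#'
#' Assigns to every index the property with the largest absolute
#' correlation; ties are broken by [property_vocabulary()] order, and an
#' index with no defined correlation is left unallocated (`NA`).
#'
#' @param corr Long correlation grid from [correlate_indices()].
#' @return A tibble with columns `index`, `property`, `r` (one row per
#'   index, in the input's index order).
#' @export
allocate_property_to_index <- function(corr) {
  corr <- tibble::as_tibble(corr)
  vocab <- property_vocabulary()
  corr$property <- factor(corr$property, levels = vocab)
  corr |>
    dplyr::group_by(.data$index) |>
    dplyr::arrange(dplyr::desc(abs(.data$r)), .data$property,
                   .by_group = TRUE) |>
    dplyr::summarise(
      property = if (all(is.na(.data$r))) NA_character_
                 else as.character(.data$property[!is.na(.data$r)][1]),
      r = if (all(is.na(.data$r))) NA_real_ else .data$r[!is.na(.data$r)][1],
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$index, unique(corr$index)))
}

#' Derive criterion directions from a property allocation
#'
#' Each index criterion inherits the benefit/cost direction of its
#' allocated physicochemical property (see [property_directions()]).
#' Unallocated indices default to benefit with a warning.
#'
#' @param alloc Allocation table from [allocate_property_to_index()].
#' @return A tibble with columns `criterion`, `property`, `direction`,
#'   usable as the `directions` argument of [topsis_rank()] and
#'   [saw_rank()].
#' @export
criterion_directions_from_properties <- function(alloc) {
  alloc <- tibble::as_tibble(alloc)
  dirs <- property_directions()
  out <- tibble::tibble(
    criterion = alloc$index,
    property = alloc$property,
    direction = dirs$direction[match(alloc$property, dirs$property)]
  )
  if (anyNA(out$direction)) {
    rlang::warn(sprintf("indices without an allocated property default to benefit: %s",
                        paste(out$criterion[is.na(out$direction)], collapse = ", ")))
    out$direction[is.na(out$direction)] <- "benefit"
  }
  out
}
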