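#' Run the full drug-ranking pipeline
#'
#' Orchestrates the whole analysis: molecular graphs (or a precomputed
#' decision matrix) -> topological indices -> entropy criterion weights ->
#' TOPSIS and SAW rankings -> rank-agreement report. Every defaulted
#' assumption (all-benefit directions, equal-weight fallback, ties) is
#' recorded in the report's `assumptions` log and emitted as messages, so
#' the configuration behind a ranking is always auditable.
#'
#' @param input One of: a named list of [molecular_graph()] objects, a
#'   single path to a SMILES list file (see [read_smiles()]), or a decision
#'   matrix data frame (first column = alternative labels).
#' @param weights `"entropy"` (default: weights derived from the decision
#'   matrix by [entropy_weights()]) or explicit weights as accepted by
#'   [topsis_rank()].
#' @param directions `"benefit"` (default: every criterion treated as
#'   benefit), `"qspr"` (directions derived from `properties` via the
#'   correlation/allocation chain), or explicit directions as accepted by
#'   [as_directions()].
#' @param properties Property table, required when `directions = "qspr"`.
#' @param saw_scheme Normalization scheme for SAW, see [saw_normalize()].
#' @param tie_tol Tie tolerance for both rankings.
#' @param equal_fallback Passed to [entropy_weights()].
#' @param out_dir Optional directory; when given, the decision matrix,
#'   weights, both score tables and the combined report are written there
#'   as CSV files (plus a full-precision JSON sidecar).
#' @return An object of class `ranking_report`: list with `decision`,
#'   `weights`, `directions`, `topsis`, `saw`, `report` (per-alternative
#'   tibble with both scores and ranks), `comparison` (from
#'   [compare_rankings()]) and `assumptions` (character log).
#' @export
#' @examples
#' smi <- system.file("extdata", "ad_drugs.smi", package = "adrank")
#' rep <- run_full_ranking(read_smiles(smi))
#' tidy(rep)
run_full_ranking <- function(input, weights = "entropy",
                             directions = "benefit", properties = NULL,
                             saw_scheme = c("max", "vector"),
                             tie_tol = 1e-12, equal_fallback = FALSE,
                             out_dir = NULL) {
  saw_scheme <- match.arg(saw_scheme)
  assumptions <- character(0)
  note <- function(msg) {
    assumptions <<- c(assumptions, msg)
    rlang::inform(paste0("adrank: ", msg))
  }

  # --- input stage -----------------------------------------------------
  if (is.character(input) && length(input) == 1L) {
    input <- read_smiles(input)
  }
  if (inherits(input, "molecular_graph")) input <- list(input)
  if (is.list(input) && !is.data.frame(input) &&
      all(vapply(input, inherits, logical(1), "molecular_graph"))) {
    idx <- compute_indices(input)
    D <- as_decision_matrix(idx)
  } else if (is.data.frame(input)) {
    D <- as_decision_matrix(input)
  } else {
    rlang::abort("`input` must be molecular graphs, a SMILES file path, or a decision matrix",
                 class = "adrank_format_error")
  }
  criteria <- names(D)[-1]

  # --- weights ---------------------------------------------------------
  if (identical(weights, "entropy")) {
    wtab <- entropy_weights(D, equal_fallback = equal_fallback)
    note("criterion weights derived objectively by the entropy method")
  } else {
    wtab <- tibble::tibble(criterion = criteria,
                           entropy = NA_real_,
                           weight = as_weight_vector(weights, criteria))
    note("criterion weights supplied by the user")
  }
  w <- stats::setNames(wtab$weight, wtab$criterion)

  # --- directions ------------------------------------------------------
  if (identical(directions, "qspr")) {
    if (is.null(properties)) {
      rlang::abort("directions = 'qspr' needs a `properties` table",
                   class = "adrank_format_error")
    }
    corr <- correlate_indices(D, properties)
    alloc <- allocate_property_to_index(corr)
    dtab <- criterion_directions_from_properties(alloc)
    dir <- as_directions(dtab[, c("criterion", "direction")], criteria)
    note(sprintf("criterion directions from QSPR property allocation (%s)",
                 paste(sprintf("%s->%s", dtab$criterion, dtab$property),
                       collapse = ", ")))
  } else if (identical(directions, "benefit")) {
    dir <- as_directions("benefit", criteria)
    note("all criteria treated as benefit (default assumption)")
  } else {
    dir <- as_directions(directions, criteria)
    note("criterion directions supplied by the user")
  }

  # --- rankings --------------------------------------------------------
  top <- topsis_rank(D, w, dir, tie_tol = tie_tol)
  sw <- saw_rank(D, w, dir, scheme = saw_scheme, tie_tol = tie_tol)
  if (length(top$ties)) note("TOPSIS closeness ties detected")
  if (length(sw$ties)) note("SAW total-score ties detected")

  report <- dplyr::inner_join(
    dplyr::select(top$scores, "alternative", topsis_closeness = "closeness",
                  topsis_rank = "rank"),
    dplyr::select(sw$scores, "alternative", saw_score = "total_score",
                  saw_rank = "rank"),
    by = "alternative"
  ) |> dplyr::arrange(.data$topsis_rank)

  comparison <- compare_rankings(
    stats::setNames(report$topsis_rank, report$alternative),
    stats::setNames(report$saw_rank, report$alternative)
  )

  out <- structure(
    list(decision = D, weights = wtab, directions = dir,
         topsis = top, saw = sw, report = report,
         comparison = comparison, assumptions = assumptions),
    class = "ranking_report"
  )
  if (!is.null(out_dir)) write_ranking_report(out, out_dir)
  out
}

write_ranking_report <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(x$decision, file.path(out_dir, "decision_matrix.csv"))
  readr::write_csv(x$weights, file.path(out_dir, "weights.csv"))
  readr::write_csv(x$topsis$scores, file.path(out_dir, "topsis.csv"))
  readr::write_csv(x$saw$scores, file.path(out_dir, "saw.csv"))
  readr::write_csv(x$report, file.path(out_dir, "report.csv"))
  sidecar <- list(
    report = x$report, kendall_tau = x$comparison$tau,
    agreement = x$comparison$agreement, assumptions = x$assumptions
  )
  writeLines(jsonlite_json(sidecar), file.path(out_dir, "report.json"))
  invisible(out_dir)
}

# serialize without adding jsonlite to Imports' hot path elsewhere
jsonlite_json <- function(x) {
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
}

#' @export
print.ranking_report <- function(x, ...) {
  cat(sprintf("<ranking_report: %d alternatives, %d criteria>\n",
              nrow(x$report), nrow(x$weights)))
  print(x$report, ...)
  cat(sprintf("Kendall tau-b between methods: %.4f\n", x$comparison$tau))
  if (length(x$comparison$agreement)) {
    cat("same rank in both methods:",
        paste(x$comparison$agreement, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname tidy-adrank
#' @method tidy ranking_report
#' @export
tidy.ranking_report <- function(x, ...) x$report

#' @rdname glance-adrank
#' @method glance ranking_report
#' @export
glance.ranking_report <- function(x, ...) {
  tibble::tibble(
    n_alternatives = nrow(x$report),
    n_criteria = nrow(x$weights),
    kendall_tau = x$comparison$tau,
    n_same_rank = length(x$comparison$agreement),
    topsis_best = x$report$alternative[which.min(x$report$topsis_rank)],
    saw_best = x$report$alternative[which.min(x$report$saw_rank)]
  )
}

#' Agreement between two rankings of the same alternatives
#'
#' Computes the tie-aware Kendall tau-b rank correlation between two
#' rankings and lists the alternatives assigned identical rank by both.
#'
#' @param r1,r2 Integer rank vectors named by alternative, or data frames
#'   with columns `alternative` and `rank`.
#' @return A list with `tau` (Kendall tau-b), `agreement` (character vector
#'   of alternatives with equal rank in both) and `table` (tibble with
#'   columns `alternative`, `rank1`, `rank2`).
#' @export
#' @examples
#' compare_rankings(c(a = 1, b = 2, c = 3), c(a = 1, b = 3, c = 2))
compare_rankings <- function(r1, r2) {
  pick <- function(r) {
    if (is.data.frame(r)) {
      stats::setNames(r$rank, r$alternative)
    } else if (is.numeric(r) && !is.null(names(r))) {
      r
    } else {
      rlang::abort("rankings must be named numeric vectors or (alternative, rank) tables",
                   class = "adrank_format_error")
    }
  }
  r1 <- pick(r1); r2 <- pick(r2)
  if (!setequal(names(r1), names(r2)) || length(r1) != length(r2)) {
    rlang::abort("the two rankings must cover the same alternative set",
                 class = "adrank_label_error")
  }
  r2 <- r2[names(r1)]
  tau <- stats::cor(r1, r2, method = "kendall")
  list(
    tau = as.numeric(tau),
    agreement = names(r1)[r1 == r2],
    table = tibble::tibble(alternative = names(r1),
                           rank1 = as.integer(r1), rank2 = as.integer(r2))
  )
}
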