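#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble is_tibble
NULL

# Competition ranking of scores (largest = rank 1) with a tie tolerance:
# values within `tol` of a tie-group's leader share the group's (minimum)
# rank and subsequent ranks are skipped.
rank_with_ties <- function(scores, tol = 1e-12) {
  stopifnot(is.numeric(scores), tol >= 0)
  ord <- order(scores, decreasing = TRUE)
  ranks <- integer(length(scores))
  group_start <- 1L
  leader <- scores[ord[1L]]
  for (i in seq_along(ord)) {
    if (leader - scores[ord[i]] > tol) {
      group_start <- i
      leader <- scores[ord[i]]
    }
    ranks[ord[i]] <- group_start
  }
  ranks
}

# Groups of alternatives tied under rank_with_ties (length > 1 only)
tie_groups <- function(labels, ranks) {
  grp <- split(labels, ranks)
  unname(grp[vapply(grp, length, 1L) > 1L])
}

# numeric matrix of the value columns of a labelled table
# (first column = labels), rownames set to the labels
table_to_matrix <- function(tbl) {
  m <- as.matrix(as.data.frame(tbl[, -1, drop = FALSE]))
  rownames(m) <- as.character(tbl[[1]])
  storage.mode(m) <- "double"
  m
}

matrix_to_table <- function(m, label_col = "alternative") {
  out <- tibble::as_tibble(as.data.frame(m))
  out <- tibble::add_column(out, !!label_col := rownames(m), .before = 1)
  out
}
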