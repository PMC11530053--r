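#' Degree-pair kernels of the built-in topological indices
#'
#' Every index in this package is a sum, over the degree-pair edge partition,
#' of `count * kernel(a, b)` where `(a, b)` are the endpoint degrees of an
#' edge. The six built-ins are the first Zagreb (`M1`, kernel `a + b`),
#' second Zagreb (`M2`, `a * b`), hyper-Zagreb (`HZ`, `(a + b)^2`),
#' harmonic (`H`, `2 / (a + b)`), forgotten (`F`, `a^2 + b^2`) and
#' sum-connectivity (`SCI`, `(a + b)^(-1/2)`) indices. Additional indices
#' registered with [register_index()] appear after the built-ins.
#'
#' @return A named list of vectorised kernel functions `f(a, b)`.
#' @export
index_kernels <- function() {
  as.list(.index_registry)[index_names()]
}

.index_registry <- new.env(parent = emptyenv())
.index_builtin <- c("M1", "M2", "HZ", "H", "F", "SCI")

local({
  .index_registry$M1 <- function(a, b) a + b
  .index_registry$M2 <- function(a, b) a * b
  .index_registry$HZ <- function(a, b) (a + b)^2
  .index_registry$H <- function(a, b) 2 / (a + b)
  .index_registry$F <- function(a, b) a^2 + b^2
  .index_registry$SCI <- function(a, b) (a + b)^(-0.5)
})

index_names <- function() {
  extras <- setdiff(ls(.index_registry), .index_builtin)
  c(.index_builtin, sort(extras))
}

#' Register an additional degree-based index
#'
#' @param name Column name the index will use in [compute_indices()] output.
#' @param kernel Vectorised function of the two endpoint degrees `(a, b)`.
#' @return `name`, invisibly.
#' @export
register_index <- function(name, kernel) {
  stopifnot(is.character(name), length(name) == 1L, is.function(kernel))
  if (name %in% .index_builtin) {
    rlang::abort(sprintf("'%s' is a built-in index and cannot be replaced", name))
  }
  assign(name, kernel, envir = .index_registry)
  invisible(name)
}

partition_index <- function(x, kernel) {
  p <- as_edge_partition(x)
  if (nrow(p) == 0L) return(0)
  sum(p$count * kernel(p$deg_a, p$deg_b))
}

#' Degree-based topological indices
#'
#' Each function evaluates one index from a degree-pair edge partition (or
#' directly from a [molecular_graph()], in which case the partition is
#' computed first). An empty partition gives 0. The hyper-Zagreb index
#' satisfies `HZ = F + 2 * M2` identically.
#'
#' @param x A [molecular_graph()] or an edge partition
#'   (see [as_edge_partition()]).
#' @return A single non-negative number.
#' @name topological-indices
#' @examples
#' donepezil <- data.frame(deg_a = c(1, 1, 2, 2, 3),
#'                         deg_b = c(2, 3, 2, 3, 3),
#'                         count = c(2, 1, 6, 18, 4))
#' first_zagreb(donepezil)     # 148
#' sum_connectivity(donepezil) # 14.3375
NULL

#' @rdname topological-indices
#' @export
first_zagreb <- function(x) partition_index(x, .index_registry$M1)

#' @rdname topological-indices
#' @export
second_zagreb <- function(x) partition_index(x, .index_registry$M2)

#' @rdname topological-indices
#' @export
hyper_zagreb <- function(x) partition_index(x, .index_registry$HZ)

#' @rdname topological-indices
#' @export
harmonic_index <- function(x) partition_index(x, .index_registry$H)

#' @rdname topological-indices
#' @export
forgotten_index <- function(x) partition_index(x, .index_registry$F)

#' @rdname topological-indices
#' @export
sum_connectivity <- function(x) partition_index(x, .index_registry$SCI)

#' Compute all registered topological indices for one or more graphs
#'
#' @param graphs A [molecular_graph()] or a (possibly named) list of them.
#' @return A tibble with one row per graph: `graph_id` followed by one
#'   numeric column per index (`M1`, `M2`, `HZ`, `H`, `F`, `SCI`, then any
#'   registered extras). This table is a valid decision matrix for the
#'   ranking stages once renamed via [as_decision_matrix()].
#' @export
#' @examples
#' g <- graph_from_smiles("C1CC1", id = "cyclopropane")
#' compute_indices(g)
compute_indices <- function(graphs) {
  if (inherits(graphs, "molecular_graph")) graphs <- list(graphs)
  kernels <- index_kernels()
  purrr::map_dfr(graphs, function(g) {
    p <- edge_partition(g)
    vals <- purrr::map_dbl(kernels, function(k) partition_index(p, k))
    tibble::tibble(graph_id = g$id, !!!as.list(vals))
  })
}
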