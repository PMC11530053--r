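#' Random connected molecular-like graph with bounded degree
#'
#' Emulates the connectivity of a hydrogen-suppressed organic skeleton: a
#' degree-capped random spanning tree (every new vertex attaches to a
#' uniformly chosen existing vertex with spare valence) plus a number of
#' extra ring-closing edges drawn as `Binomial(n_vertices, ring_density)`,
#' so the expected ring count is a fixed fraction of the molecule size.
#' The default degree cap of 4 mirrors carbon valence.
#'
#' @param n_vertices Number of vertices (`>= 2`).
#' @param max_degree Degree cap (`>= 2`), default 4.
#' @param ring_density Expected extra edges per vertex, default 0.15.
#' @param id Graph label.
#' @param seed Optional integer; the same seed reproduces the same graph
#'   and the global RNG state is left untouched.
#' @return A [molecular_graph()].
#' @export
random_molecular_graph <- function(n_vertices, max_degree = 4,
                                   ring_density = 0.15, id = "synthetic",
                                   seed = NULL) {
  stopifnot(n_vertices >= 2, max_degree >= 2, ring_density >= 0)
  build <- function() {
    labels <- sprintf(paste0("v%0", nchar(n_vertices), "d"), seq_len(n_vertices))
    deg <- stats::setNames(integer(n_vertices), labels)
    eu <- character(0); ev <- character(0)
    for (i in 2:n_vertices) {
      open <- labels[seq_len(i - 1L)][deg[seq_len(i - 1L)] < max_degree]
      parent <- if (length(open) == 1L) open else sample(open, 1L)
      eu <- c(eu, parent); ev <- c(ev, labels[i])
      deg[parent] <- deg[parent] + 1L
      deg[labels[i]] <- deg[labels[i]] + 1L
    }
    adj <- paste(pmin(eu, ev), pmax(eu, ev))
    n_extra <- stats::rbinom(1L, n_vertices, min(ring_density, 1))
    added <- 0L; attempts <- 0L
    while (added < n_extra && attempts < 50L * (n_extra + 1L)) {
      attempts <- attempts + 1L
      pair <- sample(labels, 2L)
      key <- paste(min(pair), max(pair))
      if (key %in% adj) next
      if (deg[pair[1]] >= max_degree || deg[pair[2]] >= max_degree) next
      eu <- c(eu, pair[1]); ev <- c(ev, pair[2])
      deg[pair[1]] <- deg[pair[1]] + 1L
      deg[pair[2]] <- deg[pair[2]] + 1L
      adj <- c(adj, key)
      added <- added + 1L
    }
    molecular_graph(tibble::tibble(u = eu, v = ev), id = id)
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Random strictly positive decision matrix
#'
#' Entries are independent log-normal draws (`meanlog`, `sdlog`), so every
#' entry is strictly positive; alternatives are labelled `A1..Am` and
#' criteria `C1..Cn`.
#'
#' @param m Number of alternatives (`>= 2`).
#' @param n Number of criteria (`>= 1`).
#' @param meanlog,sdlog Log-normal parameters, default `meanlog = 1`,
#'   `sdlog = 0.5`.
#' @param seed Optional integer for reproducibility.
#' @return A decision matrix tibble (see [as_decision_matrix()]).
#' @export
random_decision_matrix <- function(m, n, meanlog = 1, sdlog = 0.5,
                                   seed = NULL) {
  stopifnot(m >= 2, n >= 1)
  build <- function() {
    vals <- matrix(stats::rlnorm(m * n, meanlog, sdlog), nrow = m,
                   dimnames = list(paste0("A", seq_len(m)),
                                   paste0("C", seq_len(n))))
    as_decision_matrix(matrix_to_table(vals))
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

# default planted design: one distinct index per property, with slopes,
# intercepts and noise SDs on each property's natural scale
default_qspr_design <- function() {
  tibble::tibble(
    property = property_vocabulary(),
    index = c("M1", "M2", "HZ", "H", "F", "SCI"),
    slope = c(0.8, 1.2, 0.5, 0.02, 0.5, 15),
    intercept = c(40, 150, 80, 0.9, 60, 50),
    noise_sd = c(10, 15, 12, 0.05, 10, 20)
  )
}

#' Synthetic QSPR panel: graphs, indices and linearly planted properties
#'
#' Generates a panel of random molecular-like graphs, computes their
#' topological indices, and builds a physicochemical property table where
#' each property is a linear function of one designated index plus
#' Gaussian noise: `property = slope * index + intercept + N(0, noise_sd)`.
#' The planted design is returned as ground truth so recovery of slopes
#' (by [fit_simple_regression()]) and of the property-to-index allocation
#' (by [allocate_property_to_index()]) can be tested. Graph generation and
#' property noise use separate seed streams, so adding molecules does not
#' perturb the noise draws of existing properties.
#'
#' @param n_molecules Number of molecules, default 12.
#' @param vertex_range Inclusive range molecule sizes are drawn from,
#'   default `c(10, 28)` (drug-like heavy-atom counts).
#' @param max_degree,ring_density Passed to [random_molecular_graph()].
#' @param design Planted design: a tibble with columns `property`, `index`,
#'   `slope`, `intercept`, `noise_sd`; defaults to a bijection of the six
#'   built-in indices onto the six properties with slopes and noise on each
#'   property's natural scale.
#' @param seed Optional integer seed fixing the whole panel.
#' @return A list with elements `graphs` (named list of
#'   [molecular_graph()]), `indices` (tibble from [compute_indices()]),
#'   `properties` (property table) and `truth` (the design tibble).
#' @export
#' @examples
#' panel <- synthetic_qspr_panel(n_molecules = 6, seed = 1)
#' correlate_indices(panel$indices, panel$properties)
synthetic_qspr_panel <- function(n_molecules = 12, vertex_range = c(10, 28),
                                 max_degree = 4, ring_density = 0.15,
                                 design = default_qspr_design(),
                                 seed = NULL) {
  stopifnot(n_molecules >= 2, length(vertex_range) == 2,
            vertex_range[1] >= 2, vertex_range[1] <= vertex_range[2])
  design <- tibble::as_tibble(design)
  stopifnot(all(c("property", "index", "slope", "intercept", "noise_sd")
                %in% names(design)),
            all(design$noise_sd >= 0))
  base <- if (is.null(seed)) NULL else as.integer(seed %% 1000000L)

  draw_sizes <- function() {
    sample(seq(vertex_range[1], vertex_range[2]), n_molecules, replace = TRUE)
  }
  sizes <- if (is.null(base)) draw_sizes() else withr::with_seed(base, draw_sizes())

  graphs <- lapply(seq_len(n_molecules), function(i) {
    random_molecular_graph(
      sizes[i], max_degree = max_degree, ring_density = ring_density,
      id = sprintf("mol%02d", i),
      seed = if (is.null(base)) NULL else base + 13L * i
    )
  })
  names(graphs) <- vapply(graphs, function(g) g$id, character(1))
  idx <- compute_indices(graphs)

  props <- tibble::tibble(alternative = idx$graph_id)
  for (k in seq_len(nrow(design))) {
    d <- design[k, ]
    noise <- if (d$noise_sd == 0) {
      rep(0, n_molecules)
    } else if (is.null(base)) {
      stats::rnorm(n_molecules, 0, d$noise_sd)
    } else {
      withr::with_seed(base + 500009L + 101L * k,
                       stats::rnorm(n_molecules, 0, d$noise_sd))
    }
    props[[d$property]] <- d$slope * idx[[d$index]] + d$intercept + noise
  }
  list(graphs = graphs, indices = idx,
       properties = as_property_table(props), truth = design)
}
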