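#' Construct a molecular graph
#'
#' A molecular graph is a simple, finite, connected, undirected graph whose
#' vertices are heavy (non-hydrogen) atoms and whose edges are bonds between
#' them, ignoring bond order. All degree-based topological indices in this
#' package are computed on this object.
#'
#' @param edges A data frame with character columns `u` and `v`, one edge per
#'   row. Edges are unordered; self-loops and duplicates are rejected.
#' @param id Text label for the graph.
#' @param vertices Optional character vector of vertex identifiers; defaults
#'   to the set of edge endpoints. Isolated vertices may be declared here,
#'   but only for single-vertex graphs (any larger graph with an isolated
#'   vertex is disconnected and rejected).
#' @param connected If `TRUE` (default), require a single connected component.
#'
#' @return An object of class `molecular_graph`: a list with elements `id`,
#'   `vertices` (character) and `edges` (a tibble with columns `u`, `v`).
#' @export
#' @examples
#' molecular_graph(data.frame(u = c("a", "b"), v = c("b", "c")), id = "propane")
molecular_graph <- function(edges, id = "graph", vertices = NULL,
                            connected = TRUE) {
  edges <- tibble::as_tibble(edges)
  if (!all(c("u", "v") %in% names(edges))) {
    rlang::abort("`edges` must have columns `u` and `v`.",
                 class = "adrank_format_error")
  }
  edges <- dplyr::mutate(edges[, c("u", "v")],
                         u = as.character(.data$u), v = as.character(.data$v))
  if (anyNA(edges$u) || anyNA(edges$v)) {
    rlang::abort("edge endpoints must not be missing",
                 class = "adrank_format_error")
  }
  loops <- edges$u == edges$v
  if (any(loops)) {
    rlang::abort(
      sprintf("self-loop on vertex '%s' (graph '%s')", edges$u[loops][1], id),
      class = "adrank_self_loop"
    )
  }
  key <- paste(pmin(edges$u, edges$v), pmax(edges$u, edges$v), sep = "\r")
  if (anyDuplicated(key)) {
    d <- edges[duplicated(key), , drop = FALSE]
    rlang::abort(
      sprintf("duplicate edge %s--%s (graph '%s')", d$u[1], d$v[1], id),
      class = "adrank_duplicate_edge"
    )
  }
  vs <- sort(unique(c(vertices, edges$u, edges$v)))
  if (length(vs) == 0L) {
    rlang::abort("a molecular graph needs at least one vertex",
                 class = "adrank_format_error")
  }
  if (connected && length(vs) > 1L) {
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = vs)
    if (igraph::count_components(g) > 1L) {
      rlang::abort(
        sprintf("graph '%s' is disconnected (%d components)", id,
                igraph::count_components(g)),
        class = "adrank_disconnected_error"
      )
    }
  }
  structure(
    list(id = as.character(id), vertices = vs,
         edges = tibble::as_tibble(edges)),
    class = "molecular_graph"
  )
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("<molecular_graph '%s': %d vertices, %d edges>\n",
              x$id, length(x$vertices), nrow(x$edges)))
  invisible(x)
}

#' Vertex degrees of a molecular graph
#'
#' @param g A [molecular_graph()].
#' @return Named integer vector of degrees, one entry per vertex.
#' @export
vertex_degrees <- function(g) {
  stopifnot(inherits(g, "molecular_graph"))
  d <- table(factor(c(g$edges$u, g$edges$v), levels = g$vertices))
  stats::setNames(as.integer(d), g$vertices)
}

# SMILES alphabet pre-scan: report the first character OpenBabel would
# choke on, with its 1-based position, and check bracket balance.
check_smiles_tokens <- function(smiles) {
  chars <- strsplit(smiles, "")[[1]]
  allowed <- c(LETTERS, letters, 0:9, "(", ")", "[", "]", "=", "#", "$",
               ":", "/", "\\", ".", "-", "+", "@", "%", "*", "~")
  bad <- which(!(chars %in% allowed))
  if (length(bad)) {
    rlang::abort(
      sprintf("invalid SMILES character '%s' at position %d", chars[bad[1]],
              bad[1]),
      class = "adrank_parse_error"
    )
  }
  # outside brackets only organic-subset atom symbols may appear
  depth <- cumsum((chars == "[") - (chars == "]"))
  organic1 <- c("B", "C", "N", "O", "P", "S", "F", "I",
                "b", "c", "n", "o", "p", "s")
  i <- 1L
  while (i <= length(chars)) {
    if (depth[i] == 0L && grepl("[A-Za-z]", chars[i])) {
      two <- paste0(chars[i], if (i < length(chars)) chars[i + 1L] else "")
      if (two %in% c("Cl", "Br")) {
        i <- i + 2L
        next
      }
      if (!(chars[i] %in% organic1)) {
        rlang::abort(
          sprintf("invalid SMILES atom symbol '%s' at position %d",
                  chars[i], i),
          class = "adrank_parse_error"
        )
      }
    }
    i <- i + 1L
  }
  for (pair in list(c("(", ")"), c("[", "]"))) {
    depth <- cumsum((chars == pair[1]) - (chars == pair[2]))
    if (any(depth < 0)) {
      rlang::abort(
        sprintf("unmatched '%s' at position %d", pair[2], which(depth < 0)[1]),
        class = "adrank_parse_error"
      )
    }
    if (depth[length(depth)] != 0) {
      rlang::abort(
        sprintf("unclosed '%s' (%d unmatched)", pair[1], depth[length(depth)]),
        class = "adrank_parse_error"
      )
    }
  }
  invisible(TRUE)
}

#' Build a hydrogen-suppressed molecular graph from a SMILES string
#'
#' Heavy atoms become vertices and every bonded heavy-atom pair becomes one
#' edge, regardless of bond order or aromaticity; explicit hydrogens are
#' dropped. This bond-order-blind skeleton is the convention under which the
#' degree-pair edge partitions used by the topological indices are defined.
#'
#' @param smiles A single SMILES string.
#' @param id Text label for the resulting graph.
#' @param largest_fragment If the SMILES encodes several disconnected
#'   fragments (e.g. a salt), keep the fragment with the most vertices
#'   instead of erroring. Ties go to the fragment containing the
#'   lexicographically smallest vertex label.
#'
#' @return A [molecular_graph()].
#' @export
#' @examples
#' g <- graph_from_smiles("CC", id = "ethane")
#' length(g$vertices)  # 2
graph_from_smiles <- function(smiles, id = "mol", largest_fragment = FALSE) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  check_smiles_tokens(smiles)
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) {
      rlang::abort(
        sprintf("could not parse SMILES for '%s': %s", id, conditionMessage(e)),
        class = "adrank_parse_error"
      )
    }
  )
  ab <- ChemmineR::atomblock(sdf[[1]])
  bb <- ChemmineR::bondblock(sdf[[1]])
  if (is.null(dim(bb))) bb <- matrix(bb, nrow = 1, dimnames = list(NULL, names(bb)))
  labels <- rownames(ab)
  element <- sub("_.*$", "", labels)
  heavy <- element != "H"
  if (!any(heavy)) {
    rlang::abort(sprintf("'%s' has no heavy atoms", id),
                 class = "adrank_parse_error")
  }
  keep_v <- labels[heavy]
  e_u <- labels[bb[, 1]]
  e_v <- labels[bb[, 2]]
  keep_e <- e_u %in% keep_v & e_v %in% keep_v
  edges <- tibble::tibble(u = e_u[keep_e], v = e_v[keep_e])

  vs <- keep_v
  if (length(vs) > 1L) {
    g0 <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vs)
    comp <- igraph::components(g0)
    if (comp$no > 1L) {
      if (!largest_fragment) {
        rlang::abort(
          sprintf("SMILES for '%s' encodes %d disconnected fragments; set largest_fragment = TRUE to keep the biggest",
                  id, comp$no),
          class = "adrank_disconnected_error"
        )
      }
      sizes <- comp$csize
      best <- which(sizes == max(sizes))
      if (length(best) > 1L) {
        firsts <- vapply(best, function(k) {
          min(names(comp$membership)[comp$membership == k])
        }, character(1))
        best <- best[order(firsts)][1]
      }
      vs <- names(comp$membership)[comp$membership == best[1]]
      edges <- edges[edges$u %in% vs & edges$v %in% vs, , drop = FALSE]
    }
  }
  molecular_graph(edges, id = id, vertices = vs)
}

#' Read a SMILES list file
#'
#' One record per line, `"<id>\t<smiles>"`; lines starting with `#` and
#' blank lines are skipped.
#'
#' @param path Path to the file.
#' @inheritParams graph_from_smiles
#' @return A named list of [molecular_graph()] objects.
#' @export
read_smiles <- function(path, largest_fragment = FALSE) {
  lines <- readLines(path)
  lines <- trimws(lines, which = "right")
  keep <- nzchar(lines) & !startsWith(trimws(lines), "#")
  recs <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(vapply(recs, length, 1L) < 2L)
  if (length(bad)) {
    rlang::abort(
      sprintf("malformed SMILES record on line %d (need '<id>\\t<smiles>')",
              which(keep)[bad[1]]),
      class = "adrank_format_error"
    )
  }
  ids <- vapply(recs, `[[`, character(1), 1L)
  smi <- vapply(recs, `[[`, character(1), 2L)
  out <- purrr::map2(smi, ids, graph_from_smiles,
                     largest_fragment = largest_fragment)
  stats::setNames(out, ids)
}

#' Read molecular graphs from an edge-list TSV
#'
#' Expects a header `graph_id`, `u`, `v` and one edge per row; vertex labels
#' are opaque text and row order is irrelevant.
#'
#' @param path Path to the TSV file.
#' @return A named list of [molecular_graph()] objects, one per distinct
#'   `graph_id`.
#' @export
graphs_from_edge_list <- function(path) {
  df <- suppressWarnings(
    readr::read_tsv(path,
                    col_types = readr::cols(.default = readr::col_character()))
  )
  if (!all(c("graph_id", "u", "v") %in% names(df))) {
    rlang::abort("edge-list TSV must have columns graph_id, u, v",
                 class = "adrank_format_error")
  }
  incomplete <- which(!stats::complete.cases(df[, c("graph_id", "u", "v")]))
  if (length(incomplete)) {
    rlang::abort(
      sprintf("malformed edge-list row on line %d", incomplete[1] + 1L),
      class = "adrank_format_error"
    )
  }
  ids <- unique(df$graph_id)
  out <- lapply(ids, function(gid) {
    molecular_graph(df[df$graph_id == gid, c("u", "v")], id = gid)
  })
  stats::setNames(out, ids)
}

#' Write molecular graphs to an edge-list TSV
#'
#' @param graphs A [molecular_graph()] or a list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graphs, path) {
  if (inherits(graphs, "molecular_graph")) graphs <- list(graphs)
  df <- purrr::map_dfr(graphs, function(g) {
    tibble::tibble(graph_id = g$id, u = g$edges$u, v = g$edges$v)
  })
  readr::write_tsv(df, path)
  invisible(path)
}

#' Degree-pair edge partition of a molecular graph
#'
#' Tallies the edges of a graph by the unordered pair of their endpoint
#' degrees: the count for key `(a, b)` with `a <= b` is the number of edges
#' whose endpoints have degrees `a` and `b`. This partition is the
#' substrate on which all degree-based topological indices are evaluated.
#'
#' @param g A [molecular_graph()].
#' @return A tibble with integer columns `deg_a`, `deg_b` (`deg_a <= deg_b`)
#'   and `count`, sorted by degree pair; counts sum to the number of edges.
#'   An edgeless graph yields zero rows.
#' @export
#' @examples
#' p4 <- molecular_graph(data.frame(u = c("a", "b", "c"), v = c("b", "c", "d")))
#' edge_partition(p4)  # {(1,2): 2, (2,2): 1}
edge_partition <- function(g) {
  stopifnot(inherits(g, "molecular_graph"))
  if (nrow(g$edges) == 0L) {
    return(tibble::tibble(deg_a = integer(), deg_b = integer(),
                          count = integer()))
  }
  deg <- vertex_degrees(g)
  du <- deg[g$edges$u]
  dv <- deg[g$edges$v]
  tibble::tibble(deg_a = pmin(du, dv), deg_b = pmax(du, dv)) |>
    dplyr::count(.data$deg_a, .data$deg_b, name = "count") |>
    dplyr::arrange(.data$deg_a, .data$deg_b)
}

#' Coerce to a degree-pair edge partition
#'
#' Accepts a [molecular_graph()] (the partition is computed) or a data frame
#' with columns `deg_a`, `deg_b`, `count` (validated as-is).
#'
#' @param x Object to coerce.
#' @return A tibble with columns `deg_a`, `deg_b`, `count`.
#' @export
as_edge_partition <- function(x) {
  if (inherits(x, "molecular_graph")) return(edge_partition(x))
  x <- tibble::as_tibble(x)
  if (!all(c("deg_a", "deg_b", "count") %in% names(x))) {
    rlang::abort("an edge partition needs columns deg_a, deg_b, count",
                 class = "adrank_format_error")
  }
  x <- x[, c("deg_a", "deg_b", "count")]
  if (nrow(x) == 0L) return(x)
  if (any(x$deg_a < 1 | x$deg_b < x$deg_a)) {
    rlang::abort("edge partition keys need 1 <= deg_a <= deg_b",
                 class = "adrank_format_error")
  }
  if (any(x$count <= 0)) {
    rlang::abort("edge partition counts must be strictly positive",
                 class = "adrank_format_error")
  }
  key <- paste(x$deg_a, x$deg_b)
  if (anyDuplicated(key)) {
    rlang::abort("duplicate degree-pair keys in edge partition",
                 class = "adrank_format_error")
  }
  x
}
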