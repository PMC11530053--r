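test_that("molecular_graph validates simple connected graphs", {
  g <- molecular_graph(data.frame(u = c("a", "b"), v = c("b", "c")), id = "p3")
  expect_s3_class(g, "molecular_graph")
  expect_equal(sort(g$vertices), c("a", "b", "c"))
  expect_equal(nrow(g$edges), 2)

  expect_error(molecular_graph(data.frame(u = "a", v = "a")),
               class = "adrank_self_loop")
  expect_error(molecular_graph(data.frame(u = c("a", "b"), v = c("b", "a"))),
               class = "adrank_duplicate_edge")
  expect_error(
    molecular_graph(data.frame(u = c("a", "c"), v = c("b", "d"))),
    class = "adrank_disconnected_error"
  )
})

test_that("graph_from_smiles builds hydrogen-suppressed skeletons", {
  eth <- graph_from_smiles("CC", id = "ethane")
  expect_equal(length(eth$vertices), 2)
  expect_equal(nrow(eth$edges), 1)

  cp <- graph_from_smiles("C1CC1", id = "cyclopropane")
  expect_equal(length(cp$vertices), 3)
  expect_equal(nrow(cp$edges), 3)
  expect_true(all(vertex_degrees(cp) == 2))

  # explicit hydrogens are dropped, bond order ignored
  etoh <- graph_from_smiles("C([H])([H])([H])O", id = "methanol")
  expect_equal(length(etoh$vertices), 2)
  ethene <- graph_from_smiles("C=C", id = "ethene")
  expect_equal(nrow(ethene$edges), 1)
})

test_that("donepezil SMILES reproduces the published edge partition", {
  g <- graph_from_smiles(donepezil_smiles, id = "donepezil")
  expect_equal(length(g$vertices), 28)
  expect_equal(nrow(g$edges), 31)
  p <- edge_partition(g)
  expect_equal(as.data.frame(p), as.data.frame(donepezil_partition),
               ignore_attr = TRUE)
})

test_that("SMILES parse errors carry token positions", {
  expect_error(graph_from_smiles("C1CC(Q)"), "position",
               class = "adrank_parse_error")
  expect_error(graph_from_smiles("C1CC(C"), class = "adrank_parse_error")
  expect_error(graph_from_smiles("CC.O", id = "salt"),
               class = "adrank_disconnected_error")
})

test_that("largest_fragment keeps the biggest component, ties lexicographic", {
  g <- graph_from_smiles("CCC.O", id = "hydrate", largest_fragment = TRUE)
  expect_equal(length(g$vertices), 3)
  expect_equal(nrow(g$edges), 2)
})

test_that("edge-list TSV round-trips graphs and validates rows", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("graph_id\tu\tv", "g1\ta\tb", "g1\tb\tc"), tsv)
  gs <- graphs_from_edge_list(tsv)
  expect_named(gs, "g1")
  expect_equal(sort(vertex_degrees(gs$g1)), c(a = 1, c = 1, b = 2),
               ignore_attr = TRUE)

  writeLines(c("graph_id\tu\tv", "g1\ta\tb", "g1\ta\tb"), tsv)
  expect_error(graphs_from_edge_list(tsv), class = "adrank_duplicate_edge")
  writeLines(c("graph_id\tu\tv", "g1\ta\ta"), tsv)
  expect_error(graphs_from_edge_list(tsv), class = "adrank_self_loop")
  writeLines(c("graph_id\tu\tv", "g1\ta\tb", "g1\tc"), tsv)
  expect_error(graphs_from_edge_list(tsv), "line 3",
               class = "adrank_format_error")

  # round-trip: SMILES-built donepezil -> TSV -> identical partition
  don <- graph_from_smiles(donepezil_smiles, id = "donepezil")
  write_edge_list(don, tsv)
  don2 <- graphs_from_edge_list(tsv)$donepezil
  expect_equal(sort(unname(vertex_degrees(don2))),
               sort(unname(vertex_degrees(don))))
  expect_equal(edge_partition(don2), edge_partition(don))
})

test_that("read_smiles parses the shipped fixture and skips comments", {
  smi <- system.file("extdata", "ad_drugs.smi", package = "adrank")
  gs <- read_smiles(smi)
  expect_length(gs, 12)
  expect_true("donepezil" %in% names(gs))
  expect_equal(length(gs$metacetamol$vertices), 11)
  expect_equal(length(gs$gallic_acid$vertices), 12)
})

test_that("edge partitions match a brute-force oracle on random graphs", {
  set.seed(1)
  for (s in 1:50) {
    g <- random_molecular_graph(sample(4:25, 1), max_degree = 4, seed = s)
    p <- edge_partition(g)
    expect_equal(sum(p$count), nrow(g$edges))
    expect_equal(partition_as_table(p), oracle_partition(g))
  }
})

test_that("handshake-square identity holds: sum_E (d(u)+d(v)) = sum_V d(v)^2", {
  set.seed(2)
  for (s in 1:25) {
    g <- random_molecular_graph(sample(3:20, 1), max_degree = 5, seed = 100 + s)
    deg <- vertex_degrees(g)
    lhs <- first_zagreb(g)
    expect_equal(lhs, sum(deg^2))
  }
})

test_that("edge_partition of an edgeless graph is empty, not an error", {
  g1 <- molecular_graph(tibble::tibble(u = character(), v = character()),
                        vertices = "a", id = "K1")
  p <- edge_partition(g1)
  expect_equal(nrow(p), 0)
  expect_equal(first_zagreb(p), 0)
})
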