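test_that("vector normalization gives unit-norm columns", {
  D <- dm_from_matrix(cbind(c(3, 4)))
  expect_equal(vector_normalize(D)$C1, c(0.6, 0.8))

  D <- dm_from_matrix(cbind(rep(2, 4)))
  expect_equal(vector_normalize(D)$C1, rep(0.5, 4))  # 1/sqrt(m)

  set.seed(6)
  for (s in 1:10) {
    D <- random_decision_matrix(12, 6, seed = 600 + s)
    R <- vector_normalize(D)
    norms <- sqrt(colSums(as.matrix(R[, -1])^2))
    expect_true(all(abs(norms - 1) < 1e-12))
  }
})

test_that("weighting scales columns elementwise", {
  R <- dm_from_matrix(cbind(c(0.6, 0.8), c(0.5, 0.5)))
  V <- weight_matrix(R, c(1, 0))
  expect_equal(V$C1, c(0.6, 0.8))
  expect_equal(V$C2, c(0, 0))

  V <- weight_matrix(R, c(0.5, 0.5))
  expect_equal(as.matrix(V[, -1]), 0.5 * as.matrix(R[, -1]),
               ignore_attr = TRUE)

  expect_error(weight_matrix(R, c(0.5, 0.25, 0.25)),
               class = "adrank_dimension_error")
})

test_that("ideal points honour benefit/cost directions", {
  V <- dm_from_matrix(cbind(c(0.1, 0.3, 0.2)))
  pts <- ideal_points(V, "benefit")
  expect_equal(unname(pts$ideal), 0.3)
  expect_equal(unname(pts$anti_ideal), 0.1)

  pts <- ideal_points(V, "cost")
  expect_equal(unname(pts$ideal), 0.1)
  expect_equal(unname(pts$anti_ideal), 0.3)

  Vc <- dm_from_matrix(cbind(rep(0.5, 3)))
  pts <- ideal_points(Vc)
  expect_equal(pts$ideal, pts$anti_ideal)
})

test_that("separation measures are Euclidean distances to the ideal points", {
  V <- dm_from_matrix(cbind(c(0.2, 0.5)))
  sep <- separation_measures(V, ideal = c(C1 = 0.5), anti_ideal = c(C1 = 0.1))
  expect_equal(sep$p_plus, c(0.3, 0))
  expect_equal(sep$p_minus, c(0.1, 0.4))

  set.seed(8)
  for (s in 1:5) {
    D <- random_decision_matrix(8, 4, seed = 700 + s)
    V <- weight_matrix(vector_normalize(D), rep(0.25, 4))
    pts <- ideal_points(V)
    sep <- separation_measures(V, pts$ideal, pts$anti_ideal)
    M <- as.matrix(V[, -1])
    for (i in seq_len(nrow(M))) {
      expect_equal(sep$p_plus[i], sqrt(sum((M[i, ] - pts$ideal)^2)))
      expect_equal(sep$p_minus[i], sqrt(sum((M[i, ] - pts$anti_ideal)^2)))
    }
  }
})

test_that("closeness coefficient covers its boundary cases", {
  expect_equal(closeness_coefficient(0, 0.4), 1)
  expect_equal(closeness_coefficient(0.4, 0), 0)
  expect_equal(closeness_coefficient(0.3, 0.3), 0.5)
  expect_error(closeness_coefficient(0, 0), class = "adrank_degenerate_error")
})

test_that("a dominant alternative attains closeness 1 and rank 1", {
  D <- tibble::tibble(alternative = c("top", "mid", "low"),
                      C1 = c(9, 5, 1), C2 = c(8, 4, 2))
  res <- topsis_rank(D, c(0.6, 0.4))
  expect_equal(res$scores$closeness[1], 1)
  expect_equal(res$scores$rank[1], 1)
  expect_equal(tidy(res)$alternative[1], "top")
  expect_true(all(res$scores$closeness >= 0 & res$scores$closeness <= 1))
})

test_that("TOPSIS is invariant to positive column rescaling", {
  set.seed(9)
  for (s in 1:10) {
    D <- random_decision_matrix(12, 6, seed = 800 + s)
    w <- entropy_weights(D)
    r1 <- topsis_rank(D, w)
    D2 <- D
    j <- sample(2:7, 1)
    D2[[j]] <- D2[[j]] * 10
    r2 <- topsis_rank(D2, entropy_weights(D2))
    expect_equal(r2$scores$closeness, r1$scores$closeness, tolerance = 1e-9)
    expect_equal(r2$scores$rank, r1$scores$rank)
  }
})

test_that("TOPSIS matches a from-scratch scripted recomputation", {
  for (s in 1:20) {
    D <- random_decision_matrix(12, 6, seed = 900 + s)
    X <- as.matrix(D[, -1])
    w <- entropy_weights(D)$weight
    cost <- rep(c(FALSE, TRUE), 3)[sample(6)]
    dir <- stats::setNames(ifelse(cost, "cost", "benefit"), colnames(X))
    res <- topsis_rank(D, w, dir)
    expect_equal(res$scores$closeness, oracle_topsis(X, w, cost),
                 tolerance = 1e-12)
  }
})

test_that("permuting rows permutes closeness identically", {
  D <- random_decision_matrix(10, 4, seed = 1001)
  res <- topsis_rank(D, rep(0.25, 4))
  set.seed(10)
  perm <- sample(nrow(D))
  res2 <- topsis_rank(D[perm, ], rep(0.25, 4))
  expect_equal(res2$scores$closeness,
               res$scores$closeness[perm])
})

test_that("reversing the direction of a single criterion swaps a 2-way ranking", {
  D <- tibble::tibble(alternative = c("a", "b"), C1 = c(1, 2))
  rb <- topsis_rank(D, 1, "benefit")
  rc <- topsis_rank(D, 1, "cost")
  expect_equal(rb$scores$rank, rev(rc$scores$rank))
})

test_that("ties within tolerance share the minimum rank and are reported", {
  D <- tibble::tibble(alternative = c("a", "b", "c"),
                      C1 = c(2, 2, 1), C2 = c(3, 3, 1))
  res <- topsis_rank(D, c(0.5, 0.5))
  expect_equal(res$scores$rank, c(1, 1, 3))
  expect_length(res$ties, 1)
  expect_setequal(res$ties[[1]], c("a", "b"))
})
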