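# Independent oracles used across the suite. They deliberately avoid the
# package's own computation paths: indices are recomputed edge by edge
# without ever forming a degree-pair partition, and the MCDM oracles are
# plain base-R double loops.

# per-edge brute-force indices; degrees recounted from the raw edge list
oracle_indices <- function(g) {
  ends <- c(g$edges$u, g$edges$v)
  deg <- function(v) sum(ends == v)
  vals <- c(M1 = 0, M2 = 0, HZ = 0, H = 0, F = 0, SCI = 0)
  for (i in seq_len(nrow(g$edges))) {
    a <- deg(g$edges$u[i])
    b <- deg(g$edges$v[i])
    vals["M1"] <- vals["M1"] + (a + b)
    vals["M2"] <- vals["M2"] + a * b
    vals["HZ"] <- vals["HZ"] + (a + b)^2
    vals["H"] <- vals["H"] + 2 / (a + b)
    vals["F"] <- vals["F"] + a^2 + b^2
    vals["SCI"] <- vals["SCI"] + 1 / sqrt(a + b)
  }
  vals
}

# brute-force degree-pair tally, looping over edges
oracle_partition <- function(g) {
  ends <- c(g$edges$u, g$edges$v)
  keys <- character(0)
  for (i in seq_len(nrow(g$edges))) {
    a <- sum(ends == g$edges$u[i])
    b <- sum(ends == g$edges$v[i])
    keys <- c(keys, paste(min(a, b), max(a, b)))
  }
  tab <- table(keys)
  stats::setNames(as.integer(tab), names(tab))
}

partition_as_table <- function(p) {
  key <- paste(p$deg_a, p$deg_b)
  stats::setNames(as.integer(p$count), key)[order(key)]
}

# from-scratch TOPSIS on base matrices (dir: logical, TRUE = cost)
oracle_topsis <- function(X, w, cost) {
  R <- X
  for (j in seq_len(ncol(X))) R[, j] <- X[, j] / sqrt(sum(X[, j]^2))
  V <- R
  for (j in seq_len(ncol(X))) V[, j] <- w[j] * R[, j]
  ideal <- numeric(ncol(X)); anti <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    ideal[j] <- if (cost[j]) min(V[, j]) else max(V[, j])
    anti[j] <- if (cost[j]) max(V[, j]) else min(V[, j])
  }
  pp <- numeric(nrow(X)); pm <- numeric(nrow(X))
  for (i in seq_len(nrow(X))) {
    pp[i] <- sqrt(sum((V[i, ] - ideal)^2))
    pm[i] <- sqrt(sum((V[i, ] - anti)^2))
  }
  pm / (pp + pm)
}

# from-scratch SAW with max / (min/x) normalization
oracle_saw <- function(X, w, cost) {
  N <- X
  for (j in seq_len(ncol(X))) {
    N[, j] <- if (cost[j]) min(X[, j]) / X[, j] else X[, j] / max(X[, j])
  }
  ts <- numeric(nrow(X))
  for (i in seq_len(nrow(X))) ts[i] <- sum(w * N[i, ])
  ts
}

# O(m^2) Kendall tau-b from concordant/discordant pair counts
oracle_kendall <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[i] - x[j]); dy <- sign(y[i] - y[j])
      if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
      else if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx == dy) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

# decision matrix tibble from a bare positive matrix
dm_from_matrix <- function(X) {
  colnames(X) <- paste0("C", seq_len(ncol(X)))
  tibble::tibble(alternative = paste0("A", seq_len(nrow(X))),
                 !!!as.data.frame(X))
}

donepezil_smiles <- "COc1cc2c(cc1OC)C(=O)C(CC3CCN(CC3)Cc4ccccc4)C2"

donepezil_partition <- tibble::tibble(
  deg_a = c(1, 1, 2, 2, 3),
  deg_b = c(2, 3, 2, 3, 3),
  count = c(2, 1, 6, 18, 4)
)
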