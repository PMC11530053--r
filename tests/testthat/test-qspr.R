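make_panel_tables <- function(seed = 1, noise_scale = 1) {
  design <- adrank:::default_qspr_design()
  design$noise_sd <- design$noise_sd * noise_scale
  synthetic_qspr_panel(n_molecules = 12, design = design, seed = seed)
}

test_that("correlations hit +/-1 for exact (anti)linear properties", {
  idx <- compute_indices(lapply(1:6, function(i) {
    random_molecular_graph(8 + 2 * i, id = paste0("g", i), seed = 1600 + i)
  }))
  props <- tibble::tibble(
    alternative = idx$graph_id,
    boiling_point = 2 * idx$M1 + 5,
    density = -0.01 * idx$M1 + 2
  )
  corr <- correlate_indices(idx, props)
  expect_equal(corr$r[corr$index == "M1" & corr$property == "boiling_point"], 1)
  expect_equal(corr$r[corr$index == "M1" & corr$property == "density"], -1)
  expect_true(all(corr$n_used == 6))
})

test_that("a constant property yields NA correlation, never 0", {
  idx <- compute_indices(lapply(1:5, function(i) {
    random_molecular_graph(6 + 3 * i, id = paste0("g", i), seed = 1700 + i)
  }))
  props <- tibble::tibble(alternative = idx$graph_id,
                          density = rep(1.2, 5))
  corr <- correlate_indices(idx, props)
  expect_true(all(is.na(corr$r)))
})

test_that("missing property values are handled pairwise", {
  idx <- compute_indices(lapply(1:6, function(i) {
    random_molecular_graph(8 + 2 * i, id = paste0("g", i), seed = 1800 + i)
  }))
  props <- tibble::tibble(alternative = idx$graph_id,
                          melting_point = c(NA, 2 * idx$M1[-1]))
  corr <- correlate_indices(idx, props)
  expect_equal(corr$n_used[corr$index == "M1"], 5)
  expect_equal(corr$r[corr$index == "M1"], 1)
})

test_that("simple regression recovers exact lines and rejects degenerate x", {
  f <- fit_simple_regression(c(0, 1, 2), c(0, 2, 4))
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 0)
  expect_equal(f$r_squared, 1)

  f0 <- fit_simple_regression(c(1, 2, 3), c(5, 5, 5))
  expect_equal(f0$slope, 0)
  expect_equal(f0$r_squared, 0)

  expect_error(fit_simple_regression(c(1, 1, 1), c(1, 2, 3)),
               class = "adrank_singular_fit")
  expect_error(fit_simple_regression(c(1, 2), c(1, 2)),
               class = "adrank_format_error")
  expect_equal(f$r_squared, f$pearson_r^2, tolerance = 1e-9)
})

test_that("allocation picks the largest |r| with vocabulary-order tie-break", {
  corr <- tibble::tibble(
    index = rep("M1", 3),
    property = c("melting_point", "boiling_point", "density"),
    r = c(0.5, 0.9, -0.5),
    n_used = 12
  )
  alloc <- allocate_property_to_index(corr)
  expect_equal(alloc$property, "boiling_point")

  # |r| tie between flash_point and melting_point: earlier vocabulary wins
  corr2 <- tibble::tibble(
    index = rep("HZ", 2),
    property = c("flash_point", "melting_point"),
    r = c(0.8, -0.8),
    n_used = 12
  )
  expect_equal(allocate_property_to_index(corr2)$property, "melting_point")
})

test_that("criterion directions inherit the fixed property preferences", {
  alloc <- tibble::tibble(index = c("M1", "M2", "HZ"),
                          property = c("density", "boiling_point", NA),
                          r = c(0.9, 0.8, NA))
  expect_warning(dirs <- criterion_directions_from_properties(alloc),
                 "benefit")
  expect_equal(dirs$direction, c("cost", "benefit", "benefit"))

  tab <- property_directions()
  expect_equal(tab$direction[tab$property == "density"], "cost")
  expect_equal(tab$direction[tab$property == "boiling_point"], "benefit")
  expect_equal(tab$direction[tab$property == "flash_point"], "benefit")
  expect_equal(tab$direction[tab$property == "melting_point"], "cost")
  expect_equal(tab$direction[tab$property == "complexity"], "cost")
  expect_equal(tab$direction[tab$property == "molecular_weight"], "benefit")
})

test_that("correlation grid is invariant to affine unit changes", {
  panel <- make_panel_tables(seed = 3)
  corr <- correlate_indices(panel$indices, panel$properties)
  props2 <- panel$properties
  props2$melting_point <- props2$melting_point * 1.8 + 32  # degC -> degF
  corr2 <- correlate_indices(panel$indices, props2)
  expect_equal(corr2$r, corr$r, tolerance = 1e-12)
})

test_that("the planted allocation is recovered exactly at small noise", {
  panel <- make_panel_tables(seed = 4, noise_scale = 1e-8)
  corr <- correlate_indices(panel$indices, panel$properties)
  alloc <- allocate_property_to_index(corr)
  truth <- panel$truth
  expect_equal(alloc$property[match(truth$index, alloc$index)],
               truth$property)
  expect_true(all(corr$r[paste(corr$index, corr$property) %in%
                           paste(truth$index, truth$property)] > 0.999))
})

test_that("planted slopes are recovered within 3 SE in most replicates", {
  hits <- 0L
  total <- 0L
  for (s in 1:40) {
    panel <- make_panel_tables(seed = 2000 + s)
    truth <- panel$truth
    for (k in seq_len(nrow(truth))) {
      f <- fit_simple_regression(panel$indices[[truth$index[k]]],
                                 panel$properties[[truth$property[k]]])
      total <- total + 1L
      if (abs(f$slope - truth$slope[k]) <= 3 * f$se_slope) hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.95)
})
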