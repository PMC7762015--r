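test_that("tumor size is the product of the two dimensions", {
  expect_equal(compute_size(2.0, 1.5), 3.0)
  expect_equal(compute_size(1.7, 1.7), 1.7^2)
  expect_equal(compute_size(c(2, 3), c(1, 2)), c(2, 6))
  expect_error(compute_size(0, 1), "positive")
  expect_error(compute_size(2, -1), "positive")
})

test_that("variable mapping closes the density budget exactly", {
  # Total 1.5e5 with immune total 0.3e5 leaves C = 8e4 and N = 4e4
  fr <- stats::setNames(rep(1 / 22, 22), lm22_cell_types())
  alpha_dim <- 1.125e5
  v <- map_to_model_variables(fr, size = 1.5e5 / alpha_dim,
                              cohort_mean_size = 1,
                              alpha_dim = alpha_dim,
                              immune_fraction = 0.3e5 / alpha_dim)
  expect_equal(v[["Total"]], 1.5e5)
  expect_equal(v[["Immune"]], 0.3e5)
  expect_equal(v[["C"]], 8.0e4)
  expect_equal(v[["N"]], 4.0e4)
  expect_equal(v[["C"]] + v[["N"]] + v[["Immune"]], v[["Total"]])
})

test_that("a mean-sized tumor maps to the density scale itself", {
  fr <- stats::setNames(rep(1 / 22, 22), lm22_cell_types())
  v <- map_to_model_variables(fr, size = 0.8, cohort_mean_size = 0.8)
  expect_equal(v[["Total"]], 1.125e5)
})

test_that("doubling alpha_dim doubles densities but not dimensionless output", {
  co <- generate_cohort(generator_config(n_patients = 60, seed = 21))
  m1 <- map_cohort(co, alpha_dim = 1.125e5)
  m2 <- map_cohort(co, alpha_dim = 2.25e5)
  # cytokines are expression units and do not scale with alpha_dim
  dens_cols <- c(cell_names(), "M0", "Total", "Immune")
  expect_equal(as.matrix(m2[, dens_cols]), 2 * as.matrix(m1[, dens_cols]),
               tolerance = 1e-12)
  x1 <- extract_steady_state(m1); x2 <- extract_steady_state(m2)
  expect_equal(extract_initial_conditions(m1, floor_references(x1, x1)),
               extract_initial_conditions(m2, floor_references(x2, x2)),
               tolerance = 1e-12)
})

test_that("mapped cohorts satisfy the closure identity for every patient", {
  co <- generate_cohort(generator_config(n_patients = 80, seed = 3))
  m <- map_cohort(co)
  expect_lt(max(abs(m$C + m$N + m$Immune - m$Total) / m$Total), 1e-10)
  expect_equal(m$N, 0.5 * m$C)
})

test_that("zero immune ratios are rejected", {
  fr <- stats::setNames(rep(0, 22), lm22_cell_types())
  expect_error(map_to_model_variables(fr, 1, 1), "zero")
})

test_that("the elbow finds the planted cluster count and flags diffuse data", {
  co <- generate_cohort(generator_config())
  types <- intersect(lm22_cell_types(), colnames(co))
  ek <- elbow_k(co[, types], 1:10, seed = 1)
  expect_equal(ek$K, 5)
  expect_true(ek$confident)
  # a single diffuse profile has no sharp knee
  p1 <- default_profiles()$profiles[1, , drop = FALSE]
  cy1 <- matrix(c(9e3, 160, 1300, 8, 1.9e4), 1)
  co1 <- generate_cohort(generator_config(K = 1, profiles = p1,
                                          cytokine_means = cy1, seed = 11))
  ek1 <- elbow_k(co1[, types], 1:10, seed = 1)
  expect_false(ek1$confident)
  # degenerate range
  ek_one <- elbow_k(co[, types], 1, seed = 1)
  expect_equal(ek_one$K, 1)
})

test_that("k-means recovers planted structure and is seed-deterministic", {
  # two far-separated blobs: perfect recovery up to permutation
  set.seed(42)
  X <- rbind(matrix(stats::rnorm(50 * 3, 0, 0.05), 50),
             matrix(stats::rnorm(50 * 3, 5, 0.05), 50))
  lab <- rep(1:2, each = 50)
  cl2 <- cluster_patients(X, 2, seed = 9)
  expect_equal(adjusted_rand(cl2$labels, lab), 1)
  # planted five-cluster cohort
  co <- generate_cohort(generator_config())
  types <- intersect(lm22_cell_types(), colnames(co))
  cl5a <- cluster_patients(co[, types], 5, seed = 1)
  cl5b <- cluster_patients(co[, types], 5, seed = 1)
  expect_identical(cl5a$labels, cl5b$labels)
  expect_gte(adjusted_rand(cl5a$labels, attr(co, "truth")$labels), 0.9)
  expect_true(all(cl5a$size > 0))
})

test_that("adjusted Rand matches the reference implementation", {
  skip_if_not_installed("mclust")
  set.seed(8)
  for (i in 1:5) {
    a <- sample(1:4, 60, TRUE)
    b <- sample(1:3, 60, TRUE)
    expect_equal(adjusted_rand(a, b), mclust::adjustedRandIndex(a, b))
  }
})

test_that("steady-state extraction averages the above-average tumors", {
  co <- generate_cohort(generator_config(n_patients = 50, seed = 13))
  m <- map_cohort(co)
  # identical patients: the steady state is that patient
  one <- m[rep(1, 4), ]
  x1 <- extract_steady_state(one)
  expect_equal(as.numeric(x1), as.numeric(one[1, state_names()]),
               tolerance = 1e-12)
  # the extracted state inherits the necrotic closure exactly
  x <- extract_steady_state(m)
  expect_equal(x[["N"]] / x[["C"]], 0.5, tolerance = 1e-12)
  expect_lt(x[["M"]], attr(x, "M0"))
})

test_that("initial conditions come from the smallest tumor", {
  co <- generate_cohort(generator_config(n_patients = 50, seed = 17))
  m <- map_cohort(co)
  x_inf <- extract_steady_state(m)
  x_pos <- floor_references(x_inf, x_inf)
  init <- extract_initial_conditions(m, x_pos)
  smallest <- m[which.min(m$size), ]
  expect_equal(unname(init["C"]),
               smallest$C / x_pos[["C"]], tolerance = 1e-12)
  # a smallest patient already at the steady state maps to all-ones
  ident <- m[rep(which.min(m$size), 3), ]
  x_id <- as.numeric(ident[1, state_names()])
  names(x_id) <- state_names()
  expect_equal(unname(extract_initial_conditions(ident, x_id)), rep(1, 14))
})

test_that("printed tables reconstruct the smallest-tumor density", {
  # dimensionless C ratio times the printed steady state: ~28.8 cells/cm^3
  init1 <- initial_state(1)
  expect_equal(init1[["C"]], 3.1466e-4 * 9.1531e4, tolerance = 1e-12)
  expect_equal(init1[["C"]], 28.8, tolerance = 0.001)
  expect_equal(init1[["N"]], 0)
})
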