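test_that("scalar closed forms: dX*/dA = 1/delta, dX*/ddelta = -A/delta^2", {
  p <- decoupled_params()
  x <- decoupled_equilibrium(p)
  S <- steady_state_sensitivity(p, x)
  A <- p[["A_TN"]]; delta <- p[["delta_TN"]]
  expect_equal(S["TN", "A_TN"], 1 / delta, tolerance = 1e-10)
  expect_equal(S["TN", "delta_TN"], -A / delta^2, tolerance = 1e-10)
})

test_that("implicit differentiation matches the re-solve oracle on cluster 2", {
  p <- tbl_params(2)
  x <- cluster_steady_states(2)
  S <- steady_state_sensitivity(p, x)
  scale_col <- max(abs(x))
  for (sym in param_names()) {
    theta <- p[[sym]]
    if (theta == 0) next
    h <- 1e-4 * theta
    up <- p; up[[sym]] <- theta + h
    dn <- p; dn[[sym]] <- theta - h
    fd <- (solve_steady_state(up, x) - solve_steady_state(dn, x)) / (2 * h)
    denom <- pmax(abs(fd), 1e-6 * max(abs(fd), scale_col * 1e-12))
    expect_lt(max(abs(S[, sym] - fd) / denom), 1e-4)
  }
})

test_that("non-equilibrium inputs are gated", {
  p <- tbl_params(1)
  x <- 1.2 * as.numeric(cluster_steady_states(1))
  names(x) <- state_names()
  expect_error(steady_state_sensitivity(p, x), "not an equilibrium")
})

test_that("eigenvalue sensitivity is exact on a diagonal system and step-robust", {
  p <- decoupled_params()
  x <- decoupled_equilibrium(p)
  es <- eigenvalue_sensitivity(p, x)
  # min eigenvalue = -max decay rate (delta_Gb); only that rate moves it
  expect_equal(es[["delta_Gb"]], -1, tolerance = 1e-6)
  others <- setdiff(names(es), "delta_Gb")
  expect_lt(max(abs(es[others])), 1e-6)
  # Richardson check on a full cluster: halving the step changes < 1%
  pc <- tbl_params(1); xc <- cluster_steady_states(1)
  e1 <- eigenvalue_sensitivity(pc, xc, dtheta_rel = 1e-4)
  e2 <- eigenvalue_sensitivity(pc, xc, dtheta_rel = 5e-5)
  ref <- max(abs(e1))
  expect_lt(max(abs(e1 - e2)) / ref, 0.01)
})

test_that("faster proliferation and faster death move convergence oppositely", {
  for (cl in 1:5) {
    es <- eigenvalue_sensitivity(tbl_params(cl), cluster_steady_states(cl))
    expect_lt(es[["lambda_C"]] * es[["delta_C"]], 0)
  }
})

test_that("zero halfwidth aggregation reduces to the pointwise sensitivity", {
  p <- tbl_params(3)
  x <- cluster_steady_states(3)
  agg <- aggregate_over_region(p, x, halfwidth = 0, qoi = "cancer")
  sa <- sensitivity_analysis(p, x, qois = "cancer")
  expect_equal(agg$average, sa$S[, "cancer"], tolerance = 1e-10)
})

test_that("region average matches the closed-form integral on the decoupled system", {
  # total-density elasticity wrt delta_TN is -A/(delta * T_ref); its mean
  # over delta in delta0(1 +/- h) is -A0 ln((1+h)/(1-h)) / (2 h delta0 T_ref)
  p <- decoupled_params()
  x <- decoupled_equilibrium(p)
  h <- 0.10
  agg <- aggregate_over_region(p, x, halfwidth = h, qoi = "total")
  T_ref <- sum(x[cell_names()])
  A <- p[["A_TN"]]; delta <- p[["delta_TN"]]
  closed <- -A * log((1 + h) / (1 - h)) / (2 * h * delta * T_ref)
  expect_equal(agg$average[["delta_TN"]], closed, tolerance = 1e-4)
  expect_equal(agg$n_failed, 0)
})

test_that("sparse-grid and Monte-Carlo region averages agree on cluster 1", {
  p <- tbl_params(1)
  x <- cluster_steady_states(1)
  sg <- aggregate_over_region(p, x, halfwidth = 0.10, qoi = "cancer",
                              method = "sparse")
  mc <- aggregate_over_region(p, x, halfwidth = 0.10, qoi = "cancer",
                              method = "mc", n_mc = 1000, seed = 99)
  ref <- max(abs(sg$average))
  expect_lt(max(abs(sg$average - mc$average)) / ref, 0.05)
})

test_that("ranking is ordered, deterministic, and partitions the immune set", {
  p <- tbl_params(4)
  x <- cluster_steady_states(4)
  sa <- sensitivity_analysis(p, x, qois = c("cancer", "total"))
  rp <- rank_and_partition(sa, k = 4, qoi = "cancer")
  expect_true(all(diff(abs(rp$ranking$S)) <= 1e-14))
  expect_setequal(rp$ranking$parameter, param_names())
  expect_true(all(!rp$top_immune$parameter %in% cancer_equation_params()))
  # k beyond the parameter count returns the full ranking
  rp_all <- rank_and_partition(sa, k = 1000, qoi = "total")
  expect_equal(nrow(rp_all$top), length(param_names()))
})

test_that("the top-ranked cancer-density parameter sits in the cancer equation", {
  for (cl in 1:5) {
    sa <- sensitivity_analysis(tbl_params(cl), cluster_steady_states(cl),
                               qois = "cancer")
    top1 <- rank_and_partition(sa, 1, "cancer")$top$parameter[1]
    expect_true(top1 %in% cancer_equation_params())
  }
})

test_that("dimensionless sensitivities are invariant to cohort rescaling", {
  x <- cluster_steady_states(5)
  c_fac <- 2.9
  x_c <- c_fac * as.numeric(x); names(x_c) <- state_names()
  attr(x_c, "M0") <- c_fac * attr(x, "M0")
  sa1 <- sensitivity_analysis(tbl_params(5), x, qois = c("cancer", "eig"))
  sa2 <- sensitivity_analysis(derive_parameters(x_c), x_c,
                              qois = c("cancer", "eig"))
  expect_equal(sa1$S, sa2$S, tolerance = 1e-7)
})
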