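test_that("TGF-beta balance arithmetic matches the share formula", {
  # lambda_GbM = w * delta_Gb * Gb_inf / M_inf with w = 0.5, delta_Gb = 1
  cfg <- yaml::read_yaml(system.file("extdata", "assumptions.yaml",
                                     package = "tmekin"))
  cfg$default$Gbeta <- list(delta = 1.0, production = list(M = 0.5, Tr = 0.5))
  p <- derive_parameters(cluster_steady_states(1), load_assumptions(cfg))
  expect_equal(p[["lambda_GbM"]], 0.5 * 1.9037e4 / 1.1798e4, tolerance = 1e-12)
  expect_equal(p[["lambda_GbTr"]], 0.5 * 1.9037e4 / 2.3891e3, tolerance = 1e-12)
})

test_that("degenerate shares put the whole flux on one source", {
  cfg <- yaml::read_yaml(system.file("extdata", "assumptions.yaml",
                                     package = "tmekin"))
  cfg$default$H$production <- list("N" = 1, "M" = 0, Th = 0, TC = 0, Tr = 0)
  x <- cluster_steady_states(2)
  p <- derive_parameters(x, load_assumptions(cfg))
  expect_equal(p[["lambda_HN"]], p[["delta_H"]] * x[["H"]] / x[["N"]])
  expect_equal(unname(p[c("lambda_HM", "lambda_HTh", "lambda_HTC", "lambda_HTr")]),
               rep(0, 4))
  expect_lt(steady_state_residual(x, p)$max_scaled, 1e-10)
})

test_that("every cluster's derived parameters reproduce its equilibrium", {
  for (cl in 1:5) {
    x <- cluster_steady_states(cl)
    expect_lt(steady_state_residual(x, tbl_params(cl))$max_scaled, 1e-10)
  }
})

test_that("assumption validation catches malformed configs", {
  cfg <- yaml::read_yaml(system.file("extdata", "assumptions.yaml",
                                     package = "tmekin"))
  cfg$default$Th <- NULL
  expect_error(load_assumptions(cfg), "Th activation")
  cfg2 <- yaml::read_yaml(system.file("extdata", "assumptions.yaml",
                                      package = "tmekin"))
  cfg2$default$C$loss$natural <- 0.9
  expect_error(load_assumptions(cfg2), "sum to 1")
  cfg3 <- yaml::read_yaml(system.file("extdata", "assumptions.yaml",
                                      package = "tmekin"))
  cfg3$default$M$delta <- 0
  expect_error(load_assumptions(cfg3), "must be > 0")
})

test_that("assumptions round-trip through YAML unchanged", {
  a <- load_assumptions()
  path <- withr::local_tempfile(fileext = ".yaml")
  save_assumptions(a, path)
  expect_equal(load_assumptions(path), a, tolerance = 1e-12)
})

test_that("parameters are identifiable under matching assumptions", {
  for (seed in c(11, 29)) {
    x <- random_steady_state(seed)
    a <- random_assumptions(seed + 100)
    p <- derive_parameters(x, a)
    expect_lt(steady_state_residual(x, p)$max_scaled, 1e-10)
    # the equilibrium is recoverable from a displaced start
    x_back <- solve_steady_state(p, 0.8 * as.numeric(x))
    expect_equal(unname(x_back), unname(as.numeric(x)), tolerance = 1e-8)
    # reading the realized shares back reproduces the parameters
    a2 <- implied_assumptions(p, x)
    p2 <- derive_parameters(x, a2)
    expect_equal(as.numeric(p2), as.numeric(p), tolerance = 1e-8)
  }
})

test_that("rescaling the steady state rescales only the influx terms", {
  x <- cluster_steady_states(1)
  c_fac <- 3.7
  x_c <- c_fac * as.numeric(x)
  names(x_c) <- state_names()
  attr(x_c, "M0") <- c_fac * attr(x, "M0")
  p1 <- derive_parameters(x)
  pc <- derive_parameters(x_c)
  expect_equal(pc[["A_TN"]], c_fac * p1[["A_TN"]])
  expect_equal(pc[["A_DN"]], c_fac * p1[["A_DN"]])
  # homogeneity: F(c x; theta_c) = c F(x; theta) at arbitrary states
  set.seed(5)
  for (i in 1:3) {
    z <- as.numeric(x) * exp(stats::rnorm(14, 0, 0.4))
    names(z) <- state_names()
    zc <- c_fac * z; names(zc) <- state_names()
    expect_equal(unname(tme_rhs(zc, pc)), unname(c_fac * tme_rhs(z, p1)),
                 tolerance = 1e-10)
  }
})

test_that("stability report matches closed forms and a root-finding oracle", {
  p <- decoupled_params()
  x <- decoupled_equilibrium(p)
  st <- stability_report(p, x)
  # pure-decay reduction dX/dt = A - delta X has eigenvalue -delta
  expect_true(any(abs(st$eigenvalues - (-p[["delta_TN"]])) < 1e-12))
  expect_equal(st$min_real, -p[["delta_Gb"]], tolerance = 1e-12)  # largest decay rate
  # brute-force characteristic-polynomial roots on a 3x3 sub-block
  J <- tme_jacobian(cluster_steady_states(1), tbl_params(1))
  B <- J[c("TN", "Th", "M"), c("TN", "Th", "M")]
  tr <- sum(diag(B))
  m2 <- sum(vapply(utils::combn(3, 2, simplify = FALSE),
                   function(ix) det(B[ix, ix]), numeric(1)))
  roots <- polyroot(c(-det(B), m2, -tr, 1))
  ev <- eigen(B, only.values = TRUE)$values
  expect_equal(sort(Re(roots)), sort(Re(ev)), tolerance = 1e-8)
  # all five printed clusters sit at attracting equilibria
  for (cl in 1:5)
    expect_lt(stability_report(tbl_params(cl), cluster_steady_states(cl))$max_real, 0)
})
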