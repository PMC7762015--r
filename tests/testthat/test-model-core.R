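test_that("all-zero state leaves only the two influx terms", {
  p <- tbl_params(1)
  d <- tme_rhs(state_vector(values = stats::setNames(rep(0, 14), state_names())), p)
  expect_equal(d[["TN"]], p[["A_TN"]])
  expect_equal(d[["DN"]], p[["A_DN"]])
  expect_equal(unname(d[setdiff(state_names(), c("TN", "DN"))]), rep(0, 12))
})

test_that("non-finite inputs are rejected with the offending symbol named", {
  p <- tbl_params(1)
  x <- cluster_steady_states(1)
  x_bad <- x; x_bad[["mu1"]] <- NaN
  expect_error(tme_rhs(x_bad, p), "mu1")
  p_bad <- unclass(p); p_bad[["delta_M"]] <- NA_real_
  expect_error(tme_rhs(x, p_bad), "delta_M")
  expect_error(parameter_set(p_bad), "delta_M")
})

test_that("TGF-beta equation matches its closed form with frozen cells", {
  # with M and Tr held constant the equation is linear:
  # Gb(t) = (lambda_GbM M + lambda_GbTr Tr)/delta * (1 - exp(-delta t))
  p <- tbl_params(1)
  x <- cluster_steady_states(1)
  prod <- p[["lambda_GbM"]] * x[["M"]] + p[["lambda_GbTr"]] * x[["Tr"]]
  delta <- p[["delta_Gb"]]
  f <- function(t, y, parms) {
    s <- x; s[["Gbeta"]] <- y
    list(tme_rhs(s, p)[["Gbeta"]])
  }
  t_probe <- 1 / delta
  sol <- deSolve::ode(c(Gbeta = 0), c(0, t_probe), f, NULL,
                      rtol = 1e-10, atol = 1e-10)
  closed <- prod / delta * (1 - exp(-delta * t_probe))
  expect_equal(sol[2, "Gbeta"], closed, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("analytic Jacobian agrees with central finite differences", {
  x <- cluster_steady_states(2)
  chk <- check_jacobian(x, tbl_params(2), rel = 1e-6)
  expect_lt(chk$max_rel_err, 1e-5)
})

test_that("hand-derived Jacobian entries are reproduced", {
  p <- tbl_params(3)
  x <- cluster_steady_states(3)
  J <- tme_jacobian(x, p)
  # the HMGB1 equation is linear in H
  expect_equal(J["H", "H"], -p[["delta_H"]])
  # logistic self-derivative at C = C0 with cells/cytokines absent:
  # lambda_C (1 - 2 C/C0) - delta_C = -lambda_C - delta_C
  x0 <- stats::setNames(rep(0, 14), state_names())
  x0["C"] <- p[["C0"]]
  expect_equal(tme_jacobian(x0, p)["C", "C"], -p[["lambda_C"]] - p[["delta_C"]])
})

test_that("steady-state residual bookkeeping is exact", {
  for (cl in c(1, 4)) {
    p <- tbl_params(cl)
    x <- cluster_steady_states(cl)
    expect_lt(steady_state_residual(x, p)$max_scaled, 1e-10)
    # uniform inflation breaks the logistic balance in the C equation
    r_up <- steady_state_residual(1.1 * as.numeric(x) |>
                                    stats::setNames(state_names()), p)
    expect_gt(abs(r_up$scaled[["C"]]), 1e-3)
    # perturbing delta_M disturbs only the macrophage balance
    p2 <- p; p2[["delta_M"]] <- 1.1 * p2[["delta_M"]]
    r <- steady_state_residual(x, p2)
    expect_gt(abs(r$scaled[["M"]]), 1e-3)
    expect_lt(max(abs(r$scaled[setdiff(state_names(), "M")])), 1e-12)
  }
})

test_that("dimensionless system has the all-ones equilibrium and exact scale equivalence", {
  x_inf <- cluster_steady_states(1)
  p <- tbl_params(1)
  sys <- nondimensionalize(p, x_inf)
  expect_lt(max(abs(sys$rhs(rep(1, 14)))), 1e-10)
  # change of variables: X(t) = Xbar(t) * X_inf on [0, 500] days
  init_bar <- as.numeric(initial_condition_ratios(1))
  f_bar <- function(t, y, parms) list(sys$rhs(y))
  j_bar <- function(t, y, parms) sys$jacobian(y)
  times <- seq(0, 500, by = 5)
  sol_bar <- deSolve::ode(stats::setNames(init_bar, state_names()), times,
                          f_bar, NULL, jacfunc = j_bar, jactype = "fullusr",
                          rtol = 1e-10, atol = 1e-12, method = "lsoda")
  tr_dim <- simulate(p, initial_state(1), t_end = 500, dt = 5,
                     rtol = 1e-10, atol = 1e-12 * as.numeric(x_inf),
                     ref = as.numeric(x_inf), stop_at_steady = FALSE)
  rebuilt <- sweep(sol_bar[, -1], 2, as.numeric(x_inf), "*")
  expect_equal(unname(rebuilt), unname(tr_dim$state), tolerance = 1e-6)
})

test_that("scaled coefficients follow the ratio-of-scales rule", {
  x_inf <- cluster_steady_states(2)
  p <- tbl_params(2)
  co <- dimensionless_coefficients(nondimensionalize(p, x_inf))
  get <- function(eq, par) co$value[co$equation == eq & co$parameter == par]
  # production from N into H rescales by N_inf / H_inf
  expect_equal(get("H", "lambda_HN"),
               p[["lambda_HN"]] * x_inf[["N"]] / x_inf[["H"]])
  # pure first-order decay rates are scale invariant
  expect_equal(get("H", "delta_H"), p[["delta_H"]])
  expect_equal(get("Gbeta", "delta_Gb"), p[["delta_Gb"]])
})

test_that("nondimensionalize rejects nonpositive references", {
  x <- as.numeric(cluster_steady_states(1))
  x[5] <- 0
  expect_error(nondimensionalize(tbl_params(1), x), "positive")
})

test_that("floor_references raises only vanishing components", {
  x <- as.numeric(cluster_steady_states(3))  # DN = 0.18878, small but real
  med <- stats::setNames(as.numeric(cluster_steady_states(1)), state_names())
  expect_equal(floor_references(x, med), stats::setNames(x, state_names()))
  x[5] <- 1e-30
  floored <- floor_references(x, med)
  expect_equal(floored[["DN"]], 1e-6 * med[["DN"]])
})
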