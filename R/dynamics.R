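#' Tumor growth simulation
#'
#' Stiff integration of the network from small-tumor initial conditions.
#' Cancer cells move on a much slower time scale than cytokines, so the
#' default integrator is implicit-capable (`lsoda`, switching to BDF when
#' stiffness is detected) with the analytic Jacobian supplied.
#'
#' @param params parameter set
#' @param init initial state (nonnegative)
#' @param t_end horizon in days
#' @param rtol relative tolerance
#' @param atol absolute tolerance; by default 1e-10 times a per-variable
#'   scale (`ref`)
#' @param ref per-variable scale used for tolerances and residual scaling;
#'   defaults to `pmax(abs(init), max(init) * 1e-6)`
#' @param dt output grid spacing in days
#' @param stop_at_steady if TRUE, integration stops early once the scaled
#'   steady-state residual falls below `steady_tol`
#' @param steady_tol convergence tolerance on the scaled residual
#' @param cluster,variation optional provenance tags stored on the result
#' @return object of class `tme_trajectory`: list with `time`, `state`
#'   (matrix time x 14), `params`, `ref`, `cluster`, `variation`
#' @export
simulate <- function(params, init, t_end = 10000, rtol = 1e-8, atol = NULL,
                     ref = NULL, dt = 1, stop_at_steady = TRUE,
                     steady_tol = 1e-8, cluster = NA, variation = "nominal") {
  init <- as.numeric(init); names(init) <- state_names()
  validate_state(init)
  if (is.null(ref)) ref <- pmax(abs(init), max(abs(init)) * 1e-6)
  if (is.null(atol)) atol <- 1e-10 * ref
  times <- seq(0, t_end, by = dt)
  deriv <- function(t, y, parms) list(tme_rhs(y, params))
  jac <- function(t, y, parms) tme_jacobian(y, params)
  root <- function(t, y, parms)
    max(abs(tme_rhs(y, params) / ref)) - steady_tol
  args <- list(y = init, times = times, func = deriv, parms = NULL,
               jacfunc = jac, jactype = "fullusr",
               rtol = rtol, atol = atol, method = "lsoda")
  if (stop_at_steady) {
    args$rootfunc <- root
    args$method <- "lsodar"
  }
  sol <- suppressWarnings(do.call(deSolve::ode, args))
  n_ok <- sum(stats::complete.cases(sol))
  if (n_ok < 2L)
    stop("integration failed near t = ", signif(sol[n_ok, 1], 6), " days")
  sol <- sol[seq_len(n_ok), , drop = FALSE]
  structure(list(time = sol[, 1], state = sol[, -1, drop = FALSE],
                 params = params, ref = ref, cluster = cluster,
                 variation = variation),
            class = "tme_trajectory")
}

#' @export
print.tme_trajectory <- function(x, ...) {
  cat("<tme_trajectory> ", length(x$time), " time points on [0, ",
      max(x$time), "] days", sep = "")
  if (!is.na(x$cluster)) cat(", cluster ", x$cluster, sep = "")
  cat(" (", x$variation, ")\n", sep = "")
  invisible(x)
}

#' Round-trip simulation for one printed cluster
#'
#' Derives parameters from the printed steady state, starts from the
#' printed smallest-tumor initial conditions (dimensionless ratios times
#' the steady state) and integrates until the steady-state residual drops
#' below tolerance.
#'
#' @param cluster integer in 1..5
#' @param assumptions assumption set (defaults to the shipped config)
#' @param ... passed to [simulate()]
#' @return `tme_trajectory`
#' @export
simulate_cluster <- function(cluster, assumptions = load_assumptions(), ...) {
  x_inf <- cluster_steady_states(cluster)
  params <- derive_parameters(x_inf, assumptions)
  simulate(params, initial_state(cluster), ref = as.numeric(x_inf),
           cluster = cluster, ...)
}

#' Detect convergence to the steady state
#'
#' Scans a trajectory for the first time point at which the scaled
#' steady-state residual max-norm falls below `tol`.
#'
#' @param traj a `tme_trajectory`
#' @param params parameter set (defaults to the trajectory's own)
#' @param tol residual tolerance
#' @return list: `state` (state at detection or at the final time),
#'   `time`, `converged`
#' @export
detect_steady_state <- function(traj, params = traj$params, tol = 1e-8) {
  ref <- traj$ref
  for (i in seq_along(traj$time)) {
    x <- traj$state[i, ]
    if (max(abs(tme_rhs(x, params) / ref)) < tol)
      return(list(state = x, time = traj$time[i], converged = TRUE))
  }
  n <- length(traj$time)
  list(state = traj$state[n, ], time = traj$time[n], converged = FALSE)
}

#' One-at-a-time ten-percent variation envelope
#'
#' Re-runs the simulation with each listed parameter scaled by
#' `1 - fraction` and `1 + fraction` (two runs per parameter, never joint
#' corners) and returns the pointwise band across all runs plus the
#' nominal trajectory, mirroring the shaded sensitivity bands of the
#' cluster dynamics figures.
#'
#' @param params nominal parameter set
#' @param sensitive character vector of parameter names to vary
#' @param init initial state
#' @param fraction relative variation (default 0.10)
#' @param t_end horizon in days
#' @param ... passed to [simulate()]
#' @return list: `time`, `nominal` (matrix), `lower`, `upper` (pointwise
#'   min/max matrices), `runs` (list of all trajectories), `failed`
#'   (character vector of runs that did not integrate)
#' @export
variation_envelope <- function(params, sensitive, init, fraction = 0.10,
                               t_end = 10000, ...) {
  bad <- setdiff(sensitive, param_names())
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  nominal <- simulate(params, init, t_end = t_end, stop_at_steady = FALSE, ...)
  runs <- list(nominal = nominal)
  failed <- character()
  for (sym in sensitive) {
    for (dir in c(-1, 1)) {
      p2 <- params
      p2[[sym]] <- p2[[sym]] * (1 + dir * fraction)
      tag <- paste0(sym, ifelse(dir < 0, "-", "+"))
      tr <- tryCatch(
        simulate(parameter_set(unclass(p2)), init, t_end = t_end,
                 stop_at_steady = FALSE, variation = tag, ...),
        error = function(e) e)
      if (inherits(tr, "error")) failed <- c(failed, tag) else runs[[tag]] <- tr
    }
  }
  lower <- upper <- nominal$state
  for (tr in runs) {
    lower <- pmin(lower, tr$state)
    upper <- pmax(upper, tr$state)
  }
  list(time = nominal$time, nominal = nominal$state,
       lower = lower, upper = upper, runs = runs, failed = failed)
}

#' Count prominent reversals of the total cell density
#'
#' A transient surge of immune cells early in tumor growth shows up as a
#' local extremum of the total cell density (the nine cell variables
#' summed) before the trajectory settles. This counts direction reversals
#' whose amplitude exceeds `min_prominence` times the overall range, which
#' ignores solver-level wiggle.
#'
#' @param traj a `tme_trajectory`
#' @param min_prominence minimum reversal amplitude relative to the range
#' @param until only consider times up to this value (default: the
#'   detected convergence time)
#' @return integer count of prominent interior extrema
#' @export
count_oscillations <- function(traj, min_prominence = 1e-3, until = NULL) {
  tot <- rowSums(traj$state[, cell_names(), drop = FALSE])
  if (is.null(until)) until <- detect_steady_state(traj)$time
  tot <- tot[traj$time <= until]
  rng <- diff(range(tot))
  if (rng == 0) return(0L)
  tol <- min_prominence * rng
  piv <- tot[1]; dir <- 0; n <- 0L
  for (v in tot[-1]) {
    if (dir == 0) {
      if (abs(v - piv) >= tol) dir <- sign(v - piv)
      if (dir != 0) piv <- v
    } else if (dir > 0) {
      if (v > piv) piv <- v
      else if (v <= piv - tol) { n <- n + 1L; piv <- v; dir <- -1 }
    } else {
      if (v < piv) piv <- v
      else if (v >= piv + tol) { n <- n + 1L; piv <- v; dir <- 1 }
    }
  }
  n
}

#' Write a trajectory to CSV
#'
#' Time column in days followed by the 14 state columns in canonical order.
#' @param traj `tme_trajectory`
#' @param path output file
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(time = traj$time, traj$state, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
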