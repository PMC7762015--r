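#' Steady-state sensitivity by implicit differentiation
#'
#' Differentiating the equilibrium condition F(X*, theta) = 0 gives
#' J dX*/dtheta + dF/dtheta = 0, so the full sensitivity matrix is a
#' single linear solve with the analytic Jacobian and parameter gradient.
#'
#' @param params parameter set
#' @param x_star equilibrium (gated: scaled residual must be < `gate_tol`)
#' @param gate_tol residual gate
#' @return 14 x 59 matrix dX*/dtheta with dimnames (states x parameters)
#' @export
steady_state_sensitivity <- function(params, x_star, gate_tol = 1e-6) {
  res <- steady_state_residual(x_star, params)
  if (res$max_scaled > gate_tol)
    stop("x_star is not an equilibrium (scaled residual ",
         signif(res$max_scaled, 4), ")")
  J <- tme_jacobian(x_star, params)
  rc <- rcond(J)
  if (!is.finite(rc) || rc < 1e-14)
    stop("Jacobian numerically singular (reciprocal condition number ",
         signif(rc, 4), ")")
  G <- tme_param_gradient(x_star, params)
  -solve(J, G)
}

# equilibrium eigenvalue of record: literal minimum of the real parts by
# default, or the slowest (largest real part) mode
.eig_value <- function(J, which = c("min", "max")) {
  which <- match.arg(which)
  ev <- eigen(J, only.values = TRUE)$values
  if (which == "min") min(Re(ev)) else max(Re(ev))
}

#' Sensitivity of the convergence eigenvalue
#'
#' Central finite difference of the selected Jacobian eigenvalue (by
#' default the literal minimum of the real parts, used as the
#' convergence-speed measure) with respect to each parameter, with the
#' equilibrium re-solved at every perturbed parameter vector before the
#' Jacobian is evaluated. Possible eigenvalue crossings are detected by
#' tracking the perturbed spectrum against the nominal one and reported
#' as a warning.
#'
#' @param params parameter set
#' @param x_star equilibrium
#' @param dtheta_rel relative step (default 1e-4)
#' @param which `"min"` (literal minimum real part) or `"max"` (slowest
#'   mode, largest real part)
#' @return named vector d(lambda)/d(theta) over [param_names()]
#' @export
eigenvalue_sensitivity <- function(params, x_star, dtheta_rel = 1e-4,
                                   which = c("min", "max")) {
  which <- match.arg(which)
  res <- steady_state_residual(x_star, params)
  if (res$max_scaled > 1e-6)
    stop("x_star is not an equilibrium (scaled residual ",
         signif(res$max_scaled, 4), ")")
  ev0 <- eigen(tme_jacobian(x_star, params), only.values = TRUE)$values
  target0 <- if (which == "min") ev0[which.min(Re(ev0))] else ev0[which.max(Re(ev0))]
  pn <- param_names()
  out <- stats::setNames(numeric(length(pn)), pn)
  crossings <- character()
  for (sym in pn) {
    theta <- params[[sym]]
    h <- dtheta_rel * theta
    if (h == 0) { out[[sym]] <- 0; next }
    vals <- numeric(2)
    for (k in 1:2) {
      p2 <- params
      p2[[sym]] <- theta + c(-0.5, 0.5)[k] * h
      x2 <- solve_steady_state(p2, x_star, tol = 1e-12)
      ev <- eigen(tme_jacobian(x2, p2), only.values = TRUE)$values
      # continuity check: the eigenvalue closest to the nominal target
      # should still be the extremal one
      near <- ev[which.min(Mod(ev - target0))]
      extremal <- if (which == "min") ev[which.min(Re(ev))] else ev[which.max(Re(ev))]
      if (Mod(near - extremal) > 1e-8 * max(1, Mod(extremal)))
        crossings <- c(crossings, sym)
      vals[k] <- if (which == "min") min(Re(ev)) else max(Re(ev))
    }
    out[[sym]] <- (vals[2] - vals[1]) / h
  }
  if (length(crossings))
    warning("possible eigenvalue crossing while perturbing: ",
            paste(unique(crossings), collapse = ", "))
  out
}

# pointwise dimensionless sensitivities of all three quantities of
# interest at one parameter vector; scales are frozen at the nominal
# reference so the quantities stay comparable across the region
.pointwise_sens <- function(params, x_start, ref, qoi, dtheta_rel = 1e-4,
                            eig_which = "min") {
  x_eq <- solve_steady_state(params, x_start, tol = 1e-12)
  theta <- as.numeric(params[param_names()])
  if (qoi %in% c("cancer", "total")) {
    dX <- steady_state_sensitivity(params, x_eq)
    raw <- if (qoi == "cancer") dX["C", ] else colSums(dX[cell_names(), ])
    scale <- if (qoi == "cancer") ref[["C"]] else sum(ref[cell_names()])
    theta * raw / scale
  } else {
    theta * eigenvalue_sensitivity(params, x_eq, dtheta_rel, which = eig_which)
  }
}

#' Dimensionless sensitivity analysis of the three quantities of interest
#'
#' Computes, for every kinetic parameter, the sensitivity of (a) cancer
#' cell density, (b) total cell density (the nine cell variables; cytokines
#' excluded) and (c) the convergence eigenvalue of the Jacobian at the
#' equilibrium. Sensitivities are reported on the dimensionless scale:
#' state quantities are normalized by their steady-state reference and all
#' derivatives are taken with respect to relative parameter changes
#' (elasticities), which makes the rankings invariant to the cohort's
#' density scaling.
#'
#' @param params parameter set
#' @param x_star equilibrium (also the dimensionless reference)
#' @param qois subset of `c("cancer", "total", "eig")`
#' @param dtheta_rel finite-difference step for the eigenvalue quantity
#' @param eig_which `"min"` or `"max"`, see [eigenvalue_sensitivity()]
#' @return object of class `tme_sensitivity`: matrix `S` (parameters x
#'   quantities) plus metadata
#' @export
sensitivity_analysis <- function(params, x_star,
                                 qois = c("cancer", "total", "eig"),
                                 dtheta_rel = 1e-4, eig_which = "min") {
  qois <- match.arg(qois, several.ok = TRUE)
  ref <- as.numeric(x_star); names(ref) <- state_names()
  S <- sapply(qois, function(q)
    .pointwise_sens(params, x_star, ref, q, dtheta_rel, eig_which))
  structure(list(S = S, params = params, x_star = x_star,
                 region = NULL, eig_which = eig_which),
            class = "tme_sensitivity")
}

#' Region-averaged sensitivities
#'
#' Averages the pointwise dimensionless sensitivities over the
#' hyperrectangle `theta * (1 +/- halfwidth)`, re-solving the equilibrium
#' at every node. The default rule is a level-2 Smolyak sparse grid
#' (nested Clenshaw-Curtis: the center plus one pair of extreme points per
#' dimension, 2p + 1 nodes for p parameters); a seeded Monte-Carlo average
#' over uniform draws is available as `method = "mc"`. Nodes whose
#' equilibrium fails to re-solve are dropped and counted.
#'
#' @param params nominal parameter set
#' @param x_star nominal equilibrium
#' @param halfwidth relative half-width of the region (0 reduces to the
#'   pointwise sensitivity)
#' @param qoi one of `"cancer"`, `"total"`, `"eig"`
#' @param method `"sparse"` (level-2 Smolyak) or `"mc"`
#' @param level sparse-grid level (1 = center point, 2 = default)
#' @param n_mc Monte-Carlo sample size
#' @param seed seed for the Monte-Carlo rule
#' @param dtheta_rel,eig_which passed to the pointwise evaluation
#' @return list: `average` (named vector over parameters), `n_nodes`,
#'   `n_failed`, `method`, `halfwidth`
#' @export
aggregate_over_region <- function(params, x_star, halfwidth = 0.10,
                                  qoi = c("cancer", "total", "eig"),
                                  method = c("sparse", "mc"), level = 2,
                                  n_mc = 1000, seed = 1, dtheta_rel = 1e-4,
                                  eig_which = "min") {
  qoi <- match.arg(qoi); method <- match.arg(method)
  ref <- as.numeric(x_star); names(ref) <- state_names()
  pn <- param_names()
  theta0 <- as.numeric(params[pn])
  eval_node <- function(mult) {
    p2 <- params
    p2[pn] <- theta0 * mult
    tryCatch(.pointwise_sens(parameter_set(unclass(p2)), x_star, ref, qoi,
                             dtheta_rel, eig_which),
             error = function(e) NULL)
  }
  d <- length(pn)
  nodes <- list(); weights <- numeric()
  if (halfwidth == 0 || (method == "sparse" && level == 1)) {
    nodes <- list(rep(1, d)); weights <- 1
  } else if (method == "sparse") {
    if (level != 2) stop("sparse-grid levels 1 and 2 are supported")
    # combination technique with nested Clenshaw-Curtis rules:
    # center with weight (1 - d/3), each axis extreme with weight 1/6
    nodes <- vector("list", 2 * d + 1)
    weights <- numeric(2 * d + 1)
    nodes[[1]] <- rep(1, d); weights[1] <- 1 - d / 3
    k <- 1
    for (j in seq_len(d)) for (s in c(-1, 1)) {
      k <- k + 1
      m <- rep(1, d); m[j] <- 1 + s * halfwidth
      nodes[[k]] <- m; weights[k] <- 1 / 6
    }
  } else {
    set.seed(seed)
    nodes <- lapply(seq_len(n_mc), function(i)
      1 + halfwidth * stats::runif(d, -1, 1))
    weights <- rep(1 / n_mc, n_mc)
  }
  acc <- stats::setNames(numeric(d), pn)
  wsum <- 0; n_failed <- 0
  for (i in seq_along(nodes)) {
    v <- eval_node(nodes[[i]])
    if (is.null(v)) { n_failed <- n_failed + 1; next }
    acc <- acc + weights[i] * v
    wsum <- wsum + weights[i]
  }
  if (wsum == 0) stop("all region nodes failed to re-solve")
  list(average = acc / wsum, n_nodes = length(nodes), n_failed = n_failed,
       method = method, halfwidth = halfwidth)
}

#' Rank parameters by sensitivity and partition into overall and
#' immune-only views
#'
#' Orders parameters by decreasing absolute sensitivity (ties broken by
#' canonical symbol order). The immune-only view masks exactly the
#' parameters appearing in the cancer and necrotic-cell equations, so it
#' isolates the influence of the immune microenvironment.
#'
#' @param result a `tme_sensitivity` object, or a named sensitivity vector
#' @param k number of top parameters to report
#' @param qoi which column to rank when `result` is a `tme_sensitivity`
#' @return list: `ranking` (full data.frame with `parameter`, `S`,
#'   `immune`), `top` (top-k overall), `top_immune` (top-k immune-only)
#' @export
rank_and_partition <- function(result, k = 4, qoi = "cancer") {
  s <- if (inherits(result, "tme_sensitivity")) result$S[, qoi] else result
  pn <- names(s)
  ord <- order(-abs(s), match(pn, param_names()))
  immune <- !(pn %in% cancer_equation_params())
  ranking <- data.frame(parameter = pn[ord], S = as.numeric(s[ord]),
                        immune = immune[ord])
  k <- min(k, nrow(ranking))
  top <- ranking[seq_len(k), ]
  imm <- ranking[ranking$immune, ]
  top_immune <- imm[seq_len(min(k, nrow(imm))), ]
  list(ranking = ranking, top = top, top_immune = top_immune)
}
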