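#' Steady-state parameter estimation
#'
#' With no time-course data, kinetic constants are identified by forcing
#' every equation's production flux to balance its loss flux at the printed
#' per-cluster steady state. One scalar balance per equation cannot pin
#' down several rate constants, so a versioned assumption config supplies
#' (a) fixed decay/turnover rates taken as 1/day placeholders until
#' literature values are transcribed, and (b) nonnegative shares that
#' apportion each balanced flux among its terms. Given those, every rate
#' follows in closed form and the steady state is an equilibrium by
#' construction.
#'
#' @name parameter-estimation
NULL

.eq_groups <- list(
  H = list(fixed = "delta", production = c("N", "M", "Th", "TC", "Tr")),
  mu1 = list(fixed = "delta", production = c("Th", "M", "D")),
  mu2 = list(fixed = "delta", production = c("M", "D", "Tr")),
  Igamma = list(fixed = "delta", production = c("Th", "TC", "M")),
  Gbeta = list(fixed = "delta", production = c("M", "Tr")),
  Th = list(fixed = "turnover", production = c("D", "M", "mu1"),
            loss = c("mu2", "Tr", "natural")),
  TC = list(fixed = "turnover", production = c("Th", "D"),
            loss = c("mu2", "Tr", "natural")),
  Tr = list(fixed = "turnover", production = c("Th", "mu2", "Gbeta"),
            loss = c("mu1", "natural")),
  TN = list(fixed = "delta"),
  D = list(fixed = "turnover", production = c("H", "C"),
           loss = c("H", "C", "natural")),
  M = list(fixed = "delta", production = c("mu2", "Igamma", "Th")),
  C = list(fixed = "turnover", production = c("base", "mu1"),
           loss = c("Gbeta", "Igamma", "TC", "natural")),
  N = list(fixed = "alpha_NC")
)

.group_label <- c(TN = "TN influx", Th = "Th activation", TC = "TC activation",
                  Tr = "Tr activation", DN = "DN influx", D = "D activation",
                  M = "M activation", C = "C proliferation/death",
                  N = "N production", H = "H production",
                  mu1 = "mu1 production", mu2 = "mu2 production",
                  Igamma = "Igamma production", Gbeta = "Gbeta production")

check_shares <- function(w, expected, eq, kind) {
  lbl <- .group_label[[eq]]
  if (is.null(w)) stop("assumption config misses the ", lbl, " group (", kind, " shares)")
  missing <- setdiff(expected, names(w))
  if (length(missing))
    stop(lbl, " group (", kind, ") misses term(s): ",
         paste(missing, collapse = ", "))
  w <- unlist(w)[expected]
  if (any(w < 0)) stop(lbl, ": ", kind, " shares must be >= 0")
  if (abs(sum(w) - 1) > 1e-6)
    stop(lbl, ": ", kind, " shares must sum to 1 (got ", signif(sum(w), 8), ")")
  w / sum(w)
}

#' Load and validate the assumption config
#'
#' @param path YAML config file; defaults to the config shipped with the
#'   package. May also be a pre-parsed list with the same structure.
#' @param cluster optional cluster id; per-cluster overrides under the
#'   config's `clusters` key are merged over the defaults.
#' @return validated assumption set of class `tme_assumptions`
#' @export
load_assumptions <- function(path = NULL, cluster = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "assumptions.yaml", package = "tmekin")
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  if (is.null(cfg$default)) stop("assumption config needs a `default` section")
  a <- cfg$default
  if (!is.null(cluster) && !is.null(cfg$clusters[[as.character(cluster)]])) {
    ov <- cfg$clusters[[as.character(cluster)]]
    for (eq in names(ov)) a[[eq]] <- utils::modifyList(a[[eq]] %||% list(), ov[[eq]])
  }
  out <- list()
  for (eq in names(.eq_groups)) {
    g <- .eq_groups[[eq]]
    spec <- a[[eq]]
    if (is.null(spec)) stop("assumption config misses the ", .group_label[[eq]], " group")
    fixed <- spec[[g$fixed]]
    if (is.null(fixed) || !is.finite(fixed) || fixed <= 0)
      stop(.group_label[[eq]], ": fixed rate `", g$fixed, "` must be > 0")
    if (g$fixed == "alpha_NC" && fixed > 1)
      stop("alpha_NC must lie in (0, 1]")
    entry <- list(fixed = fixed, kind = g$fixed)
    if (!is.null(g$production))
      entry$production <- check_shares(spec$production, g$production, eq, "production")
    if (!is.null(g$loss))
      entry$loss <- check_shares(spec$loss, g$loss, eq, "loss")
    out[[eq]] <- entry
  }
  structure(out, class = "tme_assumptions")
}

#' Write an assumption set back to YAML
#'
#' Round-trips with [load_assumptions()]: the saved file reloads to an
#' identical assumption set.
#' @param assumptions a `tme_assumptions` object
#' @param path output file
#' @export
save_assumptions <- function(assumptions, path) {
  cfg <- list(version = 1, default = list(), clusters = list())
  for (eq in names(assumptions)) {
    e <- assumptions[[eq]]
    spec <- stats::setNames(list(e$fixed), e$kind)
    if (!is.null(e$production)) spec$production <- as.list(e$production)
    if (!is.null(e$loss)) spec$loss <- as.list(e$loss)
    cfg$default[[eq]] <- spec
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a parameter set from a steady state
#'
#' Solves the zeroed right-hand sides at `x_inf` under the given
#' assumptions. For cytokine-like equations the fixed decay rate sets the
#' turnover flux and production shares distribute it over source terms; for
#' cell equations a fixed per-capita turnover sets both flux sides, with
#' loss shares splitting death among its channels; influxes (naive T and
#' dendritic cells) then follow from the already-determined activation
#' fluxes. The cancer capacity is tied to the steady state as C0 = 2 C so
#' the logistic factor at equilibrium is 1/2, and the necrotic decay rate
#' closes the necrotic balance given `alpha_NC`.
#'
#' @param x_inf steady-state vector (e.g. [cluster_steady_states()])
#' @param assumptions assumption set from [load_assumptions()]
#' @param M0 macrophage capacity; defaults to the `M0` attribute of `x_inf`
#' @return `tme_params` whose scaled residual at `x_inf` is ~1e-16
#' @examples
#' x <- cluster_steady_states(1)
#' p <- derive_parameters(x)
#' steady_state_residual(x, p)$max_scaled  # ~ 0
#' @export
derive_parameters <- function(x_inf, assumptions = load_assumptions(),
                              M0 = attr(x_inf, "M0")) {
  if (!inherits(assumptions, "tme_assumptions"))
    assumptions <- load_assumptions(assumptions)
  if (is.null(M0)) stop("M0 must be supplied (attribute of x_inf or argument)")
  validate_steady_state(x_inf, M0)
  s <- as.list(x_inf)
  if (M0 <= s$M) stop("M balance unsolvable: M0 must exceed the steady-state M")
  a <- assumptions
  p <- list(M0 = M0)

  lin_prod <- function(eq, target_flux, param_prefix) {
    w <- a[[eq]]$production
    for (src in names(w)) {
      dens <- s[[src]]
      if (w[[src]] > 0 && dens <= 0)
        stop(.group_label[[eq]], ": positive share on zero steady-state source ", src)
      p[[paste0(param_prefix, src)]] <<- if (w[[src]] == 0) 0 else
        w[[src]] * target_flux / dens
    }
  }

  # cytokines: fixed decay, production shares
  p$delta_H <- a$H$fixed;    lin_prod("H", p$delta_H * s$H, "lambda_H")
  p$delta_mu1 <- a$mu1$fixed; lin_prod("mu1", p$delta_mu1 * s$mu1, "lambda_mu1")
  p$delta_mu2 <- a$mu2$fixed; lin_prod("mu2", p$delta_mu2 * s$mu2, "lambda_mu2")
  p$delta_Ig <- a$Igamma$fixed; lin_prod("Igamma", p$delta_Ig * s$Igamma, "lambda_Ig")
  p$delta_Gb <- a$Gbeta$fixed;  lin_prod("Gbeta", p$delta_Gb * s$Gbeta, "lambda_Gb")

  tcell <- function(eq, prefix) {
    r <- a[[eq]]$fixed
    wl <- a[[eq]]$loss
    for (ch in names(wl)) {
      if (ch == "natural") p[[paste0("delta_", eq)]] <<- wl[[ch]] * r
      else p[[paste0("delta_", eq, ch)]] <<- wl[[ch]] * r / s[[ch]]
    }
    wp <- a[[eq]]$production
    flux <- r * s[[eq]]
    for (src in names(wp)) {
      dens <- s[[src]]
      if (wp[[src]] > 0 && dens <= 0)
        stop(.group_label[[eq]], ": positive share on zero steady-state source ", src)
      suffix <- if (src == "Gbeta") "Gb" else src  # symbol abbreviation
      p[[paste0(prefix, suffix)]] <<- if (wp[[src]] == 0) 0 else
        wp[[src]] * flux / (dens * s$TN)
    }
    r
  }
  r_Th <- tcell("Th", "lambda_Th")
  r_TC <- tcell("TC", "lambda_TC")
  r_Tr <- tcell("Tr", "lambda_Tr")

  # naive T cells: influx balances total activation plus natural death
  p$delta_TN <- a$TN$fixed
  p$A_TN <- r_Th * s$Th + r_TC * s$TC + r_Tr * s$Tr + p$delta_TN * s$TN

  # dendritic cells: rates set on the activated equation, shared with DN
  r_D <- a$D$fixed
  wl <- a$D$loss
  p$delta_DH <- wl[["H"]] * r_D / s$H
  p$delta_DC <- wl[["C"]] * r_D / s$C
  p$delta_D <- wl[["natural"]] * r_D
  wp <- a$D$production
  if (s$DN <= 0)
    stop("D activation: DN steady state must be > 0 (floor near-zero values upstream)")
  p$lambda_DH <- wp[["H"]] * r_D * s$D / (s$H * s$DN)
  p$lambda_DC <- wp[["C"]] * r_D * s$D / (s$C * s$DN)
  p$A_DN <- r_D * s$D + (p$delta_DH * s$H + p$delta_D) * s$DN

  # macrophages: fixed decay, recruitment from the M0 - M reservoir
  p$delta_M <- a$M$fixed
  reservoir <- M0 - s$M
  wm <- a$M$production
  flux_M <- p$delta_M * s$M
  p$lambda_Mmu2 <- wm[["mu2"]] * flux_M / (s$mu2 * reservoir)
  p$lambda_MIg <- wm[["Igamma"]] * flux_M / (s$Igamma * reservoir)
  p$lambda_MTh <- wm[["Th"]] * flux_M / (s$Th * reservoir)

  # cancer: C0 = 2 C so the logistic factor is 1/2 at the steady state
  r_C <- a$C$fixed
  p$C0 <- 2 * s$C
  wl <- a$C$loss
  p$delta_CGb <- wl[["Gbeta"]] * r_C / s$Gbeta
  p$delta_CIg <- wl[["Igamma"]] * r_C / s$Igamma
  p$delta_CTC <- wl[["TC"]] * r_C / s$TC
  p$delta_C <- wl[["natural"]] * r_C
  wp <- a$C$production
  p$lambda_C <- wp[["base"]] * 2 * r_C
  p$lambda_Cmu1 <- wp[["mu1"]] * 2 * r_C / s$mu1

  # necrotic closure
  p$alpha_NC <- a$N$fixed
  p$delta_N <- p$alpha_NC * r_C * s$C / s$N

  bad <- names(p)[unlist(p) < 0]
  if (length(bad))
    stop("negative solved rate(s): ", paste(bad, collapse = ", "))
  parameter_set(unlist(p))
}

#' Assumptions implied by a parameter set at its equilibrium
#'
#' The inverse of [derive_parameters()]: reads off the turnover rates and
#' flux shares that a given parameter set realizes at a given equilibrium,
#' so that feeding them back reproduces the parameters (identifiability
#' under matching assumptions).
#'
#' @param params parameter set
#' @param x_star equilibrium of `params`
#' @return `tme_assumptions`
#' @export
implied_assumptions <- function(params, x_star) {
  p <- as.list(params); s <- as.list(x_star)
  shares <- function(fluxes) {
    w <- unlist(fluxes); w / sum(w)
  }
  out <- list(
    H = list(fixed = p$delta_H, kind = "delta",
             production = shares(list(N = p$lambda_HN * s$N, M = p$lambda_HM * s$M,
                                      Th = p$lambda_HTh * s$Th, TC = p$lambda_HTC * s$TC,
                                      Tr = p$lambda_HTr * s$Tr))),
    mu1 = list(fixed = p$delta_mu1, kind = "delta",
               production = shares(list(Th = p$lambda_mu1Th * s$Th,
                                        M = p$lambda_mu1M * s$M, D = p$lambda_mu1D * s$D))),
    mu2 = list(fixed = p$delta_mu2, kind = "delta",
               production = shares(list(M = p$lambda_mu2M * s$M, D = p$lambda_mu2D * s$D,
                                        Tr = p$lambda_mu2Tr * s$Tr))),
    Igamma = list(fixed = p$delta_Ig, kind = "delta",
                  production = shares(list(Th = p$lambda_IgTh * s$Th,
                                           TC = p$lambda_IgTC * s$TC, M = p$lambda_IgM * s$M))),
    Gbeta = list(fixed = p$delta_Gb, kind = "delta",
                 production = shares(list(M = p$lambda_GbM * s$M, Tr = p$lambda_GbTr * s$Tr)))
  )
  tc <- function(eq, loss_fluxes, prod_fluxes) {
    r <- sum(unlist(loss_fluxes))
    list(fixed = r, kind = "turnover",
         loss = shares(loss_fluxes), production = shares(prod_fluxes))
  }
  out$Th <- tc("Th",
    list(mu2 = p$delta_Thmu2 * s$mu2, Tr = p$delta_ThTr * s$Tr, natural = p$delta_Th),
    list(D = p$lambda_ThD * s$D, M = p$lambda_ThM * s$M, mu1 = p$lambda_Thmu1 * s$mu1))
  out$TC <- tc("TC",
    list(mu2 = p$delta_TCmu2 * s$mu2, Tr = p$delta_TCTr * s$Tr, natural = p$delta_TC),
    list(Th = p$lambda_TCTh * s$Th, D = p$lambda_TCD * s$D))
  out$Tr <- tc("Tr",
    list(mu1 = p$delta_Trmu1 * s$mu1, natural = p$delta_Tr),
    list(Th = p$lambda_TrTh * s$Th, mu2 = p$lambda_Trmu2 * s$mu2,
         Gbeta = p$lambda_TrGb * s$Gbeta))
  out$TN <- list(fixed = p$delta_TN, kind = "delta")
  out$D <- tc("D",
    list(H = p$delta_DH * s$H, C = p$delta_DC * s$C, natural = p$delta_D),
    list(H = p$lambda_DH * s$H, C = p$lambda_DC * s$C))
  out$M <- list(fixed = p$delta_M, kind = "delta",
                production = shares(list(mu2 = p$lambda_Mmu2 * s$mu2,
                                         Igamma = p$lambda_MIg * s$Igamma,
                                         Th = p$lambda_MTh * s$Th)))
  out$C <- tc("C",
    list(Gbeta = p$delta_CGb * s$Gbeta, Igamma = p$delta_CIg * s$Igamma,
         TC = p$delta_CTC * s$TC, natural = p$delta_C),
    list(base = p$lambda_C, mu1 = p$lambda_Cmu1 * s$mu1))
  out$N <- list(fixed = p$alpha_NC, kind = "alpha_NC")
  structure(out, class = "tme_assumptions")
}

#' Newton solver for the equilibrium
#'
#' Damped Newton iteration on the right-hand side using the analytic
#' Jacobian; used by the sensitivity module to re-solve the equilibrium
#' under perturbed parameters.
#'
#' @param params parameter set
#' @param x0 starting state (typically the unperturbed equilibrium)
#' @param tol max-norm tolerance on the scaled residual
#' @param max_iter Newton iteration cap
#' @return named equilibrium vector
#' @export
solve_steady_state <- function(params, x0, tol = 1e-12, max_iter = 100L) {
  x <- as.numeric(x0); names(x) <- state_names()
  scale <- pmax(abs(as.numeric(x0)), 1e-9 * max(abs(as.numeric(x0))))
  resid <- function(x) max(abs(tme_rhs(x, params) / scale))
  r0 <- resid(x)
  for (it in seq_len(max_iter)) {
    if (r0 < tol) return(x)
    f <- tme_rhs(x, params)
    J <- tme_jacobian(x, params)
    step <- tryCatch(solve(J, f), error = function(e)
      stop("singular Jacobian while re-solving equilibrium: ", conditionMessage(e)))
    lam <- 1
    repeat {
      x_new <- x - lam * step
      r_new <- tryCatch(resid(x_new), error = function(e) Inf)
      if (is.finite(r_new) && r_new < r0) break
      lam <- lam / 2
      if (lam < 1e-8) stop("Newton line search failed (residual ", signif(r0, 4), ")")
    }
    x <- x_new; r0 <- r_new
  }
  if (r0 >= tol) stop("equilibrium solve did not converge (residual ", signif(r0, 4), ")")
  x
}

#' Linear stability of an equilibrium
#'
#' Eigen-decomposition of the analytic Jacobian at the equilibrium. The
#' mode with the largest real part governs the asymptotic convergence
#' speed; the literal minimum of the real parts (the fastest-decaying
#' mode) is also reported, since the convergence-speed quantity of
#' interest in the sensitivity analysis is defined through it.
#'
#' @param params parameter set
#' @param x_inf equilibrium
#' @return list: `eigenvalues` (complex, sorted by decreasing real part),
#'   `max_real`, `min_real`, `slowest_mode`, `minimal_eigenvalue`,
#'   `stable` (TRUE iff `max_real < 0`)
#' @export
stability_report <- function(params, x_inf) {
  J <- tme_jacobian(x_inf, params)
  ev <- eigen(J, only.values = TRUE)$values
  ev <- ev[order(-Re(ev))]
  list(eigenvalues = ev,
       max_real = max(Re(ev)),
       min_real = min(Re(ev)),
       slowest_mode = ev[[1]],
       minimal_eigenvalue = min(Re(ev)),
       stable = max(Re(ev)) < 0)
}
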