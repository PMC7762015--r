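#' Non-dimensionalization
#'
#' Rescaling each variable by a positive reference value (its steady state)
#' turns the equilibrium into the all-ones vector and makes the dynamics
#' independent of the cohort's density scaling. The dimensionless system is
#' represented exactly by conjugation with the reference scales:
#' `F_bar(x_bar) = F(x_bar * x_ref) / x_ref`, so no term is rewritten and
#' the two formulations stay consistent to round-off by construction.
#'
#' @param params dimensional parameter set
#' @param x_ref per-variable reference scales, all > 0 (typically a
#'   [cluster_steady_states()] vector). Components exactly zero are not
#'   allowed; near-zero references (e.g. a cluster with almost no naive
#'   dendritic cells) are used as printed, and zeros must be floored by the
#'   caller (see [floor_references()]).
#' @return object of class `tme_dimless` with elements `params`, `x_ref`,
#'   and functions `rhs(x_bar)`, `jacobian(x_bar)`
#' @examples
#' x <- cluster_steady_states(2)
#' sys <- nondimensionalize(derive_parameters(x), x)
#' max(abs(sys$rhs(rep(1, 14))))  # ~ 0: all-ones is the equilibrium
#' @export
nondimensionalize <- function(params, x_ref) {
  x_ref <- as.numeric(x_ref)
  if (length(x_ref) != 14L) stop("x_ref must have 14 components")
  if (any(!is.finite(x_ref)) || any(x_ref <= 0))
    stop("all reference values must be positive and finite; floor zeros first")
  names(x_ref) <- state_names()
  rhs <- function(x_bar) {
    x_bar <- as.numeric(x_bar); names(x_bar) <- state_names()
    tme_rhs(x_bar * x_ref, params) / x_ref
  }
  jac <- function(x_bar) {
    x_bar <- as.numeric(x_bar); names(x_bar) <- state_names()
    J <- tme_jacobian(x_bar * x_ref, params)
    sweep(J, 1, x_ref, "/") * rep(x_ref, each = 14L)
  }
  structure(list(params = params, x_ref = x_ref, rhs = rhs, jacobian = jac),
            class = "tme_dimless")
}

#' Scaled coefficients of the dimensionless system
#'
#' Per-equation view of the rescaling: each term's coefficient multiplied
#' by the ratio of its source-variable scales to the target-variable scale
#' (for example the HMGB1 production rate from necrotic cells becomes
#' `lambda_HN * N_ref / H_ref`). Pure first-order decay rates are
#' scale-invariant. T-cell activation coefficients are listed twice -- once
#' scaled for their own equation and once for the naive T-cell balance --
#' because the two equations have different target scales.
#'
#' @param sys a `tme_dimless` system
#' @return data.frame with columns `equation`, `parameter`, `value`
#' @export
dimensionless_coefficients <- function(sys) {
  p <- as.list(sys$params); r <- as.list(sys$x_ref)
  row <- function(eq, par, value) data.frame(equation = eq, parameter = par, value = value)
  out <- rbind(
    row("H", "lambda_HN", p$lambda_HN * r$N / r$H),
    row("H", "lambda_HM", p$lambda_HM * r$M / r$H),
    row("H", "lambda_HTh", p$lambda_HTh * r$Th / r$H),
    row("H", "lambda_HTC", p$lambda_HTC * r$TC / r$H),
    row("H", "lambda_HTr", p$lambda_HTr * r$Tr / r$H),
    row("H", "delta_H", p$delta_H),
    row("mu1", "lambda_mu1Th", p$lambda_mu1Th * r$Th / r$mu1),
    row("mu1", "lambda_mu1M", p$lambda_mu1M * r$M / r$mu1),
    row("mu1", "lambda_mu1D", p$lambda_mu1D * r$D / r$mu1),
    row("mu1", "delta_mu1", p$delta_mu1),
    row("mu2", "lambda_mu2M", p$lambda_mu2M * r$M / r$mu2),
    row("mu2", "lambda_mu2D", p$lambda_mu2D * r$D / r$mu2),
    row("mu2", "lambda_mu2Tr", p$lambda_mu2Tr * r$Tr / r$mu2),
    row("mu2", "delta_mu2", p$delta_mu2),
    row("Igamma", "lambda_IgTh", p$lambda_IgTh * r$Th / r$Igamma),
    row("Igamma", "lambda_IgTC", p$lambda_IgTC * r$TC / r$Igamma),
    row("Igamma", "lambda_IgM", p$lambda_IgM * r$M / r$Igamma),
    row("Igamma", "delta_Ig", p$delta_Ig),
    row("Gbeta", "lambda_GbM", p$lambda_GbM * r$M / r$Gbeta),
    row("Gbeta", "lambda_GbTr", p$lambda_GbTr * r$Tr / r$Gbeta),
    row("Gbeta", "delta_Gb", p$delta_Gb),
    row("Th", "lambda_ThD", p$lambda_ThD * r$D * r$TN / r$Th),
    row("Th", "lambda_ThM", p$lambda_ThM * r$M * r$TN / r$Th),
    row("Th", "lambda_Thmu1", p$lambda_Thmu1 * r$mu1 * r$TN / r$Th),
    row("Th", "delta_Thmu2", p$delta_Thmu2 * r$mu2),
    row("Th", "delta_ThTr", p$delta_ThTr * r$Tr),
    row("Th", "delta_Th", p$delta_Th),
    row("TC", "lambda_TCTh", p$lambda_TCTh * r$Th * r$TN / r$TC),
    row("TC", "lambda_TCD", p$lambda_TCD * r$D * r$TN / r$TC),
    row("TC", "delta_TCmu2", p$delta_TCmu2 * r$mu2),
    row("TC", "delta_TCTr", p$delta_TCTr * r$Tr),
    row("TC", "delta_TC", p$delta_TC),
    row("Tr", "lambda_TrTh", p$lambda_TrTh * r$Th * r$TN / r$Tr),
    row("Tr", "lambda_Trmu2", p$lambda_Trmu2 * r$mu2 * r$TN / r$Tr),
    row("Tr", "lambda_TrGb", p$lambda_TrGb * r$Gbeta * r$TN / r$Tr),
    row("Tr", "delta_Trmu1", p$delta_Trmu1 * r$mu1),
    row("Tr", "delta_Tr", p$delta_Tr),
    row("TN", "A_TN", p$A_TN / r$TN),
    row("TN", "lambda_ThD", p$lambda_ThD * r$D),
    row("TN", "lambda_ThM", p$lambda_ThM * r$M),
    row("TN", "lambda_Thmu1", p$lambda_Thmu1 * r$mu1),
    row("TN", "lambda_TCTh", p$lambda_TCTh * r$Th),
    row("TN", "lambda_TCD", p$lambda_TCD * r$D),
    row("TN", "lambda_TrTh", p$lambda_TrTh * r$Th),
    row("TN", "lambda_Trmu2", p$lambda_Trmu2 * r$mu2),
    row("TN", "lambda_TrGb", p$lambda_TrGb * r$Gbeta),
    row("TN", "delta_TN", p$delta_TN),
    row("DN", "A_DN", p$A_DN / r$DN),
    row("DN", "lambda_DH", p$lambda_DH * r$H),
    row("DN", "lambda_DC", p$lambda_DC * r$C),
    row("DN", "delta_DH", p$delta_DH * r$H),
    row("DN", "delta_D", p$delta_D),
    row("D", "lambda_DH", p$lambda_DH * r$H * r$DN / r$D),
    row("D", "lambda_DC", p$lambda_DC * r$C * r$DN / r$D),
    row("D", "delta_DH", p$delta_DH * r$H),
    row("D", "delta_DC", p$delta_DC * r$C),
    row("D", "delta_D", p$delta_D),
    row("M", "lambda_Mmu2", p$lambda_Mmu2 * r$mu2),
    row("M", "lambda_MIg", p$lambda_MIg * r$Igamma),
    row("M", "lambda_MTh", p$lambda_MTh * r$Th),
    row("M", "M0", p$M0 / r$M),
    row("M", "delta_M", p$delta_M),
    row("C", "lambda_C", p$lambda_C),
    row("C", "lambda_Cmu1", p$lambda_Cmu1 * r$mu1),
    row("C", "C0", p$C0 / r$C),
    row("C", "delta_CGb", p$delta_CGb * r$Gbeta),
    row("C", "delta_CIg", p$delta_CIg * r$Igamma),
    row("C", "delta_CTC", p$delta_CTC * r$TC),
    row("C", "delta_C", p$delta_C),
    row("N", "alpha_NC", p$alpha_NC * r$C / r$N),
    row("N", "delta_CGb", p$delta_CGb * r$Gbeta),
    row("N", "delta_CIg", p$delta_CIg * r$Igamma),
    row("N", "delta_CTC", p$delta_CTC * r$TC),
    row("N", "delta_C", p$delta_C),
    row("N", "delta_N", p$delta_N)
  )
  out
}

#' Floor vanishing components of a reference vector
#'
#' Non-dimensionalization divides by the reference values, however small
#' a printed value may be, but components that are zero (or numerically
#' indistinguishable from zero, as can happen for a cell type essentially
#' absent from a cluster) are disallowed. The documented floor raises any
#' component below 1e-6 times the cohort median of that variable up to
#' that floor; values already above it are returned as printed.
#'
#' @param x_ref reference vector with possible (near-)zeros
#' @param cohort_median named vector of cohort-median values per variable
#' @return floored reference vector
#' @export
floor_references <- function(x_ref, cohort_median) {
  x <- as.numeric(x_ref); names(x) <- state_names()
  med <- as.numeric(cohort_median)[match(state_names(), names(cohort_median))]
  floor_at <- 1e-6 * med
  low <- which(x < floor_at)
  if (length(low)) {
    if (any(!is.finite(med[low])) || any(med[low] <= 0))
      stop("cannot floor: cohort median missing or nonpositive for ",
           paste(state_names()[low], collapse = ", "))
    x[low] <- floor_at[low]
  }
  x
}
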