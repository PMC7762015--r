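#' Right-hand side of the tumor-immune ODE system
#'
#' Time derivatives (per day) of the 14 state variables. The network:
#' cytokines are produced linearly by their source cells and decay
#' first-order; T-cell activation terms multiply the naive pool TN;
#' dendritic cells are activated by HMGB1 and by cancer-derived signals
#' and lose cells to HMGB1-impaired maturation and cancer-induced death;
#' activated macrophages recruit from the conserved pool M0 - M; cancer
#' follows logistic growth (rate boosted by the carcinogenic pool mu1) with
#' losses to TGF-beta, IFN-gamma, cytotoxic killing and intrinsic death;
#' a fraction `alpha_NC` of that death flux feeds the necrotic pool, which
#' releases HMGB1.
#'
#' @param state named state vector (see [state_vector()])
#' @param params parameter set (see [parameter_set()])
#' @return named numeric vector of derivatives, in state order
#' @export
tme_rhs <- function(state, params) {
  validate_state(state, allow_negative = TRUE)
  pv <- as.numeric(params)
  if (any(!is.finite(pv))) {
    bad <- names(params)[!is.finite(pv)]
    stop("non-finite parameter(s): ", paste(bad, collapse = ", "))
  }
  x <- as.list(state)
  p <- as.list(params)
  with(c(x, p), {
    act_Th <- lambda_ThD * D + lambda_ThM * M + lambda_Thmu1 * mu1
    act_TC <- lambda_TCTh * Th + lambda_TCD * D
    act_Tr <- lambda_TrTh * Th + lambda_Trmu2 * mu2 + lambda_TrGb * Gbeta
    dc_act <- lambda_DH * H + lambda_DC * C
    death_C <- delta_CGb * Gbeta + delta_CIg * Igamma + delta_CTC * TC + delta_C

    c(
      TN = A_TN - (act_Th + act_TC + act_Tr) * TN - delta_TN * TN,
      Th = act_Th * TN - (delta_Thmu2 * mu2 + delta_ThTr * Tr + delta_Th) * Th,
      TC = act_TC * TN - (delta_TCmu2 * mu2 + delta_TCTr * Tr + delta_TC) * TC,
      Tr = act_Tr * TN - (delta_Trmu1 * mu1 + delta_Tr) * Tr,
      DN = A_DN - dc_act * DN - (delta_DH * H + delta_D) * DN,
      D  = dc_act * DN - (delta_DH * H + delta_DC * C + delta_D) * D,
      M  = (lambda_Mmu2 * mu2 + lambda_MIg * Igamma + lambda_MTh * Th) * (M0 - M) -
             delta_M * M,
      C  = (lambda_C + lambda_Cmu1 * mu1) * C * (1 - C / C0) - death_C * C,
      N  = alpha_NC * death_C * C - delta_N * N,
      H  = lambda_HN * N + lambda_HM * M + lambda_HTh * Th +
             lambda_HTC * TC + lambda_HTr * Tr - delta_H * H,
      mu1 = lambda_mu1Th * Th + lambda_mu1M * M + lambda_mu1D * D - delta_mu1 * mu1,
      mu2 = lambda_mu2M * M + lambda_mu2D * D + lambda_mu2Tr * Tr - delta_mu2 * mu2,
      Igamma = lambda_IgTh * Th + lambda_IgTC * TC + lambda_IgM * M - delta_Ig * Igamma,
      Gbeta  = lambda_GbM * M + lambda_GbTr * Tr - delta_Gb * Gbeta
    )
  })
}

#' Analytic Jacobian of the right-hand side
#'
#' Entry (i, j) is the partial derivative of the i-th equation with respect
#' to the j-th state variable, both in canonical order. Hand-derived;
#' [check_jacobian()] cross-checks it against central finite differences.
#'
#' @inheritParams tme_rhs
#' @return 14 x 14 matrix with dimnames
#' @export
tme_jacobian <- function(state, params) {
  validate_state(state, allow_negative = TRUE)
  x <- as.list(state)
  p <- as.list(params)
  nm <- state_names()
  J <- matrix(0, 14, 14, dimnames = list(nm, nm))
  with(c(x, p), {
    act_Th <- lambda_ThD * D + lambda_ThM * M + lambda_Thmu1 * mu1
    act_TC <- lambda_TCTh * Th + lambda_TCD * D
    act_Tr <- lambda_TrTh * Th + lambda_Trmu2 * mu2 + lambda_TrGb * Gbeta
    dc_act <- lambda_DH * H + lambda_DC * C
    death_C <- delta_CGb * Gbeta + delta_CIg * Igamma + delta_CTC * TC + delta_C
    prolif <- lambda_C + lambda_Cmu1 * mu1

    J["TN", "TN"] <- -(act_Th + act_TC + act_Tr) - delta_TN
    J["TN", "Th"] <- -(lambda_TCTh + lambda_TrTh) * TN
    J["TN", "D"]  <- -(lambda_ThD + lambda_TCD) * TN
    J["TN", "M"]  <- -lambda_ThM * TN
    J["TN", "mu1"] <- -lambda_Thmu1 * TN
    J["TN", "mu2"] <- -lambda_Trmu2 * TN
    J["TN", "Gbeta"] <- -lambda_TrGb * TN

    J["Th", "TN"] <- act_Th
    J["Th", "Th"] <- -(delta_Thmu2 * mu2 + delta_ThTr * Tr + delta_Th)
    J["Th", "Tr"] <- -delta_ThTr * Th
    J["Th", "D"]  <- lambda_ThD * TN
    J["Th", "M"]  <- lambda_ThM * TN
    J["Th", "mu1"] <- lambda_Thmu1 * TN
    J["Th", "mu2"] <- -delta_Thmu2 * Th

    J["TC", "TN"] <- act_TC
    J["TC", "Th"] <- lambda_TCTh * TN
    J["TC", "TC"] <- -(delta_TCmu2 * mu2 + delta_TCTr * Tr + delta_TC)
    J["TC", "Tr"] <- -delta_TCTr * TC
    J["TC", "D"]  <- lambda_TCD * TN
    J["TC", "mu2"] <- -delta_TCmu2 * TC

    J["Tr", "TN"] <- act_Tr
    J["Tr", "Th"] <- lambda_TrTh * TN
    J["Tr", "Tr"] <- -(delta_Trmu1 * mu1 + delta_Tr)
    J["Tr", "mu1"] <- -delta_Trmu1 * Tr
    J["Tr", "mu2"] <- lambda_Trmu2 * TN
    J["Tr", "Gbeta"] <- lambda_TrGb * TN

    J["DN", "DN"] <- -dc_act - (delta_DH * H + delta_D)
    J["DN", "C"]  <- -lambda_DC * DN
    J["DN", "H"]  <- -(lambda_DH + delta_DH) * DN

    J["D", "DN"] <- dc_act
    J["D", "D"]  <- -(delta_DH * H + delta_DC * C + delta_D)
    J["D", "C"]  <- lambda_DC * DN - delta_DC * D
    J["D", "H"]  <- lambda_DH * DN - delta_DH * D

    J["M", "Th"] <- lambda_MTh * (M0 - M)
    J["M", "M"]  <- -(lambda_Mmu2 * mu2 + lambda_MIg * Igamma + lambda_MTh * Th) -
                      delta_M
    J["M", "mu2"] <- lambda_Mmu2 * (M0 - M)
    J["M", "Igamma"] <- lambda_MIg * (M0 - M)

    J["C", "TC"] <- -delta_CTC * C
    J["C", "C"]  <- prolif * (1 - 2 * C / C0) - death_C
    J["C", "mu1"] <- lambda_Cmu1 * C * (1 - C / C0)
    J["C", "Igamma"] <- -delta_CIg * C
    J["C", "Gbeta"]  <- -delta_CGb * C

    J["N", "TC"] <- alpha_NC * delta_CTC * C
    J["N", "C"]  <- alpha_NC * death_C
    J["N", "N"]  <- -delta_N
    J["N", "Igamma"] <- alpha_NC * delta_CIg * C
    J["N", "Gbeta"]  <- alpha_NC * delta_CGb * C

    J["H", "Th"] <- lambda_HTh
    J["H", "TC"] <- lambda_HTC
    J["H", "Tr"] <- lambda_HTr
    J["H", "M"]  <- lambda_HM
    J["H", "N"]  <- lambda_HN
    J["H", "H"]  <- -delta_H

    J["mu1", "Th"] <- lambda_mu1Th
    J["mu1", "D"]  <- lambda_mu1D
    J["mu1", "M"]  <- lambda_mu1M
    J["mu1", "mu1"] <- -delta_mu1

    J["mu2", "Tr"] <- lambda_mu2Tr
    J["mu2", "D"]  <- lambda_mu2D
    J["mu2", "M"]  <- lambda_mu2M
    J["mu2", "mu2"] <- -delta_mu2

    J["Igamma", "Th"] <- lambda_IgTh
    J["Igamma", "TC"] <- lambda_IgTC
    J["Igamma", "M"]  <- lambda_IgM
    J["Igamma", "Igamma"] <- -delta_Ig

    J["Gbeta", "Tr"] <- lambda_GbTr
    J["Gbeta", "M"]  <- lambda_GbM
    J["Gbeta", "Gbeta"] <- -delta_Gb
    J
  })
}

#' Finite-difference cross-check of the analytic Jacobian
#'
#' @inheritParams tme_rhs
#' @param rel relative step per variable (absolute floor taken from the
#'   largest state component)
#' @return list with the analytic matrix, the numeric matrix, and the
#'   maximum relative discrepancy
#' @export
check_jacobian <- function(state, params, rel = 1e-6) {
  Ja <- tme_jacobian(state, params)
  Jn <- Ja * 0
  floor_h <- rel * max(abs(state), 1)
  for (j in seq_len(14)) {
    h <- max(rel * abs(state[[j]]), floor_h * 1e-4)
    up <- state; up[j] <- up[j] + h
    dn <- state; dn[j] <- dn[j] - h
    Jn[, j] <- (tme_rhs(up, params) - tme_rhs(dn, params)) / (2 * h)
  }
  scale <- max(abs(Ja))
  list(analytic = Ja, numeric = Jn,
       max_rel_err = max(abs(Ja - Jn)) / scale)
}

#' Gradient of the right-hand side with respect to the parameters
#'
#' Analytic matrix of partial derivatives of each equation with respect to
#' each kinetic parameter (columns in [param_names()] order), used by the
#' implicit-differentiation sensitivity solver. Activation rates appear in
#' two equations (their own and the naive T-cell balance) and are handled
#' accordingly; `C0` and `M0` are the only parameters entering nonlinearly
#' and linearly-in-capacity respectively.
#'
#' @inheritParams tme_rhs
#' @return 14 x 59 matrix with dimnames
#' @export
tme_param_gradient <- function(state, params) {
  x <- as.list(state)
  p <- as.list(params)
  nm <- state_names()
  pn <- param_names()
  G <- matrix(0, 14, length(pn), dimnames = list(nm, pn))
  with(c(x, p), {
    death_C <- delta_CGb * Gbeta + delta_CIg * Igamma + delta_CTC * TC + delta_C
    log_fac <- C * (1 - C / C0)

    # cytokine production / decay
    G["H", "lambda_HN"] <- N;  G["H", "lambda_HM"] <- M
    G["H", "lambda_HTh"] <- Th; G["H", "lambda_HTC"] <- TC
    G["H", "lambda_HTr"] <- Tr; G["H", "delta_H"] <- -H
    G["mu1", "lambda_mu1Th"] <- Th; G["mu1", "lambda_mu1M"] <- M
    G["mu1", "lambda_mu1D"] <- D;   G["mu1", "delta_mu1"] <- -mu1
    G["mu2", "lambda_mu2M"] <- M;   G["mu2", "lambda_mu2D"] <- D
    G["mu2", "lambda_mu2Tr"] <- Tr; G["mu2", "delta_mu2"] <- -mu2
    G["Igamma", "lambda_IgTh"] <- Th; G["Igamma", "lambda_IgTC"] <- TC
    G["Igamma", "lambda_IgM"] <- M;   G["Igamma", "delta_Ig"] <- -Igamma
    G["Gbeta", "lambda_GbM"] <- M; G["Gbeta", "lambda_GbTr"] <- Tr
    G["Gbeta", "delta_Gb"] <- -Gbeta

    # T-cell activation terms appear with opposite sign in the TN balance
    G["Th", "lambda_ThD"] <- D * TN;   G["TN", "lambda_ThD"] <- -D * TN
    G["Th", "lambda_ThM"] <- M * TN;   G["TN", "lambda_ThM"] <- -M * TN
    G["Th", "lambda_Thmu1"] <- mu1 * TN; G["TN", "lambda_Thmu1"] <- -mu1 * TN
    G["Th", "delta_Thmu2"] <- -mu2 * Th
    G["Th", "delta_ThTr"] <- -Tr * Th
    G["Th", "delta_Th"] <- -Th

    G["TC", "lambda_TCTh"] <- Th * TN; G["TN", "lambda_TCTh"] <- -Th * TN
    G["TC", "lambda_TCD"] <- D * TN;   G["TN", "lambda_TCD"] <- -D * TN
    G["TC", "delta_TCmu2"] <- -mu2 * TC
    G["TC", "delta_TCTr"] <- -Tr * TC
    G["TC", "delta_TC"] <- -TC

    G["Tr", "lambda_TrTh"] <- Th * TN;    G["TN", "lambda_TrTh"] <- -Th * TN
    G["Tr", "lambda_Trmu2"] <- mu2 * TN;  G["TN", "lambda_Trmu2"] <- -mu2 * TN
    G["Tr", "lambda_TrGb"] <- Gbeta * TN; G["TN", "lambda_TrGb"] <- -Gbeta * TN
    G["Tr", "delta_Trmu1"] <- -mu1 * Tr
    G["Tr", "delta_Tr"] <- -Tr

    G["TN", "A_TN"] <- 1
    G["TN", "delta_TN"] <- -TN

    # dendritic cells: activation and HMGB1 loss shared between DN and D
    G["DN", "A_DN"] <- 1
    G["DN", "lambda_DH"] <- -H * DN; G["D", "lambda_DH"] <- H * DN
    G["DN", "lambda_DC"] <- -C * DN; G["D", "lambda_DC"] <- C * DN
    G["DN", "delta_DH"] <- -H * DN;  G["D", "delta_DH"] <- -H * D
    G["D", "delta_DC"] <- -C * D
    G["DN", "delta_D"] <- -DN; G["D", "delta_D"] <- -D

    G["M", "lambda_Mmu2"] <- mu2 * (M0 - M)
    G["M", "lambda_MIg"] <- Igamma * (M0 - M)
    G["M", "lambda_MTh"] <- Th * (M0 - M)
    G["M", "delta_M"] <- -M
    G["M", "M0"] <- lambda_Mmu2 * mu2 + lambda_MIg * Igamma + lambda_MTh * Th

    G["C", "lambda_C"] <- log_fac
    G["C", "lambda_Cmu1"] <- mu1 * log_fac
    G["C", "C0"] <- (lambda_C + lambda_Cmu1 * mu1) * C^2 / C0^2
    G["C", "delta_CGb"] <- -Gbeta * C; G["N", "delta_CGb"] <- alpha_NC * Gbeta * C
    G["C", "delta_CIg"] <- -Igamma * C; G["N", "delta_CIg"] <- alpha_NC * Igamma * C
    G["C", "delta_CTC"] <- -TC * C;     G["N", "delta_CTC"] <- alpha_NC * TC * C
    G["C", "delta_C"] <- -C;            G["N", "delta_C"] <- alpha_NC * C

    G["N", "alpha_NC"] <- death_C * C
    G["N", "delta_N"] <- -N
    G
  })
}

#' Scaled steady-state residual
#'
#' Evaluates the right-hand side and reports it relative to a per-variable
#' scale, so "how far from equilibrium" is comparable across cell densities
#' and cytokine levels. Used as the acceptance gate for derived parameters
#' and for convergence detection.
#'
#' @inheritParams tme_rhs
#' @param scale per-variable scale; defaults to `pmax(abs(state), tiny)`
#' @return list with `residual` (raw derivative), `scaled` (residual/scale)
#'   and `max_scaled` (max-norm of the scaled residual)
#' @export
steady_state_residual <- function(state, params, scale = NULL) {
  r <- tme_rhs(state, params)
  if (is.null(scale)) scale <- pmax(abs(state), 1e-12 * max(abs(state), 1))
  s <- r / scale
  list(residual = r, scaled = s, max_scaled = max(abs(s)))
}
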