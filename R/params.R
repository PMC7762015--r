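#' Parameter space
#'
#' All kinetic constants of the network. Naming follows the field's
#' convention: `lambda_*` for production/activation/proliferation rates,
#' `delta_*` for decay and death rates, `A_*` for constant influx, with the
#' source variable appended (e.g. `lambda_HN` produces H from N;
#' `delta_CTC` is cancer killing by cytotoxic cells). `M0` is the conserved
#' total macrophage capacity, `C0` the cancer carrying capacity, `alpha_NC`
#' the fraction of dying cancer cells that become necrotic, and `alpha_dim`
#' the density scaling used when mapping cohort tables to densities
#' (`alpha_dim` never enters the dynamics).
#'
#' @name parameter-space
NULL

param_template <- function() {
  c(
    # HMGB1 (H)
    "lambda_HN", "lambda_HM", "lambda_HTh", "lambda_HTC", "lambda_HTr", "delta_H",
    # carcinogenic cytokines (mu1)
    "lambda_mu1Th", "lambda_mu1M", "lambda_mu1D", "delta_mu1",
    # immunosuppressive agents (mu2)
    "lambda_mu2M", "lambda_mu2D", "lambda_mu2Tr", "delta_mu2",
    # IFN-gamma
    "lambda_IgTh", "lambda_IgTC", "lambda_IgM", "delta_Ig",
    # TGF-beta
    "lambda_GbM", "lambda_GbTr", "delta_Gb",
    # helper T cells
    "lambda_ThD", "lambda_ThM", "lambda_Thmu1",
    "delta_Thmu2", "delta_ThTr", "delta_Th",
    # cytotoxic cells
    "lambda_TCTh", "lambda_TCD", "delta_TCmu2", "delta_TCTr", "delta_TC",
    # regulatory T cells
    "lambda_TrTh", "lambda_Trmu2", "lambda_TrGb", "delta_Trmu1", "delta_Tr",
    # naive T cells
    "A_TN", "delta_TN",
    # dendritic cells
    "A_DN", "lambda_DH", "lambda_DC", "delta_DH", "delta_DC", "delta_D",
    # macrophages
    "lambda_Mmu2", "lambda_MIg", "lambda_MTh", "delta_M", "M0",
    # cancer cells
    "lambda_C", "lambda_Cmu1", "C0",
    "delta_CGb", "delta_CIg", "delta_CTC", "delta_C",
    # necrotic cells
    "alpha_NC", "delta_N",
    # cohort density scaling (not a dynamic rate)
    "alpha_dim"
  )
}

#' Names of all kinetic parameters entering the dynamics
#'
#' Excludes `alpha_dim`, which only scales cohort data to densities.
#' @return character vector (59 names)
#' @export
param_names <- function() setdiff(param_template(), "alpha_dim")

# decay rates that must be strictly positive
.strict_deltas <- c("delta_H", "delta_mu1", "delta_mu2", "delta_Ig", "delta_Gb",
                    "delta_Th", "delta_TC", "delta_Tr", "delta_TN", "delta_D",
                    "delta_M", "delta_C", "delta_N")

#' Construct and validate a parameter set
#'
#' @param ... named parameter values, or a single named vector/list. Every
#'   name in [param_names()] must be present; `alpha_dim` is optional and
#'   defaults to 1.125e5.
#' @return named numeric vector of class `tme_params`
#' @export
parameter_set <- function(...) {
  dots <- list(...)
  v <- if (length(dots) == 1L && is.null(names(dots)) || (length(dots) == 1L && length(dots[[1]]) > 1L))
    unlist(dots[[1]]) else unlist(dots)
  nm <- param_template()
  if (!("alpha_dim" %in% names(v))) v[["alpha_dim"]] <- 1.125e5
  extra <- setdiff(names(v), nm)
  if (length(extra)) stop("unknown parameter(s): ", paste(extra, collapse = ", "))
  missing <- setdiff(nm, names(v))
  if (length(missing)) stop("missing parameter(s): ", paste(missing, collapse = ", "))
  p <- as.numeric(v[nm]); names(p) <- nm
  validate_params(p)
  structure(p, class = "tme_params")
}

validate_params <- function(p) {
  if (any(!is.finite(p))) {
    bad <- names(p)[!is.finite(p)]
    stop("non-finite parameter(s): ", paste(bad, collapse = ", "))
  }
  if (any(p < 0)) {
    bad <- names(p)[p < 0]
    stop("negative parameter(s): ", paste(bad, collapse = ", "))
  }
  zero_bad <- .strict_deltas[p[.strict_deltas] <= 0]
  if (length(zero_bad)) stop("decay rate(s) must be > 0: ", paste(zero_bad, collapse = ", "))
  if (p[["C0"]] <= 0) stop("C0 must be > 0")
  if (p[["M0"]] <= 0) stop("M0 must be > 0")
  if (p[["alpha_NC"]] <= 0 || p[["alpha_NC"]] > 1)
    stop("alpha_NC must lie in (0, 1]")
  invisible(p)
}

#' @export
print.tme_params <- function(x, ...) {
  cat("<tme_params> ", length(param_names()), " kinetic parameters\n", sep = "")
  print(stats::setNames(as.numeric(x), names(x)), ...)
  invisible(x)
}

#' Parameters appearing in the cancer and necrotic-cell equations
#'
#' The "immune-only" view of the sensitivity analysis excludes exactly
#' these, so that rankings reflect the immune microenvironment rather than
#' intrinsic tumor kinetics.
#' @return character vector
#' @export
cancer_equation_params <- function() {
  c("lambda_C", "lambda_Cmu1", "C0",
    "delta_CGb", "delta_CIg", "delta_CTC", "delta_C",
    "alpha_NC", "delta_N")
}

#' Serialize / deserialize parameter sets and steady states
#'
#' Flat key-value YAML, keys being the symbol names of
#' [parameter-space] or [state-space].
#'
#' @param x a `tme_params` vector or named steady-state vector
#' @param path file path
#' @name tme-io
#' @export
write_params <- function(x, path) {
  yaml::write_yaml(as.list(stats::setNames(as.numeric(x), names(x))), path)
  invisible(path)
}

#' @rdname tme-io
#' @export
read_params <- function(path) {
  parameter_set(unlist(yaml::read_yaml(path)))
}
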