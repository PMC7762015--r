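#' State space of the tumor-immune network
#'
#' The model tracks nine cell populations and five cytokine pools inside a
#' colonic tumor. Cells are densities in cells/cm^3; cytokines are bulk
#' RNA-seq-derived expression levels in arbitrary (but cohort-fixed) units.
#' All matrices, trajectories and files in the package use one fixed ordering:
#'
#' \describe{
#'   \item{TN}{naive T cells}
#'   \item{Th}{helper T cells}
#'   \item{TC}{cytotoxic cells (CD8+ T cells and activated NK cells)}
#'   \item{Tr}{regulatory T cells}
#'   \item{DN}{naive dendritic cells}
#'   \item{D}{activated dendritic cells}
#'   \item{M}{activated macrophages (all TAM sub-types pooled)}
#'   \item{C}{cancer cells}
#'   \item{N}{necrotic cells}
#'   \item{H}{HMGB1, the DAMP released by necrotic cells}
#'   \item{mu1}{carcinogenic cytokine pool (IL-6, IL-17, IL-21, IL-22)}
#'   \item{mu2}{immunosuppressive pool (IL-10, CCL20)}
#'   \item{Igamma}{interferon gamma}
#'   \item{Gbeta}{TGF-beta}
#' }
#'
#' Naive macrophages are not a state: total macrophage capacity M0 is
#' conserved, so MN = M0 - M is reported on demand.
#'
#' @name state-space
NULL

#' Canonical variable names, in model order
#' @return character vector of length 14
#' @export
state_names <- function() {
  c("TN", "Th", "TC", "Tr", "DN", "D", "M", "C", "N",
    "H", "mu1", "mu2", "Igamma", "Gbeta")
}

#' Names of the nine cell-density variables
#' @return character vector of length 9
#' @export
cell_names <- function() state_names()[1:9]

#' Construct a named state vector
#'
#' @param ... named components; every name must be one of [state_names()]
#'   and every one of the 14 variables must be supplied (or use `values`).
#' @param values optionally, a full named numeric vector instead of `...`.
#' @return named numeric vector of length 14 in canonical order
#' @examples
#' x <- state_vector(TN = 1e4, Th = 5e3, TC = 2e3, Tr = 2e3, DN = 300,
#'                   D = 600, M = 1e4, C = 9e4, N = 4.5e4, H = 9e3,
#'                   mu1 = 160, mu2 = 1300, Igamma = 8, Gbeta = 1.9e4)
#' @export
state_vector <- function(..., values = NULL) {
  v <- if (is.null(values)) unlist(list(...)) else values
  nm <- state_names()
  missing <- setdiff(nm, names(v))
  extra <- setdiff(names(v), nm)
  if (length(extra)) stop("unknown state component(s): ", paste(extra, collapse = ", "))
  if (length(missing)) stop("missing state component(s): ", paste(missing, collapse = ", "))
  out <- as.numeric(v[nm])
  names(out) <- nm
  validate_state(out)
  out
}

validate_state <- function(x, allow_negative = FALSE) {
  if (length(x) != 14L) stop("state must have 14 components")
  if (any(!is.finite(x))) {
    bad <- state_names()[!is.finite(x)]
    stop("non-finite state component(s): ", paste(bad, collapse = ", "))
  }
  if (!allow_negative && any(x < 0)) {
    bad <- state_names()[x < 0]
    stop("negative state component(s): ", paste(bad, collapse = ", "))
  }
  invisible(x)
}

#' Printed per-cluster steady states
#'
#' Large tumors within each immune-pattern cluster are assumed to sit near
#' their steady state; this returns the transcribed per-cluster mean
#' densities shipped with the package (cells/cm^3, cytokines in expression
#' units), together with the macrophage capacity M0.
#'
#' @param cluster optional integer in 1..5; if given, a single steady state
#'   is returned as a named vector with attribute `M0`.
#' @return data.frame of all five clusters, or a named state vector
#' @export
cluster_steady_states <- function(cluster = NULL) {
  path <- system.file("extdata", "cluster_steady_states.csv", package = "tmekin")
  tab <- utils::read.csv(path)
  if (is.null(cluster)) return(tab)
  stopifnot(length(cluster) == 1L, cluster %in% tab$cluster)
  row <- tab[tab$cluster == cluster, ]
  x <- state_vector(values = unlist(row[state_names()]))
  attr(x, "M0") <- row$M0
  validate_steady_state(x, row$M0)
  x
}

validate_steady_state <- function(x_inf, M0) {
  validate_state(x_inf)
  if (any(x_inf[setdiff(state_names(), "DN")] <= 0))
    stop("steady-state components (other than DN) must be positive")
  if (x_inf[["DN"]] < 0) stop("DN steady state must be nonnegative")
  if (x_inf[["M"]] >= M0) stop("steady-state M must be below the capacity M0")
  ratio <- x_inf[["N"]] / x_inf[["C"]]
  if (abs(ratio - 0.5) > 5e-4)
    stop("necrotic closure violated: N/C = ", signif(ratio, 6), " (expected 0.5)")
  invisible(x_inf)
}

#' Printed dimensionless initial conditions
#'
#' Each cluster's smallest tumor, expressed relative to that cluster's
#' steady state (so a value of 1 means "already at the steady-state level").
#' Multiply componentwise by [cluster_steady_states()] to obtain dimensional
#' initial conditions.
#'
#' @param cluster optional integer in 1..5
#' @return data.frame, or a named dimensionless state vector
#' @export
initial_condition_ratios <- function(cluster = NULL) {
  path <- system.file("extdata", "initial_conditions.csv", package = "tmekin")
  tab <- utils::read.csv(path)
  if (is.null(cluster)) return(tab)
  stopifnot(length(cluster) == 1L, cluster %in% tab$cluster)
  state_vector(values = unlist(tab[tab$cluster == cluster, state_names()]))
}

#' Dimensional initial conditions for one cluster
#'
#' Convenience wrapper: the printed dimensionless initial conditions scaled
#' back by the printed steady state.
#'
#' @param cluster integer in 1..5
#' @return named state vector (dimensional units)
#' @export
initial_state <- function(cluster) {
  x_inf <- cluster_steady_states(cluster)
  ratio <- initial_condition_ratios(cluster)
  out <- as.numeric(ratio) * as.numeric(x_inf)
  names(out) <- state_names()
  out
}
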