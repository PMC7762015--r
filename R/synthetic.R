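#' Synthetic cohort generation
#'
#' Emulates the statistical structure of a deconvolved tumor cohort: each
#' patient carries nonnegative immune-cell fractions on the 22-type
#' simplex drawn around one of K planted cluster profiles, tumor
#' dimensions whose product follows a truncated log-normal, and bulk
#' cytokine expression levels around planted cluster means. The planted
#' truth (labels, profiles, density targets) travels with the table so
#' recovery can be scored.
#'
#' @name synthetic-cohort
NULL

#' Default planted cluster profiles
#'
#' Five immune-fraction profiles over the 22-type panel whose pooled,
#' scaled densities reproduce the shipped per-cluster steady-state table
#' up to one common feasibility factor: profile mass on the mapped types
#' is proportional to the printed immune densities (using a shared
#' denominator across clusters so between-cluster contrasts are
#' preserved), and the remaining mass is spread over the unmapped types.
#'
#' @param mapping cell-type mapping
#' @return list: `profiles` (5 x 22 matrix, rows on the simplex),
#'   `immune_targets` (5 x 8 matrix of planted densities for
#'   TN, Th, TC, Tr, DN, D, M and the naive-macrophage top-up, in
#'   cells/cm^3 at the default `alpha_dim`)
#' @export
default_profiles <- function(mapping = load_cell_mapping()) {
  tab <- cluster_steady_states()
  imm_cols <- c("TN", "Th", "TC", "Tr", "DN", "D", "M")
  dens <- as.matrix(tab[, imm_cols])
  dens <- cbind(dens, MN = tab$M0 - tab$M)  # naive macrophages
  totals <- rowSums(dens)
  denom <- 1.05 * max(totals)  # keep every cluster on the simplex
  mass <- dens / denom
  types <- lm22_cell_types()
  profiles <- matrix(0, 5, length(types), dimnames = list(NULL, types))
  split_into <- function(group_types, m, weights = NULL) {
    if (is.null(weights)) weights <- rep(1 / length(group_types), length(group_types))
    outer(m, weights)
  }
  assign <- list(TN = c(0.7, 0.3), Th = c(0.6, 0.4), TC = c(0.7, 0.3),
                 Tr = 1, DN = 1, D = 1, M = c(0.5, 0.5), MN = 1)
  groups <- c(mapping$variables, list(MN = mapping$naive_macrophages))
  for (g in names(groups)) {
    w <- assign[[g]]
    profiles[, groups[[g]]] <- split_into(groups[[g]], mass[, g], w)
  }
  leftover <- 1 - rowSums(profiles)
  unmapped <- setdiff(types, unlist(groups))
  profiles[, unmapped] <- leftover / length(unmapped)
  imm_scale <- 0.4 * 1.125e5
  list(profiles = profiles, immune_targets = mass * imm_scale)
}

#' Generator configuration
#'
#' @param n_patients cohort size (default 300, the scale of a typical
#'   public tumor expression cohort)
#' @param K number of planted clusters
#' @param profiles K x 22 matrix of cluster mean fractions (rows on the
#'   simplex); default [default_profiles()]
#' @param concentration Dirichlet concentration for within-cluster noise
#'   (larger = tighter; default 200)
#' @param size_median median tumor size in cm^2 (log-normal; default 0.6)
#' @param size_sigma log-normal sigma (default 0.5)
#' @param min_size_frac lower truncation of the size distribution as a
#'   fraction of the median, so even the smallest tumor has measurable
#'   dimensions and a nonnegative mapped cancer density (default 0.5)
#' @param aspect range of the tumor longest/shortest aspect ratio
#' @param cytokine_means K x 5 matrix of planted cluster means for
#'   `H, mu1, mu2, Igamma, Gbeta`; defaults to the shipped steady-state
#'   table
#' @param cytokine_cv log-normal coefficient of variation for cytokines
#' @param seed seed fixing all randomness
#' @return list of class `tme_generator_config`
#' @export
generator_config <- function(n_patients = 300, K = 5, profiles = NULL,
                             concentration = 200, size_median = 0.6,
                             size_sigma = 0.5, min_size_frac = 0.5,
                             aspect = c(1, 2.5), cytokine_means = NULL,
                             cytokine_cv = 0.15, seed = 7) {
  if (n_patients < K) stop("n_patients must be >= K")
  prof_info <- NULL
  if (is.null(profiles)) {
    prof_info <- default_profiles()
    profiles <- prof_info$profiles
    if (K != nrow(profiles)) profiles <- profiles[rep_len(seq_len(5), K), , drop = FALSE]
  }
  profiles <- as.matrix(profiles)
  if (nrow(profiles) != K) stop("profiles must have K rows")
  if (any(profiles < 0)) stop("profiles must be nonnegative")
  if (any(abs(rowSums(profiles) - 1) > 1e-8))
    stop("profile rows must lie on the simplex (sum to 1)")
  if (any(rowSums(profiles > 0) < 2)) stop("degenerate profile row")
  if (is.null(cytokine_means)) {
    tab <- cluster_steady_states()
    cytokine_means <- as.matrix(tab[, c("H", "mu1", "mu2", "Igamma", "Gbeta")])
    if (K != nrow(cytokine_means))
      cytokine_means <- cytokine_means[rep_len(seq_len(5), K), , drop = FALSE]
  }
  structure(list(n_patients = n_patients, K = K, profiles = profiles,
                 concentration = concentration, size_median = size_median,
                 size_sigma = size_sigma, min_size_frac = min_size_frac,
                 aspect = aspect, cytokine_means = as.matrix(cytokine_means),
                 cytokine_cv = cytokine_cv, seed = seed,
                 immune_targets = prof_info$immune_targets),
            class = "tme_generator_config")
}

rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), n,
              length(alpha), byrow = TRUE)
  zero <- alpha == 0
  g[, zero] <- 0
  g / rowSums(g)
}

#' Generate a synthetic cohort with planted cluster structure
#'
#' @param config a [generator_config()]
#' @return data.frame (one row per patient: `patient_id`, 22 fraction
#'   columns, `longest_cm`, `shortest_cm`, cytokines, clinical labels)
#'   with attribute `truth`: list of `labels`, `profiles`,
#'   `cytokine_means`, `immune_targets`
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "tme_generator_config"))
  set.seed(config$seed)
  n <- config$n_patients; K <- config$K
  labels <- rep_len(seq_len(K), n)[sample.int(n)]
  types <- colnames(config$profiles)
  fr <- matrix(0, n, length(types), dimnames = list(NULL, types))
  for (k in seq_len(K)) {
    idx <- which(labels == k)
    if (!length(idx)) next
    alpha <- config$concentration * config$profiles[k, ]
    fr[idx, ] <- if (config$concentration <= 0)
      matrix(config$profiles[k, ], length(idx), length(types), byrow = TRUE)
      else rdirichlet(length(idx), alpha)
  }
  lo <- config$min_size_frac * config$size_median
  size <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      s <- stats::rlnorm(1, log(config$size_median), config$size_sigma)
      if (s >= lo) { size[i] <- s; break }
    }
  }
  aspect <- stats::runif(n, config$aspect[1], config$aspect[2])
  longest <- sqrt(size * aspect)
  shortest <- sqrt(size / aspect)
  cv <- config$cytokine_cv
  sdlog <- sqrt(log(1 + cv^2))
  cyt <- config$cytokine_means[labels, , drop = FALSE] *
    matrix(stats::rlnorm(n * 5, -sdlog^2 / 2, sdlog), n, 5)
  colnames(cyt) <- c("H", "mu1", "mu2", "Igamma", "Gbeta")
  clinical <- data.frame(
    vital_status = sample(c("Alive", "Dead"), n, TRUE, c(0.75, 0.25)),
    tumor_status = sample(c("Tumor free", "With tumor"), n, TRUE, c(0.6, 0.4)),
    stage = sample(paste0("Stage ", c("I", "II", "III", "IV")), n, TRUE,
                   c(0.2, 0.4, 0.25, 0.15)),
    gender = sample(c("Female", "Male"), n, TRUE))
  cohort <- cbind(data.frame(patient_id = sprintf("SYN-%04d", seq_len(n))),
                  as.data.frame(fr),
                  data.frame(longest_cm = longest, shortest_cm = shortest),
                  as.data.frame(cyt), clinical)
  attr(cohort, "truth") <- list(labels = labels, profiles = config$profiles,
                                cytokine_means = config$cytokine_means,
                                immune_targets = config$immune_targets)
  cohort
}

#' Printed-table fixtures
#'
#' The five transcribed per-cluster steady states and dimensionless
#' initial conditions in one object, each validated against the
#' steady-state invariants (positivity, M below capacity, necrotic
#' closure N = C/2).
#'
#' @return list: `steady_states` (list of 5 named vectors with `M0`
#'   attributes), `initial_ratios` (list of 5 named vectors)
#' @export
generate_from_tables <- function() {
  list(steady_states = lapply(1:5, cluster_steady_states),
       initial_ratios = lapply(1:5, initial_condition_ratios))
}

#' Run the whole cohort pipeline on a table
#'
#' Clusters the cohort, maps every patient to model variables, extracts
#' per-cluster steady states and initial conditions, derives per-cluster
#' parameters, and reports linear stability. This is the synthetic-data
#' counterpart of the study pipeline, usable on any table in the same
#' shape.
#'
#' @param cohort cohort data.frame (see [generate_cohort()])
#' @param K number of clusters
#' @param seed RNG seed for clustering
#' @param mapping,alpha_dim passed to [map_cohort()]
#' @param assumptions assumption set for [derive_parameters()]
#' @return list per cluster: `steady_state`, `init_ratio`, `params`,
#'   `stability`; plus `labels` and the mapped table
#' @export
run_cohort_pipeline <- function(cohort, K = 5, seed = 1,
                                mapping = load_cell_mapping(),
                                alpha_dim = 1.125e5,
                                assumptions = load_assumptions()) {
  types <- intersect(lm22_cell_types(), colnames(cohort))
  cl <- cluster_patients(cohort[, types], K, seed = seed)
  mapped <- map_cohort(cohort, mapping = mapping, alpha_dim = alpha_dim)
  med <- apply(mapped[, state_names()], 2, stats::median)
  clusters <- lapply(seq_len(K), function(k) {
    sub <- mapped[cl$labels == k, , drop = FALSE]
    x_inf <- extract_steady_state(sub)
    x_pos <- floor_references(x_inf, med)
    attr(x_pos, "M0") <- attr(x_inf, "M0")
    names(x_pos) <- state_names()
    init <- extract_initial_conditions(sub, x_pos)
    params <- derive_parameters(x_pos, assumptions)
    list(steady_state = x_pos, init_ratio = init, params = params,
         stability = stability_report(params, x_pos))
  })
  list(clusters = clusters, labels = cl$labels, mapped = mapped)
}
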