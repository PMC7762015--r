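#' Cohort pipeline: from deconvolution tables to model variables
#'
#' Bulk-tumor deconvolution estimates the fraction of each immune cell
#' type in a tumor from its gene expression profile. This module turns a
#' CIBERSORTx-style fraction table plus tumor dimensions into the model's
#' densities, groups patients into immune-pattern clusters with K-means,
#' and extracts per-cluster steady states (above-average-size tumors) and
#' initial conditions (the smallest tumor).
#'
#' @name cohort-pipeline
NULL

#' The 22-type deconvolution panel
#' @return character vector of column names used in cohort tables
#' @export
lm22_cell_types <- function() {
  c("B.cells.naive", "B.cells.memory", "Plasma.cells",
    "T.cells.CD8", "T.cells.CD4.naive",
    "T.cells.CD4.memory.resting", "T.cells.CD4.memory.activated",
    "T.cells.follicular.helper", "T.cells.regulatory.Tregs",
    "T.cells.gamma.delta", "NK.cells.resting", "NK.cells.activated",
    "Monocytes", "Macrophages.M0", "Macrophages.M1", "Macrophages.M2",
    "Dendritic.cells.resting", "Dendritic.cells.activated",
    "Mast.cells.resting", "Mast.cells.activated",
    "Eosinophils", "Neutrophils")
}

#' Load the deconvolution-type to model-variable mapping
#'
#' @param path YAML mapping file; defaults to the config shipped with the
#'   package
#' @return list with `variables` (named list of cell-type vectors) and
#'   `naive_macrophages`
#' @export
load_cell_mapping <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "celltype_mapping.yaml", package = "tmekin")
  cfg <- yaml::read_yaml(path)
  need <- c("TN", "Th", "TC", "Tr", "DN", "D", "M")
  missing <- setdiff(need, names(cfg$variables))
  if (length(missing))
    stop("cell mapping misses model variable(s): ", paste(missing, collapse = ", "))
  all_types <- c(unlist(cfg$variables), cfg$naive_macrophages)
  dup <- all_types[duplicated(all_types)]
  if (length(dup))
    stop("cell type(s) mapped twice: ", paste(unique(dup), collapse = ", "))
  cfg[c("variables", "naive_macrophages")]
}

#' Tumor size from its two measured dimensions
#'
#' The working definition of tumor size is the product of the longest and
#' the shortest dimension, in cm^2.
#'
#' @param longest,shortest tumor dimensions in cm, both > 0 (vectorized)
#' @return size in cm^2
#' @examples
#' compute_size(2.0, 1.5)  # 3.0
#' @export
compute_size <- function(longest, shortest) {
  if (any(!is.finite(longest)) || any(!is.finite(shortest)) ||
      any(longest <= 0) || any(shortest <= 0))
    stop("tumor dimensions must be positive")
  longest * shortest
}

#' Map one patient's fractions and size to model variables
#'
#' Total cell density is proportional to tumor size
#' (`alpha_dim * size / cohort_mean_size`); each immune variable is its
#' pooled deconvolution fraction scaled so the patient's immune
#' compartment totals `0.4 * alpha_dim`; cancer cells fill two thirds of
#' the non-immune remainder and necrotic cells half the cancer density,
#' which closes the identity C + N + Immune = Total exactly. Cytokine
#' levels, when present in the record, pass through unscaled (they are
#' expression units, not densities).
#'
#' @param fractions named vector of deconvolution fractions (>= 0)
#' @param size tumor size in cm^2
#' @param cohort_mean_size mean size over the whole cohort
#' @param cytokines optional named vector with `H`, `mu1`, `mu2`,
#'   `Igamma`, `Gbeta`
#' @param mapping cell-type mapping (see [load_cell_mapping()])
#' @param alpha_dim density scaling (cells/cm^3 at the mean tumor size)
#' @param immune_fraction fraction of total density occupied by immune
#'   cells after scaling (0.4 as printed; see the methods vignette for the
#'   discussion of this convention)
#' @return named vector: the 14 model variables plus `M0`, `Total`,
#'   `Immune`, `size`
#' @export
map_to_model_variables <- function(fractions, size, cohort_mean_size,
                                   cytokines = NULL,
                                   mapping = load_cell_mapping(),
                                   alpha_dim = 1.125e5,
                                   immune_fraction = 0.4) {
  if (cohort_mean_size <= 0) stop("cohort mean size must be > 0")
  fr <- unlist(fractions)
  if (any(fr < 0)) stop("deconvolution fractions must be >= 0")
  tot_ratio <- sum(fr)
  if (tot_ratio <= 0) stop("sum of immune cell ratios is zero")
  total <- alpha_dim * size / cohort_mean_size
  s <- immune_fraction * alpha_dim / tot_ratio
  pool <- function(types) sum(fr[intersect(types, names(fr))]) * s
  v <- c(TN = pool(mapping$variables$TN), Th = pool(mapping$variables$Th),
         TC = pool(mapping$variables$TC), Tr = pool(mapping$variables$Tr),
         DN = pool(mapping$variables$DN), D = pool(mapping$variables$D),
         M = pool(mapping$variables$M))
  immune_total <- tot_ratio * s  # = immune_fraction * alpha_dim
  C <- (2 / 3) * (total - immune_total)
  if (C < 0)
    stop("negative cancer density: tumor size ", signif(size, 4),
         " cm^2 is below ", immune_fraction, " of the cohort mean")
  M0 <- v[["M"]] + pool(mapping$naive_macrophages)
  cyt <- c(H = NA_real_, mu1 = NA_real_, mu2 = NA_real_,
           Igamma = NA_real_, Gbeta = NA_real_)
  if (!is.null(cytokines)) {
    cy <- unlist(cytokines)
    cyt[intersect(names(cyt), names(cy))] <- cy[intersect(names(cyt), names(cy))]
  }
  c(v, C = C, N = 0.5 * C, cyt,
    M0 = M0, Total = total, Immune = immune_total, size = size)
}

#' Map a whole cohort table to model variables
#'
#' @param cohort data.frame with the 22 deconvolution columns (see
#'   [lm22_cell_types()]), `longest_cm`, `shortest_cm`, optionally the five
#'   cytokine columns and clinical labels
#' @param mapping,alpha_dim,immune_fraction see [map_to_model_variables()]
#' @return data.frame: one row per patient with `patient_id`, `size`, the
#'   14 model variables, `M0`, `Total`, `Immune`
#' @export
map_cohort <- function(cohort, mapping = load_cell_mapping(),
                       alpha_dim = 1.125e5, immune_fraction = 0.4) {
  types <- intersect(lm22_cell_types(), colnames(cohort))
  if (length(types) < 2L)
    stop("cohort table has no recognizable deconvolution columns")
  size <- compute_size(cohort$longest_cm, cohort$shortest_cm)
  mean_size <- mean(size)
  cyt_cols <- intersect(c("H", "mu1", "mu2", "Igamma", "Gbeta"), colnames(cohort))
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    cyt <- if (length(cyt_cols)) unlist(cohort[i, cyt_cols]) else NULL
    map_to_model_variables(unlist(cohort[i, types]), size[i], mean_size,
                           cytokines = cyt, mapping = mapping,
                           alpha_dim = alpha_dim,
                           immune_fraction = immune_fraction)
  })
  out <- as.data.frame(do.call(rbind, rows))
  id <- if ("patient_id" %in% colnames(cohort)) cohort$patient_id
        else seq_len(nrow(cohort))
  cbind(data.frame(patient_id = id), out)
}

#' Suggest the number of immune-pattern clusters by the elbow method
#'
#' Runs K-means over a range of K and locates the elbow of the
#' within-cluster sum-of-squares curve. Splitting below the true cluster
#' count removes real structure and drops the inertia sharply; splitting
#' beyond it only shaves noise, so the drops collapse onto a plateau. The
#' elbow is therefore taken as the largest K whose inertia drop both
#' dominates the plateau (more than `tail_factor` times the tail-median
#' drop) and is sharp (more than `sharp_factor` times the next drop). A
#' curve with no such K -- e.g. a single diffuse cloud, whose drops decay
#' smoothly -- yields `confident = FALSE` and falls back to the point of
#' maximum curvature.
#'
#' @param fractions matrix/data.frame of deconvolution fractions (patients
#'   x cell types)
#' @param k_range candidate K values (default 1:10); should extend well
#'   past the suspected cluster count so the plateau is visible
#' @param seed RNG seed
#' @param n_init number of K-means restarts per K
#' @param tail_factor,sharp_factor knee-detection thresholds (see above)
#' @return list: `K`, `k_range`, `inertia`, `drops`, `confident`
#' @export
elbow_k <- function(fractions, k_range = 1:10, seed = 1, n_init = 10,
                    tail_factor = 5, sharp_factor = 3) {
  X <- as.matrix(fractions)
  if (nrow(X) < max(k_range)) stop("need at least max(k_range) records")
  if (nrow(unique(X)) < 2L) stop("degenerate input: all rows identical")
  k_range <- sort(unique(k_range))
  set.seed(seed)
  inertia <- vapply(k_range, function(k) {
    if (k == 1) sum(scale(X, scale = FALSE)^2)
    else stats::kmeans(X, centers = k, nstart = n_init, iter.max = 50)$tot.withinss
  }, numeric(1))
  nk <- length(k_range)
  if (nk == 1L)
    return(list(K = k_range, k_range = k_range, inertia = inertia,
                drops = NA_real_, confident = FALSE))
  drops <- c(NA_real_, -diff(inertia))  # drops[i] = I(k_{i-1}) - I(k_i)
  # plateau level: median drop over the upper third of the range
  tail_idx <- seq(max(3L, ceiling(2 * nk / 3)), nk)
  tail_level <- stats::median(drops[tail_idx], na.rm = TRUE)
  candidate <- rep(FALSE, nk)
  for (i in 2:(nk - 1)) {
    candidate[i] <- is.finite(drops[i]) &&
      drops[i] > tail_factor * max(tail_level, 0) &&
      drops[i] > sharp_factor * max(drops[i + 1], 0)
  }
  if (any(candidate)) {
    K <- k_range[max(which(candidate))]
    confident <- TRUE
  } else {
    curv <- rep(NA_real_, nk)
    for (i in seq(2, nk - 1))
      curv[i] <- inertia[i - 1] - 2 * inertia[i] + inertia[i + 1]
    K <- if (all(is.na(curv))) k_range[which.min(inertia)]
         else k_range[which.max(curv)]
    confident <- FALSE
  }
  list(K = K, k_range = k_range, inertia = inertia, drops = drops,
       confident = confident)
}

#' Cluster patients by immune pattern
#'
#' K-means on the deconvolution fractions of all panel cell types (not the
#' pooled model variables). Deterministic given the seed; empty clusters
#' trigger a re-initialization up to a retry cap.
#'
#' @param fractions matrix/data.frame (patients x cell types)
#' @param K number of clusters
#' @param seed RNG seed
#' @param n_init K-means restarts
#' @param retries re-initialization cap for empty clusters
#' @return list of class `tme_clusters`: `labels` (1..K per patient),
#'   `centers` (K x types mean profiles), `K`, `size` (cluster sizes)
#' @export
cluster_patients <- function(fractions, K, seed = 1, n_init = 10, retries = 5) {
  X <- as.matrix(fractions)
  if (K > nrow(X)) stop("K exceeds the number of records")
  for (attempt in 0:retries) {
    set.seed(seed + attempt)
    km <- tryCatch(stats::kmeans(X, centers = K, nstart = n_init, iter.max = 50),
                   error = function(e) e)
    if (!inherits(km, "error") && all(tabulate(km$cluster, K) > 0)) {
      return(structure(list(labels = km$cluster, centers = km$centers,
                            K = K, size = tabulate(km$cluster, K)),
                       class = "tme_clusters"))
    }
  }
  stop("K-means produced an empty cluster in every re-initialization")
}

#' Adjusted Rand index between two label vectors
#'
#' Chance-corrected agreement between two partitions, used to score
#' recovery of planted cluster structure (1 = identical up to label
#' permutation, ~0 = chance).
#'
#' @param a,b integer/factor label vectors of equal length
#' @return numeric scalar
#' @export
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

#' Extract a cluster steady state from mapped patient records
#'
#' The mean of the model variables over the patients whose tumor size lies
#' above the cluster average: large tumors are taken to sit near their
#' steady state.
#'
#' @param mapped data.frame from [map_cohort()], already restricted to one
#'   cluster
#' @return named steady-state vector with attribute `M0`
#' @export
extract_steady_state <- function(mapped) {
  if (!nrow(mapped)) stop("no records in cluster")
  above <- mapped$size > mean(mapped$size)
  if (!any(above)) above <- mapped$size >= mean(mapped$size)
  sub <- mapped[above, , drop = FALSE]
  if (anyNA(sub[, state_names()]))
    stop("cytokine columns are required to extract a steady state")
  x <- colMeans(sub[, state_names()])
  x <- state_vector(values = x)
  M0 <- mean(sub$M0)
  attr(x, "M0") <- M0
  validate_steady_state(x, M0)
  x
}

#' Extract dimensionless initial conditions from a cluster's smallest tumor
#'
#' The smallest tumor (ties broken by patient id order) is taken as the
#' cluster's earliest observable disease stage; its variables divided by
#' the cluster steady state give the dimensionless initial conditions.
#'
#' @param mapped data.frame from [map_cohort()], one cluster
#' @param x_inf cluster steady state (positive; floor near-zero components
#'   with [floor_references()] first)
#' @return named dimensionless state vector
#' @export
extract_initial_conditions <- function(mapped, x_inf) {
  if (!nrow(mapped)) stop("no records in cluster")
  x_inf <- as.numeric(x_inf)
  if (any(x_inf <= 0)) stop("x_inf must be positive (apply floor_references first)")
  ord <- order(mapped$size, mapped$patient_id)
  smallest <- mapped[ord[1], , drop = FALSE]
  if (anyNA(smallest[, state_names()]))
    stop("cytokine columns are required to extract initial conditions")
  out <- as.numeric(smallest[, state_names()]) / x_inf
  names(out) <- state_names()
  out
}
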