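#' ALE smoothing kernel specification
#'
#' ALE models each reported peak as a 3-D Gaussian whose width reflects
#' between-template and between-subject spatial uncertainty. The per-
#' experiment FWHM shrinks with the number of subjects:
#' `sqrt(fwhm_template^2 + fwhm_subject^2 / n)`. Defaults are the empirical
#' constants of the revised ALE algorithm (5.7 mm template, 11.6 mm
#' between-subject); both are configurable.
#'
#' @param fwhm_template template-uncertainty FWHM, mm.
#' @param fwhm_subject between-subject FWHM, mm.
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(fwhm_template = 5.7, fwhm_subject = 11.6) {
  stopifnot(fwhm_template > 0, fwhm_subject > 0)
  structure(list(fwhm_template = fwhm_template, fwhm_subject = fwhm_subject),
            class = "kernel_spec")
}

#' @param kernel a `kernel_spec`.
#' @param n_subjects subject count of the experiment.
#' @describeIn kernel_spec combined FWHM (mm) for an experiment with
#'   `n_subjects` subjects; strictly decreasing in n, bounded below by the
#'   template FWHM.
#' @export
fwhm_for <- function(kernel, n_subjects) {
  sqrt(kernel$fwhm_template^2 + kernel$fwhm_subject^2 / n_subjects)
}

FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))

# Gaussian peak expressed as per-voxel probability: density at distance 0
# ((2*pi*sigma^2)^(-3/2)) times the voxel volume, capped at 1.
ma_peak <- function(sigma, voxel_volume) {
  min(1, (2 * pi * sigma^2)^(-1.5) * voxel_volume)
}

#' Modeled-activation map of one experiment
#'
#' Each focus is replaced by a 3-D Gaussian (FWHM from
#' [fwhm_for()]) scaled so it integrates to ~1 over mm^3 and expressed as a
#' per-voxel activation probability; the foci of one experiment combine by
#' voxel-wise maximum (the revised algorithm's non-additive rule), so
#' coincident foci do not inflate the map. A `combine = "prob_union"`
#' alternative (1 - prod(1 - g_i)) is available.
#'
#' @param exp an [experiment()].
#' @param grid target grid geometry (or any grid-like object).
#' @param kernel a [kernel_spec()].
#' @param combine focus-combination rule within the experiment.
#' @return A [stat_map()] of modeled-activation probabilities in \[0, 1\].
#'   Foci outside the grid are dropped with a warning.
#' @export
modeled_activation_map <- function(exp, grid, kernel = kernel_spec(),
                                   combine = c("max", "prob_union")) {
  combine <- match.arg(combine)
  g <- grid_geometry(grid)
  foci <- matrix(exp$foci, ncol = 3)
  vox <- mm_to_voxel(g, foci)
  inside <- apply(vox > -0.5 & sweep(vox, 2, g$dim - 0.5, "<"), 1, all)
  if (!all(inside)) {
    warning(sum(!inside), " focus/foci of experiment '", exp$id,
            "' fall outside the grid and were dropped", call. = FALSE)
    foci <- foci[inside, , drop = FALSE]
  }
  sigma <- fwhm_for(kernel, exp$n_subjects) * FWHM_TO_SIGMA
  peak <- ma_peak(sigma, prod(voxel_dims(g$affine)))
  vals <- if (nrow(foci) == 0L) {
    array(0, dim = g$dim)
  } else if (combine == "max") {
    ma_map_cpp(g$dim, g$affine, foci, sigma, peak)
  } else {
    one_minus <- array(1, dim = g$dim)
    for (i in seq_len(nrow(foci)))
      one_minus <- one_minus *
        (1 - ma_map_cpp(g$dim, g$affine, foci[i, , drop = FALSE], sigma, peak))
    1 - one_minus
  }
  stat_map(vals, g$affine, g$space)
}

#' Probabilistic union of modeled-activation maps
#'
#' The ALE statistic: `1 - prod(1 - MA_i)` voxel-wise over experiments'
#' modeled-activation maps. Order-invariant, monotone (adding an experiment
#' never lowers any voxel), values stay in \[0, 1\].
#'
#' @param ma_maps list of [stat_map()]s on a common grid with values in
#'   \[0, 1\].
#' @return A [stat_map()] of ALE values.
#' @export
ale_union <- function(ma_maps) {
  stopifnot(length(ma_maps) >= 1L)
  g <- grid_geometry(ma_maps[[1]])
  one_minus <- array(1, dim = g$dim)
  for (m in ma_maps) {
    stop_if_grid_mismatch(ma_maps[[1]], m, "MA maps")
    one_minus <- one_minus * (1 - m$values)
  }
  stat_map(1 - one_minus, g$affine, g$space)
}

# ALE values (array) for a list of experiments whose foci may be overridden
# (used by the relocation null). foci_override: list parallel to experiments
# of n x 3 matrices, or NULL.
ale_values <- function(experiments, g, kernel, foci_override = NULL) {
  one_minus <- array(1, dim = g$dim)
  vol <- prod(voxel_dims(g$affine))
  for (i in seq_along(experiments)) {
    e <- experiments[[i]]
    foci <- if (is.null(foci_override)) e$foci else foci_override[[i]]
    sigma <- fwhm_for(kernel, e$n_subjects) * FWHM_TO_SIGMA
    ma <- ma_map_cpp(g$dim, g$affine, foci, sigma, ma_peak(sigma, vol))
    one_minus <- one_minus * (1 - ma)
  }
  1 - one_minus
}

# Observed in-mask ALE + permutation matrix (in-mask voxels x n_perm) from
# uniform relocation of every focus to in-mask voxel centers (counts and
# subject numbers preserved). Deterministic given seed.
ale_permutation_matrix <- function(foci_table, g, mask_values, kernel,
                                   n_perm, seed) {
  exps <- foci_table$experiments
  centers <- inmask_centers(g, mask_values)
  observed_arr <- ale_values(exps, g, kernel)
  observed <- observed_arr[centers$idx]
  nf <- vapply(exps, function(e) nrow(e$foci), 1L)
  M <- length(centers$idx)
  perm <- matrix(0, nrow = M, ncol = n_perm)
  with_seed(seed, {
    for (p in seq_len(n_perm)) {
      relocated <- lapply(nf, function(k)
        centers$mm[sample.int(M, k, replace = TRUE), , drop = FALSE])
      perm[, p] <- ale_values(exps, g, kernel, relocated)[centers$idx]
    }
  })
  list(observed = observed, observed_arr = observed_arr, perm = perm,
       idx = centers$idx, g = g)
}

perm_p_values <- function(observed, perm) {
  (1 + rowSums(perm >= observed)) / (ncol(perm) + 1)
}

#' Voxel-wise ALE permutation null
#'
#' Builds the null by relocating every experiment's foci uniformly at
#' random to in-mask voxel centers (focus counts and subject numbers
#' preserved), recomputing the ALE map each time. Voxel p-values use the
#' add-one estimator `(1 + k) / (n_perm + 1)` so p is never zero.
#'
#' @param foci_table a [foci_table()].
#' @param grid analysis grid.
#' @param mask [brain_mask()] restricting relocation and inference
#'   (default: whole grid).
#' @param kernel a [kernel_spec()].
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed; same seed, same p-map.
#' @return A [stat_map()] of uncorrected voxel p-values (1 outside the
#'   mask).
#' @export
ale_voxel_null <- function(foci_table, grid, mask = NULL,
                           kernel = kernel_spec(), n_perm = 1000,
                           seed = NULL) {
  stopifnot(n_perm >= 100)
  g <- grid_geometry(grid)
  mv <- mask_values_for(mask, g)
  pm <- ale_permutation_matrix(foci_table, g, mv, kernel, n_perm, seed)
  p <- array(1, dim = g$dim)
  p[pm$idx] <- perm_p_values(pm$observed, pm$perm)
  stat_map(p, g$affine, g$space)
}

mask_values_for <- function(mask, g) {
  if (is.null(mask)) return(NULL)
  stop_if_grid_mismatch(mask, g, "mask and grid")
  if (!any(mask$values)) stop("mask is empty", call. = FALSE)
  mask$values
}

# Per-voxel critical value for the cluster-forming threshold, pooled over
# the observed map and all permutations so that observed and permuted maps
# are treated exchangeably: a map value v is supra-threshold iff
# #{other maps >= v} <= kmax, kmax = max k with (1+k)/(n_perm+1) < alpha,
# which is equivalent to v > (kmax+2)-th largest of the pooled n_perm+1
# values. Returns Inf when alpha is unattainable at this n_perm.
forming_critical <- function(observed, perm, alpha) {
  n_perm <- ncol(perm)
  # largest integer k with (1+k)/(n_perm+1) < alpha
  kmax <- ceiling(alpha * (n_perm + 1) - 1 - 1e-12) - 1
  if (kmax < 0) return(rep(Inf, nrow(perm)))
  pooled <- cbind(observed, perm)
  apply(pooled, 1, function(v) sort(v, decreasing = TRUE)[kmax + 2])
}

label_array <- function(values, connectivity = 26) {
  label_components_cpp(values, dim(values), as.integer(connectivity))
}

cluster_table_from <- function(labels, value_arr, g) {
  ids <- sort(unique(labels[labels > 0L]))
  if (!length(ids))
    return(data.frame(label = integer(), peak_x = numeric(),
                      peak_y = numeric(), peak_z = numeric(),
                      peak_value = numeric(), size_mm3 = numeric()))
  vol <- prod(voxel_dims(g$affine))
  rows <- lapply(ids, function(id) {
    vox <- which(labels == id)
    peak <- vox[which.max(value_arr[vox])]
    mm <- voxel_to_mm(g, arrayInd(peak, dim(labels)) - 1L)
    data.frame(label = id, peak_x = mm[1], peak_y = mm[2], peak_z = mm[3],
               peak_value = max(value_arr[vox]), size_mm3 = length(vox) * vol)
  })
  do.call(rbind, rows)
}

#' ALE meta-analysis with cluster-level FWE correction
#'
#' Full cluster-level inference in one pass: computes the observed ALE map,
#' a foci-relocation permutation null, voxel p-values, supra-threshold
#' clusters at the cluster-forming threshold, and a max-cluster-size null
#' (the same permutations thresholded at the same per-voxel critical
#' value). Clusters survive when their permutation FWE p-value is at most
#' `fwe_p`.
#'
#' @inheritParams ale_voxel_null
#' @param cluster_forming_p uncorrected voxel threshold that defines
#'   clusters.
#' @param fwe_p family-wise error level for cluster size.
#' @param connectivity 6 or 26 neighbor connectivity.
#' @return An object of class `ale_result`: fields `ale_map`, `p_map`,
#'   `thresholded` (ALE values on surviving clusters, 0 elsewhere),
#'   `cluster_table` (sorted by size, with FWE p), `null_max_size_mm3`,
#'   `params`, `foci_table`.
#' @export
cluster_level_fwe <- function(foci_table, grid, mask = NULL,
                              kernel = kernel_spec(),
                              cluster_forming_p = 0.001, fwe_p = 0.05,
                              n_perm = 1000, seed = NULL,
                              connectivity = 26) {
  g <- grid_geometry(grid)
  mv <- mask_values_for(mask, g)
  pm <- ale_permutation_matrix(foci_table, g, mv, kernel, n_perm, seed)
  pvals <- perm_p_values(pm$observed, pm$perm)
  crit <- forming_critical(pm$observed, pm$perm, cluster_forming_p)
  vol <- prod(voxel_dims(g$affine))

  supra <- array(FALSE, dim = g$dim)
  supra[pm$idx] <- pm$observed > crit
  labels <- label_array(supra, connectivity)
  tab <- cluster_table_from(labels, pm$observed_arr, g)

  # null of the maximum cluster size, same forming rule per permutation
  null_max <- vapply(seq_len(n_perm), function(j) {
    s <- array(FALSE, dim = g$dim)
    s[pm$idx] <- pm$perm[, j] > crit
    lab <- label_array(s, connectivity)
    if (any(lab > 0L)) max(tabulate(lab[lab > 0L])) * vol else 0
  }, numeric(1))

  if (nrow(tab)) {
    tab$p_fwe <- vapply(tab$size_mm3, function(s)
      (1 + sum(null_max >= s)) / (n_perm + 1), numeric(1))
    tab <- tab[order(-tab$size_mm3, tab$label), , drop = FALSE]
    keep <- tab$p_fwe <= fwe_p
    surviving <- tab$label[keep]
    tab <- tab[keep, , drop = FALSE]
  } else {
    tab$p_fwe <- numeric()
    surviving <- integer()
  }
  thr <- array(0, dim = g$dim)
  if (length(surviving)) {
    sel <- labels %in% surviving
    thr[sel] <- pm$observed_arr[sel]
  }
  if (nrow(tab)) tab$label <- seq_len(nrow(tab))
  rownames(tab) <- NULL

  p_arr <- array(1, dim = g$dim)
  p_arr[pm$idx] <- pvals
  structure(list(
    ale_map = stat_map(pm$observed_arr, g$affine, g$space),
    p_map = stat_map(p_arr, g$affine, g$space),
    thresholded = stat_map(thr, g$affine, g$space),
    cluster_table = tab,
    cluster_labels = labels,
    null_max_size_mm3 = null_max,
    params = list(cluster_forming_p = cluster_forming_p, fwe_p = fwe_p,
                  n_perm = n_perm, seed = seed, connectivity = connectivity),
    foci_table = foci_table
  ), class = "ale_result")
}

#' @export
print.ale_result <- function(x, ...) {
  cat(sprintf(
    "<ale_result> %d experiments, %d surviving cluster(s) (forming p<%g, FWE p<=%g, %d perms)\n",
    n_experiments(x$foci_table), nrow(x$cluster_table),
    x$params$cluster_forming_p, x$params$fwe_p, x$params$n_perm))
  if (nrow(x$cluster_table)) print(x$cluster_table)
  invisible(x)
}

as_thresholded_map <- function(x) {
  if (inherits(x, "ale_result")) x$thresholded
  else if (inherits(x, "stat_map")) x
  else stop("expected an ale_result or stat_map", call. = FALSE)
}

#' Conjunction of two thresholded ALE maps
#'
#' Voxel-wise minimum of the two thresholded maps: nonzero only where both
#' analyses survive.
#'
#' @param a,b [cluster_level_fwe()] results or already-thresholded
#'   [stat_map()]s on a common grid.
#' @return A [stat_map()].
#' @export
conjunction <- function(a, b) {
  ma <- as_thresholded_map(a); mb <- as_thresholded_map(b)
  stop_if_grid_mismatch(ma, mb)
  stat_map(pmin(ma$values, mb$values), ma$affine, ma$space)
}

#' Contrast between two ALE analyses
#'
#' Tests where one task's ALE exceeds the other's by permuting task labels:
#' the pooled experiments are randomly reassigned to the two groups (sizes
#' preserved) `n_perm` times, giving a voxel null for the ALE difference.
#' The returned difference map keeps voxels significant in either direction
#' at `p_threshold` (uncorrected) and lying inside the union of the two
#' thresholded maps.
#'
#' @param a,b [cluster_level_fwe()] results for the two tasks.
#' @param pooled pooled [foci_table()]; defaults to the union of the two
#'   analyses' experiments.
#' @param n_perm label permutations.
#' @param seed integer seed.
#' @param p_threshold uncorrected significance threshold for the
#'   difference.
#' @param kernel kernel used for the permuted recomputations (defaults to a
#'   fresh [kernel_spec()]).
#' @return A [stat_map()] of thresholded ALE differences (a - b).
#' @export
contrast <- function(a, b, pooled = NULL, n_perm = 1000, seed = NULL,
                     p_threshold = 0.01, kernel = kernel_spec()) {
  stopifnot(inherits(a, "ale_result"), inherits(b, "ale_result"))
  stop_if_grid_mismatch(a$ale_map, b$ale_map)
  na <- n_experiments(a$foci_table); nb <- n_experiments(b$foci_table)
  if (na < 2 || nb < 2)
    stop("contrast needs at least 2 experiments per group", call. = FALSE)
  if (is.null(pooled))
    pooled <- foci_table(c(a$foci_table$experiments, b$foci_table$experiments),
                         name = "pooled")
  if (n_experiments(pooled) != na + nb)
    stop("pooled table must contain the union of both groups' experiments",
         call. = FALSE)
  g <- grid_geometry(a$ale_map)
  obs <- a$ale_map$values - b$ale_map$values
  exps <- pooled$experiments
  ge_obs <- array(0L, dim = g$dim); le_obs <- array(0L, dim = g$dim)
  with_seed(seed, {
    for (p in seq_len(n_perm)) {
      pick <- sample.int(na + nb, na)
      d <- ale_values(exps[pick], g, kernel) -
        ale_values(exps[-pick], g, kernel)
      ge_obs <- ge_obs + (d >= obs)
      le_obs <- le_obs + (d <= obs)
    }
  })
  p_pos <- (1 + ge_obs) / (n_perm + 1)
  p_neg <- (1 + le_obs) / (n_perm + 1)
  union_mask <- a$thresholded$values > 0 | b$thresholded$values > 0
  out <- array(0, dim = g$dim)
  sig <- union_mask & (p_pos < p_threshold | p_neg < p_threshold)
  out[sig] <- obs[sig]
  stat_map(out, g$affine, g$space)
}

#' Overlap of two thresholded maps
#'
#' Connected components of the voxel set where both maps are nonzero; the
#' component peak is the voxel maximizing `min(a, b)`.
#'
#' @param a,b thresholded [stat_map()]s (or `ale_result`s) on a common
#'   grid.
#' @param connectivity 6 or 26.
#' @return A cluster table data frame (`label`, `peak_x/y/z`, `peak_value`,
#'   `size_mm3`), empty when the maps are disjoint.
#' @export
thresholded_overlap <- function(a, b, connectivity = 26) {
  ma <- as_thresholded_map(a); mb <- as_thresholded_map(b)
  stop_if_grid_mismatch(ma, mb)
  g <- grid_geometry(ma)
  both <- ma$values != 0 & mb$values != 0
  labels <- label_array(both, connectivity)
  cluster_table_from(labels, pmin(ma$values, mb$values), g)
}
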