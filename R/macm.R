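#' Seed region of interest
#'
#' A seed for meta-analytic connectivity modeling: either an ALE cluster's
#' voxel set or a sphere around a coordinate, held as a [brain_mask()].
#'
#' @param mask a [brain_mask()] with at least one voxel.
#' @param name seed name (used in messages and outputs).
#' @param source provenance tag (`"ale_cluster"`, `"sphere"`, ...).
#' @return An object of class `seed_roi`.
#' @export
seed_roi <- function(mask, name = "seed", source = "mask") {
  stopifnot(inherits(mask, "brain_mask"))
  structure(list(mask = mask, name = name, source = source),
            class = "seed_roi")
}

#' @describeIn seed_roi spherical seed: all voxels whose center lies within
#'   `radius` mm of `center` on `grid`.
#' @param grid grid geometry for the sphere voxelization.
#' @param center mm coordinate.
#' @param radius mm.
#' @export
sphere_seed <- function(grid, center, radius, name = "sphere") {
  g <- grid_geometry(grid)
  cc <- inmask_centers(g, NULL)
  d2 <- (cc$mm[, 1] - center[1])^2 + (cc$mm[, 2] - center[2])^2 +
    (cc$mm[, 3] - center[3])^2
  vals <- array(FALSE, dim = g$dim)
  vals[cc$idx[d2 <= radius^2]] <- TRUE
  seed_roi(brain_mask(vals, g$affine), name = name, source = "sphere")
}

#' Select database experiments activating a seed
#'
#' An experiment is selected when at least one of its foci falls inside the
#' seed: the focus is mapped to its containing voxel (nearest voxel center)
#' and that voxel must be in the seed mask. Foci outside the grid never
#' match. Results are sorted by experiment id for stable downstream order.
#'
#' @param db a [coordinate_database()] (any [foci_table()] works).
#' @param seed a [seed_roi()].
#' @return Character vector of selected experiment ids.
#' @export
select_experiments <- function(db, seed) {
  stopifnot(inherits(db, "foci_table"), inherits(seed, "seed_roi"))
  if (!any(seed$mask$values)) stop("seed mask is empty", call. = FALSE)
  g <- grid_geometry(seed$mask)
  hit <- vapply(db$experiments, function(e) {
    vox <- round(mm_to_voxel(g, e$foci))
    ok <- vox >= 0 & sweep(vox, 2, g$dim - 1L, "<=")
    inside <- which(apply(ok, 1, all))
    length(inside) > 0 &&
      any(seed$mask$values[vox[inside, , drop = FALSE] + 1L])
  }, logical(1))
  sort(vapply(db$experiments[hit], `[[`, "", "id"))
}

#' Meta-analytic connectivity modeling (MACM)
#'
#' Pools the foci of all database experiments that activate the seed, runs
#' an ALE analysis over them, converts the voxel permutation p-map to
#' Benjamini-Hochberg q-values within the analysis mask, keeps voxels with
#' q below `q` and connected clusters strictly larger than `min_mm3`.
#'
#' @param db a [coordinate_database()].
#' @param seed a [seed_roi()].
#' @param kernel a [kernel_spec()].
#' @param mask analysis [brain_mask()] (default whole grid of the seed).
#' @param q voxel-wise FDR level.
#' @param min_mm3 minimum surviving cluster volume, mm^3 (strict).
#' @param n_perm relocation permutations for the voxel null.
#' @param seed_rng integer RNG seed.
#' @param connectivity 6 or 26.
#' @return An object of class `coactivation_result`: `ale_map`,
#'   `thresholded`, `surviving_clusters`, `n_experiments_selected`,
#'   `selected_ids`, `fdr_q`.
#' @export
coactivation_map <- function(db, seed, kernel = kernel_spec(), mask = NULL,
                             q = 0.05, min_mm3 = 200, n_perm = 1000,
                             seed_rng = NULL, connectivity = 26) {
  ids <- select_experiments(db, seed)
  if (length(ids) < 2)
    stop("insufficient experiments for seed '", seed$name, "': ",
         length(ids), " selected (need >= 2)", call. = FALSE)
  keep <- vapply(db$experiments, function(e) e$id %in% ids, logical(1))
  sel <- foci_table(db$experiments[keep], name = paste0("macm_", seed$name))
  g <- grid_geometry(seed$mask)
  mv <- mask_values_for(mask, g)
  pm <- ale_permutation_matrix(sel, g, mv, kernel, n_perm, seed_rng)
  pvals <- perm_p_values(pm$observed, pm$perm)
  rej <- fdr_threshold(pvals, q)
  thr <- array(0, dim = g$dim)
  thr[pm$idx[rej]] <- pm$observed[rej]
  thr_map <- stat_map(thr, g$affine, g$space)
  clusters <- filter_clusters(thr_map, min_mm3 = min_mm3,
                              connectivity = connectivity)
  # zero out voxels in dropped (small) clusters
  labels <- label_array(thr != 0, connectivity)
  sizes <- tabulate(labels[labels > 0L]) * prod(voxel_dims(g$affine))
  drop <- which(sizes <= min_mm3)
  if (length(drop)) thr_map$values[labels %in% drop] <- 0
  p_arr <- array(1, dim = g$dim)
  p_arr[pm$idx] <- pvals
  structure(list(ale_map = stat_map(pm$observed_arr, g$affine, g$space),
                 p_map = stat_map(p_arr, g$affine, g$space),
                 thresholded = thr_map,
                 surviving_clusters = clusters,
                 n_experiments_selected = length(ids),
                 selected_ids = ids, fdr_q = q, min_mm3 = min_mm3),
            class = "coactivation_result")
}

#' @export
print.coactivation_result <- function(x, ...) {
  cat(sprintf("<coactivation_result> %d experiments selected, %d cluster(s) at FDR q<%g, >%g mm3\n",
              x$n_experiments_selected, nrow(x$surviving_clusters),
              x$fdr_q, x$min_mm3))
  invisible(x)
}

#' Benjamini-Hochberg voxel-wise FDR rejection
#'
#' Step-up FDR control at level `q`: rejects all p-values whose BH-adjusted
#' value is at most `q`.
#'
#' @param p_values vector of p-values in (0, 1\].
#' @param q FDR level.
#' @return Logical rejection indicator, same length as `p_values`.
#' @export
fdr_threshold <- function(p_values, q = 0.05) {
  if (!length(p_values)) stop("empty p-value vector", call. = FALSE)
  p.adjust(p_values, method = "BH") <= q
}

#' Filter clusters by minimum volume
#'
#' Connected components of the nonzero voxels of a thresholded map; only
#' components strictly larger than `min_mm3` are kept.
#'
#' @param map thresholded [stat_map()].
#' @param min_mm3 strict minimum volume in mm^3.
#' @param connectivity 6 or 26.
#' @return Cluster table data frame as in [thresholded_overlap()].
#' @export
filter_clusters <- function(map, min_mm3 = 200, connectivity = 26) {
  stopifnot(inherits(map, "stat_map"))
  g <- grid_geometry(map)
  labels <- label_array(map$values != 0, connectivity)
  tab <- cluster_table_from(labels, map$values, g)
  tab <- tab[tab$size_mm3 > min_mm3, , drop = FALSE]
  if (nrow(tab)) tab <- tab[order(-tab$size_mm3), , drop = FALSE]
  if (nrow(tab)) tab$label <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}
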