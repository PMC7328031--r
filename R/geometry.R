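#' Statistic map on a voxel grid
#'
#' A `stat_map` holds a 3-D array of statistic values together with the
#' 4x4 affine mapping 0-based voxel indices to RAS mm coordinates, and a
#' coordinate-space tag. It is the container for ALE maps, term meta-maps
#' and permuted maps throughout the package.
#'
#' @param values numeric 3-D array.
#' @param affine numeric 4x4 voxel-to-mm transform (0-based voxel indices,
#'   RAS mm on output); must be invertible.
#' @param space coordinate space tag, `"MNI152"` or `"Talairach"`.
#' @return An object of class `stat_map` with fields `values`, `affine`,
#'   `space`.
#' @seealso [mni_grid()], [toy_grid()], [read_stat_map()]
#' @export
stat_map <- function(values, affine, space = c("MNI152", "Talairach")) {
  space <- match.arg(space)
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("stat_map values must be a 3-D array, got ", length(dim(values)),
         " dimensions", call. = FALSE)
  affine <- check_affine(affine)
  structure(list(values = values, affine = affine, space = space),
            class = "stat_map")
}

check_affine <- function(affine) {
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("affine must be 4x4", call. = FALSE)
  storage.mode(affine) <- "double"
  det3 <- det(affine[1:3, 1:3])
  if (!is.finite(det3) || abs(det3) < 1e-12)
    stop("affine is singular", call. = FALSE)
  vs <- voxel_dims(affine)
  if (any(vs <= 0)) stop("voxel size must be positive on every axis",
                         call. = FALSE)
  affine
}

voxel_dims <- function(affine) sqrt(colSums(affine[1:3, 1:3]^2))

#' @export
print.stat_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<stat_map> %dx%dx%d voxels, %s space, voxel %s mm\n",
              d[1], d[2], d[3], x$space,
              paste(signif(voxel_dims(x$affine), 3), collapse = "x")))
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("  values in [%.4g, %.4g]\n", rng[1], rng[2]))
  invisible(x)
}

#' Binary mask on a voxel grid
#'
#' @param values logical 3-D array with at least one `TRUE` voxel.
#' @param affine 4x4 voxel-to-mm transform.
#' @return An object of class `brain_mask`.
#' @export
brain_mask <- function(values, affine) {
  values <- as.array(values)
  storage.mode(values) <- "logical"
  if (length(dim(values)) != 3L) stop("mask must be 3-D", call. = FALSE)
  if (!any(values)) stop("mask has no TRUE voxel", call. = FALSE)
  structure(list(values = values, affine = check_affine(affine)),
            class = "brain_mask")
}

#' Integer parcellation volume
#'
#' Voxel labels partition the in-mask volume into parcels; 0 is background.
#'
#' @param labels integer 3-D array, nonnegative; every nonzero label must
#'   occur at least once.
#' @param affine 4x4 voxel-to-mm transform.
#' @return An object of class `parcellation` with `labels`, `affine`,
#'   `n_parcels`.
#' @export
parcellation <- function(labels, affine) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L) stop("parcellation must be 3-D", call. = FALSE)
  if (any(labels < 0) || any(labels != round(labels)))
    stop("parcel labels must be nonnegative integers", call. = FALSE)
  storage.mode(labels) <- "integer"
  ids <- sort(unique(labels[labels > 0L]))
  structure(list(labels = labels, affine = check_affine(affine),
                 n_parcels = length(ids), parcel_ids = ids),
            class = "parcellation")
}

# Extract (dim, affine, space) from anything grid-like.
grid_geometry <- function(x) {
  if (inherits(x, "stat_map"))
    return(list(dim = dim(x$values), affine = x$affine, space = x$space))
  if (inherits(x, "brain_mask"))
    return(list(dim = dim(x$values), affine = x$affine, space = "MNI152"))
  if (inherits(x, "parcellation"))
    return(list(dim = dim(x$labels), affine = x$affine, space = "MNI152"))
  if (is.list(x) && !is.null(x$dim) && !is.null(x$affine))
    return(list(dim = as.integer(x$dim), affine = check_affine(x$affine),
                space = x$space %||% "MNI152"))
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as a grid", call. = FALSE)
}

#' Standard and toy analysis grids
#'
#' `mni_grid()` returns the 2 mm isotropic MNI152-shaped analysis grid
#' (91 x 109 x 91); `toy_grid()` returns a small centered isotropic grid for
#' desk-scale analyses and tests.
#'
#' @param voxel voxel edge length in mm.
#' @param dim grid dimensions (voxels per axis).
#' @return A grid geometry list with fields `dim`, `affine`, `space`,
#'   usable wherever a grid is expected.
#' @export
mni_grid <- function(voxel = 2) {
  dim <- as.integer(round(c(182, 218, 182) / voxel))
  affine <- rbind(c(-voxel, 0, 0, 90), c(0, voxel, 0, -126),
                  c(0, 0, voxel, -72), c(0, 0, 0, 1))
  list(dim = dim, affine = affine, space = "MNI152")
}

#' @rdname mni_grid
#' @export
toy_grid <- function(dim = c(16, 16, 16), voxel = 2) {
  dim <- as.integer(dim)
  half <- (dim - 1) / 2 * voxel
  affine <- diag(c(voxel, voxel, voxel, 1))
  affine[1:3, 4] <- -half
  list(dim = dim, affine = affine, space = "MNI152")
}

#' Constant-value map / full mask on a grid
#'
#' @param grid a grid geometry, `stat_map`, `brain_mask` or `parcellation`.
#' @param value fill value.
#' @return `empty_map()` a `stat_map`; `full_mask()` a `brain_mask` covering
#'   the whole grid.
#' @export
empty_map <- function(grid, value = 0) {
  g <- grid_geometry(grid)
  stat_map(array(value, dim = g$dim), g$affine, g$space)
}

#' @rdname empty_map
#' @export
full_mask <- function(grid) {
  g <- grid_geometry(grid)
  brain_mask(array(TRUE, dim = g$dim), g$affine)
}

# Same-grid check: identical dims, affines within tol mm.
same_grid <- function(a, b, tol = 1e-4) {
  ga <- grid_geometry(a); gb <- grid_geometry(b)
  all(ga$dim == gb$dim) && max(abs(ga$affine - gb$affine)) <= tol
}

stop_if_grid_mismatch <- function(a, b, what = "maps") {
  if (!same_grid(a, b))
    stop(what, " are not on the same grid (dim/affine mismatch)",
         call. = FALSE)
  invisible(TRUE)
}

# mm -> continuous 0-based voxel index (rows of xyz)
mm_to_voxel <- function(geom, xyz) {
  xyz <- matrix(xyz, ncol = 3)
  inv <- solve(geom$affine)
  t(inv %*% rbind(t(xyz), 1))[, 1:3, drop = FALSE]
}

# 0-based voxel indices (rows) -> mm
voxel_to_mm <- function(geom, ijk) {
  ijk <- matrix(ijk, ncol = 3)
  t(geom$affine %*% rbind(t(ijk), 1))[, 1:3, drop = FALSE]
}

# mm coordinates of every in-mask voxel center (mask logical array or NULL)
inmask_centers <- function(geom, mask_values = NULL) {
  idx <- if (is.null(mask_values)) seq_len(prod(geom$dim)) else which(mask_values)
  ijk <- arrayInd(idx, geom$dim) - 1L
  list(idx = idx, mm = voxel_to_mm(geom, ijk))
}

#' Mean map value inside a spherical ROI
#'
#' Averages the map over all voxels whose center lies within `radius` mm
#' (Euclidean) of `center`. If no voxel center falls inside the sphere the
#' single nearest voxel's value is returned, so that very small radii
#' degrade gracefully to nearest-voxel sampling.
#'
#' @param map a `stat_map`.
#' @param center numeric length-3 mm coordinate; must lie inside the grid
#'   bounding box.
#' @param radius sphere radius in mm (> 0). The 4 mm default matches the
#'   sampling-site ROI used for expression-atlas extraction.
#' @return Scalar mean.
#' @export
sample_sphere_mean <- function(map, center, radius = 4) {
  stopifnot(inherits(map, "stat_map"), length(center) == 3, radius > 0)
  g <- grid_geometry(map)
  vc <- mm_to_voxel(g, center)[1, ]
  if (any(vc < -0.5) || any(vc > g$dim - 0.5))
    stop("sphere center (", paste(signif(center, 4), collapse = ", "),
         ") mm lies outside the grid", call. = FALSE)
  vs <- voxel_dims(g$affine)
  halfw <- ceiling(radius / vs) + 1
  lo <- pmax(0L, floor(vc - halfw)); hi <- pmin(g$dim - 1L, ceiling(vc + halfw))
  cand <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2],
                                k = lo[3]:hi[3]))
  mm <- voxel_to_mm(g, cand)
  d2 <- (mm[, 1] - center[1])^2 + (mm[, 2] - center[2])^2 +
    (mm[, 3] - center[3])^2
  inside <- d2 <= radius^2
  pick <- if (any(inside)) cand[inside, , drop = FALSE] else
    cand[which.min(d2), , drop = FALSE]
  mean(map$values[pick + 1L])
}
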