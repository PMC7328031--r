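#' Read and write statistic maps, masks and parcellations as NIfTI
#'
#' Thin wrappers around RNifti preserving the voxel-to-mm affine. Integer
#' data round-trip bit-true; floating point within float precision.
#'
#' @param path NIfTI-1/2 file (`.nii` or `.nii.gz`).
#' @param space coordinate-space tag to attach on read.
#' @return `read_stat_map()` a [stat_map()]; `read_mask()` a [brain_mask()]
#'   (nonzero voxels); `read_parcellation()` a [parcellation()].
#' @export
read_stat_map <- function(path, space = "MNI152") {
  arr <- read_nifti_array(path)
  stat_map(arr$values, arr$affine, space)
}

#' @rdname read_stat_map
#' @export
read_mask <- function(path) {
  arr <- read_nifti_array(path)
  brain_mask(arr$values != 0, arr$affine)
}

#' @rdname read_stat_map
#' @export
read_parcellation <- function(path) {
  arr <- read_nifti_array(path)
  parcellation(round(arr$values), arr$affine)
}

read_nifti_array <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  values <- as.array(img)
  # plain array: drop niftiImage class and header attributes
  values <- array(as.vector(values), dim = dim(values))
  nd <- length(dim(values))
  if (nd == 4L && dim(values)[4] == 1L) {
    values <- array(values, dim = dim(values)[1:3])
    nd <- 3L
  }
  if (nd != 3L)
    stop("expected a 3-D image, got ", nd, " dimensions in ", path,
         call. = FALSE)
  affine <- unclass(RNifti::xform(img))
  attributes(affine) <- list(dim = c(4L, 4L))
  list(values = values, affine = affine)
}

#' @param x a `stat_map`, `brain_mask` or `parcellation`.
#' @rdname read_stat_map
#' @export
write_stat_map <- function(x, path) {
  values <- if (inherits(x, "parcellation")) x$labels else x$values
  if (is.logical(values)) {
    storage.mode(values) <- "integer"
  }
  img <- RNifti::asNifti(values)
  img <- RNifti::`sform<-`(img, structure(x$affine, code = 4L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
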