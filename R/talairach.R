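#' Talairach to MNI coordinate conversion
#'
#' Applies an affine transform to a Talairach-space coordinate to obtain
#' its MNI-space equivalent. The default is the inverse of the Lancaster
#' et al. icbm_spm2tal ("icbm2tal") best-fit affine, the transform family
#' used by standard coordinate-conversion tooling; any 4x4 affine can be
#' supplied instead.
#'
#' @param coord numeric length-3 (x, y, z) mm, or an n x 3 matrix.
#' @param transform 4x4 affine applied to the homogeneous coordinate;
#'   defaults to [lancaster_tal2mni()].
#' @return Converted coordinate(s), same shape as the input.
#' @export
tal2mni <- function(coord, transform = lancaster_tal2mni()) {
  transform <- as.matrix(transform)
  if (!all(dim(transform) == c(4, 4)))
    stop("transform must be 4x4", call. = FALSE)
  if (abs(det(transform)) < 1e-12)
    stop("transform matrix is singular", call. = FALSE)
  was_vec <- is.null(dim(coord))
  xyz <- matrix(as.numeric(coord), ncol = 3)
  if (!all(is.finite(xyz))) stop("coordinates must be finite", call. = FALSE)
  out <- t(transform %*% rbind(t(xyz), 1))[, 1:3, drop = FALSE]
  if (was_vec) drop(out) else out
}

#' @describeIn tal2mni The default transform: inverse of the published
#'   icbm_spm2tal matrix (MNI/ICBM to Talairach best-fit affine).
#' @export
lancaster_tal2mni <- function() solve(icbm_spm2tal())

#' @describeIn tal2mni The published icbm_spm2tal affine (MNI -> Talairach).
#' @export
icbm_spm2tal <- function() {
  rbind(c(0.9254, 0.0024, -0.0118, -1.0207),
        c(-0.0048, 0.9316, -0.0871, -1.7667),
        c(0.0152, 0.0883, 0.8924, 4.0926),
        c(0, 0, 0, 1))
}
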