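#' Term meta-map set
#'
#' A collection of behavioral-term meta-analytic maps (e.g. "inhibition",
#' "working memory") on a common grid, with the mask that defines the
#' voxels entering similarity computations.
#'
#' @param terms character vector of term names.
#' @param maps list of [stat_map()]s, one per term, grid-compatible.
#' @param mask a [brain_mask()] on the same grid.
#' @return An object of class `term_map_set`.
#' @export
term_map_set <- function(terms, maps, mask) {
  stopifnot(length(terms) == length(maps), inherits(mask, "brain_mask"))
  for (m in maps) stop_if_grid_mismatch(mask, m, "term maps and mask")
  structure(list(terms = as.character(terms), maps = maps, mask = mask),
            class = "term_map_set")
}

#' Spatial similarity index between two maps
#'
#' Pearson correlation of the two maps' values over in-mask voxels - the
#' similarity index used to profile co-activation maps against term
#' meta-maps.
#'
#' @param a,b [stat_map()]s on a common grid.
#' @param mask a [brain_mask()]; needs >= 3 in-mask voxels.
#' @return Correlation coefficient in \[-1, 1\]. Zero variance in either
#'   map raises an error (callers may catch and record a missing entry).
#' @export
spatial_similarity <- function(a, b, mask) {
  stop_if_grid_mismatch(a, b)
  stop_if_grid_mismatch(a, mask, "map and mask")
  va <- a$values[mask$values]; vb <- b$values[mask$values]
  if (length(va) < 3) stop("need at least 3 in-mask voxels", call. = FALSE)
  if (sd(va) == 0 || sd(vb) == 0)
    stop("undefined correlation: zero variance within the mask",
         call. = FALSE)
  cor(va, vb)
}

#' Similarity matrix of co-activation maps against term meta-maps
#'
#' @param coact named list of [stat_map()]s (e.g. MACM co-activation
#'   maps).
#' @param terms a [term_map_set()].
#' @return Matrix (rows = co-activation maps, columns = terms) of
#'   similarity indices; entries whose correlation is undefined (zero
#'   variance) are `NA` with a warning.
#' @export
profile_maps <- function(coact, terms) {
  stopifnot(inherits(terms, "term_map_set"), length(coact) >= 1)
  rn <- names(coact) %||% paste0("map", seq_along(coact))
  m <- matrix(NA_real_, nrow = length(coact), ncol = length(terms$terms),
              dimnames = list(rn, terms$terms))
  n_missing <- 0L
  for (i in seq_along(coact))
    for (j in seq_along(terms$terms)) {
      r <- tryCatch(spatial_similarity(coact[[i]], terms$maps[[j]],
                                       terms$mask),
                    error = function(e) NA_real_)
      if (is.na(r)) n_missing <- n_missing + 1L
      m[i, j] <- r
    }
  if (n_missing > 0)
    warning(n_missing, " similarity entr(y/ies) undefined (zero variance), recorded as NA",
            call. = FALSE)
  m
}

#' Rank terms by mean similarity
#'
#' Orders terms by the column mean of the similarity matrix, descending;
#' ties break alphabetically for reproducibility.
#'
#' @param m similarity matrix from [profile_maps()].
#' @return Data frame with columns `term`, `mean_r`, in rank order.
#' @export
rank_terms <- function(m) {
  if (!length(m)) stop("empty similarity matrix", call. = FALSE)
  mu <- colMeans(m, na.rm = TRUE)
  ord <- order(-mu, colnames(m) %||% as.character(seq_along(mu)))
  data.frame(term = (colnames(m) %||% as.character(seq_along(mu)))[ord],
             mean_r = unname(mu[ord]), stringsAsFactors = FALSE)
}
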