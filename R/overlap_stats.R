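#' Gene-list overlap count and percentage
#'
#' `overlap_count()` is the size of the set intersection of two gene
#' lists; `overlap_percentage()` expresses a count as a percentage of the
#' list-size threshold `x` (1212 of 2000 -> 60.6).
#'
#' @param a,b gene lists (character vectors).
#' @return `overlap_count()` an integer; `overlap_percentage()` a percent
#'   in \[0, 100\].
#' @export
overlap_count <- function(a, b) {
  length(intersect(as.character(a), as.character(b)))
}

#' @param count overlap count.
#' @param x list-size threshold used to form both lists.
#' @rdname overlap_count
#' @export
overlap_percentage <- function(count, x) {
  stopifnot(x >= 1)
  if (count > x) stop("overlap count exceeds the threshold x", call. = FALSE)
  100 * count / x
}

#' Overall spatial similarity within a gene list
#'
#' Mean and standard deviation of the pairwise Pearson correlations
#' between the listed genes' site-expression vectors, computed per donor
#' and pooled (averaged) over donors. Used to match random gene lists to
#' the spatial-similarity level of the observed lists.
#'
#' @param genes gene list (>= 2 genes present in the atlas; absent genes
#'   are dropped with a `message`).
#' @param gene_atlas gene-level [expression_atlas()].
#' @param cortical_only restrict to cortical sites.
#' @return List with `per_donor` (data frame `donor`, `mean`, `sd`),
#'   pooled `mean` and `sd`.
#' @export
list_spatial_similarity <- function(genes, gene_atlas,
                                    cortical_only = TRUE) {
  stopifnot(gene_atlas$level == "gene")
  genes <- as.character(genes)
  present <- genes %in% rownames(gene_atlas$donors[[1]]$expr)
  if (any(!present))
    message(sum(!present), " gene(s) absent from the atlas excluded")
  genes <- genes[present]
  if (length(genes) < 2)
    stop("need >= 2 genes present in the atlas", call. = FALSE)
  rows <- lapply(names(gene_atlas$donors), function(d) {
    dn <- gene_atlas$donors[[d]]
    keep <- if (cortical_only) which(dn$sites$cortical) else
      seq_len(nrow(dn$sites))
    cm <- suppressWarnings(cor(t(dn$expr[genes, keep, drop = FALSE])))
    vals <- cm[upper.tri(cm)]
    vals <- vals[is.finite(vals)]
    data.frame(donor = d, mean = mean(vals),
               sd = if (length(vals) > 1) sd(vals) else 0,
               stringsAsFactors = FALSE)
  })
  per_donor <- do.call(rbind, rows)
  list(per_donor = per_donor, mean = mean(per_donor$mean),
       sd = mean(per_donor$sd))
}

new_null_distribution <- function(draws, n_requested, filter, observed) {
  p <- (1 + sum(draws >= observed)) / (length(draws) + 1)
  structure(list(draws = draws, n_requested = n_requested,
                 n_retained = length(draws), filter = filter,
                 mean = mean(draws), sd = sd(draws),
                 observed = observed, p_value = p),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> %d/%d draws retained, null %.2f +/- %.2f, observed %g, p = %.4g\n",
              x$n_retained, x$n_requested, x$mean, x$sd, x$observed,
              x$p_value))
  invisible(x)
}

#' Similarity-constrained random-gene-list overlap null
#'
#' Draws `n_draws` pairs of uniform random gene subsets (sizes `sizes`,
#' without replacement within each list) from the universe and records
#' their overlap counts. When a similarity `filter` is given, only pairs
#' whose pooled [list_spatial_similarity()] (computed on the union of the
#' two lists) falls inside both the mean and sd windows are retained -
#' a control for spatial autocorrelation of expression. The empirical
#' p-value for `observed` uses the add-one estimator over retained draws.
#'
#' @param sizes integer length-2: the two list sizes (e.g. c(2531, 1529)).
#' @param universe either an integer (number of genes; symbols are then
#'   synthesized) or a character vector of gene symbols.
#' @param observed observed overlap count.
#' @param n_draws number of random pairs (5000 in the reference design).
#' @param filter `NULL` (no similarity constraint) or a list with `mean`
#'   and `sd`, each a length-2 window, e.g.
#'   `list(mean = c(0.05, 0.07), sd = c(0.25, 0.29))`.
#' @param gene_atlas gene-level [expression_atlas()]; required when
#'   `filter` is set.
#' @param seed integer seed.
#' @return A `null_distribution` object (draws, retention, mean, sd,
#'   p_value).
#' @export
constrained_random_null <- function(sizes, universe, observed,
                                    n_draws = 5000, filter = NULL,
                                    gene_atlas = NULL, seed = NULL) {
  stopifnot(length(sizes) == 2, observed <= min(sizes))
  symbols <- if (is.character(universe)) universe else
    sprintf("G%05d", seq_len(universe))
  N <- length(symbols)
  if (any(sizes > N)) stop("list sizes exceed the universe", call. = FALSE)
  if (!is.null(filter) && is.null(gene_atlas))
    stop("similarity filter requires a gene_atlas", call. = FALSE)
  draws <- numeric(0)
  with_seed(seed, {
    for (i in seq_len(n_draws)) {
      a <- sample.int(N, sizes[1])
      b <- sample.int(N, sizes[2])
      if (!is.null(filter)) {
        sim <- list_spatial_similarity(symbols[union(a, b)], gene_atlas)
        ok <- sim$mean >= filter$mean[1] && sim$mean <= filter$mean[2] &&
          sim$sd >= filter$sd[1] && sim$sd <= filter$sd[2]
        if (!ok) next
      }
      draws <- c(draws, length(intersect(a, b)))
    }
  })
  if (!length(draws))
    stop("filter too strict: 0 of ", n_draws, " draws retained",
         call. = FALSE)
  new_null_distribution(draws, n_draws, filter, observed)
}

#' Parcellation-restricted map permutation
#'
#' Spatially permutes a statistic map while respecting a functional
#' parcellation: each parcel's mean statistic is computed, a uniform
#' random permutation of parcel labels is drawn, and every voxel receives
#' the mean value of the parcel its label maps to. Background voxels are
#' untouched and the multiset of parcel means is conserved exactly. The
#' `"within_parcel"` alternative instead shuffles voxel values inside each
#' parcel, preserving parcel means but destroying sub-parcel structure.
#'
#' @param map a [stat_map()].
#' @param parc a [parcellation()] on the same grid with >= 2 parcels.
#' @param seed integer seed.
#' @param method `"parcel_means"` (default) or `"within_parcel"`.
#' @return A permuted [stat_map()].
#' @export
parcel_permute_map <- function(map, parc, seed = NULL,
                               method = c("parcel_means", "within_parcel")) {
  method <- match.arg(method)
  stopifnot(inherits(map, "stat_map"), inherits(parc, "parcellation"))
  stop_if_grid_mismatch(map, parc, "map and parcellation")
  if (parc$n_parcels < 2)
    stop("parcellation must have at least 2 parcels", call. = FALSE)
  ids <- parc$parcel_ids
  out <- map$values
  with_seed(seed, {
    if (method == "parcel_means") {
      means <- vapply(ids, function(id)
        mean(map$values[parc$labels == id]), numeric(1))
      perm <- sample.int(length(ids))
      for (i in seq_along(ids))
        out[parc$labels == ids[i]] <- means[perm[i]]
    } else {
      for (id in ids) {
        vox <- which(parc$labels == id)
        out[vox] <- map$values[vox[sample.int(length(vox))]]
      }
    }
  })
  stat_map(out, map$affine, map$space)
}

#' Permuted-map overlap null
#'
#' The map-permutation alternative to the random-list null: both maps are
#' spatially permuted ([parcel_permute_map()]) `n` times; each time the
#' full activation-gene-expression association is rerun on both permuted
#' maps, the top-`x` lists are formed, pairs are optionally retained by
#' the similarity filter, and the overlap of the pair is recorded.
#'
#' @param map_a,map_b the two observed [stat_map()]s.
#' @param parc a [parcellation()].
#' @param gene_atlas gene-level [expression_atlas()].
#' @param x list-size threshold.
#' @param n number of map permutations (100 in the reference design).
#' @param filter similarity filter as in [constrained_random_null()].
#' @param seed integer seed.
#' @param radius sphere radius, mm.
#' @param cortical_only restrict to cortical sites.
#' @param observed observed overlap count; computed from the unpermuted
#'   maps when `NULL`.
#' @return A `null_distribution` object.
#' @export
permuted_map_null <- function(map_a, map_b, parc, gene_atlas, x, n = 100,
                              filter = NULL, seed = NULL, radius = 4,
                              cortical_only = TRUE, observed = NULL) {
  top_list <- function(m) {
    tab <- gene_association_table(gene_atlas, m, radius = radius,
                                  cortical_only = cortical_only)
    select_top_genes(tab, x)
  }
  if (is.null(observed))
    observed <- overlap_count(top_list(map_a), top_list(map_b))
  draws <- numeric(0)
  with_seed(seed, {
    for (i in seq_len(n)) {
      pa <- parcel_permute_map(map_a, parc, seed = NULL)
      pb <- parcel_permute_map(map_b, parc, seed = NULL)
      la <- top_list(pa); lb <- top_list(pb)
      if (!is.null(filter)) {
        sim <- list_spatial_similarity(union(la, lb), gene_atlas,
                                       cortical_only = cortical_only)
        ok <- sim$mean >= filter$mean[1] && sim$mean <= filter$mean[2] &&
          sim$sd >= filter$sd[1] && sim$sd <= filter$sd[2]
        if (!ok) next
      }
      draws <- c(draws, overlap_count(la, lb))
    }
  })
  if (!length(draws))
    stop("filter too strict: 0 of ", n, " permutations retained",
         call. = FALSE)
  new_null_distribution(draws, n, filter, observed)
}

ranked_list <- function(table, x_max) {
  as.character(select_top_genes(table, x_max))
}

# overlap counts of two ranked lists at every x in x_grid, via the rank at
# which each common gene has entered both prefixes
prefix_overlap_counts <- function(ra, rb, x_grid) {
  common <- intersect(ra, rb)
  if (!length(common)) return(rep(0L, length(x_grid)))
  m <- sort(pmax(match(common, ra), match(common, rb)))
  findInterval(x_grid, m)
}

#' Threshold-sweep overlap curves
#'
#' For every threshold `x` in the grid, forms the top-`x` gene list from
#' each association table and averages the overlap percentage within three
#' categories of list pairs: pairs of inhibitory-task lists
#' (`within_control`), inhibitory-task vs DMN (`inhibition_vs_dmn`), and
#' inhibitory-task vs permuted-map lists
#' (`inhibition_vs_permutation`).
#'
#' @param inhibition_tables named list of [gene_association_table()]s for
#'   the inhibitory tasks (>= 2).
#' @param dmn_table association table for the DMN control map.
#' @param permuted_tables list of association tables from permuted maps
#'   (>= 1).
#' @param x_grid thresholds (default 1 to 2000, step 10). Values exceeding
#'   the shortest ranked list are truncated with a warning.
#' @return An object of class `sweep_curves`: `curves` (data frame `x` +
#'   one column per category of mean percentages) and `observations`
#'   (long data frame `x`, `category`, `pair`, `percentage`), the unit of
#'   observation for [compare_categories()].
#' @export
threshold_sweep <- function(inhibition_tables, dmn_table, permuted_tables,
                            x_grid = seq(1, 2000, by = 10)) {
  stopifnot(length(inhibition_tables) >= 2, length(permuted_tables) >= 1)
  inames <- names(inhibition_tables) %||%
    paste0("task", seq_along(inhibition_tables))
  pnames <- names(permuted_tables) %||%
    paste0("perm", seq_along(permuted_tables))
  x_max <- max(x_grid)
  ri <- lapply(inhibition_tables, ranked_list, x_max = x_max)
  rd <- ranked_list(dmn_table, x_max)
  rp <- lapply(permuted_tables, ranked_list, x_max = x_max)
  shortest <- min(vapply(c(ri, list(rd), rp), length, 1L))
  if (max(x_grid) > shortest) {
    warning("x grid truncated at ", shortest,
            " (shortest ranked list)", call. = FALSE)
    x_grid <- x_grid[x_grid <= shortest]
  }
  obs <- list()
  add_pair <- function(category, pair, la, lb) {
    cnt <- prefix_overlap_counts(la, lb, x_grid)
    obs[[length(obs) + 1L]] <<- data.frame(
      x = x_grid, category = category, pair = pair,
      percentage = 100 * cnt / x_grid, stringsAsFactors = FALSE)
  }
  for (i in seq_along(ri))
    for (j in seq_along(ri))
      if (i < j)
        add_pair("within_control", paste(inames[i], inames[j], sep = "|"),
                 ri[[i]], ri[[j]])
  for (i in seq_along(ri))
    add_pair("inhibition_vs_dmn", paste(inames[i], "dmn", sep = "|"),
             ri[[i]], rd)
  for (i in seq_along(ri))
    for (j in seq_along(rp))
      add_pair("inhibition_vs_permutation",
               paste(inames[i], pnames[j], sep = "|"), ri[[i]], rp[[j]])
  observations <- do.call(rbind, obs)
  curves <- data.frame(x = x_grid)
  for (cat in c("within_control", "inhibition_vs_dmn",
                "inhibition_vs_permutation")) {
    sub <- observations[observations$category == cat, , drop = FALSE]
    curves[[cat]] <- vapply(x_grid, function(xx)
      mean(sub$percentage[sub$x == xx]), numeric(1))
  }
  structure(list(curves = curves, observations = observations),
            class = "sweep_curves")
}

#' Compare two overlap categories
#'
#' Two-sample t-test (Welch by default) on the per-(threshold, pair)
#' overlap percentages of two sweep categories.
#'
#' @param curves a [threshold_sweep()] result.
#' @param pair character length-2: the two category names.
#' @param var_equal use the pooled-variance (Student) variant.
#' @return List with `mean1`, `mean2`, `t`, `df`, `p` (two-sided).
#' @export
compare_categories <- function(curves,
                               pair = c("within_control",
                                        "inhibition_vs_dmn"),
                               var_equal = FALSE) {
  stopifnot(inherits(curves, "sweep_curves"), length(pair) == 2)
  ob <- curves$observations
  v1 <- ob$percentage[ob$category == pair[1]]
  v2 <- ob$percentage[ob$category == pair[2]]
  if (length(v1) < 2 || length(v2) < 2)
    stop("need >= 2 observations per category", call. = FALSE)
  tt <- t.test(v1, v2, var.equal = var_equal)
  list(mean1 = mean(v1), mean2 = mean(v2), t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value)
}
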