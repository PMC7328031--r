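#' Synthetic foci corpus with planted loci
#'
#' Generates a corpus of experiments whose foci scatter isotropically
#' around planted ground-truth loci, plus an optional Poisson count of
#' uniformly placed false foci per experiment - the stand-in for a curated
#' study corpus. Every generator in this module is a pure function of its
#' arguments and `seed`.
#'
#' @param loci matrix (L x 3) of planted mm coordinates (may have 0 rows
#'   only when `false_foci_rate > 0`).
#' @param n_experiments number of experiments.
#' @param n_subjects_range integer length-2; per-experiment subject counts
#'   are uniform in this range.
#' @param scatter_sd isotropic Gaussian scatter of true foci, mm.
#' @param false_foci_rate Poisson mean of uniform false foci per
#'   experiment.
#' @param grid analysis grid (bounds for false foci and clipping).
#' @param foci_per_locus true foci drawn per planted locus per experiment.
#' @param seed integer seed.
#' @return List with `foci_table` and `ground_truth` (planted loci, seed,
#'   parameters).
#' @export
generate_foci_corpus <- function(loci, n_experiments,
                                 n_subjects_range = c(10, 30),
                                 scatter_sd = 6, false_foci_rate = 0,
                                 grid = toy_grid(), foci_per_locus = 1,
                                 seed = NULL) {
  stopifnot(scatter_sd >= 0, n_experiments >= 1)
  loci <- matrix(as.numeric(loci), ncol = 3)
  if (nrow(loci) == 0 && false_foci_rate <= 0)
    stop("no planted loci and zero false-foci rate: nothing to generate",
         call. = FALSE)
  g <- grid_geometry(grid)
  corners <- voxel_to_mm(g, rbind(c(0, 0, 0), g$dim - 1L))
  lo <- pmin(corners[1, ], corners[2, ]); hi <- pmax(corners[1, ], corners[2, ])
  with_seed(seed, {
    exps <- lapply(seq_len(n_experiments), function(i) {
      true_foci <- if (nrow(loci)) {
        reps <- loci[rep(seq_len(nrow(loci)), each = foci_per_locus), ,
                     drop = FALSE]
        reps + matrix(rnorm(length(reps), sd = scatter_sd), ncol = 3)
      } else matrix(numeric(), ncol = 3)
      n_false <- if (false_foci_rate > 0) rpois(1, false_foci_rate) else 0L
      false_foci <- if (n_false > 0)
        cbind(runif(n_false, lo[1], hi[1]), runif(n_false, lo[2], hi[2]),
              runif(n_false, lo[3], hi[3])) else matrix(numeric(), ncol = 3)
      foci <- rbind(true_foci, false_foci)
      # keep foci inside the grid bounds (scatter can escape a toy box)
      foci <- foci[apply(sweep(foci, 2, lo, ">=") &
                           sweep(foci, 2, hi, "<="), 1, all), , drop = FALSE]
      if (nrow(foci) == 0) foci <- loci[1, , drop = FALSE]
      experiment(id = sprintf("exp%03d", i), study_id = sprintf("study%03d", i),
                 n_subjects = sample(n_subjects_range[1]:n_subjects_range[2], 1),
                 foci = foci)
    })
    list(foci_table = foci_table(exps, name = "synthetic_corpus"),
         ground_truth = list(planted_loci = loci, scatter_sd = scatter_sd,
                             false_foci_rate = false_foci_rate,
                             seed = seed))
  })
}

#' Synthetic coordinate database with planted co-activation networks
#'
#' Each network is a set of loci that its experiments report together
#' (with scatter); `mixing` is the probability that any single focus is
#' drawn from a random other network instead, blurring network boundaries.
#' Stands in for a large literature coordinate database.
#'
#' @param networks list of loci matrices (one per network).
#' @param n_experiments_per_network integer (recycled over networks).
#' @param mixing focus-level contamination probability in \[0, 1\].
#' @param scatter_sd focus scatter, mm.
#' @param n_subjects_range per-experiment subject-count range.
#' @param grid analysis grid.
#' @param seed integer seed.
#' @return A [coordinate_database()]; each experiment carries a
#'   `network` label.
#' @export
generate_coordinate_database <- function(networks,
                                         n_experiments_per_network,
                                         mixing = 0, scatter_sd = 4,
                                         n_subjects_range = c(10, 30),
                                         grid = toy_grid(), seed = NULL) {
  stopifnot(length(networks) >= 1, mixing >= 0, mixing <= 1)
  nets <- lapply(networks, function(m) matrix(as.numeric(m), ncol = 3))
  n_per <- rep_len(n_experiments_per_network, length(nets))
  with_seed(seed, {
    exps <- list()
    for (w in seq_along(nets)) {
      for (i in seq_len(n_per[w])) {
        src <- nets[[w]]
        foci <- src + matrix(rnorm(length(src), sd = scatter_sd), ncol = 3)
        if (mixing > 0 && length(nets) > 1) {
          swap <- runif(nrow(foci)) < mixing
          for (r in which(swap)) {
            other <- nets[[sample(setdiff(seq_along(nets), w), 1)]]
            foci[r, ] <- other[sample(nrow(other), 1), ] +
              rnorm(3, sd = scatter_sd)
          }
        }
        id <- sprintf("net%d_exp%03d", w, i)
        exps[[length(exps) + 1L]] <- experiment(
          id = id, study_id = id,
          n_subjects = sample(n_subjects_range[1]:n_subjects_range[2], 1),
          foci = foci, labels = c(network = as.character(w)))
      }
    }
    coordinate_database(exps, name = "synthetic_database")
  })
}

#' Synthetic expression atlas with planted map-correlated genes
#'
#' Emulates a donor-wise expression atlas: per donor, sampling sites are
#' drawn at random in-grid voxel centers; planted genes' site expression
#' is `rho * standardize(map at sites) + sqrt(1 - rho^2) * noise`, other
#' genes are pure standard-normal noise; each gene optionally expands to
#' several probes with probe-level jitter.
#'
#' @param map target [stat_map()] the planted genes track.
#' @param n_donors number of donors (6, the atlas design, by default).
#' @param n_sites_per_donor sampling sites per donor.
#' @param n_genes total genes.
#' @param n_planted number of planted genes.
#' @param rho target spatial correlation of planted genes, in \[0, 1\].
#' @param probes_per_gene probes per gene (1 = gene-level atlas with probe
#'   ids equal to gene symbols).
#' @param probe_jitter_sd sd of probe-level noise around the gene value.
#' @param cortical_fraction fraction of sites flagged cortical.
#' @param radius sphere radius used for the map signal at sites, mm.
#' @param seed integer seed.
#' @return List with `atlas` (an [expression_atlas()], probe-level if
#'   `probes_per_gene > 1`) and `ground_truth` (planted gene symbols, rho,
#'   seed).
#' @export
generate_expression_atlas <- function(map, n_donors = 6,
                                      n_sites_per_donor = 300,
                                      n_genes = 500, n_planted = 20,
                                      rho = 0.5, probes_per_gene = 1,
                                      probe_jitter_sd = 0.1,
                                      cortical_fraction = 1, radius = 4,
                                      seed = NULL) {
  if (rho < 0 || rho > 1) stop("rho must be in [0, 1]", call. = FALSE)
  stopifnot(n_planted <= n_genes, n_sites_per_donor >= 3)
  g <- grid_geometry(map)
  centers <- inmask_centers(g, NULL)
  genes <- sprintf("G%04d", seq_len(n_genes))
  with_seed(seed, {
    planted <- sort(sample(genes, n_planted))
    donors <- lapply(seq_len(n_donors), function(d) {
      pick <- sample.int(nrow(centers$mm), n_sites_per_donor)
      mm <- centers$mm[pick, , drop = FALSE]
      sig <- vapply(seq_len(n_sites_per_donor), function(i)
        sample_sphere_mean(map, mm[i, ], radius), numeric(1))
      if (sd(sig) == 0)
        stop("target map constant over drawn sites; cannot plant signal",
             call. = FALSE)
      sig <- (sig - mean(sig)) / sd(sig)
      expr <- matrix(rnorm(n_genes * n_sites_per_donor),
                     nrow = n_genes, dimnames = list(genes, NULL))
      ip <- genes %in% planted
      expr[ip, ] <- rho * matrix(sig, nrow = sum(ip), ncol = length(sig),
                                 byrow = TRUE) +
        sqrt(1 - rho^2) * expr[ip, , drop = FALSE]
      n_cort <- max(1L, round(cortical_fraction * n_sites_per_donor))
      cortical <- rep(FALSE, n_sites_per_donor)
      cortical[sample.int(n_sites_per_donor, n_cort)] <- TRUE
      sites <- data.frame(site_id = sprintf("s%03d", seq_len(n_sites_per_donor)),
                          x = mm[, 1], y = mm[, 2], z = mm[, 3],
                          cortical = cortical, stringsAsFactors = FALSE)
      if (probes_per_gene > 1) {
        idx <- rep(seq_len(n_genes), each = probes_per_gene)
        expr <- expr[idx, , drop = FALSE] +
          matrix(rnorm(length(idx) * n_sites_per_donor, sd = probe_jitter_sd),
                 nrow = length(idx))
        rownames(expr) <- sprintf("%s_p%d", genes[idx],
                                  rep(seq_len(probes_per_gene), n_genes))
      }
      list(sites = sites, expr = expr)
    })
    names(donors) <- sprintf("donor%d", seq_len(n_donors))
    probe_map <- if (probes_per_gene > 1)
      data.frame(probe_id = rownames(donors[[1]]$expr),
                 gene_symbol = rep(genes, each = probes_per_gene),
                 stringsAsFactors = FALSE) else NULL
    atlas <- expression_atlas(donors, probe_map,
                              level = if (probes_per_gene > 1) "probe" else "gene")
    list(atlas = atlas,
         ground_truth = list(planted_genes = planted, rho = rho,
                             seed = seed))
  })
}

#' Synthetic Voronoi parcellation
#'
#' Labels every (in-mask) voxel by its nearest of `n_parcels` random
#' centroid voxels - a contiguous-region stand-in for a functional brain
#' parcellation.
#'
#' @param grid analysis grid.
#' @param n_parcels number of parcels (>= 2, <= in-mask voxel count).
#' @param mask optional [brain_mask()]; outside voxels get label 0.
#' @param seed integer seed.
#' @return A [parcellation()].
#' @export
generate_parcellation <- function(grid, n_parcels, mask = NULL,
                                  seed = NULL) {
  g <- grid_geometry(grid)
  mv <- if (is.null(mask)) NULL else mask_values_for(mask, g)
  centers <- inmask_centers(g, mv)
  M <- length(centers$idx)
  if (n_parcels < 2 || n_parcels > M)
    stop("n_parcels must be in [2, ", M, "]", call. = FALSE)
  with_seed(seed, {
    cid <- sample.int(M, n_parcels)
    cmm <- centers$mm[cid, , drop = FALSE]
    lab <- max.col(-vapply(seq_len(n_parcels), function(p)
      (centers$mm[, 1] - cmm[p, 1])^2 + (centers$mm[, 2] - cmm[p, 2])^2 +
        (centers$mm[, 3] - cmm[p, 3])^2, numeric(M)), ties.method = "first")
    arr <- array(0L, dim = g$dim)
    arr[centers$idx] <- lab
    parcellation(arr, g$affine)
  })
}

#' Synthetic annotation table with a planted enriched term
#'
#' Background terms annotate uniform random gene subsets (each gene
#' annotated with probability `background_density`); the planted term
#' annotates its stated gene set plus the same background noise.
#'
#' @param genes gene universe.
#' @param n_terms number of background terms.
#' @param planted list with `term` (name) and `genes` (subset of the
#'   universe), or `NULL`.
#' @param background_density per-gene annotation probability.
#' @param namespace namespace tag for all generated terms.
#' @param seed integer seed.
#' @return An [annotation_table()].
#' @export
generate_annotations <- function(genes, n_terms, planted = NULL,
                                 background_density = 0.05,
                                 namespace = "BP", seed = NULL) {
  genes <- unique(as.character(genes))
  if (!is.null(planted) && length(setdiff(planted$genes, genes)))
    stop("planted genes must be a subset of the universe", call. = FALSE)
  with_seed(seed, {
    rows <- list()
    for (i in seq_len(n_terms)) {
      set <- genes[runif(length(genes)) < background_density]
      if (!length(set)) set <- sample(genes, 1)
      rows[[length(rows) + 1L]] <- data.frame(
        term_id = sprintf("T%04d", i),
        term_name = sprintf("synthetic background term %d", i),
        namespace = namespace, gene = set, stringsAsFactors = FALSE)
    }
    if (!is.null(planted)) {
      extra <- genes[runif(length(genes)) < background_density]
      set <- union(planted$genes, extra)
      rows[[length(rows) + 1L]] <- data.frame(
        term_id = "T_PLANTED", term_name = planted$term,
        namespace = namespace, gene = set, stringsAsFactors = FALSE)
    }
    annotation_table(do.call(rbind, rows), universe = genes)
  })
}
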