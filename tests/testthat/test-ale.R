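test_that("kernel FWHM shrinks with sample size toward the template floor", {
  k <- kernel_spec()
  ns <- c(5, 10, 20, 50, 200)
  f <- fwhm_for(k, ns)
  expect_true(all(diff(f) < 0))
  expect_true(all(f > k$fwhm_template))
  expect_equal(fwhm_for(k, 20), sqrt(5.7^2 + 11.6^2 / 20))
})

test_that("modeled-activation maps are unimodal and combine by maximum", {
  g <- toy_grid(c(15, 15, 15), 2)
  e1 <- fixed_experiment("a", c(0, 0, 0))
  ma <- modeled_activation_map(e1, g)
  expect_true(all(ma$values >= 0 & ma$values <= 1))
  peak_idx <- which.max(ma$values)
  expect_equal(arrayInd(peak_idx, dim(ma$values)), matrix(c(8L, 8L, 8L), 1))
  # strictly decreasing with distance along an axis
  line <- ma$values[8:15, 8, 8]
  expect_true(all(diff(line) < 0))

  # duplicated focus changes nothing (max rule)
  e2 <- fixed_experiment("b", c(0, 0, 0, 0, 0, 0))
  expect_equal(modeled_activation_map(e2, g)$values, ma$values)

  # far-separated foci each attain the single-focus peak
  g2 <- toy_grid(c(41, 15, 15), 2)
  ek <- kernel_spec(10, 1)
  e3 <- experiment("c", n_subjects = 10000,
                   foci = rbind(c(-25, 0, 0), c(25, 0, 0)))
  ma3 <- modeled_activation_map(e3, g2, ek)
  single <- modeled_activation_map(
    experiment("d", n_subjects = 10000, foci = rbind(c(-25, 0, 0))), g2, ek)
  expect_equal(ma3$values[which.max(single$values)], max(single$values),
               tolerance = 1e-9)

  expect_warning(
    modeled_activation_map(fixed_experiment("e", c(150, 150, 150)), g),
    "outside the grid")
})

test_that("ALE union follows 1 - prod(1 - MA) and is order-invariant", {
  g <- toy_grid(c(4, 4, 4), 2)
  aff <- aletx:::grid_geometry(g)$affine
  mk <- function(v) stat_map(array(v, c(4, 4, 4)), aff)
  u <- ale_union(list(mk(0.2), mk(0.3)))
  expect_equal(u$values[1], 1 - 0.8 * 0.7) # 0.44
  one <- mk(0.17)
  expect_equal(ale_union(list(one))$values, one$values)
  set.seed(5)
  maps <- lapply(1:5, function(i) mk(runif(64)))
  u1 <- ale_union(maps)
  u2 <- ale_union(maps[c(4, 2, 5, 1, 3)])
  expect_equal(u1$values, u2$values)
  # monotone: adding an experiment's map never lowers any voxel
  u3 <- ale_union(c(maps, list(mk(runif(64)))))
  expect_true(all(u3$values >= u1$values - 1e-15))
  expect_error(ale_union(list(mk(0.1), stat_map(array(0, c(5, 5, 5)),
                                                aff))), "grid")
})

test_that("voxel null is deterministic and degenerates to p = 1 off-signal", {
  g <- toy_grid(c(6, 6, 6), 2)
  ft <- foci_table(list(fixed_experiment("a", c(0, 0, 0)),
                        fixed_experiment("b", c(2, 2, 2))))
  p1 <- ale_voxel_null(ft, g, n_perm = 100, seed = 11)
  p2 <- ale_voxel_null(ft, g, n_perm = 100, seed = 11)
  expect_identical(p1$values, p2$values)
  expect_true(all(p1$values > 0 & p1$values <= 1))

  # foci far outside the grid: observed ALE 0, p = 1 everywhere
  far <- foci_table(list(fixed_experiment("z", c(150, 150, 150))))
  pfar <- ale_voxel_null(far, g, n_perm = 100, seed = 2)
  expect_true(all(pfar$values == 1))
})

test_that("voxel null on a 2x2x2 grid matches exhaustive placement", {
  g <- toy_grid(c(2, 2, 2), 2)
  geom <- aletx:::grid_geometry(g)
  centers <- aletx:::inmask_centers(geom, NULL)
  # focus off voxel centers so no placement ties the observed value
  focus <- c(0.4, -0.3, 0.2)
  n <- 14L
  ft <- foci_table(list(experiment("a", n_subjects = n,
                                   foci = rbind(focus))))
  sigma <- fwhm_for(kernel_spec(), n) / (2 * sqrt(2 * log(2)))
  peak <- (2 * pi * sigma^2)^(-1.5) * 8
  gauss_map <- function(src) {
    d2 <- (centers$mm[, 1] - src[1])^2 + (centers$mm[, 2] - src[2])^2 +
      (centers$mm[, 3] - src[3])^2
    peak * exp(-d2 / (2 * sigma^2))
  }
  obs <- gauss_map(focus)
  placements <- t(vapply(seq_len(8), function(i) gauss_map(centers$mm[i, ]),
                         numeric(8)))
  q <- colMeans(placements >= matrix(obs, 8, 8, byrow = TRUE))
  n_perm <- 4000
  pmap <- ale_voxel_null(ft, g, n_perm = n_perm, seed = 99)
  mc_sd <- sqrt(q * (1 - q) / n_perm) + 1e-3
  expect_true(all(abs(pmap$values[centers$idx] - q) < 4 * mc_sd + 1 / n_perm))
})

test_that("cluster-level FWE recovers a planted cluster at its locus", {
  g <- toy_grid(c(16, 16, 16), 2)
  locus <- c(4, -2, 0)
  exps <- lapply(1:20, function(i)
    fixed_experiment(sprintf("e%02d", i), locus, n = 20))
  res <- cluster_level_fwe(foci_table(exps), g, cluster_forming_p = 0.01,
                           n_perm = 200, seed = 21)
  expect_equal(nrow(res$cluster_table), 1L)
  peak <- unlist(res$cluster_table[1, c("peak_x", "peak_y", "peak_z")])
  expect_lte(sqrt(sum((peak - locus)^2)), 2 * sqrt(3) + 1e-9) # within 1 voxel
  expect_true(all(res$ale_map$values >= 0 & res$ale_map$values <= 1))
  expect_equal(res$cluster_table$peak_value[1],
               max(res$thresholded$values))
  # sizes equal voxel count times voxel volume by construction
  expect_equal(res$cluster_table$size_mm3[1] %% 8, 0)
})

test_that("conjunction is the voxel-wise minimum of thresholded maps", {
  g <- toy_grid(c(8, 8, 8), 2)
  aff <- aletx:::grid_geometry(g)$affine
  a <- array(0, c(8, 8, 8)); b <- array(0, c(8, 8, 8))
  a[2:4, 2:4, 2] <- 0.5
  b[6:8, 6:8, 6] <- 0.4
  expect_true(all(conjunction(stat_map(a, aff), stat_map(b, aff))$values == 0))
  m <- stat_map(a, aff)
  expect_equal(conjunction(m, m)$values, a)
  # overlap engineered on exactly 10 voxels
  b2 <- array(0, c(8, 8, 8))
  b2[2:4, 2:4, 2] <- 0.3   # 9 voxels overlap
  b2[5, 2, 2] <- 0.3
  a2 <- a; a2[5, 2, 2] <- 0.6
  cj <- conjunction(stat_map(a2, aff), stat_map(b2, aff))
  expect_equal(sum(cj$values > 0), 10)
  expect_equal(cj$values[2, 2, 2], 0.3)
})

test_that("contrast finds a planted group difference and is seeded", {
  g <- toy_grid(c(12, 12, 12), 2)
  la <- c(-6, 0, 0); lb <- c(6, 0, 0)
  ea <- lapply(1:10, function(i) fixed_experiment(paste0("a", i), la, n = 20))
  eb <- lapply(1:10, function(i) fixed_experiment(paste0("b", i), lb, n = 20))
  ra <- cluster_level_fwe(foci_table(ea), g, cluster_forming_p = 0.01,
                          n_perm = 150, seed = 1)
  rb <- cluster_level_fwe(foci_table(eb), g, cluster_forming_p = 0.01,
                          n_perm = 150, seed = 2)
  d1 <- contrast(ra, rb, n_perm = 199, seed = 5, p_threshold = 0.05)
  d2 <- contrast(ra, rb, n_perm = 199, seed = 5, p_threshold = 0.05)
  expect_identical(d1$values, d2$values)
  vox_a <- round(aletx:::mm_to_voxel(aletx:::grid_geometry(g), la))[1, ] + 1
  vox_b <- round(aletx:::mm_to_voxel(aletx:::grid_geometry(g), lb))[1, ] + 1
  expect_gt(d1$values[vox_a[1], vox_a[2], vox_a[3]], 0)
  expect_lt(d1$values[vox_b[1], vox_b[2], vox_b[3]], 0)
  expect_error(contrast(ra, rb, pooled = foci_table(ea)), "union")
})

test_that("thresholded overlap components match a flood-fill oracle", {
  g <- toy_grid(c(10, 10, 10), 2)
  aff <- aletx:::grid_geometry(g)$affine
  a <- array(0, c(10, 10, 10)); b <- array(0, c(10, 10, 10))
  a[2:3, 2:3, 2:3] <- 1; b[2:3, 2:3, 2:3] <- 2          # blob 1
  a[7:9, 7:8, 7] <- 1.5; b[7:9, 7:8, 7] <- 0.5          # blob 2
  a[5, 5, 5] <- 3                                        # only in a
  tab <- thresholded_overlap(stat_map(a, aff), stat_map(b, aff))
  both <- a != 0 & b != 0
  oracle <- flood_labels(both)
  expect_equal(nrow(tab), max(oracle))
  expect_equal(sort(tab$size_mm3), sort(tabulate(oracle[oracle > 0]) * 8))
  # identical one-blob maps -> a single component equal to the blob
  m1 <- array(0, c(10, 10, 10)); m1[4:6, 4:6, 4] <- 1   # 9-voxel slab
  t1 <- thresholded_overlap(stat_map(m1, aff), stat_map(m1, aff))
  expect_equal(nrow(t1), 1L)
  expect_equal(t1$size_mm3, 9 * 8)
  # disjoint maps -> empty table
  m2 <- array(0, c(10, 10, 10)); m2[8, 8, 8] <- 1
  expect_equal(nrow(thresholded_overlap(stat_map(m1, aff),
                                        stat_map(m2, aff))), 0L)
})
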