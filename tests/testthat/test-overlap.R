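test_that("overlap count and percentage arithmetic", {
  a <- sprintf("g%04d", 1:100)
  expect_equal(overlap_count(a, a), 100)
  expect_equal(overlap_count(a, sprintf("h%04d", 1:50)), 0)
  expect_equal(overlap_count(a, rev(a)[1:30]), 30)
  expect_equal(overlap_count(a[1:10], a[5:20]), overlap_count(a[5:20], a[1:10]))
  expect_equal(overlap_percentage(1212, 2000), 60.6)
  expect_equal(overlap_percentage(0, 500), 0)
  expect_equal(overlap_percentage(500, 500), 100)
  expect_error(overlap_percentage(600, 500), "exceeds")
})

test_that("list spatial similarity equals the pairwise-correlation oracle", {
  mm <- cbind(seq(-6, 6, by = 2), 0, 0)
  e1 <- rbind(u = c(1, 2, 3, 4, 5, 6, 7), v = c(1, 2, 3, 4, 5, 6, 7),
              w = c(2, 1, 4, 3, 6, 5, 7), n1 = rnorm(7), n2 = rnorm(7))
  atlas <- manual_atlas(list(e1), list(sites_df(mm)))
  # two identical genes: mean 1, sd 0
  s2 <- list_spatial_similarity(c("u", "v"), atlas)
  expect_equal(s2$mean, 1.0)
  expect_equal(s2$sd, 0)
  # three genes: mean/sd over the three pairwise correlations
  s3 <- list_spatial_similarity(c("u", "v", "w"), atlas)
  prs <- c(cor(e1["u", ], e1["v", ]), cor(e1["u", ], e1["w", ]),
           cor(e1["v", ], e1["w", ]))
  expect_equal(s3$mean, mean(prs))
  expect_equal(s3$sd, sd(prs))
  # absent genes are dropped with a message; < 2 left is an error
  expect_message(list_spatial_similarity(c("u", "v", "nope"), atlas),
                 "absent")
  expect_error(suppressMessages(
    list_spatial_similarity(c("u", "nope"), atlas)), ">= 2 genes")
  # many independent random genes: mean similarity near zero
  set.seed(12)
  big <- matrix(rnorm(60 * 500), nrow = 60,
                dimnames = list(sprintf("r%02d", 1:60), NULL))
  atl2 <- manual_atlas(list(big), list(sites_df(matrix(rnorm(1500), 500, 3))))
  sbig <- list_spatial_similarity(rownames(big), atl2)
  expect_lt(abs(sbig$mean), 0.1)
})

test_that("unconstrained random-list null matches hypergeometric expectation", {
  nd <- constrained_random_null(c(120, 80), universe = 1000, observed = 60,
                                n_draws = 2000, seed = 31)
  expect_equal(nd$n_retained, 2000)
  exp_mean <- 120 * 80 / 1000  # 9.6
  se <- nd$sd / sqrt(nd$n_retained)
  expect_lt(abs(nd$mean - exp_mean), 4 * se)
  # far-above-null observation gets the minimum attainable p
  expect_equal(nd$p_value, 1 / 2001)
  # degenerate: both lists are the whole universe
  ndN <- constrained_random_null(c(50, 50), universe = 50, observed = 50,
                                 n_draws = 50, seed = 1)
  expect_true(all(ndN$draws == 50))
  expect_equal(ndN$p_value, 1)
  # determinism
  nd2 <- constrained_random_null(c(120, 80), universe = 1000, observed = 60,
                                 n_draws = 2000, seed = 31)
  expect_identical(nd$draws, nd2$draws)
})

test_that("similarity filter retains only pairs inside both windows", {
  set.seed(5)
  expr <- matrix(rnorm(40 * 200), nrow = 40,
                 dimnames = list(sprintf("g%02d", 1:40), NULL))
  atlas <- manual_atlas(list(expr), list(sites_df(matrix(rnorm(600), 200, 3))))
  # windows centered on the null similarity of independent genes
  filt <- list(mean = c(-0.05, 0.05), sd = c(0, 0.2))
  nd <- constrained_random_null(c(10, 10), rownames(expr), observed = 9,
                                n_draws = 40, filter = filt,
                                gene_atlas = atlas, seed = 8)
  expect_lte(nd$n_retained, nd$n_requested)
  expect_gt(nd$n_retained, 0)
  # impossible windows raise the filter-too-strict error
  bad <- list(mean = c(0.9, 0.95), sd = c(0, 0.001))
  expect_error(constrained_random_null(c(10, 10), rownames(expr), 9,
                                       n_draws = 20, filter = bad,
                                       gene_atlas = atlas, seed = 8),
               "filter too strict")
})

test_that("parcel permutation conserves parcel means and background", {
  g <- toy_grid(c(8, 8, 8), 2)
  aff <- aletx:::grid_geometry(g)$affine
  set.seed(9)
  m <- stat_map(array(rnorm(512), c(8, 8, 8)), aff)
  labs <- array(0L, c(8, 8, 8))
  labs[1:4, , ] <- 1L; labs[5:8, 1:4, ] <- 2L; labs[5:8, 5:8, 1:4] <- 3L
  # leave labs[5:8, 5:8, 5:8] as background
  parc <- parcellation(labs, aff)
  means <- vapply(1:3, function(i) mean(m$values[labs == i]), numeric(1))
  pm <- parcel_permute_map(m, parc, seed = 4)
  got <- vapply(1:3, function(i) unique(pm$values[labs == i]), numeric(1))
  expect_setequal(round(got, 12), round(means, 12))
  expect_equal(pm$values[labs == 0L], m$values[labs == 0L])
  # two-parcel conservation case with means 1 and 5
  m2 <- stat_map(array(rep(c(1, 5), each = 256), c(8, 8, 8)), aff)
  labs2 <- array(rep(1:2, each = 256), c(8, 8, 8))
  parc2 <- parcellation(labs2, aff)
  pm2 <- parcel_permute_map(m2, parc2, seed = 123)
  expect_setequal(unique(as.vector(pm2$values)), c(1, 5))
  # within-parcel variant preserves each parcel's value multiset
  pw <- parcel_permute_map(m, parc, seed = 2, method = "within_parcel")
  for (i in 1:3)
    expect_setequal(pw$values[labs == i], m$values[labs == i])
  expect_error(parcel_permute_map(m, parcellation(array(1L, c(8, 8, 8)),
                                                  aff), seed = 1),
               "at least 2 parcels")
})

test_that("parcel permutation statistics match 4!-enumeration", {
  g <- toy_grid(c(8, 8, 8), 2)
  aff <- aletx:::grid_geometry(g)$affine
  set.seed(14)
  m <- stat_map(array(rnorm(512), c(8, 8, 8)), aff)
  parc <- generate_parcellation(g, 4, seed = 3)
  labs <- parc$labels
  means <- vapply(parc$parcel_ids, function(i) mean(m$values[labs == i]),
                  numeric(1))
  # oracle: mean correlation with the original over all 24 permutations
  perms <- as.matrix(expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 4), ]
  fill <- function(assign_means) {
    v <- m$values
    for (i in 1:4) v[labs == parc$parcel_ids[i]] <- assign_means[i]
    as.vector(v)
  }
  orig <- as.vector(m$values)
  oracle_r <- mean(apply(perms, 1, function(pr) cor(orig, fill(means[pr]))))
  emp <- vapply(1:100, function(s)
    cor(orig, as.vector(parcel_permute_map(m, parc, seed = s)$values)),
    numeric(1))
  # 100 draws from the 24-permutation distribution: compare means
  expect_lt(abs(mean(emp) - oracle_r),
            4 * sd(apply(perms, 1, function(pr) cor(orig, fill(means[pr])))) /
              sqrt(100) + 0.02)
})

test_that("threshold sweep curves and category comparison behave", {
  genes <- sprintf("g%04d", 1:600)
  t_same <- fake_assoc_table(genes, scores = 600:1)
  sw <- threshold_sweep(list(a = t_same, b = t_same), t_same, list(t_same),
                        x_grid = seq(1, 301, by = 10))
  expect_equal(nrow(sw$curves), 31)
  expect_true(all(sw$curves$within_control == 100))
  expect_true(all(sw$curves$inhibition_vs_dmn == 100))
  expect_true(all(sw$curves$inhibition_vs_permutation == 100))

  # an independent random DMN ranking: overlap near chance x/N * 100
  set.seed(20)
  N <- 600
  t_a <- fake_assoc_table(genes, scores = N:1)
  t_b <- fake_assoc_table(sample(genes), scores = N:1)
  t_dmn <- fake_assoc_table(sample(genes), scores = N:1)
  xg <- seq(50, 550, by = 50)
  sw2 <- threshold_sweep(list(a = t_a, b = t_b), t_dmn, list(t_b), xg)
  chance <- 100 * xg / N
  expect_lt(mean(abs(sw2$curves$inhibition_vs_dmn - chance)), 10)

  # truncation warning when x exceeds the ranked lists
  short <- fake_assoc_table(genes[1:50], scores = 50:1)
  expect_warning(threshold_sweep(list(a = short, b = short), short,
                                 list(short), seq(1, 2000, 10)),
                 "truncated")

  # Student-variant category comparison against the hand t value
  obs <- rbind(data.frame(x = 1:3, category = "within_control", pair = "p1",
                          percentage = c(1, 2, 3)),
               data.frame(x = 1:3, category = "inhibition_vs_dmn",
                          pair = "p2", percentage = c(4, 5, 6)))
  fake_curves <- structure(list(curves = NULL, observations = obs),
                           class = "sweep_curves")
  cmp <- compare_categories(fake_curves, var_equal = TRUE)
  expect_equal(cmp$t, (2 - 5) / sqrt(2 / 3), tolerance = 1e-9)
  expect_equal(cmp$mean1, 2)
  expect_equal(cmp$mean2, 5)
  # identical categories: t = 0, p = 1
  obs2 <- obs; obs2$percentage <- c(1, 2, 3, 1, 2, 3)
  same <- structure(list(curves = NULL, observations = obs2),
                    class = "sweep_curves")
  cmp2 <- compare_categories(same)
  expect_equal(cmp2$t, 0)
  expect_equal(cmp2$p, 1)
})

test_that("top-x prefix overlaps are monotone in x", {
  set.seed(33)
  genes <- sprintf("g%03d", 1:200)
  ra <- sample(genes); rb <- sample(genes)
  xg <- seq(1, 200, by = 7)
  counts <- aletx:::prefix_overlap_counts(ra, rb, xg)
  # oracle: direct intersection of prefixes
  oracle <- vapply(xg, function(x) length(intersect(ra[1:x], rb[1:x])), 1L)
  expect_equal(counts, oracle)
  expect_true(all(diff(counts) >= 0))
})
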