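# Shared fixtures built in code: tiny grids, hand-made maps and atlases.

grid8 <- function(voxel = 2) toy_grid(c(8, 8, 8), voxel)

# stat_map from a function of mm coordinates f(x, y, z)
map_from_fun <- function(grid, f) {
  g <- aletx:::grid_geometry(grid)
  cc <- aletx:::inmask_centers(g, NULL)
  vals <- array(f(cc$mm[, 1], cc$mm[, 2], cc$mm[, 3]), dim = g$dim)
  stat_map(vals, g$affine, g$space)
}

# brute-force sphere mean: loop over every voxel center
brute_sphere_mean <- function(map, center, radius) {
  g <- aletx:::grid_geometry(map)
  cc <- aletx:::inmask_centers(g, NULL)
  d <- sqrt((cc$mm[, 1] - center[1])^2 + (cc$mm[, 2] - center[2])^2 +
              (cc$mm[, 3] - center[3])^2)
  inside <- d <= radius
  if (any(inside)) mean(map$values[cc$idx[inside]]) else
    map$values[cc$idx[which.min(d)]]
}

# independent flood-fill labeling (26-neighbor) used as oracle
flood_labels <- function(mask_arr) {
  dims <- dim(mask_arr)
  lab <- array(0L, dims)
  cur <- 0L
  for (s in which(mask_arr)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      ijk <- arrayInd(v, dims)
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        n <- ijk + c(dx, dy, dz)
        if (any(n < 1) || any(n > dims)) next
        w <- n[1] + dims[1] * ((n[2] - 1) + dims[2] * (n[3] - 1))
        if (mask_arr[w] && lab[w] == 0L) { lab[w] <- cur; queue <- c(queue, w) }
      }
    }
  }
  lab
}

# experiments with fixed foci, for hand-checked fixtures
fixed_experiment <- function(id, foci, n = 15) {
  experiment(id = id, n_subjects = n, foci = matrix(foci, ncol = 3,
                                                    byrow = TRUE))
}

# gene-level atlas built from explicit per-donor expression matrices
manual_atlas <- function(expr_list, sites_list) {
  donors <- lapply(seq_along(expr_list), function(i)
    list(sites = sites_list[[i]], expr = expr_list[[i]]))
  names(donors) <- paste0("donor", seq_along(donors))
  expression_atlas(donors, NULL, level = "gene")
}

sites_df <- function(mm, cortical = TRUE) {
  data.frame(site_id = sprintf("s%03d", seq_len(nrow(mm))),
             x = mm[, 1], y = mm[, 2], z = mm[, 3],
             cortical = rep_len(cortical, nrow(mm)),
             stringsAsFactors = FALSE)
}

# a fake association table with a prescribed gene ranking
fake_assoc_table <- function(genes, scores = rev(seq_along(genes)),
                             name = "map") {
  tab <- data.frame(gene = genes, combined_z = scores,
                    combined_r = tanh(scores), t = scores * 3,
                    p = exp(-scores), n_donors = 6L,
                    stringsAsFactors = FALSE)
  attr(tab, "map_name") <- name
  class(tab) <- c("gene_association_table", "data.frame")
  tab
}
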