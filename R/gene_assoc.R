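#' Donor-wise expression atlas
#'
#' Postmortem-atlas-style data: for each donor, a table of sampling sites
#' (MNI mm coordinates plus a cortical flag) and a probe-by-site (or, after
#' [aggregate_probes()], gene-by-site) expression matrix, together with the
#' probe-to-gene map.
#'
#' @param donors named list; each element a list with `sites` (data frame
#'   with columns `site_id`, `x`, `y`, `z`, `cortical`) and `expr` (numeric
#'   matrix, rows = probes or genes with rownames, columns = sites).
#' @param probe_map data frame with columns `probe_id`, `gene_symbol`
#'   (`NULL` once the atlas is gene-level).
#' @param level `"probe"` or `"gene"`.
#' @return An object of class `expression_atlas`.
#' @export
expression_atlas <- function(donors, probe_map = NULL,
                             level = c("probe", "gene")) {
  level <- match.arg(level)
  stopifnot(length(donors) >= 1)
  if (is.null(names(donors))) names(donors) <- paste0("donor", seq_along(donors))
  for (d in names(donors)) {
    dn <- donors[[d]]
    if (nrow(dn$sites) < 2) stop("donor '", d, "' has fewer than 2 sites",
                                 call. = FALSE)
    if (ncol(dn$expr) != nrow(dn$sites))
      stop("donor '", d, "': expression columns must match site count",
           call. = FALSE)
    if (!all(is.finite(dn$expr)))
      stop("donor '", d, "': non-finite expression values", call. = FALSE)
    if (is.null(rownames(dn$expr)))
      stop("donor '", d, "': expression matrix needs rownames", call. = FALSE)
    if (!all(c("x", "y", "z", "cortical") %in% names(dn$sites)))
      stop("donor '", d, "': sites need columns x, y, z, cortical",
           call. = FALSE)
  }
  if (level == "gene" &&
      anyDuplicated(rownames(donors[[1]]$expr)))
    stop("gene-level atlas must have unique gene symbols", call. = FALSE)
  structure(list(donors = donors, probe_map = probe_map, level = level),
            class = "expression_atlas")
}

#' @export
print.expression_atlas <- function(x, ...) {
  ns <- vapply(x$donors, function(d) nrow(d$sites), 1L)
  cat(sprintf("<expression_atlas> %d donors, %d %ss, %s sites/donor\n",
              length(x$donors), nrow(x$donors[[1]]$expr), x$level,
              paste(range(ns), collapse = "-")))
  invisible(x)
}

#' Read/write an expression atlas directory
#'
#' On-disk layout: one subdirectory per donor containing `sites.tsv`
#' (`site_id`, `x`, `y`, `z`, `cortical`), `expression.tsv` (first column
#' the probe/gene id, one column per site) and, for probe-level atlases,
#' `probes.tsv` (`probe_id`, `gene_symbol`).
#'
#' @param dir atlas directory.
#' @return An [expression_atlas()].
#' @export
read_expression_atlas <- function(dir) {
  dds <- sort(list.dirs(dir, recursive = FALSE))
  if (!length(dds)) stop("no donor subdirectories in ", dir, call. = FALSE)
  probe_map <- NULL
  donors <- lapply(dds, function(dd) {
    sites <- read.delim(file.path(dd, "sites.tsv"), sep = "\t",
                        stringsAsFactors = FALSE)
    sites$cortical <- as.logical(sites$cortical)
    em <- read.delim(file.path(dd, "expression.tsv"), sep = "\t",
                     check.names = FALSE, stringsAsFactors = FALSE)
    expr <- as.matrix(em[, -1, drop = FALSE])
    rownames(expr) <- em[[1]]
    pf <- file.path(dd, "probes.tsv")
    if (file.exists(pf))
      probe_map <<- read.delim(pf, sep = "\t", stringsAsFactors = FALSE)
    list(sites = sites, expr = expr)
  })
  names(donors) <- basename(dds)
  expression_atlas(donors, probe_map,
                   level = if (is.null(probe_map)) "gene" else "probe")
}

#' @param atlas an [expression_atlas()].
#' @rdname read_expression_atlas
#' @export
write_expression_atlas <- function(atlas, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (d in names(atlas$donors)) {
    dd <- file.path(dir, d)
    dir.create(dd, showWarnings = FALSE)
    dn <- atlas$donors[[d]]
    write.table(dn$sites, file.path(dd, "sites.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    em <- data.frame(id = rownames(dn$expr), dn$expr, check.names = FALSE)
    names(em)[1] <- if (atlas$level == "probe") "probe_id" else "gene_symbol"
    write.table(em, file.path(dd, "expression.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    if (!is.null(atlas$probe_map))
      write.table(atlas$probe_map, file.path(dd, "probes.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' Aggregate probes to gene level
#'
#' Averages, per site, all probes mapping to the same gene symbol. Probes
#' without a gene mapping are excluded (count reported via `message`).
#'
#' @param atlas a probe-level [expression_atlas()].
#' @return A gene-level [expression_atlas()]; rows are the distinct mapped
#'   genes, sorted.
#' @export
aggregate_probes <- function(atlas) {
  stopifnot(inherits(atlas, "expression_atlas"))
  if (atlas$level == "gene") return(atlas)
  pm <- atlas$probe_map
  donors <- lapply(atlas$donors, function(dn) {
    probes <- rownames(dn$expr)
    gene <- pm$gene_symbol[match(probes, pm$probe_id)]
    drop <- is.na(gene) | gene == ""
    if (any(drop))
      message(sum(drop), " probe(s) without gene mapping excluded")
    expr <- dn$expr[!drop, , drop = FALSE]
    gene <- gene[!drop]
    agg <- rowsum(expr, group = gene)
    cnt <- table(gene)
    agg <- agg / as.vector(cnt[rownames(agg)])
    list(sites = dn$sites, expr = agg)
  })
  expression_atlas(donors, probe_map = NULL, level = "gene")
}

#' Sample a statistic map at atlas sites
#'
#' For every retained sampling site (cortical sites only, by default, per
#' the cortical restriction of the association analysis) the mean map
#' value inside a spherical ROI of `radius` mm is extracted.
#'
#' @param map a [stat_map()].
#' @param atlas an [expression_atlas()].
#' @param radius sphere radius, mm (4 mm default).
#' @param cortical_only drop non-cortical sites before sampling.
#' @return Named list, one numeric vector per donor (with a `sites`
#'   attribute giving the retained site indices).
#' @export
map_values_at_sites <- function(map, atlas, radius = 4,
                                cortical_only = TRUE) {
  stopifnot(inherits(map, "stat_map"), inherits(atlas, "expression_atlas"))
  out <- lapply(atlas$donors, function(dn) {
    keep <- if (cortical_only) which(dn$sites$cortical) else
      seq_len(nrow(dn$sites))
    if (!length(keep))
      stop("all sites excluded by the cortical restriction", call. = FALSE)
    v <- vapply(keep, function(i)
      sample_sphere_mean(map, c(dn$sites$x[i], dn$sites$y[i], dn$sites$z[i]),
                         radius), numeric(1))
    attr(v, "sites") <- keep
    v
  })
  out
}

#' Per-donor gene-map correlations
#'
#' Pearson correlation, per gene and donor, between the gene's expression
#' across retained sites and the map values at those sites. Genes with
#' zero expression variance in a donor are recorded as `NA` for that
#' donor (not propagated as errors).
#'
#' @param gene_atlas gene-level [expression_atlas()].
#' @param map_vectors output of [map_values_at_sites()].
#' @return Numeric matrix, genes x donors.
#' @export
donor_correlations <- function(gene_atlas, map_vectors) {
  stopifnot(gene_atlas$level == "gene",
            identical(names(gene_atlas$donors), names(map_vectors)))
  genes <- rownames(gene_atlas$donors[[1]]$expr)
  out <- matrix(NA_real_, nrow = length(genes), ncol = length(map_vectors),
                dimnames = list(genes, names(map_vectors)))
  for (d in names(map_vectors)) {
    mv <- map_vectors[[d]]
    keep <- attr(mv, "sites")
    if (length(mv) < 3)
      stop("donor '", d, "' has fewer than 3 retained sites", call. = FALSE)
    if (sd(mv) == 0)
      stop("map has zero variance across donor '", d,
           "' sampling sites; association undefined", call. = FALSE)
    expr <- gene_atlas$donors[[d]]$expr[, keep, drop = FALSE]
    sds <- apply(expr, 1, sd)
    ok <- sds > 0
    if (any(ok))
      out[rownames(expr)[ok], d] <-
        as.vector(cor(as.numeric(mv), t(expr[ok, , drop = FALSE])))
  }
  out
}

#' Random-effects combination of donor correlations
#'
#' Fisher z-transforms the per-donor correlations and tests their mean
#' against zero with a one-sample t-test across donors (one-sided,
#' positive association, matching the positive-only gene selection). The
#' combined correlation is `tanh(mean z)`.
#'
#' @param rs per-donor correlation values (`NA`s dropped).
#' @return List with `combined_r`, `combined_z`, `t`, `p` (one-sided),
#'   `n_donors`, `zero_variance` flag. With zero variance across donors
#'   and nonzero mean, `p` is set to the smallest representable double and
#'   flagged.
#' @export
combine_random_effects <- function(rs) {
  rs <- rs[!is.na(rs)]
  if (length(rs) < 2)
    stop("insufficient donors: need >= 2 defined correlations", call. = FALSE)
  z <- atanh(pmin(pmax(rs, -1 + 1e-15), 1 - 1e-15))
  k <- length(z)
  mz <- mean(z)
  s <- sd(z)
  if (s == 0) {
    p <- if (mz > 0) .Machine$double.xmin else if (mz < 0) 1 else 0.5
    return(list(combined_r = tanh(mz), combined_z = mz,
                t = if (mz == 0) 0 else sign(mz) * Inf, p = p,
                n_donors = k, zero_variance = TRUE))
  }
  tstat <- mz / (s / sqrt(k))
  list(combined_r = tanh(mz), combined_z = mz, t = tstat,
       p = pt(tstat, df = k - 1, lower.tail = FALSE),
       n_donors = k, zero_variance = FALSE)
}

#' Activation-gene-expression association table
#'
#' The full association pipeline for one statistic map: sphere-sample the
#' map at every retained atlas site, correlate each gene's expression with
#' the map per donor, and combine across donors with the random-effects
#' model.
#'
#' @param gene_atlas gene-level [expression_atlas()] (probe-level input is
#'   aggregated first).
#' @param map a [stat_map()].
#' @param radius sphere radius, mm.
#' @param cortical_only restrict to cortical sites.
#' @return Data frame (one row per gene) with `gene`, `combined_z`,
#'   `combined_r`, `t`, `p`, `n_donors`; per-donor correlations in
#'   `attr(, "donor_r")`. Genes defined in fewer than 2 donors are
#'   excluded (count via `message`).
#' @export
gene_association_table <- function(gene_atlas, map, radius = 4,
                                   cortical_only = TRUE) {
  if (gene_atlas$level == "probe") gene_atlas <- aggregate_probes(gene_atlas)
  mv <- map_values_at_sites(map, gene_atlas, radius = radius,
                            cortical_only = cortical_only)
  rmat <- donor_correlations(gene_atlas, mv)
  n_def <- rowSums(!is.na(rmat))
  drop <- n_def < 2
  if (any(drop))
    message(sum(drop), " gene(s) defined in fewer than 2 donors excluded")
  rmat <- rmat[!drop, , drop = FALSE]
  comb <- apply(rmat, 1, combine_random_effects)
  tab <- data.frame(
    gene = rownames(rmat),
    combined_z = vapply(comb, `[[`, 1, "combined_z"),
    combined_r = vapply(comb, `[[`, 1, "combined_r"),
    t = vapply(comb, `[[`, 1, "t"),
    p = vapply(comb, `[[`, 1, "p"),
    n_donors = vapply(comb, `[[`, 1L, "n_donors"),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  attr(tab, "donor_r") <- rmat
  attr(tab, "map_name") <- attr(map, "name") %||% "map"
  class(tab) <- c("gene_association_table", "data.frame")
  tab
}

#' Top-x associated gene list
#'
#' Ranks genes by the combined Fisher-z statistic, descending, among genes
#' with a positive combined correlation (negative associations are not
#' interpreted), and returns the top `x`. Ties break by gene symbol.
#'
#' @param table a [gene_association_table()].
#' @param x list-size threshold (e.g. 500, 1000, 1500, 2000).
#' @param rank_by `"combined_z"` (default) or `"p"`; the orders coincide
#'   when every gene is measured in the same number of donors.
#' @return Character vector of gene symbols (class `gene_list`) with
#'   attributes `threshold` and `source`. Empty, with a warning, when no
#'   gene is positively correlated.
#' @export
select_top_genes <- function(table, x, rank_by = c("combined_z", "p")) {
  rank_by <- match.arg(rank_by)
  stopifnot(x >= 1)
  pos <- table[table$combined_r > 0, , drop = FALSE]
  if (!nrow(pos)) {
    warning("no positively correlated genes; returning empty list",
            call. = FALSE)
    return(structure(character(), class = "gene_list", threshold = x,
                     source = attr(table, "map_name")))
  }
  ord <- if (rank_by == "combined_z") order(-pos$combined_z, pos$gene) else
    order(pos$p, pos$gene)
  genes <- pos$gene[ord][seq_len(min(x, nrow(pos)))]
  structure(genes, class = "gene_list", threshold = x,
            source = attr(table, "map_name"))
}
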