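#' Genotype matrix container
#'
#' Holds alt-allele dosages (0/1/2, `NA` for missing) for individuals x
#' biallelic SNP loci, an optional read-depth matrix of the same shape, and
#' optional reference coordinates (data frame `individual, lat, lon` and
#' optionally `population`) for reference individuals; query individuals
#' (rafts of unknown origin) simply have no coordinate row.
#'
#' @param genotypes Integer matrix (individuals x loci), dimnames required.
#' @param depths Optional numeric matrix of per-cell read depths.
#' @param coords Optional data frame with columns `individual, lat, lon`
#'   (and optionally `population`).
#' @return A `genotype_matrix` list.
#' @export
genotype_matrix <- function(genotypes, depths = NULL, coords = NULL) {
  genotypes <- as.matrix(genotypes)
  if (is.null(rownames(genotypes)))
    rownames(genotypes) <- paste0("ind", seq_len(nrow(genotypes)))
  if (is.null(colnames(genotypes)))
    colnames(genotypes) <- paste0("snp", seq_len(ncol(genotypes)))
  ok <- genotypes %in% c(0, 1, 2) | is.na(genotypes)
  if (!all(ok)) stop("genotype_matrix: genotypes must be 0, 1, 2 or NA")
  if (!is.null(depths)) {
    depths <- as.matrix(depths)
    stopifnot(all(dim(depths) == dim(genotypes)), all(depths >= 0, na.rm = TRUE))
  }
  structure(list(genotypes = genotypes, depths = depths, coords = coords),
            class = "genotype_matrix")
}

#' SNP and individual filtering
#'
#' Applies, in order: (1) depth masking - cells with read depth below
#' `min_depth` are set missing; (2) locus filters - loci with missingness
#' above `max_missing` or minor allele count below `min_mac` are dropped;
#' (3) individual filter - individuals retaining fewer than
#' `min_snps_per_ind` called loci are dropped. Defaults follow the
#' GBS filtering protocol: depth >= 5, missingness <= 0.2, MAC >= 2,
#' >= 5000 SNPs per individual.
#'
#' @param g A [genotype_matrix()].
#' @param min_depth Minimum read depth for a call (cells below become `NA`).
#' @param max_missing Maximum per-locus missingness proportion.
#' @param min_mac Minimum minor allele count per locus.
#' @param min_snps_per_ind Minimum called loci per retained individual.
#' @return A filtered [genotype_matrix()].
#' @export
filter_genotypes <- function(g, min_depth = 5, max_missing = 0.2,
                             min_mac = 2, min_snps_per_ind = 5000) {
  stopifnot(min_depth >= 0, max_missing >= 0, min_mac >= 0,
            min_snps_per_ind >= 0)
  gt <- g$genotypes
  dp <- g$depths
  if (!is.null(dp)) gt[dp < min_depth] <- NA
  miss <- colMeans(is.na(gt))
  alt <- colSums(gt, na.rm = TRUE)
  ncall <- colSums(!is.na(gt))
  mac <- pmin(alt, 2 * ncall - alt)          # minor allele count
  keep_loci <- miss <= max_missing & mac >= min_mac
  if (!any(keep_loci))
    stop("filter_genotypes: all loci removed; empty panel")
  gt <- gt[, keep_loci, drop = FALSE]
  if (!is.null(dp)) dp <- dp[, keep_loci, drop = FALSE]
  keep_ind <- rowSums(!is.na(gt)) >= min_snps_per_ind
  if (!any(keep_ind))
    stop("filter_genotypes: all individuals removed")
  gt <- gt[keep_ind, , drop = FALSE]
  if (!is.null(dp)) dp <- dp[keep_ind, , drop = FALSE]
  coords <- g$coords
  if (!is.null(coords))
    coords <- coords[coords$individual %in% rownames(gt), , drop = FALSE]
  genotype_matrix(gt, dp, coords)
}

#' Pairwise genotype distance
#'
#' Distance between two individuals is the mean, over loci called in both,
#' of `|g_i - g_j| / 2`; it lies in [0, 1], attaining 1 only for opposite
#' homozygotes at every shared locus. A stand-in metric for tree building
#' from dosage data.
#'
#' @param g A [genotype_matrix()].
#' @return A `dist` object over individuals.
#' @export
genotype_distance <- function(g) {
  gt <- g$genotypes
  if (nrow(gt) < 3) stop("genotype_distance: need >= 3 individuals")
  n <- nrow(gt)
  called <- !is.na(gt)
  gt0 <- gt; gt0[!called] <- 0
  # sum over co-called loci of |gi - gj| via the identity on dosage levels
  ind <- lapply(0:2, function(v) (gt == v & called) * 1)
  co <- called %*% t(called)
  if (any(co[upper.tri(co)] == 0)) {
    bad <- which(co == 0 & upper.tri(co), arr.ind = TRUE)[1, ]
    stop(sprintf("genotype_distance: individuals %s and %s share no called loci",
                 rownames(gt)[bad[1]], rownames(gt)[bad[2]]))
  }
  # |gi-gj| = 1*(het vs hom) + 2*(opposite hom)
  d_sum <- ind[[1]] %*% t(ind[[2]]) + ind[[2]] %*% t(ind[[1]]) +
    ind[[2]] %*% t(ind[[3]]) + ind[[3]] %*% t(ind[[2]]) +
    2 * (ind[[1]] %*% t(ind[[3]]) + ind[[3]] %*% t(ind[[1]]))
  d <- (d_sum / co) / 2
  rownames(d) <- colnames(d) <- rownames(gt)
  stats::as.dist(d)
}

#' Neighbour-joining tree with locus-bootstrap supports
#'
#' Builds a neighbour-joining tree on [genotype_distance()], midpoint-roots
#' it, and attaches internal-node supports as the percentage of
#' locus-resampled bootstrap trees containing each bipartition. NJ plus
#' bootstrap stands in for maximum-likelihood inference; the assignment rule
#' downstream only consumes topology and supports.
#'
#' @param g A [genotype_matrix()] with >= 4 individuals.
#' @param n_boot Number of bootstrap resamplings of loci (default 100).
#' @param seed Integer RNG seed.
#' @return An [ape::phylo] tree with `node.label` holding percent supports.
#' @export
build_support_tree <- function(g, n_boot = 100, seed = 1L) {
  if (nrow(g$genotypes) < 4) stop("build_support_tree: need >= 4 individuals")
  if (n_boot < 1) stop("build_support_tree: n_boot must be >= 1")
  build <- function(gm) {
    tr <- ape::nj(genotype_distance(genotype_matrix(gm)))
    tr$edge.length[tr$edge.length < 0] <- 0
    phangorn::midpoint(tr)
  }
  tree <- build(g$genotypes)
  L <- ncol(g$genotypes)
  counts <- withr::with_seed(seed, {
    boots <- lapply(seq_len(n_boot), function(b) {
      loci <- sample.int(L, L, replace = TRUE)
      build(g$genotypes[, loci, drop = FALSE])
    })
    ape::prop.clades(tree, boots, rooted = FALSE)
  })
  counts[is.na(counts)] <- 0
  sup <- round(100 * counts / n_boot, 1)
  sup[1] <- 100  # root bipartition is trivial
  tree$node.label <- sup
  tree
}

#' Source assignment by clade traversal
#'
#' Ascends from a query tip toward the root and stops at the first internal
#' node whose bootstrap support exceeds `support_threshold` (default 80) and
#' whose clade contains at least one reference individual. The reference
#' coordinates spanned by that clade become the inferred source; the
#' confidence tier reflects the clade's spatial extent: a single population
#' is `population`, a span up to `localized_km` is `localized_region`, wider
#' is `broad_region`. If no node on the root path qualifies the query is
#' `unassigned`.
#'
#' @param tree A support tree from [build_support_tree()].
#' @param query Tip label of the query individual.
#' @param ref_coords Data frame `individual, lat, lon` (optionally
#'   `population`) for reference individuals.
#' @param support_threshold Percent support required (default 80; the rule
#'   is support strictly greater than the threshold).
#' @param localized_km Maximum span (km) for the `localized_region` tier.
#' @return A list of class `source_assignment` with `query`, `tier`,
#'   `locations` (data frame), `anchor_support`.
#' @export
assign_source <- function(tree, query, ref_coords, support_threshold = 80,
                          localized_km = 150) {
  tip_idx <- match(query, tree$tip.label)
  if (is.na(tip_idx)) stop("assign_source: query not found in tree: ", query)
  ntip <- length(tree$tip.label)
  parent_of <- function(node) tree$edge[tree$edge[, 2] == node, 1]
  supports <- suppressWarnings(as.numeric(tree$node.label))
  node <- tip_idx
  repeat {
    p <- parent_of(node)
    if (length(p) == 0) break  # reached the root without a qualifying node
    sup <- supports[p - ntip]
    tips <- ape::extract.clade(tree, p)$tip.label
    refs <- ref_coords[ref_coords$individual %in% setdiff(tips, query), ,
                       drop = FALSE]
    if (!is.na(sup) && sup > support_threshold && nrow(refs) > 0) {
      span <- 0
      if (nrow(refs) > 1) {
        pr <- t(utils::combn(nrow(refs), 2))
        span <- max(haversine_km(refs$lat[pr[, 1]], refs$lon[pr[, 1]],
                                 refs$lat[pr[, 2]], refs$lon[pr[, 2]]))
      }
      single_pop <- if ("population" %in% names(refs))
        length(unique(refs$population)) == 1 else span == 0
      tier <- if (single_pop) "population"
      else if (span <= localized_km) "localized_region"
      else "broad_region"
      return(structure(list(query = query, tier = tier, locations = refs,
                            anchor_support = sup, span_km = span),
                       class = "source_assignment"))
    }
    node <- p
  }
  structure(list(query = query, tier = "unassigned",
                 locations = ref_coords[0, , drop = FALSE],
                 anchor_support = NA_real_, span_km = NA_real_),
            class = "source_assignment")
}

#' Convert a source assignment to a drift target zone
#'
#' The zone is the stretch of coastline between the two most distant
#' assigned reference locations (inclusive), each coastline point matched by
#' nearest neighbour, buffered by the drift hit radius. Ties in "most
#' distant" are broken by first occurrence in tip order.
#'
#' @param a A `source_assignment` with non-empty locations.
#' @param coastline Data frame `lat, lon` of ordered coastline points.
#' @param buffer_km Hit radius for the resulting [target_zone()] (default 2).
#' @return A [target_zone()].
#' @export
assignment_to_zone <- function(a, coastline, buffer_km = 2) {
  if (a$tier == "unassigned" || nrow(a$locations) == 0)
    stop("assignment_to_zone: query is unassigned; skip drift modelling")
  loc <- a$locations
  nearest <- vapply(seq_len(nrow(loc)), function(i)
    which.min(haversine_km(loc$lat[i], loc$lon[i],
                           coastline$lat, coastline$lon)), 1L)
  if (nrow(loc) == 1) {
    i <- nearest[1]
    return(target_zone(coastline$lat[i], coastline$lon[i], buffer_km))
  }
  pr <- t(utils::combn(nrow(loc), 2))
  dd <- haversine_km(loc$lat[pr[, 1]], loc$lon[pr[, 1]],
                     loc$lat[pr[, 2]], loc$lon[pr[, 2]])
  best <- pr[which.max(dd), ]   # which.max takes the first maximum (ties)
  rng <- sort(nearest[best])
  idx <- rng[1]:rng[2]
  target_zone(coastline$lat[idx], coastline$lon[idx], buffer_km)
}

#' Read / write genotype matrices as TSV
#'
#' The genotype TSV has individuals as rows and loci as columns, cells
#' 0/1/2/NA; an optional depth TSV shares the layout; coordinates are a TSV
#' `individual, lat, lon[, population]`.
#'
#' @param path Genotype TSV path.
#' @param depths_path,coords_path Optional companion files.
#' @return A [genotype_matrix()].
#' @export
read_genotypes_tsv <- function(path, depths_path = NULL, coords_path = NULL) {
  gt <- as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
  dp <- if (!is.null(depths_path))
    as.matrix(utils::read.delim(depths_path, row.names = 1, check.names = FALSE))
  co <- if (!is.null(coords_path)) utils::read.delim(coords_path)
  genotype_matrix(gt, dp, co)
}

#' @rdname read_genotypes_tsv
#' @param g A [genotype_matrix()].
#' @export
write_genotypes_tsv <- function(g, path, depths_path = NULL,
                                coords_path = NULL) {
  utils::write.table(g$genotypes, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  if (!is.null(depths_path) && !is.null(g$depths))
    utils::write.table(g$depths, depths_path, sep = "\t", quote = FALSE,
                       col.names = NA)
  if (!is.null(coords_path) && !is.null(g$coords))
    utils::write.table(g$coords, coords_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}
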