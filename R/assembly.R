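#' Phylogenetic binning of an ASV tree
#'
#' Partitions tree tips into bins of at least `min_bin` taxa (default 24,
#' the bin size used by the binned assembly framework). Clades are visited
#' bottom-up; the first time a clade's unassigned tips reach `min_bin` they
#' are emitted as a bin. Tips left over at the root are merged into the
#' nearest bin by mean cophenetic distance. With fewer tips than `min_bin`
#' the whole tree becomes a single bin, with a warning.
#'
#' @param tree An [ape::phylo] with all table taxa as tips.
#' @param min_bin Minimum bin size (default 24).
#' @return A list of character vectors (bins); the vectors partition
#'   `tree$tip.label`.
#' @export
bin_tree <- function(tree, min_bin = 24) {
  ntip <- length(tree$tip.label)
  if (ntip < min_bin) {
    warning("bin_tree: fewer tips than min_bin; single-bin fallback")
    return(list(tree$tip.label))
  }
  tips_of <- function(node) {
    if (node <= ntip) return(node)
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, tips_of))
  }
  assigned <- rep(FALSE, ntip)
  bins <- list()
  # postorder edge matrix lists children before parents
  po <- stats::reorder(tree, "postorder")
  nodes <- unique(po$edge[, 1])
  for (node in nodes) {
    tp <- tips_of(node)
    un <- tp[!assigned[tp]]
    if (length(un) >= min_bin) {
      bins[[length(bins) + 1]] <- tree$tip.label[un]
      assigned[un] <- TRUE
    }
  }
  left <- which(!assigned)
  if (length(left)) {
    coph <- stats::cophenetic(tree)
    for (i in left) {
      dists <- vapply(bins, function(b)
        mean(coph[tree$tip.label[i], b]), 0)
      j <- which.min(dists)
      bins[[j]] <- c(bins[[j]], tree$tip.label[i])
    }
  }
  bins
}

# columnwise minima of a matrix via pmin (fast, no extra deps)
.row_mins <- function(m) do.call(pmin, as.data.frame(m))

# abundance-weighted beta mean nearest taxon distance between two relative
# abundance vectors (named by taxon) on a cophenetic matrix
.bmntd <- function(pa, pb, coph) {
  ta <- names(pa); tb <- names(pb)
  d <- coph[ta, tb, drop = FALSE]
  mina <- .row_mins(d)                 # per taxon in a: nearest in b
  minb <- .row_mins(t(d))              # per taxon in b: nearest in a
  0.5 * (sum(pa * mina) + sum(pb * minb))
}

#' Beta nearest taxon index for a sample pair within a bin
#'
#' Computes the abundance-weighted beta mean nearest taxon distance
#' (betaMNTD) between two communities restricted to a phylogenetic bin, and
#' standardises it against a null distribution obtained by shuffling each
#' community's bin taxa across the bin's own tips (independent shuffles for
#' the two communities) `n_null` times:
#' `betaNTI = (observed - null mean) / null sd`, so that identical
#' communities - whose observed betaMNTD of 0 is the minimum of the null
#' support - score strongly negative. A degenerate null (sd = 0, e.g. a
#' star tree) yields `bnti = 0` with `degenerate = TRUE`.
#'
#' @param a,b Count (or relative abundance) vectors named by taxon.
#' @param bin Character vector of bin member taxa.
#' @param coph Cophenetic distance matrix of the full tree (taxon x taxon).
#' @param n_null Number of null shuffles (default 100).
#' @param seed Integer RNG seed.
#' @return List with `bnti`, `observed`, `null_mean`, `null_sd`,
#'   `null_quantiles` (2.5/50/97.5 percent), `degenerate`.
#' @export
bnti_pair <- function(a, b, bin, coph, n_null = 100, seed = 1L) {
  pa <- a[bin][a[bin] > 0]
  pb <- b[bin][b[bin] > 0]
  if (!length(pa) || !length(pb))
    stop("bnti_pair: a sample has no bin member present")
  pa <- pa / sum(pa); pb <- pb / sum(pb)
  cb <- coph[bin, bin, drop = FALSE]
  obs <- .bmntd(pa, pb, cb)
  nb <- length(bin)
  nulls <- withr::with_seed(seed, {
    vapply(seq_len(n_null), function(k) {
      # independent random tip placements for each community
      ia <- stats::setNames(sample.int(nb), bin)
      ib <- stats::setNames(sample.int(nb), bin)
      d <- cb[ia[names(pa)], ib[names(pb)], drop = FALSE]
      0.5 * (sum(pa * .row_mins(d)) + sum(pb * .row_mins(base::t(d))))
    }, 0)
  })
  mu <- mean(nulls); sdv <- stats::sd(nulls)
  degen <- !is.finite(sdv) || sdv < 1e-12
  list(bnti = if (degen) 0 else (obs - mu) / sdv,
       observed = obs, null_mean = mu, null_sd = sdv,
       null_quantiles = stats::quantile(nulls, c(0.025, 0.5, 0.975),
                                        names = FALSE),
       degenerate = degen)
}

# draw one null community preserving richness and total abundance:
# occupancy-weighted colonisation, abundance-weighted filling
.rc_null_draw <- function(richness, total, pool_occ, pool_abund) {
  taxa <- names(pool_occ)
  k <- min(richness, length(taxa))
  chosen <- sample(taxa, k, prob = pool_occ)
  x <- stats::setNames(rep(1, k), chosen)
  extra <- total - k
  if (extra > 0) {
    pr <- pool_abund[chosen]
    add <- stats::rmultinom(1, extra, prob = pr / sum(pr))[, 1]
    x <- x + add
  }
  out <- stats::setNames(numeric(length(taxa)), taxa)
  out[chosen] <- x
  out
}

#' Raup-Crick metric with Bray-Curtis
#'
#' Position of the observed Bray-Curtis dissimilarity within a null
#' distribution of communities drawn from the regional pool preserving each
#' sample's richness and total abundance (colonists weighted by pool
#' occupancy, individuals by pool abundance), rescaled to [-1, 1]:
#' `RC = 2 * (P(null < obs) + 0.5 P(null = obs)) - 1`.
#'
#' @param a,b Equal-depth count vectors named by taxon.
#' @param pool_occ Named occupancy weights of the taxon pool.
#' @param pool_abund Named abundance weights of the taxon pool.
#' @param n_null Number of null draws (default 100).
#' @param seed Integer RNG seed.
#' @return Scalar RCbray in [-1, 1].
#' @export
rcbray_pair <- function(a, b, pool_occ, pool_abund, n_null = 100, seed = 1L) {
  if (!length(pool_occ) || all(pool_occ == 0)) stop("rcbray_pair: empty pool")
  if (is.null(names(pool_occ))) names(pool_occ) <- names(a)
  if (is.null(names(pool_abund))) names(pool_abund) <- names(a)
  if (is.null(names(pool_occ))) names(pool_occ) <-
      paste0("t", seq_along(pool_occ))
  if (is.null(names(pool_abund))) names(pool_abund) <- names(pool_occ)
  bc <- function(x, y) sum(abs(x - y)) / sum(x + y)
  obs <- bc(a, b)
  ra <- sum(a > 0); rb <- sum(b > 0)
  ta <- sum(a); tb <- sum(b)
  nulls <- withr::with_seed(seed, {
    vapply(seq_len(n_null), function(k) {
      na <- .rc_null_draw(ra, ta, pool_occ, pool_abund)
      nb <- .rc_null_draw(rb, tb, pool_occ, pool_abund)
      bc(na, nb)
    }, 0)
  })
  eps <- 1e-12
  2 * (mean(nulls < obs - eps) + 0.5 * mean(abs(nulls - obs) <= eps)) - 1
}

# five-way decision tree from bNTI (or confidence exceedance) and RCbray
.classify_process <- function(selected, direction, rc, rc_threshold = 0.95) {
  if (selected) {
    if (direction > 0) "heterogeneous_selection" else "homogeneous_selection"
  } else if (!is.na(rc) && rc > rc_threshold) {
    "dispersal_limitation"
  } else if (!is.na(rc) && rc < -rc_threshold) {
    "homogenizing_dispersal"
  } else "drift"
}

#' Partition community assembly processes
#'
#' For every admissible sample pair and every phylogenetic bin, infers the
#' governing assembly process: selection when the phylogenetic turnover is
#' extreme (|betaNTI| > `bnti_threshold` in `ses` mode, or observed
#' betaMNTD outside the central 95 percent of its null in `confidence`
#' mode), signed heterogeneous (+) vs homogeneous (-); otherwise dispersal
#' limitation (`RCbray > rc_threshold`), homogenizing dispersal
#' (`RCbray < -rc_threshold`) or drift. Non-raft pairs can be restricted to
#' within-population comparisons to respect meta-community structure (the
#' default, matching the within-population turnover rule). Bin calls are
#' aggregated to group-level fractions weighting each bin by the mean
#' relative abundance of its taxa across the pair.
#'
#' @param t A rarefied [community_table()] with `status` and `population`
#'   metadata.
#' @param tree [ape::phylo] containing all table taxa.
#' @param n_null Null draws for both metrics (default 100).
#' @param min_bin Bin size (default 24).
#' @param bnti_threshold,rc_threshold Decision thresholds (1.96, 0.95).
#' @param mode `"confidence"` (null-quantile exceedance, the default) or
#'   `"ses"` (standard-effect size).
#' @param within_population_for_nonrafts Restrict non-raft pairs to the same
#'   population (default TRUE).
#' @param seed Integer RNG seed.
#' @return A list of class `process_fractions`: `fractions` (group x
#'   process data frame), `pairs` (per-pair-per-bin calls), `bins`.
#' @export
partition_processes <- function(t, tree, n_null = 100, min_bin = 24,
                                bnti_threshold = 1.96, rc_threshold = 0.95,
                                mode = c("confidence", "ses"),
                                within_population_for_nonrafts = TRUE,
                                seed = 1L) {
  mode <- match.arg(mode)
  cnt <- t$counts
  taxa <- colnames(cnt)
  if (!all(taxa %in% tree$tip.label))
    stop("partition_processes: tree is missing table taxa")
  tree <- ape::keep.tip(tree, taxa)
  coph <- stats::cophenetic(tree)
  bins <- bin_tree(tree, min_bin)
  md <- t$metadata
  groups <- intersect(c("non_raft", "raft"), unique(md$status))
  processes <- c("heterogeneous_selection", "homogeneous_selection",
                 "dispersal_limitation", "homogenizing_dispersal", "drift")
  pool_occ <- colMeans(cnt > 0)
  pool_abund <- colSums(cnt) / sum(cnt)
  pair_rows <- list()
  frac <- list()
  for (grp in groups) {
    smp <- rownames(cnt)[md$status == grp]
    if (length(smp) < 2) stop("partition_processes: group ", grp, " too small")
    pr <- base::t(utils::combn(length(smp), 2))
    if (grp == "non_raft" && within_population_for_nonrafts &&
        "population" %in% names(md)) {
      pops <- md$population[match(smp, md$sample)]
      keep <- pops[pr[, 1]] == pops[pr[, 2]]
      pr <- pr[keep, , drop = FALSE]
    }
    if (nrow(pr) < 2)
      stop("partition_processes: group ", grp, " has < 2 admissible pairs")
    pair_frac <- matrix(0, nrow(pr), length(processes),
                        dimnames = list(NULL, processes))
    for (q in seq_len(nrow(pr))) {
      sa <- smp[pr[q, 1]]; sb <- smp[pr[q, 2]]
      a <- cnt[sa, ]; b <- cnt[sb, ]
      w <- numeric(length(bins))
      calls <- character(length(bins))
      for (bi in seq_along(bins)) {
        bintaxa <- bins[[bi]]
        pa_present <- sum(a[bintaxa]) > 0
        pb_present <- sum(b[bintaxa]) > 0
        w[bi] <- mean(c(sum(a[bintaxa]) / sum(a), sum(b[bintaxa]) / sum(b)))
        if (!pa_present || !pb_present) { calls[bi] <- NA_character_; next }
        seed_qb <- (seed + 7919L * q + 104729L * bi) %% .Machine$integer.max
        bn <- bnti_pair(a, b, bintaxa, coph, n_null = n_null, seed = seed_qb)
        if (mode == "ses") {
          selected <- !bn$degenerate && abs(bn$bnti) > bnti_threshold
          direction <- bn$bnti
        } else {
          selected <- !bn$degenerate &&
            (bn$observed < bn$null_quantiles[1] ||
               bn$observed > bn$null_quantiles[3])
          direction <- bn$observed - bn$null_quantiles[2]
        }
        rc <- NA_real_
        if (!selected) {
          ab <- a[bintaxa]; bb <- b[bintaxa]
          rc <- rcbray_pair(ab, bb,
                            pool_occ[bintaxa] + 1e-9,
                            pool_abund[bintaxa] + 1e-9,
                            n_null = n_null, seed = seed_qb + 1L)
        }
        calls[bi] <- .classify_process(selected, direction, rc, rc_threshold)
        pair_rows[[length(pair_rows) + 1]] <-
          data.frame(group = grp, sample_a = sa, sample_b = sb, bin = bi,
                     weight = w[bi], bnti = bn$bnti, observed_bmntd = bn$observed,
                     rcbray = rc, process = calls[bi])
      }
      ok <- !is.na(calls)
      if (!any(ok)) next
      wq <- w[ok] / sum(w[ok])
      for (k in which(ok))
        pair_frac[q, calls[k]] <- pair_frac[q, calls[k]] + w[k] / sum(w[ok])
    }
    frac[[grp]] <- colMeans(pair_frac)
  }
  fractions <- do.call(rbind, lapply(names(frac), function(g)
    data.frame(group = g, t(frac[[g]]))))
  structure(list(fractions = fractions,
                 pairs = do.call(rbind, pair_rows),
                 bins = bins, mode = mode, n_null = n_null, seed = seed),
            class = "process_fractions")
}
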