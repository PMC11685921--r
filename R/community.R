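#' Community table container
#'
#' Samples x taxa counts with per-sample metadata. Metadata must contain a
#' `status` column (`raft`, `non_raft` or `seawater`); `population`,
#' `raft_time`, `sst` and `sigma_sst` are carried when available and feed
#' the statistical layer.
#'
#' @param counts Non-negative integer matrix, samples in rows, taxa (ASVs)
#'   in columns; dimnames required.
#' @param metadata Data frame keyed by `sample` with at least a `status`
#'   column.
#' @param taxonomy Optional data frame `taxon, genus`.
#' @return A `community_table` list.
#' @export
community_table <- function(counts, metadata, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("community_table: negative counts")
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("S", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("ASV", seq_len(ncol(counts)))
  if (!"sample" %in% names(metadata))
    metadata$sample <- rownames(counts)
  if (!"status" %in% names(metadata))
    stop("community_table: metadata must have a status column")
  if (!all(rownames(counts) %in% metadata$sample))
    stop("community_table: metadata missing for some samples")
  metadata <- metadata[match(rownames(counts), metadata$sample), , drop = FALSE]
  structure(list(counts = counts, metadata = metadata, taxonomy = taxonomy),
            class = "community_table")
}

#' @export
print.community_table <- function(x, ...) {
  cat(sprintf("<community_table: %d samples x %d taxa>\n",
              nrow(x$counts), ncol(x$counts)))
  print(table(x$metadata$status))
  invisible(x)
}

#' Subset a community table by sample
#' @param t A [community_table()].
#' @param samples Character vector of sample names or logical index.
#' @export
subset_samples <- function(t, samples) {
  if (is.logical(samples)) samples <- rownames(t$counts)[samples]
  keep <- rownames(t$counts) %in% samples
  community_table(t$counts[keep, , drop = FALSE],
                  t$metadata[keep, , drop = FALSE], t$taxonomy)
}

#' Merge replicate samples by summing counts
#'
#' Replicate blade swabs of the same physical specimen are merged by
#' summing their counts; metadata is taken from the first replicate.
#'
#' @param t A [community_table()].
#' @param group Vector (length = samples) of specimen identifiers.
#' @export
merge_replicates <- function(t, group) {
  stopifnot(length(group) == nrow(t$counts))
  agg <- rowsum(t$counts, group)
  md <- t$metadata[!duplicated(group), , drop = FALSE]
  md$sample <- unique(group)[match(rownames(agg), unique(group))]
  md <- md[match(rownames(agg), md$sample), , drop = FALSE]
  community_table(agg, md, t$taxonomy)
}

#' Rarefy to even depth
#'
#' Per sample, draws `depth` reads without replacement; samples with fewer
#' than `depth` total reads are dropped. The default depth of 4000 matches
#' the rarefaction depth of the amplicon workflow.
#'
#' @param t A [community_table()].
#' @param depth Target depth (default 4000).
#' @param seed Integer RNG seed.
#' @return A rarefied [community_table()].
#' @export
rarefy <- function(t, depth = 4000, seed = 1L) {
  if (depth <= 0) stop("rarefy: depth must be positive")
  tot <- rowSums(t$counts)
  keep <- tot >= depth
  if (!any(keep)) stop("rarefy: no sample reaches the requested depth")
  cnt <- t$counts[keep, , drop = FALSE]
  withr::with_seed(seed, {
    for (i in seq_len(nrow(cnt))) {
      x <- cnt[i, ]
      if (sum(x) == depth) next
      reads <- rep.int(seq_along(x), x)
      drawn <- sample(reads, depth, replace = FALSE)
      cnt[i, ] <- tabulate(drawn, nbins = length(x))
    }
  })
  community_table(cnt, t$metadata[keep, , drop = FALSE], t$taxonomy)
}

#' Alpha diversity per sample
#'
#' Species richness, Shannon entropy (nats) and Pielou's evenness
#' (`shannon / ln(richness)`). Pielou is `NA` for samples with richness
#' <= 1, where it is undefined.
#'
#' @param t A rarefied [community_table()].
#' @return Data frame `sample, richness, shannon, pielou`.
#' @export
alpha_diversity <- function(t) {
  res <- lapply(seq_len(nrow(t$counts)), function(i) {
    x <- t$counts[i, ]
    x <- x[x > 0]
    rich <- length(x)
    p <- x / sum(x)
    sh <- -sum(p * log(p))
    data.frame(sample = rownames(t$counts)[i], richness = rich, shannon = sh,
               pielou = if (rich > 1) sh / log(rich) else NA_real_)
  })
  do.call(rbind, res)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = sum(|x_i - y_i|) / sum(x_i + y_i)`, computed on equal-depth
#' samples.
#'
#' @param t A [community_table()] (or a plain counts matrix).
#' @return A `dist` object.
#' @export
bray_curtis <- function(t) {
  cnt <- if (inherits(t, "community_table")) t$counts else as.matrix(t)
  if (any(rowSums(cnt) == 0)) stop("bray_curtis: empty sample")
  vegan::vegdist(cnt, method = "bray")
}

#' Dysbiosis score from centroid distances
#'
#' Embeds the dissimilarity matrix by principal-coordinates analysis
#' (retaining positive-eigenvalue axes), computes the non-raft and raft
#' group centroids, and scores every sample as
#' (distance to non-raft centroid) - (distance to raft centroid):
#' values above 0 indicate dysbiosis relative to the non-raft reference
#' state. The non-raft reference can be restricted (e.g. to populations
#' overlapping raft sources) via `reference_filter`.
#'
#' @param d A `dist` of samples (e.g. [bray_curtis()]).
#' @param status Character vector (`raft` / `non_raft`) aligned with the
#'   labels of `d`.
#' @param reference_filter Optional character vector of sample names the
#'   non-raft centroid may use.
#' @return Data frame `sample, status, score`.
#' @export
dysbiosis_score <- function(d, status, reference_filter = NULL) {
  labs <- attr(d, "Labels")
  stopifnot(length(status) == length(labs))
  ref <- labs[status == "non_raft"]
  if (!is.null(reference_filter)) ref <- intersect(ref, reference_filter)
  raft <- labs[status == "raft"]
  if (length(ref) < 2 || length(raft) < 2)
    stop("dysbiosis_score: each group needs >= 2 samples")
  # negative eigenvalues are expected for Bray-Curtis; they are dropped below
  pc <- suppressWarnings(stats::cmdscale(d, k = length(labs) - 1, eig = TRUE))
  pos <- pc$eig > 1e-8 * max(pc$eig)
  pos <- pos[seq_len(ncol(pc$points))]
  emb <- pc$points[, pos, drop = FALSE]
  cen_ref <- colMeans(emb[labs %in% ref, , drop = FALSE])
  cen_raft <- colMeans(emb[labs %in% raft, , drop = FALSE])
  d_ref <- sqrt(rowSums(sweep(emb, 2, cen_ref)^2))
  d_raft <- sqrt(rowSums(sweep(emb, 2, cen_raft)^2))
  data.frame(sample = labs, status = status, score = d_ref - d_raft,
             row.names = NULL)
}

# occupancy ranking index for the core walk: mean of overall occupancy and
# mean per-population occupancy; ties by mean relative abundance, then label
.core_ranking <- function(counts, population) {
  occ_all <- colMeans(counts > 0)
  if (is.null(population)) population <- rep("all", nrow(counts))
  pops <- unique(population)
  occ_pop <- sapply(pops, function(p)
    colMeans(counts[population == p, , drop = FALSE] > 0))
  occ_pop <- if (is.null(dim(occ_pop))) occ_pop else rowMeans(occ_pop)
  rel <- sweep(counts, 1, rowSums(counts), "/")
  mra <- colMeans(rel)
  idx <- (occ_all + occ_pop) / 2
  ord <- order(-idx, -mra, colnames(counts))
  list(order = ord, occupancy = occ_all)
}

#' Core microbiome by incremental Bray-Curtis contribution
#'
#' Ranks taxa by a site-weighted occupancy index (mean of overall occupancy
#' and mean per-population occupancy; abundance breaks ties), then walks the
#' ranking computing the proportion of total Bray-Curtis dissimilarity
#' explained by the top-i taxa. The core is the smallest prefix after which
#' the marginal gain in explained dissimilarity drops below `stop_fraction`
#' (default 0.03, the "last 3 percent decrease" rule). Core taxa are
#' expected to occur in at least 80 percent of samples; a warning is issued
#' if a reported core taxon falls below `min_occupancy`.
#'
#' @param t_nonraft A [community_table()] of non-raft samples from
#'   populations overlapping raft sources.
#' @param stop_fraction Marginal-gain stop rule (default 0.03).
#' @param min_occupancy Occupancy expected of core taxa (default 0.8).
#' @return A list of class `core_set`: `core` (taxon labels), `ranking`,
#'   `explained` (cumulative explained proportion per rank), `occupancy`.
#' @export
core_taxa <- function(t_nonraft, stop_fraction = 0.03, min_occupancy = 0.8) {
  cnt <- t_nonraft$counts
  if (nrow(cnt) < 4) stop("core_taxa: need >= 4 samples")
  pop <- t_nonraft$metadata$population
  rk <- .core_ranking(cnt, pop)
  ord <- rk$order
  n <- nrow(cnt)
  pr <- t(utils::combn(n, 2))
  i1 <- pr[, 1]; i2 <- pr[, 2]
  denom <- rowSums(cnt)[i1] + rowSums(cnt)[i2]
  bc_full <- vegan::vegdist(cnt, "bray")
  mean_bc_full <- mean(bc_full)
  # cumulative top-i |x - y| sums over pairs, in ranked order
  absdiff <- abs(cnt[i1, ord, drop = FALSE] - cnt[i2, ord, drop = FALSE])
  cum <- t(apply(absdiff, 1, cumsum))
  explained <- colMeans(cum / denom) / mean_bc_full
  gains <- diff(c(0, explained))
  qual <- which(gains >= stop_fraction)
  k <- if (length(qual)) max(qual) else 1L
  core <- colnames(cnt)[ord][seq_len(k)]
  occ <- rk$occupancy[core]
  if (any(occ < min_occupancy))
    warning("core_taxa: core taxa below the expected occupancy: ",
            paste(core[occ < min_occupancy], collapse = ", "))
  structure(list(core = core, ranking = colnames(cnt)[ord],
                 explained = explained, occupancy = rk$occupancy,
                 stop_fraction = stop_fraction),
            class = "core_set")
}

#' Classify taxa as core / abundant / rare and partition reads
#'
#' Non-core taxa with a mean relative abundance in the non-raft reference
#' above `abundance_cutoff` (default 0.1 percent) are `abundant`; the rest
#' are `rare`. Per-sample fractions of reads in each class sum to 1.
#'
#' @param t A [community_table()] (all samples to be partitioned).
#' @param core Character vector of core taxa (subset of table taxa).
#' @param abundance_cutoff Mean relative-abundance threshold (default 0.001).
#' @param reference_samples Samples on which mean abundances are computed
#'   (default: the table's non-raft samples).
#' @return A list with `classification` (data frame `taxon, class`) and
#'   `fractions` (data frame `sample, core, abundant, rare`).
#' @export
classify_and_partition <- function(t, core, abundance_cutoff = 0.001,
                                   reference_samples = NULL) {
  taxa <- colnames(t$counts)
  if (!all(core %in% taxa))
    stop("classify_and_partition: core set is not a subset of table taxa")
  if (is.null(reference_samples))
    reference_samples <- rownames(t$counts)[t$metadata$status == "non_raft"]
  refc <- t$counts[rownames(t$counts) %in% reference_samples, , drop = FALSE]
  rel <- sweep(refc, 1, pmax(rowSums(refc), 1), "/")
  mra <- colMeans(rel)
  cls <- ifelse(taxa %in% core, "core",
                ifelse(mra > abundance_cutoff, "abundant", "rare"))
  relall <- sweep(t$counts, 1, rowSums(t$counts), "/")
  fr <- sapply(c("core", "abundant", "rare"), function(cl)
    rowSums(relall[, cls == cl, drop = FALSE]))
  fr <- as.data.frame(fr)
  fr$sample <- rownames(t$counts)
  list(classification = data.frame(taxon = taxa, class = cls,
                                   mean_ref_abundance = mra, row.names = NULL),
       fractions = fr[, c("sample", "core", "abundant", "rare")])
}

#' Community-weighted mean rRNA operon count
#'
#' Aggregates counts to genus level and returns, per sample, the weighted
#' mean of genus-level mean rRNA operon counts (an rrnDB-style lookup),
#' weights being genus relative abundances renormalised over genera with a
#' known count. The trait proxies maximum growth rate.
#'
#' @param t A [community_table()] with genus annotations in `taxonomy`.
#' @param traits Data frame `genus, mean_copies` (copies > 0).
#' @return Data frame `sample, rrna_trait` (`NA` when no annotated genus has
#'   a known count).
#' @export
weighted_rrna_trait <- function(t, traits) {
  if (is.null(t$taxonomy)) stop("weighted_rrna_trait: taxonomy required")
  stopifnot(all(traits$mean_copies > 0))
  genus <- t$taxonomy$genus[match(colnames(t$counts), t$taxonomy$taxon)]
  lut <- stats::setNames(traits$mean_copies, tolower(traits$genus))
  cop <- lut[tolower(genus)]
  res <- vapply(seq_len(nrow(t$counts)), function(i) {
    x <- t$counts[i, ]
    known <- !is.na(cop) & x > 0
    if (!any(known)) return(NA_real_)
    w <- x[known] / sum(x[known])
    sum(w * cop[known])
  }, 0)
  data.frame(sample = rownames(t$counts), rrna_trait = res, row.names = NULL)
}

#' Read / write community tables as TSV
#'
#' The counts TSV stores taxa as rows and samples as columns (the common
#' ASV-table orientation); metadata is a sidecar TSV keyed by `sample`;
#' taxonomy a TSV `taxon, genus`.
#'
#' @param counts_path,metadata_path,taxonomy_path File paths.
#' @return A [community_table()].
#' @export
read_community_tsv <- function(counts_path, metadata_path,
                               taxonomy_path = NULL) {
  cnt <- as.matrix(utils::read.delim(counts_path, row.names = 1,
                                     check.names = FALSE))
  md <- utils::read.delim(metadata_path)
  tx <- if (!is.null(taxonomy_path)) utils::read.delim(taxonomy_path)
  community_table(t(cnt), md, tx)
}

#' @rdname read_community_tsv
#' @param t A [community_table()].
#' @export
write_community_tsv <- function(t, counts_path, metadata_path,
                                taxonomy_path = NULL) {
  m <- base::t(t$counts)
  utils::write.table(m, counts_path, sep = "\t", quote = FALSE, col.names = NA)
  utils::write.table(t$metadata, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(taxonomy_path) && !is.null(t$taxonomy))
    utils::write.table(t$taxonomy, taxonomy_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(counts_path)
}
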