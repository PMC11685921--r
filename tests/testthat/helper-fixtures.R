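# shared fixture builders; everything is generated in code, no data files

# spatially uniform field over a generous box and time span
uniform_field <- function(value, kind = "scalar",
                          lats = c(-48, -42), lons = c(164, 176),
                          times = c(0, 400), n = 2) {
  la <- seq(lats[1], lats[2], length.out = n)
  lo <- seq(lons[1], lons[2], length.out = n)
  tm <- seq(times[1], times[2], length.out = n)
  grid_field(la, lo, tm, array(value, c(n, n, n)), kind)
}

# SST field linear in longitude (a stationary front), constant in time
lon_gradient_field <- function(slope = 1, lats = c(-48, -42),
                               lons = c(164, 176), times = c(0, 400)) {
  la <- seq(lats[1], lats[2], length.out = 3)
  lo <- seq(lons[1], lons[2], length.out = 25)
  tm <- seq(times[1], times[2], length.out = 2)
  vals <- array(0, c(2, 3, 25))
  for (t in 1:2) vals[t, , ] <- matrix(slope * lo, 3, 25, byrow = TRUE)
  grid_field(la, lo, tm, vals, "scalar")
}

# single idealised particle with no leeway
bare_particle <- function(lat = -45, lon = 170, time = 30) {
  data.frame(particle_id = 1L, lat = lat, lon = lon, time = time,
             crosswind_sign = 1L, class = "none",
             dw_slope = 0, cw_slope = 0)
}

# tiny community table
toy_table <- function(counts, status = NULL, population = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("S", seq_len(nrow(counts)))
  md <- data.frame(sample = rownames(counts),
                   status = if (is.null(status)) "non_raft" else status)
  if (!is.null(population)) md$population <- population
  community_table(counts, md)
}

# brute-force reference implementation of the genotype filter contract
oracle_filter <- function(gt, dp, min_depth = 5, max_missing = 0.2,
                          min_mac = 2, min_snps = 3) {
  if (!is.null(dp)) for (i in seq_len(nrow(gt))) for (j in seq_len(ncol(gt)))
    if (!is.na(dp[i, j]) && dp[i, j] < min_depth) gt[i, j] <- NA
  keep_l <- logical(ncol(gt))
  for (j in seq_len(ncol(gt))) {
    col <- gt[, j]
    miss <- mean(is.na(col))
    alt <- sum(col, na.rm = TRUE)
    tot <- 2 * sum(!is.na(col))
    mac <- min(alt, tot - alt)
    keep_l[j] <- miss <= max_missing && mac >= min_mac
  }
  gt <- gt[, keep_l, drop = FALSE]
  keep_i <- apply(gt, 1, function(r) sum(!is.na(r)) >= min_snps)
  gt[keep_i, , drop = FALSE]
}

# all permutations of 1..n (used by the exhaustive betaMNTD null oracle)
perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- perms(n - 1)
  out <- NULL
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

# plain-R betaMNTD (oracle, independent of the package internals)
oracle_bmntd <- function(pa, pb, d) {
  mina <- apply(d[names(pa), names(pb), drop = FALSE], 1, min)
  minb <- apply(d[names(pa), names(pb), drop = FALSE], 2, min)
  0.5 * (sum(pa * mina) + sum(pb * minb))
}
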