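#' Synthetic scenario configuration
#'
#' Bundles every knob of the synthetic world in one list. Defaults describe
#' a small southern-hemisphere coastal domain with three water masses of
#' differing SST mean and temporal variance, six genetically structured
#' source populations strung along a western coastline, non-raft host
#' communities under strong homogeneous selection with a planted 14-taxon
#' core, and raft communities whose expected richness follows a hump in
#' sigma-SST and whose dispersion grows with perturbation.
#'
#' @param domain `c(lat_min, lat_max, lon_min, lon_max)` in degrees.
#' @param res_deg Grid resolution (degrees).
#' @param n_days Length of the daily time axis.
#' @param sst_means Mean SST per latitudinal water mass (south to north).
#' @param sst_noise_sd Temporal AR(1) innovation sd per water mass.
#' @param sst_ar AR(1) coefficient of the water-mass temperature anomaly.
#' @param current_v0 Peak speed (m/s) of the shore-parallel (northward) jet.
#' @param current_u0 Uniform offshore (eastward) drift speed (m/s); forward
#'   flow carries material from the coast toward the open sea, so backward
#'   trajectories converge on the coastline.
#' @param current_width Jet e-folding width in degrees of longitude.
#' @param current_offset Jet axis distance from the coast (degrees).
#' @param wind_sd Wind-component innovation sd (m/s).
#' @param n_populations,n_ind_per_pop,n_snps,n_queries Host-genetics sizes.
#' @param divergence_scale Per-step allele-frequency drift along the coast
#'   (the isolation-by-distance knob).
#' @param n_taxa Number of ASVs in the regional pool.
#' @param core_size Planted core size (default 14).
#' @param n_nonraft,n_raft Sample counts.
#' @param depth Sequencing depth drawn per sample (before rarefaction).
#' @param conc_nonraft Dirichlet concentration of non-raft communities
#'   (high = strong homogeneous selection).
#' @param akp_slope Per-degree-C drop rate of the raft Dirichlet
#'   concentration with sigma-SST (dispersion increase; the
#'   Anna-Karenina knob).
#' @param ish_peak,ish_width,ish_base,ish_amp Planted richness hump:
#'   expected available richness `ish_base + ish_amp *
#'   exp(-(sigma - ish_peak)^2 / (2 ish_width^2))`.
#' @param n_particles Particles per raft in the pipeline driver (the
#'   field-scale presets of 99999/9999 are impractical for tests).
#' @param dt_hours,max_drift_days Drift integration controls.
#' @param rarefy_depth Rarefaction depth (default 4000).
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(domain = c(-47, -43, 166, 172),
                            res_deg = 0.25, n_days = 60,
                            sst_means = c(10, 13, 16),
                            sst_noise_sd = c(0.4, 1.0, 0.6),
                            sst_ar = 0.7,
                            current_v0 = 0.35, current_width = 0.8,
                            current_offset = 0.7, current_u0 = 0.08,
                            wind_sd = 4,
                            n_populations = 6, n_ind_per_pop = 12,
                            n_snps = 500, n_queries = 20,
                            divergence_scale = 0.15,
                            n_taxa = 150, core_size = 14,
                            n_nonraft = 36, n_raft = 24,
                            depth = 6000,
                            conc_nonraft = 400,
                            akp_slope = 1.2,
                            ish_peak = 1.5, ish_width = 0.8,
                            ish_base = 40, ish_amp = 45,
                            n_particles = 40, dt_hours = 1,
                            max_drift_days = 20,
                            rarefy_depth = 4000) {
  cfg <- as.list(environment())
  stopifnot(domain[1] < domain[2], domain[3] < domain[4],
            n_populations >= 2, n_taxa >= core_size, core_size >= 1)
  structure(cfg, class = "scenario_config")
}

# AR(1) series of length n with innovation sd s and coefficient phi
.ar1 <- function(n, phi, s) {
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, s / sqrt(1 - phi^2))
  for (i in seq_len(n - 1))
    x[i + 1] <- phi * x[i] + stats::rnorm(1, 0, s)
  x
}

#' Generate the synthetic environment
#'
#' SST: latitudinal water masses with distinct means (smooth logistic
#' fronts) and per-mass AR(1) temperature anomalies, plus a weak in-mass
#' meridional gradient. Currents: a shore-parallel northward jet hugging
#' the western (coastal) edge. Wind: spatially uniform AR(1) components.
#' All fields are deterministic given the seed.
#'
#' @param cfg A [scenario_config()].
#' @param seed Integer RNG seed.
#' @return List of [grid_field()]s: `sst`, `current_u`, `current_v`,
#'   `wind_u`, `wind_v`, plus `coastline` (data frame of coastal points
#'   along the western edge).
#' @export
gen_environment <- function(cfg, seed = 1L) {
  lats <- seq(cfg$domain[1], cfg$domain[2], by = cfg$res_deg)
  lons <- seq(cfg$domain[3], cfg$domain[4], by = cfg$res_deg)
  times <- seq(0, cfg$n_days - 1)
  nm <- length(cfg$sst_means)
  # front latitudes split the domain into nm equal bands
  fronts <- cfg$domain[1] + (seq_len(nm - 1) / nm) * diff(cfg$domain[1:2])
  withr::with_seed(seed, {
    anom <- sapply(seq_len(nm), function(m)
      .ar1(length(times), cfg$sst_ar, cfg$sst_noise_sd[m]))
    # mass membership weights per latitude (soft logistic fronts)
    wts <- sapply(seq_len(nm), function(m) {
      lo <- if (m == 1) -Inf else fronts[m - 1]
      hi <- if (m == nm) Inf else fronts[m]
      stats::plogis((lats - lo) / 0.15) * (1 - stats::plogis((lats - hi) / 0.15))
    })
    wts <- wts / rowSums(wts)
    mean_lat <- as.vector(wts %*% cfg$sst_means) + 0.05 * (lats - mean(lats))
    sst <- array(0, c(length(times), length(lats), length(lons)))
    for (ti in seq_along(times)) {
      slice <- mean_lat + as.vector(wts %*% anom[ti, ])
      sst[ti, , ] <- matrix(slice, length(lats), length(lons))
    }
    jet <- cfg$current_v0 *
      exp(-((lons - cfg$domain[3] - cfg$current_offset) / cfg$current_width)^2)
    cu <- array(cfg$current_u0, c(length(times), length(lats), length(lons)))
    cv <- array(0, c(length(times), length(lats), length(lons)))
    for (ti in seq_along(times))
      cv[ti, , ] <- matrix(jet, length(lats), length(lons), byrow = TRUE)
    wu_t <- .ar1(length(times), 0.6, cfg$wind_sd)
    wv_t <- .ar1(length(times), 0.6, cfg$wind_sd)
    wu <- array(rep(wu_t, length(lats) * length(lons)),
                c(length(times), length(lats), length(lons)))
    wv <- array(rep(wv_t, length(lats) * length(lons)),
                c(length(times), length(lats), length(lons)))
    coast_lat <- seq(cfg$domain[1], cfg$domain[2], by = cfg$res_deg / 10)
    coastline <- data.frame(lat = coast_lat,
                            lon = cfg$domain[3] + 0.05 +
                              0.1 * sin(coast_lat * 2))
    list(sst = grid_field(lats, lons, times, sst, "scalar"),
         current_u = grid_field(lats, lons, times, cu, "vector_u"),
         current_v = grid_field(lats, lons, times, cv, "vector_v"),
         wind_u = grid_field(lats, lons, times, wu, "vector_u"),
         wind_v = grid_field(lats, lons, times, wv, "vector_v"),
         coastline = coastline)
  })
}

#' Generate genetically structured host populations
#'
#' Populations sit at equal spacing along the synthetic coastline; allele
#' frequencies perform a stepping-stone random walk from population to
#' population (isolation by distance, step sd `divergence_scale`), and
#' individuals are binomial draws from their population's frequencies.
#' Query individuals (rafts of unknown origin) are drawn from known
#' populations with the truth recorded.
#'
#' @param cfg A [scenario_config()].
#' @param seed Integer RNG seed.
#' @param coastline Optional coastline (from [gen_environment()]); a
#'   straight western coast is synthesised otherwise.
#' @return List: `genotypes` (a [genotype_matrix()] of references and
#'   queries; coords only for references), `ref_coords`, `truth` (data
#'   frame `query, population, lat, lon`), `pop_coords`, `coastline`.
#' @export
gen_host_populations <- function(cfg, seed = 1L, coastline = NULL) {
  if (is.null(coastline)) {
    coast_lat <- seq(cfg$domain[1], cfg$domain[2], length.out = 200)
    coastline <- data.frame(lat = coast_lat,
                            lon = cfg$domain[3] + 0.05 + 0.1 * sin(coast_lat * 2))
  }
  npop <- cfg$n_populations
  pos <- round(seq(1, nrow(coastline), length.out = npop))
  pop_coords <- data.frame(population = paste0("pop", seq_len(npop)),
                           lat = coastline$lat[pos], lon = coastline$lon[pos])
  if (cfg$divergence_scale == 0 && cfg$n_queries > 0)
    warning("gen_host_populations: divergence 0; assignment unidentifiable")
  withr::with_seed(seed, {
    p0 <- stats::runif(cfg$n_snps, 0.15, 0.85)
    freqs <- matrix(0, npop, cfg$n_snps)
    freqs[1, ] <- p0
    for (k in 2:npop)
      freqs[k, ] <- pmin(0.99, pmax(0.01,
        freqs[k - 1, ] + stats::rnorm(cfg$n_snps, 0, cfg$divergence_scale)))
    draw <- function(pop) {
      g <- stats::rbinom(cfg$n_snps, 2, freqs[pop, ])
      stats::setNames(g, paste0("snp", seq_len(cfg$n_snps)))
    }
    refs <- lapply(seq_len(npop), function(k)
      base::t(vapply(seq_len(cfg$n_ind_per_pop), function(i) draw(k),
                     integer(cfg$n_snps))))
    gref <- do.call(rbind, refs)
    rownames(gref) <- paste0("pop", rep(seq_len(npop), each = cfg$n_ind_per_pop),
                             "_ind", rep(seq_len(cfg$n_ind_per_pop), npop))
    qpop <- sample.int(npop, cfg$n_queries, replace = TRUE)
    gq <- base::t(vapply(qpop, function(k) draw(k), integer(cfg$n_snps)))
    rownames(gq) <- paste0("query", seq_len(cfg$n_queries))
    ref_coords <- data.frame(
      individual = rownames(gref),
      population = rep(pop_coords$population, each = cfg$n_ind_per_pop),
      lat = rep(pop_coords$lat, each = cfg$n_ind_per_pop),
      lon = rep(pop_coords$lon, each = cfg$n_ind_per_pop))
    # small coordinate scatter so reference individuals are not co-located
    ref_coords$lat <- ref_coords$lat + stats::rnorm(nrow(ref_coords), 0, 0.02)
    ref_coords$lon <- ref_coords$lon + stats::rnorm(nrow(ref_coords), 0, 0.02)
    truth <- data.frame(query = rownames(gq),
                        population = pop_coords$population[qpop],
                        lat = pop_coords$lat[qpop], lon = pop_coords$lon[qpop])
    list(genotypes = genotype_matrix(rbind(gref, gq), coords = ref_coords),
         ref_coords = ref_coords, truth = truth,
         pop_coords = pop_coords, coastline = coastline)
  })
}

# contiguous genus labels along the tip order of a tree
.assign_genera <- function(tree, genus_size = 5) {
  tips <- tree$tip.label
  ng <- ceiling(length(tips) / genus_size)
  genus <- paste0("genus", rep(seq_len(ng), each = genus_size))[seq_along(tips)]
  data.frame(taxon = tips, genus = genus)
}

#' Generate raft and non-raft microbial communities with planted truth
#'
#' Builds a random ASV tree whose first clade-block of taxa is
#' host-associated (including the planted core) and whose remainder is a
#' neutral water-column pool. Non-raft samples are Dirichlet-multinomial
#' draws around a core-dominated host profile with high concentration
#' (strong homogeneous selection; planted core present in >= 80 percent of
#' samples). Raft samples mix the host profile with the water pool - the
#' mixing weight grows with rafting time - restricted to a support whose
#' expected size follows the planted richness hump in sigma-SST, with
#' Dirichlet concentration shrinking as sigma-SST grows (rising
#' dispersion, the Anna-Karenina direction). Water genera carry higher
#' rRNA operon counts than host genera (faster colonist growth).
#'
#' @param cfg A [scenario_config()].
#' @param raft_covariates Data frame with one row per raft sample, columns
#'   `raft_time` (days) and `sigma_sst` (degrees C); defaults are drawn to
#'   span the hump.
#' @param seed Integer RNG seed.
#' @return List: `table` (a [community_table()] with metadata incl.
#'   covariates), `tree` ([ape::phylo]), `traits` (genus trait table),
#'   `truth` (list with `core`, `host_taxa`, `water_taxa`, `ish`,
#'   `akp_slope`, per-sample regime).
#' @export
gen_microbiomes <- function(cfg, raft_covariates = NULL, seed = 1L) {
  if (cfg$core_size > cfg$n_taxa) stop("gen_microbiomes: core size > n_taxa")
  withr::with_seed(seed, {
    tree <- ape::rtree(cfg$n_taxa, tip.label = paste0("ASV", seq_len(cfg$n_taxa)))
    tips <- tree$tip.label
    n_host <- max(cfg$core_size + 20, round(0.4 * cfg$n_taxa))
    host_taxa <- tips[seq_len(n_host)]
    water_taxa <- setdiff(tips, host_taxa)
    core <- host_taxa[seq_len(cfg$core_size)]
    taxonomy <- .assign_genera(tree)
    genera <- unique(taxonomy$genus)
    host_genera <- unique(taxonomy$genus[taxonomy$taxon %in% host_taxa])
    copies <- stats::setNames(
      ifelse(genera %in% host_genera,
             exp(stats::rnorm(length(genera), log(2), 0.2)),
             exp(stats::rnorm(length(genera), log(5), 0.2))), genera)
    traits <- data.frame(genus = genera, mean_copies = as.numeric(copies))
    # host profile: core dominates, other host taxa moderate, water absent
    w_host <- stats::setNames(numeric(cfg$n_taxa), tips)
    w_host[core] <- stats::rlnorm(cfg$core_size, log(40), 0.25)
    w_host[setdiff(host_taxa, core)] <-
      stats::rlnorm(n_host - cfg$core_size, log(2), 0.5)
    w_host <- w_host / sum(w_host)
    w_water <- stats::setNames(numeric(cfg$n_taxa), tips)
    w_water[water_taxa] <- stats::rlnorm(length(water_taxa), log(1), 0.6)
    w_water <- w_water / sum(w_water)
    npop <- cfg$n_populations
    dm_draw <- function(pi, conc, depth, support = NULL) {
      p <- pi
      if (!is.null(support)) {
        p[setdiff(names(p), support)] <- 0
        if (sum(p) == 0) p[support] <- 1
        p <- p / sum(p)
      }
      alpha <- conc * p
      gam <- stats::rgamma(length(alpha), shape = alpha)
      gam[alpha == 0] <- 0
      if (sum(gam) == 0) gam[which.max(alpha)] <- 1
      stats::rmultinom(1, depth, prob = gam / sum(gam))[, 1]
    }
    # non-rafts
    nr <- lapply(seq_len(cfg$n_nonraft), function(i)
      dm_draw(w_host, cfg$conc_nonraft, cfg$depth))
    # rafts
    if (is.null(raft_covariates)) {
      raft_covariates <- data.frame(
        raft_time = stats::runif(cfg$n_raft, 2, 60),
        sigma_sst = stats::runif(cfg$n_raft, 0.1, 3))
    }
    nr_sigma <- stats::runif(cfg$n_nonraft, 0.2, 0.8)
    rf <- lapply(seq_len(nrow(raft_covariates)), function(i) {
      rt <- raft_covariates$raft_time[i]
      sg <- raft_covariates$sigma_sst[i]
      w <- rt / (rt + 20)            # water fraction grows with raft time
      pi_mix <- (1 - w) * w_host + w * w_water
      rich <- round(cfg$ish_base + cfg$ish_amp *
                      exp(-(sg - cfg$ish_peak)^2 / (2 * cfg$ish_width^2)))
      rich <- min(max(rich, cfg$core_size + 5), cfg$n_taxa)
      # support: core always available, rest sampled by mixture weight
      pool <- setdiff(tips, core)
      support <- c(core, sample(pool, rich - cfg$core_size,
                                prob = pi_mix[pool] + 1e-6))
      conc <- cfg$conc_nonraft / (1 + cfg$akp_slope * sg)
      dm_draw(pi_mix, conc, cfg$depth, support)
    })
    counts <- do.call(rbind, c(nr, rf))
    rownames(counts) <- c(paste0("nonraft", seq_len(cfg$n_nonraft)),
                          paste0("raft", seq_len(nrow(raft_covariates))))
    colnames(counts) <- tips
    metadata <- data.frame(
      sample = rownames(counts),
      status = c(rep("non_raft", cfg$n_nonraft),
                 rep("raft", nrow(raft_covariates))),
      population = c(paste0("pop", rep_len(seq_len(npop), cfg$n_nonraft)),
                     rep(NA_character_, nrow(raft_covariates))),
      raft_time = c(rep(0, cfg$n_nonraft), raft_covariates$raft_time),
      sigma_sst = c(nr_sigma, raft_covariates$sigma_sst),
      sst = stats::runif(nrow(counts), 10, 16))
    truth <- list(core = core, host_taxa = host_taxa, water_taxa = water_taxa,
                  ish = list(peak = cfg$ish_peak, width = cfg$ish_width,
                             base = cfg$ish_base, amp = cfg$ish_amp),
                  akp_slope = cfg$akp_slope,
                  water_genera = setdiff(genera, host_genera))
    list(table = community_table(counts, metadata, taxonomy),
         tree = tree, traits = traits, truth = truth)
  })
}

#' Calibration scenarios for assembly partitioning
#'
#' `gen_neutral_communities` draws every sample from one broad regional
#' pool (pure ecological drift: no phylogenetic habitat signal), while
#' `gen_filtered_communities` confines all abundance to one small clade
#' (strong homogeneous selection). Both return a [community_table()] (all
#' samples labelled `non_raft`, one population) and the tree.
#'
#' @param n_samples,n_taxa,depth Scenario sizes.
#' @param seed Integer RNG seed.
#' @return List `table`, `tree`.
#' @export
gen_neutral_communities <- function(n_samples = 8, n_taxa = 48,
                                    depth = 1000, seed = 1L) {
  withr::with_seed(seed, {
    tree <- ape::rtree(n_taxa, tip.label = paste0("ASV", seq_len(n_taxa)))
    pool <- stats::rlnorm(n_taxa, 0, 0.3)
    pool <- pool / sum(pool)
    counts <- base::t(stats::rmultinom(n_samples, depth, pool))
    rownames(counts) <- paste0("S", seq_len(n_samples))
    colnames(counts) <- tree$tip.label
    md <- data.frame(sample = rownames(counts), status = "non_raft",
                     population = "pop1")
    list(table = community_table(counts, md), tree = tree)
  })
}

#' @rdname gen_neutral_communities
#' @param clade_size Number of viable taxa (one tight clade).
#' @export
gen_filtered_communities <- function(n_samples = 8, n_taxa = 48,
                                     clade_size = 8, depth = 1000, seed = 1L) {
  withr::with_seed(seed, {
    tree <- ape::rtree(n_taxa, tip.label = paste0("ASV", seq_len(n_taxa)))
    # the viable clade: tips of the first internal clade of the right size
    sizes <- vapply(seq_len(tree$Nnode) + n_taxa, function(nd)
      length(ape::extract.clade(tree, nd)$tip.label), 0)
    cand <- which(sizes >= clade_size)
    node <- (seq_len(tree$Nnode) + n_taxa)[cand[which.min(sizes[cand])]]
    viable <- ape::extract.clade(tree, node)$tip.label[seq_len(clade_size)]
    pool <- stats::setNames(numeric(n_taxa), tree$tip.label)
    pool[viable] <- stats::rlnorm(clade_size, 0, 0.3)
    pool <- pool / sum(pool)
    counts <- base::t(stats::rmultinom(n_samples, depth, pool))
    rownames(counts) <- paste0("S", seq_len(n_samples))
    colnames(counts) <- tree$tip.label
    md <- data.frame(sample = rownames(counts), status = "non_raft",
                     population = "pop1")
    list(table = community_table(counts, md), tree = tree)
  })
}

#' Generate surrogate drifter tracks
#'
#' Forward-advects `n` surface particles seeded at random offshore
#' positions through the synthetic current and wind fields, adding small
#' Gaussian observation noise to the recorded positions. Tracks are at
#' least `track_days` long (default 14 > the 11-day matching window).
#'
#' @param cfg A [scenario_config()].
#' @param fields Output of [gen_environment()].
#' @param n Number of drifters (default 21, the validation set size).
#' @param track_days Track length in days.
#' @param obs_noise_deg Positional observation noise sd (degrees).
#' @param seed Integer RNG seed.
#' @return List of [trajectory()] objects with ascending times.
#' @export
gen_drifter_tracks <- function(cfg, fields, n = 21, track_days = 14,
                               obs_noise_deg = 0, seed = 1L) {
  withr::with_seed(seed, {
    lat0 <- stats::runif(n, cfg$domain[1] + 0.5, cfg$domain[2] - 3)
    lon0 <- stats::runif(n, cfg$domain[3] + 1.5, cfg$domain[4] - 2)
    parts <- data.frame(particle_id = seq_len(n), lat = lat0, lon = lon0,
                        time = 0, crosswind_sign = 1L, class = "drifter",
                        dw_slope = 0.01, cw_slope = 0)
    trs <- advect_particles(parts, fields$current_u, fields$current_v,
                            fields$wind_u, fields$wind_v, target = NULL,
                            domain = cfg$domain,
                            dt_hours = 6, max_days = track_days,
                            forward = TRUE)
    lapply(trs, function(tr) {
      st <- tr$states
      if (obs_noise_deg > 0) {
        st$lat <- st$lat + stats::rnorm(nrow(st), 0, obs_noise_deg)
        st$lon <- st$lon + stats::rnorm(nrow(st), 0, obs_noise_deg)
      }
      trajectory(st, tr$status)
    })
  })
}
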