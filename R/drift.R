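#' Leeway drift classes
#'
#' A leeway class describes how strongly a floating object is dragged by the
#' 10-m wind, split into a downwind and a crosswind component, each a
#' fraction ("slope") of the wind speed with a between-particle standard
#' deviation. The person-in-water classes PIW-1 (unknown state), PIW-5
#' (scuba suit, face up) and PIW-6 (deceased, face down) are shipped with
#' approximate default coefficients; they are configuration, not measured
#' kelp-raft constants, and synthetic scenarios may define their own.
#'
#' @param name Class label.
#' @param downwind_slope,downwind_sd Downwind leeway slope and its sd
#'   (fraction of wind speed).
#' @param crosswind_slope,crosswind_sd Crosswind leeway slope and its sd.
#' @return A `leeway_class` list.
#' @export
leeway_class <- function(name, downwind_slope, downwind_sd = 0,
                         crosswind_slope = 0, crosswind_sd = 0) {
  stopifnot(downwind_slope >= 0, downwind_sd >= 0,
            crosswind_slope >= 0, crosswind_sd >= 0)
  structure(list(name = name,
                 downwind_slope = downwind_slope, downwind_sd = downwind_sd,
                 crosswind_slope = crosswind_slope, crosswind_sd = crosswind_sd),
            class = "leeway_class")
}

#' @rdname leeway_class
#' @export
default_leeway_classes <- function() {
  list(
    `PIW-1` = leeway_class("PIW-1", 0.0096, 0.0029, 0.0040, 0.0012),
    `PIW-5` = leeway_class("PIW-5", 0.0068, 0.0024, 0.0030, 0.0010),
    `PIW-6` = leeway_class("PIW-6", 0.0154, 0.0039, 0.0060, 0.0020)
  )
}

.EARTH_R_KM <- 6371

#' Haversine distance
#'
#' Great-circle distance on a spherical Earth (R = 6371 km). Vectorised.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in degrees.
#' @return Distance in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * .EARTH_R_KM * asin(pmin(1, sqrt(a)))
}

#' Coastal target zone for the drift hit test
#'
#' A target zone is a set of coastal points (degrees); a particle "reaches"
#' the zone when it comes within `hit_radius_km` of any zone point
#' (default 2 km, the hit radius used for the drift termination rule).
#'
#' @param lat,lon Numeric vectors of zone point coordinates.
#' @param hit_radius_km Hit radius in km (> 0).
#' @return A `target_zone` list.
#' @export
target_zone <- function(lat, lon, hit_radius_km = 2) {
  stopifnot(length(lat) == length(lon), length(lat) >= 1, hit_radius_km > 0)
  structure(list(lat = as.numeric(lat), lon = as.numeric(lon),
                 hit_radius_km = hit_radius_km),
            class = "target_zone")
}

#' Seed leeway particles around a collection site
#'
#' Particles are seeded area-uniformly on a disc of `radius_km` around the
#' site (default 1 km, matching the release protocol), with release times
#' uniform in +/- `time_jitter_days` of the collection time, a random
#' crosswind sign, a leeway class drawn from `class_mix`, and per-particle
#' downwind/crosswind slopes drawn from truncated-at-zero normal
#' distributions around the class coefficients.
#'
#' @param site_lat,site_lon Collection coordinates (degrees).
#' @param collection_time Collection time (days).
#' @param n Number of particles (>= 1).
#' @param radius_km Seeding radius in km (> 0); use a tiny value for "at the
#'   site".
#' @param time_jitter_days Half-width of the uniform release-time jitter.
#' @param classes Named list of [leeway_class()] objects.
#' @param class_mix Named numeric weights over `classes` (default equal).
#' @param seed Integer RNG seed; identical seeds give identical particles.
#' @return A data frame of particle states: `particle_id, lat, lon, time,
#'   crosswind_sign, class, dw_slope, cw_slope`.
#' @export
seed_particles <- function(site_lat, site_lon, collection_time, n,
                           radius_km = 1, time_jitter_days = 1,
                           classes = default_leeway_classes(),
                           class_mix = NULL, seed = 1L) {
  if (n < 1) stop("seed_particles: n must be >= 1")
  if (radius_km <= 0) stop("seed_particles: radius_km must be > 0")
  if (is.null(class_mix)) class_mix <- stats::setNames(rep(1, length(classes)),
                                                       names(classes))
  class_mix <- class_mix / sum(class_mix)
  withr::with_seed(seed, {
    r <- radius_km * sqrt(stats::runif(n))
    th <- stats::runif(n, 0, 2 * pi)
    dlat <- (r * cos(th) / .EARTH_R_KM) * (180 / pi)
    dlon <- (r * sin(th) / (.EARTH_R_KM * cos(site_lat * pi / 180))) * (180 / pi)
    tms <- collection_time + stats::runif(n, -time_jitter_days, time_jitter_days)
    sgn <- sample(c(-1L, 1L), n, replace = TRUE)
    cls <- sample(names(classes), n, replace = TRUE, prob = class_mix)
    dw_m <- vapply(classes[cls], function(c) c$downwind_slope, 0)
    dw_s <- vapply(classes[cls], function(c) c$downwind_sd, 0)
    cw_m <- vapply(classes[cls], function(c) c$crosswind_slope, 0)
    cw_s <- vapply(classes[cls], function(c) c$crosswind_sd, 0)
    dw <- stats::qnorm(stats::runif(n, stats::pnorm(0, dw_m, pmax(dw_s, 1e-12)), 1),
                       dw_m, pmax(dw_s, 1e-12))
    cw <- stats::qnorm(stats::runif(n, stats::pnorm(0, cw_m, pmax(cw_s, 1e-12)), 1),
                       cw_m, pmax(cw_s, 1e-12))
    data.frame(particle_id = seq_len(n),
               lat = site_lat + dlat, lon = site_lon + dlon, time = tms,
               crosswind_sign = sgn, class = cls,
               dw_slope = dw, cw_slope = cw,
               row.names = NULL)
  })
}

#' Leeway velocity of particles in a wind field
#'
#' The downwind component is `dw_slope` times the wind vector; the crosswind
#' component is `crosswind_sign * cw_slope` times the wind speed, directed
#' perpendicular to the wind (sign +1 rotates the wind vector by +90
#' degrees). Zero wind gives zero leeway.
#'
#' @param wind_u,wind_v Wind components (m/s), recycled against particles.
#' @param particles Particle data frame from [seed_particles()] (columns
#'   `dw_slope`, `cw_slope`, `crosswind_sign`).
#' @return A list with components `u` and `v` (m/s).
#' @export
leeway_velocity <- function(wind_u, wind_v, particles) {
  dw <- particles$dw_slope
  cw <- particles$cw_slope * particles$crosswind_sign
  list(u = dw * wind_u - cw * wind_v,
       v = dw * wind_v + cw * wind_u)
}

#' Trajectory container
#'
#' @param states Data frame with columns `time`, `lat`, `lon`, time-ordered
#'   (decreasing for backward runs).
#' @param status One of `"reached_target"`, `"left_domain"`, `"timed_out"`.
#' @return A `trajectory` list with `elapsed_days = |first.time - last.time|`.
#' @export
trajectory <- function(states, status) {
  status <- match.arg(status, c("reached_target", "left_domain", "timed_out"))
  stopifnot(nrow(states) >= 1)
  structure(list(states = states, status = status,
                 elapsed_days = abs(states$time[1] - states$time[nrow(states)])),
            class = "trajectory")
}

#' Backward leeway advection of a particle ensemble
#'
#' Euler integration with an hourly default time step, run backward in time:
#' the total velocity (ambient current plus wind leeway) is negated and
#' positions are stepped with a metres-to-degrees conversion using the local
#' cosine of latitude on a spherical Earth. No stochastic diffusion is
#' added. Each particle terminates on the first of: coming within the target
#' zone's hit radius (`reached_target`), leaving the domain box
#' (`left_domain`), or drifting for `max_days` (`timed_out`, default 730
#' days = two years).
#'
#' @param particles Data frame from [seed_particles()].
#' @param current_u,current_v,wind_u,wind_v [grid_field()]s of forcing
#'   components (m/s). Winds may be `NULL` for current-only runs.
#' @param target A [target_zone()] or `NULL` (no hit test).
#' @param domain Numeric vector `c(lat_min, lat_max, lon_min, lon_max)`.
#' @param dt_hours Euler step (hours, default 1).
#' @param max_days Maximum drift duration (days, default 730).
#' @param forward If `TRUE`, integrate forward in time instead (used for
#'   surrogate drifter generation).
#' @return A list of [trajectory()] objects, one per particle.
#' @export
advect_particles <- function(particles, current_u, current_v,
                             wind_u = NULL, wind_v = NULL,
                             target = NULL,
                             domain = c(-50, -20, 120, 179),
                             dt_hours = 1, max_days = 730,
                             forward = FALSE) {
  if (dt_hours <= 0) stop("advect_particles: dt_hours must be > 0")
  n <- nrow(particles)
  dt_days <- dt_hours / 24
  dt_sec <- dt_hours * 3600
  tdir <- if (forward) 1 else -1
  # forcing must cover the full possible integration window
  t_range <- range(particles$time, particles$time + tdir * max_days)
  for (f in list(current_u, current_v, wind_u, wind_v)) {
    if (is.null(f)) next
    if (t_range[1] < min(f$times) - 1e-9 || t_range[2] > max(f$times) + 1e-9)
      stop("advect_particles: forcing fields do not cover the integration time range")
  }
  n_steps <- ceiling(max_days / dt_days)
  lat <- particles$lat; lon <- particles$lon; tm <- particles$time
  active <- rep(TRUE, n)
  status <- rep(NA_character_, n)
  hist <- vector("list", n)
  for (i in seq_len(n)) hist[[i]] <- list(time = tm[i], lat = lat[i], lon = lon[i])
  rec <- function(i) {
    hist[[i]]$time <<- c(hist[[i]]$time, tm[i])
    hist[[i]]$lat <<- c(hist[[i]]$lat, lat[i])
    hist[[i]]$lon <<- c(hist[[i]]$lon, lon[i])
  }
  in_domain <- function(la, lo)
    la >= domain[1] & la <= domain[2] & lo >= domain[3] & lo <= domain[4]
  hit <- function(la, lo) {
    if (is.null(target)) return(rep(FALSE, length(la)))
    vapply(seq_along(la), function(i)
      min(haversine_km(la[i], lo[i], target$lat, target$lon)) <=
        target$hit_radius_km, TRUE)
  }
  # particles already at the target at release
  h0 <- hit(lat, lon)
  status[h0] <- "reached_target"; active[h0] <- FALSE
  step <- 0L
  while (any(active) && step < n_steps) {
    step <- step + 1L
    idx <- which(active)
    cu <- interpolate_field(current_u, lat[idx], lon[idx], tm[idx])
    cv <- interpolate_field(current_v, lat[idx], lon[idx], tm[idx])
    if (!is.null(wind_u)) {
      wu <- interpolate_field(wind_u, lat[idx], lon[idx], tm[idx])
      wv <- interpolate_field(wind_v, lat[idx], lon[idx], tm[idx])
      lw <- leeway_velocity(wu, wv, particles[idx, , drop = FALSE])
      cu <- cu + lw$u; cv <- cv + lw$v
    }
    # Euler step, negated for backward time
    dx <- tdir * cu * dt_sec
    dy <- tdir * cv * dt_sec
    lat[idx] <- lat[idx] + (dy / (.EARTH_R_KM * 1000)) * (180 / pi)
    lon[idx] <- lon[idx] +
      (dx / (.EARTH_R_KM * 1000 * cos(lat[idx] * pi / 180))) * (180 / pi)
    tm[idx] <- tm[idx] + tdir * dt_days
    for (i in idx) rec(i)
    out <- !in_domain(lat[idx], lon[idx])
    status[idx[out]] <- "left_domain"; active[idx[out]] <- FALSE
    idx2 <- idx[!out]
    if (length(idx2)) {
      hh <- hit(lat[idx2], lon[idx2])
      status[idx2[hh]] <- "reached_target"; active[idx2[hh]] <- FALSE
    }
  }
  status[is.na(status)] <- "timed_out"
  lapply(seq_len(n), function(i)
    trajectory(data.frame(time = hist[[i]]$time, lat = hist[[i]]$lat,
                          lon = hist[[i]]$lon),
               status[i]))
}

#' @rdname advect_particles
#' @param particle A single-row particle data frame (or a list coercible to
#'   one).
#' @export
advect_backward <- function(particle, current_u, current_v,
                            wind_u = NULL, wind_v = NULL, target = NULL,
                            domain = c(-50, -20, 120, 179),
                            dt_hours = 1, max_days = 730) {
  advect_particles(as.data.frame(particle), current_u, current_v,
                   wind_u, wind_v, target, domain, dt_hours, max_days)[[1]]
}

#' Summarise a raft's backward-drift ensemble
#'
#' Computes the fraction of particles whose backward trajectory reached the
#' target zone, the median time-to-source among those, and representative
#' SST statistics: the median across successful trajectories of the
#' per-trajectory mean SST and of the per-trajectory sigma-SST. With zero
#' successful particles the medians are `NA` (flagged, not an error).
#'
#' @param trajectories List of [trajectory()] objects.
#' @param sst Optional SST [grid_field()]; `NULL` skips the SST summaries.
#' @param successful_only If `TRUE` (default) representative SST statistics
#'   use only trajectories that reached the target.
#' @return A list of class `raft_drift_summary`.
#' @export
summarize_raft <- function(trajectories, sst = NULL, successful_only = TRUE) {
  stopifnot(length(trajectories) >= 1)
  st <- vapply(trajectories, function(t) t$status, "")
  el <- vapply(trajectories, function(t) t$elapsed_days, 0)
  reached <- st == "reached_target"
  keep <- if (successful_only) reached else rep(TRUE, length(trajectories))
  rep_sst <- rep_sig <- NA_real_
  times <- el[reached]
  if (!is.null(sst) && any(keep)) {
    es <- lapply(trajectories[keep], function(t)
      tryCatch(trajectory_env_stats(t, sst), error = function(e) NULL))
    mu <- vapply(es, function(e) if (is.null(e)) NA_real_ else e$mean_sst, 0)
    sg <- vapply(es, function(e) if (is.null(e)) NA_real_ else e$sigma_sst, 0)
    rep_sst <- stats::median(mu, na.rm = TRUE)
    rep_sig <- stats::median(sg, na.rm = TRUE)
  }
  structure(list(
    n_particles = length(trajectories),
    fraction_reached = mean(reached),
    times_to_source = times,
    median_raft_time = if (any(reached)) stats::median(times) else NA_real_,
    representative_sst = rep_sst,
    representative_sigma_sst = rep_sig,
    termination_tally = table(factor(st, levels = c("reached_target",
                                                    "left_domain", "timed_out")))
  ), class = "raft_drift_summary")
}

#' SST statistics over the final window of a drifter track
#'
#' Restricts a (forward-in-time) drifter trajectory to its final
#' `window_days` days and returns SST statistics along it, for pairing real
#' drifters against modelled-equivalent trajectory ensembles.
#'
#' @param drifter_track A [trajectory()] with ascending times.
#' @param sst SST [grid_field()].
#' @param window_days Window length (days, default 11 - the median
#'   successful rafting period).
#' @return An [env_stats()] object.
#' @export
match_drifter_window <- function(drifter_track, sst, window_days = 11) {
  st <- drifter_track$states
  t_end <- max(st$time)
  t_start <- t_end - window_days
  if (min(st$time) > t_start + 1e-9)
    stop("match_drifter_window: track shorter than the requested window")
  sub <- st[st$time >= t_start - 1e-9, , drop = FALSE]
  trajectory_env_stats(list(states = sub), sst)
}

#' Write trajectories to CSV
#'
#' One row per (particle, step): `particle_id, step, time, lat, lon, status`.
#'
#' @param trajectories List of [trajectory()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories_csv <- function(trajectories, path) {
  rows <- lapply(seq_along(trajectories), function(i) {
    t <- trajectories[[i]]
    data.frame(particle_id = i, step = seq_len(nrow(t$states)) - 1L,
               time = t$states$time, lat = t$states$lat, lon = t$states$lon,
               status = t$status)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
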