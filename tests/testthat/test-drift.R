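test_that("seeding respects radius, time jitter and determinism", {
  p1 <- seed_particles(-45, 170, 100, n = 1000, radius_km = 1, seed = 42)
  d <- haversine_km(-45, 170, p1$lat, p1$lon)
  expect_true(all(d <= 1 + 1e-9))
  expect_true(all(abs(p1$time - 100) <= 1))
  expect_true(all(p1$crosswind_sign %in% c(-1L, 1L)))
  expect_true(all(p1$dw_slope >= 0) && all(p1$cw_slope >= 0))
  p2 <- seed_particles(-45, 170, 100, n = 1000, radius_km = 1, seed = 42)
  expect_identical(p1, p2)
  p3 <- seed_particles(-45, 170, 100, n = 50, radius_km = 1e-9, seed = 1)
  expect_true(all(haversine_km(-45, 170, p3$lat, p3$lon) < 1e-6))
  expect_error(seed_particles(-45, 170, 100, n = 0), "n must be")
  expect_error(seed_particles(-45, 170, 100, n = 5, radius_km = 0), "radius")
})

test_that("leeway velocity follows the downwind/crosswind geometry", {
  p <- data.frame(dw_slope = 0.02, cw_slope = 0, crosswind_sign = 1L)
  lw <- leeway_velocity(10, 0, p)
  expect_equal(c(lw$u, lw$v), c(0.2, 0))
  expect_equal(unlist(leeway_velocity(0, 0, p)), c(u = 0, v = 0))
  pm <- data.frame(dw_slope = 0, cw_slope = 0.01, crosswind_sign = -1L)
  lw2 <- leeway_velocity(10, 0, pm)
  expect_equal(c(lw2$u, lw2$v), c(0, -0.1))
  # crosswind is perpendicular: rotating the wind rotates the leeway
  pp <- data.frame(dw_slope = 0, cw_slope = 0.01, crosswind_sign = 1L)
  lw3 <- leeway_velocity(0, 10, pp)
  expect_equal(c(lw3$u, lw3$v), c(-0.1, 0))
})

test_that("backward Euler advection matches the uniform-current closed form", {
  cu <- uniform_field(0.5, "vector_u")
  cv <- uniform_field(0, "vector_v")
  tr <- advect_backward(bare_particle(), cu, cv, max_days = 1)
  endp <- tr$states[nrow(tr$states), ]
  disp <- haversine_km(-45, 170, endp$lat, endp$lon)
  expect_equal(disp, 43.2, tolerance = 1e-3)   # 0.5 m/s * 86400 s
  expect_lt(endp$lon, 170)                      # due west of start
  expect_equal(endp$lat, -45, tolerance = 1e-9)
  expect_equal(tr$status, "timed_out")
  expect_equal(tr$elapsed_days, 1, tolerance = 1e-9)

  # a 2 km target disc centred on the analytic endpoint is hit in ~1 day
  tz <- target_zone(endp$lat, endp$lon, hit_radius_km = 2)
  tr2 <- advect_backward(bare_particle(), cu, cv, target = tz, max_days = 5)
  expect_equal(tr2$status, "reached_target")
  expect_equal(tr2$elapsed_days, 1, tolerance = 0.05)

  # zero forcing: stationary, times out
  z <- uniform_field(0, "vector_u")
  tr3 <- advect_backward(bare_particle(), z, z, max_days = 2)
  expect_equal(tr3$status, "timed_out")
  expect_equal(tr3$states$lat[1], tr3$states$lat[nrow(tr3$states)])

  # forcing that does not cover the integration window errors up front
  short <- grid_field(c(-48, -42), c(164, 176), c(29, 31),
                      array(0.1, c(2, 2, 2)), "vector_u")
  expect_error(advect_backward(bare_particle(), short, cv, max_days = 10),
               "cover")
})

test_that("backward-then-forward advection is reversible in a static zonal flow", {
  cu <- uniform_field(0.4, "vector_u")
  cv <- uniform_field(0, "vector_v")
  back <- advect_backward(bare_particle(), cu, cv, max_days = 2)
  endp <- back$states[nrow(back$states), ]
  fwd <- advect_particles(bare_particle(lat = endp$lat, lon = endp$lon,
                                        time = endp$time),
                          cu, cv, forward = TRUE, max_days = 2)[[1]]
  fin <- fwd$states[nrow(fwd$states), ]
  expect_lt(abs(fin$lat - (-45)), 1e-6)
  expect_lt(abs(fin$lon - 170), 1e-6)
})

test_that("halving the time step perturbs endpoints by O(dt) only", {
  # spatially varying current so the step size matters
  la <- seq(-48, -42, length.out = 13)
  lo <- seq(164, 176, length.out = 25)
  uu <- array(0, c(2, 13, 25)); vv <- array(0, c(2, 13, 25))
  for (t in 1:2) {
    uu[t, , ] <- matrix(0.3 * sin(lo / 2), 13, 25, byrow = TRUE)
    vv[t, , ] <- 0.2 * cos(la) %o% rep(1, 25)
  }
  cu <- grid_field(la, lo, c(0, 400), uu, "vector_u")
  cv <- grid_field(la, lo, c(0, 400), vv, "vector_v")
  ends <- lapply(c(2, 1, 0.5, 0.25), function(dt) {
    tr <- advect_backward(bare_particle(), cu, cv, dt_hours = dt, max_days = 2)
    unlist(tr$states[nrow(tr$states), c("lat", "lon")])
  })
  diffs <- vapply(1:3, function(i) sqrt(sum((ends[[i]] - ends[[i + 1]])^2)), 0)
  expect_true(all(diff(diffs) < 0))          # successive refinement shrinks
  expect_lt(diffs[3], diffs[1])              # and converges as dt -> 0
})

test_that("trajectories are invariant to crosswind sign when the slope is zero", {
  cu <- uniform_field(0.2, "vector_u"); cv <- uniform_field(0, "vector_v")
  wu <- uniform_field(5, "vector_u"); wv <- uniform_field(3, "vector_v")
  p <- bare_particle(); p$dw_slope <- 0.02
  pminus <- p; pminus$crosswind_sign <- -1L
  t1 <- advect_backward(p, cu, cv, wu, wv, max_days = 1)
  t2 <- advect_backward(pminus, cu, cv, wu, wv, max_days = 1)
  expect_equal(t1$states, t2$states)
})

test_that("raft summaries aggregate reach fraction, time and SST medians", {
  mk <- function(el, status) {
    trajectory(data.frame(time = c(30, 30 - el), lat = -45, lon = 170), status)
  }
  trs <- c(lapply(c(3, 5, 7), mk, status = "reached_target"),
           lapply(rep(1, 7), mk, status = "left_domain"))
  sm <- summarize_raft(trs)
  expect_equal(sm$fraction_reached, 0.3)
  expect_equal(sm$median_raft_time, 5)
  expect_equal(sort(sm$times_to_source), c(3, 5, 7))

  sst <- uniform_field(13)
  same <- lapply(rep(4, 5), mk, status = "reached_target")
  sm2 <- summarize_raft(same, sst)
  expect_equal(sm2$representative_sst, 13)
  expect_equal(sm2$representative_sigma_sst, 0)

  none <- lapply(rep(2, 4), mk, status = "left_domain")
  sm3 <- summarize_raft(none, sst)
  expect_equal(sm3$fraction_reached, 0)
  expect_true(is.na(sm3$median_raft_time))
  expect_true(is.na(sm3$representative_sst))
})

test_that("drifter windows restrict to the trailing days and match closed forms", {
  sst <- uniform_field(9, times = c(0, 40), n = 41)
  stat_track <- trajectory(data.frame(time = 0:20, lat = -45, lon = 170),
                           "timed_out")
  expect_equal(match_drifter_window(stat_track, sst)$sigma_sst, 0)

  # crossing a linear front at constant speed: samples are an arithmetic
  # sequence; sample sd of n equally spaced values d apart is d*sqrt(n(n+1)/12)
  front <- lon_gradient_field(slope = 1)
  mv <- trajectory(data.frame(time = 0:20, lat = -45, lon = 165 + 0.2 * (0:20)),
                   "timed_out")
  es <- match_drifter_window(mv, front, window_days = 11)
  expect_equal(es$n_samples, 12)  # 6-hourly would differ; daily states here
  d <- 0.2
  expect_equal(es$sigma_sst, d * sqrt(12 * 13 / 12), tolerance = 1e-9)
  expect_equal(formals(match_drifter_window)$window_days, 11)
  short <- trajectory(data.frame(time = 0:5, lat = -45, lon = 170), "timed_out")
  expect_error(match_drifter_window(short, sst), "shorter")
})

test_that("trajectory CSV export is tidy", {
  tr <- list(trajectory(data.frame(time = 2:0, lat = c(-45, -45.1, -45.2),
                                   lon = 170:172), "timed_out"))
  p <- withr::local_tempfile(fileext = ".csv")
  write_trajectories_csv(tr, p)
  df <- read.csv(p)
  expect_equal(names(df), c("particle_id", "step", "time", "lat", "lon",
                            "status"))
  expect_equal(nrow(df), 3)
  expect_equal(df$status, rep("timed_out", 3))
})
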