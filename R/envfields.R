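#' Gridded environmental fields
#'
#' A `grid_field` holds a scalar or vector-component field sampled on a
#' regular latitude/longitude/time grid: sea surface temperature (degrees C)
#' or current/wind velocity components (m/s). Values are stored as a
#' 3-dimensional array indexed (time, lat, lon). An optional validity mask
#' marks land (or otherwise invalid) cells.
#'
#' @param lats Numeric vector of latitudes, strictly ascending (degrees).
#' @param lons Numeric vector of longitudes, strictly ascending (degrees).
#' @param times Numeric vector of times in days since an arbitrary epoch,
#'   strictly ascending and (for multi-slice fields) regularly spaced.
#' @param values Numeric array with dim `c(length(times), length(lats),
#'   length(lons))`.
#' @param kind One of `"scalar"`, `"vector_u"`, `"vector_v"`.
#' @param mask Optional logical matrix `(lat, lon)`; `TRUE` marks valid
#'   (water) cells. `NULL` means everywhere valid.
#' @return An object of class `grid_field`.
#' @export
grid_field <- function(lats, lons, times, values, kind = "scalar", mask = NULL) {
  kind <- match.arg(kind, c("scalar", "vector_u", "vector_v"))
  if (length(lats) < 1 || length(lons) < 1 || length(times) < 1)
    stop("grid_field: empty axis")
  if (any(diff(lats) <= 0)) stop("grid_field: lats must be strictly ascending")
  if (any(diff(lons) <= 0)) stop("grid_field: lons must be strictly ascending")
  if (any(diff(times) <= 0)) stop("grid_field: times must be strictly ascending")
  values <- array(as.numeric(values),
                  dim = c(length(times), length(lats), length(lons)))
  if (is.null(mask)) {
    if (anyNA(values)) stop("grid_field: NaN/NA values without a mask")
  } else {
    mask <- matrix(as.logical(mask), length(lats), length(lons))
    for (ti in seq_along(times)) {
      sl <- matrix(values[ti, , ], length(lats), length(lons))
      if (anyNA(sl[mask])) stop("grid_field: NA values inside the valid mask")
    }
  }
  structure(list(lats = lats, lons = lons, times = times,
                 values = values, kind = kind, mask = mask),
            class = "grid_field")
}

#' @export
print.grid_field <- function(x, ...) {
  cat(sprintf("<grid_field %s: %d times x %d lats x %d lons>\n",
              x$kind, length(x$times), length(x$lats), length(x$lons)))
  cat(sprintf("  lat [%.3f, %.3f]  lon [%.3f, %.3f]  time [%.2f, %.2f] days\n",
              min(x$lats), max(x$lats), min(x$lons), max(x$lons),
              min(x$times), max(x$times)))
  invisible(x)
}

# locate x on an ascending axis; returns list(i0, w) with
# value = (1-w)*axis[i0] + w*axis[i0+1]; degenerate single-point axes allowed
.axis_locate <- function(axis, x, name) {
  n <- length(axis)
  eps <- 1e-9 * max(1, abs(axis[n] - axis[1]))
  if (any(x < axis[1] - eps) || any(x > axis[n] + eps))
    stop(sprintf("interpolate_field: query out of bounds on %s axis", name))
  if (n == 1L) return(list(i0 = rep(1L, length(x)), w = rep(0, length(x))))
  i0 <- findInterval(x, axis, rightmost.closed = TRUE)
  i0[i0 < 1L] <- 1L
  i0[i0 >= n] <- n - 1L
  w <- (x - axis[i0]) / (axis[i0 + 1L] - axis[i0])
  w <- pmin(1, pmax(0, w))
  list(i0 = i0, w = w)
}

# values at (ti, lat-index, lon-index) for vectors of indices
.fld_at <- function(field, ti, ai, oi) {
  d <- dim(field$values)
  field$values[cbind(ti, ai, oi)]
}

#' Interpolate a gridded field at points
#'
#' Bilinear interpolation in space and linear interpolation in time; exact at
#' grid nodes. When a validity mask is present and a corner of the enclosing
#' cell is masked, the corner value is replaced with the nearest valid corner
#' of the same cell; if all four corners are masked, an error is raised.
#'
#' @param field A [grid_field()].
#' @param lat,lon,time Numeric vectors (recycled to a common length) of query
#'   coordinates; must lie within the grid bounds.
#' @return Numeric vector of interpolated values.
#' @export
interpolate_field <- function(field, lat, lon, time) {
  n <- max(length(lat), length(lon), length(time))
  lat <- rep_len(lat, n); lon <- rep_len(lon, n); time <- rep_len(time, n)
  la <- .axis_locate(field$lats, lat, "lat")
  lo <- .axis_locate(field$lons, lon, "lon")
  tt <- .axis_locate(field$times, time, "time")
  nlat <- length(field$lats); nlon <- length(field$lons); nt <- length(field$times)
  a0 <- la$i0; a1 <- pmin(a0 + 1L, nlat)
  o0 <- lo$i0; o1 <- pmin(o0 + 1L, nlon)
  t0 <- tt$i0; t1 <- pmin(t0 + 1L, nt)

  corner <- function(ti, ai, oi) {
    v <- .fld_at(field, ti, ai, oi)
    if (!is.null(field$mask)) {
      invalid <- !field$mask[cbind(ai, oi)]
      if (any(invalid)) v[invalid] <- NA_real_
    }
    v
  }
  # spatial corners at each of two time slices
  bil <- function(ti) {
    v00 <- corner(ti, a0, o0); v01 <- corner(ti, a0, o1)
    v10 <- corner(ti, a1, o0); v11 <- corner(ti, a1, o1)
    if (!is.null(field$mask)) {
      m <- cbind(v00, v01, v10, v11)
      bad <- is.na(m)
      if (any(bad)) {
        # distances (in fractional cell units) from query to the 4 corners
        wa <- la$w; wo <- lo$w
        dist2 <- cbind(wa^2 + wo^2, wa^2 + (1 - wo)^2,
                       (1 - wa)^2 + wo^2, (1 - wa)^2 + (1 - wo)^2)
        for (r in which(rowSums(bad) > 0)) {
          ok <- which(!bad[r, ])
          if (!length(ok))
            stop("interpolate_field: all enclosing cell corners are masked")
          nn <- ok[which.min(dist2[r, ok])]
          m[r, is.na(m[r, ])] <- m[r, nn]
        }
        v00 <- m[, 1]; v01 <- m[, 2]; v10 <- m[, 3]; v11 <- m[, 4]
      }
    }
    (1 - la$w) * ((1 - lo$w) * v00 + lo$w * v01) +
      la$w * ((1 - lo$w) * v10 + lo$w * v11)
  }
  s0 <- bil(t0)
  if (all(tt$w == 0)) return(s0)
  s1 <- bil(t1)
  (1 - tt$w) * s0 + tt$w * s1
}

#' Environmental summary statistics
#'
#' Mean and sample standard deviation of sea surface temperature over a set
#' of samples, the sigma-SST statistic used as a proxy for environmental
#' variability.
#'
#' @param values Numeric vector of SST samples.
#' @return A list of class `env_stats` with `mean_sst`, `sigma_sst`,
#'   `n_samples`.
#' @export
env_stats <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  structure(list(mean_sst = if (n >= 1) mean(values) else NA_real_,
                 sigma_sst = if (n >= 2) stats::sd(values) else NA_real_,
                 n_samples = n),
            class = "env_stats")
}

#' SST statistics along a trajectory
#'
#' Interpolates SST at every trajectory state that falls inside the grid
#' (in space and time) and returns the mean and sample standard deviation.
#' Out-of-bounds states are dropped; at least two in-bounds states are
#' required.
#'
#' @param traj A [trajectory()] (or any list with a `states` data frame
#'   holding `time`, `lat`, `lon`).
#' @param sst A scalar [grid_field()] of SST.
#' @return An [env_stats()] object.
#' @export
trajectory_env_stats <- function(traj, sst) {
  st <- traj$states
  inb <- st$lat >= min(sst$lats) & st$lat <= max(sst$lats) &
    st$lon >= min(sst$lons) & st$lon <= max(sst$lons) &
    st$time >= min(sst$times) & st$time <= max(sst$times)
  if (sum(inb) < 2)
    stop("trajectory_env_stats: fewer than 2 in-bounds trajectory points")
  v <- interpolate_field(sst, st$lat[inb], st$lon[inb], st$time[inb])
  env_stats(v)
}

#' SST statistics at a fixed point over a trailing window
#'
#' Samples the field at its native (daily) time resolution at a fixed
#' location for the `window_days` days up to and including `end_time`, i.e.
#' the window `[end_time - window_days + 1, end_time]`. The default window of
#' 11 days is the median successful macroalgal rafting period.
#'
#' @param sst A scalar [grid_field()].
#' @param lat,lon Query point (degrees).
#' @param end_time End of the window (days).
#' @param window_days Window length in days (default 11).
#' @return An [env_stats()] object.
#' @export
static_point_stats <- function(sst, lat, lon, end_time, window_days = 11) {
  if (window_days < 2) stop("static_point_stats: window_days must be >= 2")
  t0 <- end_time - window_days + 1
  if (t0 < min(sst$times) - 1e-9 || end_time > max(sst$times) + 1e-9)
    stop("static_point_stats: window exceeds the field's time range")
  ts <- sst$times[sst$times >= t0 - 1e-9 & sst$times <= end_time + 1e-9]
  if (length(ts) < 2)
    stop("static_point_stats: fewer than 2 native time samples in window")
  v <- interpolate_field(sst, rep(lat, length(ts)), rep(lon, length(ts)), ts)
  env_stats(v)
}

#' Write / read a gridded field as long-format CSV
#'
#' Plain-text dialect with columns `time, lat, lon, value`; masked cells are
#' omitted. Round-trips exactly for finite values.
#'
#' @param field A [grid_field()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_field_csv <- function(field, path) {
  grid <- expand.grid(time = field$times, lat = field$lats, lon = field$lons,
                      KEEP.OUT.ATTRS = FALSE)
  val <- as.vector(field$values)
  keep <- rep(TRUE, nrow(grid))
  if (!is.null(field$mask)) {
    mk <- expand.grid(t = seq_along(field$times), a = seq_along(field$lats),
                      o = seq_along(field$lons), KEEP.OUT.ATTRS = FALSE)
    keep <- field$mask[cbind(mk$a, mk$o)]
  }
  df <- data.frame(time = grid$time[keep], lat = grid$lat[keep],
                   lon = grid$lon[keep], value = val[keep])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_field_csv
#' @param kind Field kind passed to [grid_field()].
#' @export
read_field_csv <- function(path, kind = "scalar") {
  df <- utils::read.csv(path)
  need <- c("time", "lat", "lon", "value")
  if (!all(need %in% names(df)))
    stop("read_field_csv: expected columns time,lat,lon,value in ", path)
  lats <- sort(unique(df$lat)); lons <- sort(unique(df$lon))
  times <- sort(unique(df$time))
  arr <- array(NA_real_, c(length(times), length(lats), length(lons)))
  ti <- match(df$time, times); ai <- match(df$lat, lats); oi <- match(df$lon, lons)
  arr[cbind(ti, ai, oi)] <- df$value
  mask <- NULL
  if (anyNA(arr)) {
    # cells missing at every time are masked (land); partial gaps are errors
    miss <- apply(is.na(arr), c(2, 3), all)
    partial <- apply(is.na(arr), c(2, 3), any) & !miss
    if (any(partial))
      stop("read_field_csv: cells with partial time coverage in ", path)
    mask <- !miss
  }
  grid_field(lats, lons, times, arr, kind = kind, mask = mask)
}
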