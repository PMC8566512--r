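# Lagrangian backtracking of sinking particles through a reversed flow field,
# sea-ice origin classification, and trajectory statistics.

#' Gridded ocean velocity field
#'
#' Regular lon/lat/depth/time grid of eastward (`u`), northward (`v`) and
#' upward (`w`) velocities in m/s. Depth is in metres, positive down; time is
#' in days (by convention day-of-year). All axes must be strictly monotonic
#' and all values finite.
#'
#' @param lon,lat,depth,time Axis vectors.
#' @param u,v,w Arrays of dimension `c(nlon, nlat, ndepth, ntime)`.
#' @return An object of class `velocity_field`.
#' @export
velocity_field <- function(lon, lat, depth, time, u, v, w) {
  for (ax in list(lon = lon, lat = lat, depth = depth, time = time)) {
    if (!.is_strictly_monotonic(ax)) {
      stop("velocity_field axes must be strictly monotonic with >= 2 values",
           call. = FALSE)
    }
  }
  dims <- c(length(lon), length(lat), length(depth), length(time))
  for (comp in list(u = u, v = v, w = w)) {
    if (!identical(dim(comp), as.integer(dims))) {
      stop("u, v, w must have dim c(nlon, nlat, ndepth, ntime)", call. = FALSE)
    }
    if (!all(is.finite(comp))) stop("velocities must be finite", call. = FALSE)
  }
  structure(list(lon = lon, lat = lat, depth = depth, time = time,
                 u = u, v = v, w = w),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("velocity_field: %d lon x %d lat x %d depth x %d time\n",
              length(x$lon), length(x$lat), length(x$depth), length(x$time)))
  cat(sprintf("  lon [%g, %g] deg, lat [%g, %g] deg, depth [%g, %g] m, time [%g, %g] d\n",
              min(x$lon), max(x$lon), min(x$lat), max(x$lat),
              min(x$depth), max(x$depth), min(x$time), max(x$time)))
  invisible(x)
}

#' Sea-ice concentration series
#'
#' @param lon,lat,time Axis vectors (time in days, typically daily slices).
#' @param conc Array `c(nlon, nlat, ntime)` of concentrations in `[0, 1]`.
#' @return An object of class `ice_series`.
#' @export
ice_series <- function(lon, lat, time, conc) {
  for (ax in list(lon, lat, time)) {
    if (!.is_strictly_monotonic(ax)) {
      stop("ice_series axes must be strictly monotonic", call. = FALSE)
    }
  }
  if (!identical(dim(conc),
                 as.integer(c(length(lon), length(lat), length(time))))) {
    stop("conc must have dim c(nlon, nlat, ntime)", call. = FALSE)
  }
  if (any(conc < 0 | conc > 1, na.rm = TRUE)) {
    stop("ice concentrations must lie in [0, 1]", call. = FALSE)
  }
  structure(list(lon = lon, lat = lat, time = time, conc = conc),
            class = "ice_series")
}

#' Particle release specification
#'
#' Describes where and when virtual particles are released for backtracking:
#' at a station, 300 m above the seafloor by default, once per release date,
#' rising through the reversed field at the given sinking speed.
#'
#' @param lon,lat Station coordinates (deg).
#' @param seafloor_depth Seafloor depth at the station (m).
#' @param sinking_speed_m_d Particle sinking speed (m/d), > 0.
#' @param release_offset Height above the seafloor at which particles start
#'   (m), default 300.
#' @param release_dates Numeric days (day-of-year) of release; default daily
#'   over a year.
#' @param time_step_min Integration step (minutes), default 30.
#' @param store_interval_h Position storage interval (hours), default 2
#'   (bi-hourly).
#' @param surfacing_window Numeric `c(first, last)` day; only particles
#'   surfacing inside this window enter surfacing statistics. Default
#'   `c(61, 213)`, i.e. March 1 - July 31 of a leap year.
#' @param max_steps Safety cap on integration steps.
#' @return An object of class `release_spec`.
#' @export
release_spec <- function(lon, lat, seafloor_depth, sinking_speed_m_d,
                         release_offset = 300,
                         release_dates = seq(1, 366),
                         time_step_min = 30, store_interval_h = 2,
                         surfacing_window = c(61, 213),
                         max_steps = 20000L) {
  .stopifnot_scalar_pos(sinking_speed_m_d, "sinking_speed_m_d")
  .stopifnot_scalar_pos(time_step_min, "time_step_min")
  .stopifnot_scalar_pos(store_interval_h, "store_interval_h")
  release_depth <- seafloor_depth - release_offset
  if (release_depth <= 0) {
    stop("release depth (seafloor_depth - release_offset) must be positive",
         call. = FALSE)
  }
  structure(list(lon = lon, lat = lat, seafloor_depth = seafloor_depth,
                 release_offset = release_offset,
                 release_depth = release_depth,
                 release_dates = release_dates,
                 sinking_speed_m_d = sinking_speed_m_d,
                 time_step_min = time_step_min,
                 store_interval_h = store_interval_h,
                 surfacing_window = surfacing_window,
                 max_steps = as.integer(max_steps)),
            class = "release_spec")
}

#' Sea-ice classification parameters
#'
#' @param threshold Concentration threshold in (0, 1); default 0.15. Cells at
#'   or above the threshold count as ice-covered (inclusive convention).
#' @return An object of class `ice_params`.
#' @export
ice_params <- function(threshold = 0.15) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    stop("threshold must lie in (0, 1)", call. = FALSE)
  }
  structure(list(threshold = threshold), class = "ice_params")
}

# index + fractional weight along one axis for linear interpolation;
# clamp = FALSE marks out-of-range queries with NA fractions
.axis_locate <- function(axis, x) {
  n <- length(axis)
  i <- findInterval(x, axis, rightmost.closed = TRUE)
  out <- x < axis[1] | x > axis[n]
  i <- pmin(pmax(i, 1L), n - 1L)
  frac <- (x - axis[i]) / (axis[i + 1L] - axis[i])
  frac[out] <- NA_real_
  list(i = i, frac = frac)
}

#' Interpolate a velocity field at arbitrary points
#'
#' Trilinear in lon/lat/depth and linear in time; exact at grid nodes.
#' Queries outside the grid hull return `NA` (the out-of-domain signal; the
#' caller decides the particle's fate).
#'
#' @param field A [velocity_field()].
#' @param lon,lat,depth,time Query coordinates (vectorised, recycled to a
#'   common length).
#' @return `data.frame(u, v, w)` with one row per query point.
#' @export
interpolate_field <- function(field, lon, lat, depth, time) {
  stopifnot(inherits(field, "velocity_field"))
  n <- max(length(lon), length(lat), length(depth), length(time))
  lon <- rep_len(lon, n); lat <- rep_len(lat, n)
  depth <- rep_len(depth, n); time <- rep_len(time, n)
  loc <- list(.axis_locate(field$lon, lon), .axis_locate(field$lat, lat),
              .axis_locate(field$depth, depth), .axis_locate(field$time, time))
  ok <- !Reduce(`|`, lapply(loc, function(l) is.na(l$frac)))
  out <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("u", "v", "w")))
  if (any(ok)) {
    acc <- matrix(0, sum(ok), 3)
    fr <- lapply(loc, function(l) l$frac[ok])
    ii <- lapply(loc, function(l) l$i[ok])
    for (corner in 0:15) {
      d <- c(corner %% 2, corner %/% 2 %% 2, corner %/% 4 %% 2, corner %/% 8)
      wgt <- rep(1, sum(ok))
      idx <- matrix(0L, sum(ok), 4)
      for (k in 1:4) {
        wgt <- wgt * if (d[k] == 1) fr[[k]] else 1 - fr[[k]]
        idx[, k] <- ii[[k]] + d[k]
      }
      acc[, 1] <- acc[, 1] + wgt * field$u[idx]
      acc[, 2] <- acc[, 2] + wgt * field$v[idx]
      acc[, 3] <- acc[, 3] + wgt * field$w[idx]
    }
    out[ok, ] <- acc
  }
  as.data.frame(out)
}

#' Backtrack sinking particles to the surface
#'
#' Integrates particle positions backward in time through the reversed flow
#' field: per step of length `dt`, the horizontal displacement is
#' `-(u, v) * dt` and the vertical displacement is the reversed net particle
#' velocity, so the particle rises at the sinking speed minus the (upward
#' positive) model vertical velocity. Integration uses explicit Euler at the
#' configured step (default 30 min; `integrator = "rk4"` is available for
#' convergence checks) and stops when the particle reaches the top grid
#' level, leaves the domain (frozen and flagged, excluded from surfacing
#' statistics), or hits the step cap. Positions are stored every
#' `store_interval_h` hours.
#'
#' @param field A [velocity_field()].
#' @param release A [release_spec()]; the release position must lie inside
#'   the grid.
#' @param integrator `"euler"` (default) or `"rk4"`.
#' @return An object of class `trajectory_ensemble`: a list with `summary`
#'   (one row per particle: release date, status, surfacing lon/lat/time,
#'   `in_window`) and `paths` (per particle matrix of stored
#'   time/lon/lat/depth).
#' @export
backtrack <- function(field, release, integrator = c("euler", "rk4")) {
  stopifnot(inherits(field, "velocity_field"), inherits(release, "release_spec"))
  integrator <- match.arg(integrator)
  surface_depth <- min(field$depth)
  z0 <- release$release_depth
  if (z0 > max(field$depth) || z0 < min(field$depth) ||
      release$lon < min(field$lon) || release$lon > max(field$lon) ||
      release$lat < min(field$lat) || release$lat > max(field$lat)) {
    stop("release position outside the velocity grid", call. = FALSE)
  }
  if (any(release$release_dates < min(field$time) |
          release$release_dates > max(field$time))) {
    stop("release dates outside the field time span", call. = FALSE)
  }
  n <- length(release$release_dates)
  dt_s <- release$time_step_min * 60
  dt_d <- dt_s / 86400
  ws_ms <- release$sinking_speed_m_d / 86400
  k_store <- max(1L, round(release$store_interval_h * 60 / release$time_step_min))
  m_per_deg <- pi / 180 * .EARTH_RADIUS_KM * 1000

  plon <- rep(release$lon, n); plat <- rep(release$lat, n)
  pdep <- rep(z0, n); ptim <- as.numeric(release$release_dates)
  status <- rep("active", n)
  surf <- data.frame(lon = rep(NA_real_, n), lat = NA_real_, time = NA_real_)

  n_slots <- release$max_steps %/% k_store + 2L
  hist_arr <- array(NA_real_, dim = c(n, n_slots, 4),
                    dimnames = list(NULL, NULL, c("time", "lon", "lat", "depth")))
  hist_arr[, 1, ] <- cbind(ptim, plon, plat, pdep)
  slot <- rep(1L, n)

  record <- function(i) {
    slot[i] <<- slot[i] + 1L
    hist_arr[cbind(rep(i, each = 1), slot[i], 1)] <<- ptim[i]
    hist_arr[cbind(i, slot[i], 2)] <<- plon[i]
    hist_arr[cbind(i, slot[i], 3)] <<- plat[i]
    hist_arr[cbind(i, slot[i], 4)] <<- pdep[i]
  }

  deriv <- function(lon, lat, dep, tim) {
    uvw <- interpolate_field(field, lon, lat, dep, tim)
    list(dlon = -uvw$u / (m_per_deg * cos(lat * pi / 180)) * dt_s,
         dlat = -uvw$v / m_per_deg * dt_s,
         ddep = -(ws_ms - uvw$w) * dt_s,
         na = !is.finite(uvw$u))
  }

  for (step in seq_len(release$max_steps)) {
    act <- which(status == "active")
    if (!length(act)) break
    d1 <- deriv(plon[act], plat[act], pdep[act], ptim[act])
    if (integrator == "rk4") {
      d2 <- deriv(plon[act] + d1$dlon / 2, plat[act] + d1$dlat / 2,
                  pdep[act] + d1$ddep / 2, ptim[act] - dt_d / 2)
      d3 <- deriv(plon[act] + d2$dlon / 2, plat[act] + d2$dlat / 2,
                  pdep[act] + d2$ddep / 2, ptim[act] - dt_d / 2)
      d4 <- deriv(plon[act] + d3$dlon, plat[act] + d3$dlat,
                  pdep[act] + d3$ddep, ptim[act] - dt_d)
      dlon <- (d1$dlon + 2 * d2$dlon + 2 * d3$dlon + d4$dlon) / 6
      dlat <- (d1$dlat + 2 * d2$dlat + 2 * d3$dlat + d4$dlat) / 6
      ddep <- (d1$ddep + 2 * d2$ddep + 2 * d3$ddep + d4$ddep) / 6
      bad <- d1$na | d2$na | d3$na | d4$na
    } else {
      dlon <- d1$dlon; dlat <- d1$dlat; ddep <- d1$ddep; bad <- d1$na
    }
    status[act[bad]] <- "exited"
    mv <- act[!bad]
    if (length(mv)) {
      plon[mv] <- plon[mv] + dlon[!bad]
      plat[mv] <- plat[mv] + dlat[!bad]
      pdep[mv] <- pdep[mv] + ddep[!bad]
      ptim[mv] <- ptim[mv] - dt_d
      up <- mv[pdep[mv] <= surface_depth]
      if (length(up)) {
        pdep[up] <- surface_depth
        status[up] <- "surfaced"
        surf$lon[up] <- plon[up]; surf$lat[up] <- plat[up]
        surf$time[up] <- ptim[up]
        for (i in up) record(i)
      }
      if (step %% k_store == 0) {
        still <- mv[status[mv] == "active"]
        for (i in still) record(i)
      }
    }
  }
  status[status == "active"] <- "max_steps"

  in_window <- status == "surfaced" &
    surf$time >= release$surfacing_window[1] &
    surf$time <= release$surfacing_window[2]
  paths <- lapply(seq_len(n), function(i) {
    hist_arr[i, seq_len(slot[i]), , drop = FALSE][1, , ]
  })
  structure(list(
    summary = data.frame(particle = seq_len(n),
                         release_date = release$release_dates,
                         status = status,
                         surf_lon = surf$lon, surf_lat = surf$lat,
                         surf_time = surf$time,
                         in_window = in_window),
    paths = paths, release = release, surface_depth = surface_depth),
    class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  tab <- table(x$summary$status)
  cat(sprintf("trajectory_ensemble: %d particles (%s); %d surfaced in window\n",
              nrow(x$summary),
              paste(names(tab), tab, sep = "=", collapse = ", "),
              sum(x$summary$in_window)))
  invisible(x)
}

.surfaced <- function(traj) {
  stopifnot(inherits(traj, "trajectory_ensemble"))
  traj$summary[traj$summary$in_window, , drop = FALSE]
}

.nearest_index <- function(axis, x) {
  pmin(pmax(findInterval(x, (axis[-1] + axis[-length(axis)]) / 2) + 1L, 1L),
       length(axis))
}

#' Classify particle surface origins by sea-ice concentration
#'
#' A surfaced particle is labelled ice-covered when the ice concentration at
#' its surfacing position and date (nearest grid cell, nearest daily slice)
#' is at or above the threshold (inclusive convention). The percentage is
#' computed over surfaced-in-window particles only.
#'
#' @param traj A [backtrack()] result.
#' @param ice An [ice_series()].
#' @param params An [ice_params()].
#' @return `list(labels, pct_ice_covered)`; `labels` has one entry per
#'   particle (`"ice-covered"`, `"ice-free"` or `NA` for particles without a
#'   surfacing record).
#' @export
classify_origin <- function(traj, ice, params = ice_params()) {
  stopifnot(inherits(ice, "ice_series"), inherits(params, "ice_params"))
  s <- .surfaced(traj)
  labels <- rep(NA_character_, nrow(traj$summary))
  if (nrow(s) == 0) {
    warning("no particles surfaced within the window")
    return(list(labels = labels, pct_ice_covered = NA_real_))
  }
  ci <- .nearest_index(ice$lon, s$surf_lon)
  cj <- .nearest_index(ice$lat, s$surf_lat)
  ck <- .nearest_index(ice$time, s$surf_time)
  conc <- ice$conc[cbind(ci, cj, ck)]
  lab <- ifelse(conc >= params$threshold, "ice-covered", "ice-free")
  labels[s$particle] <- lab
  list(labels = labels,
       pct_ice_covered = 100 * mean(lab == "ice-covered"))
}

#' Catchment radius of surfaced particles
#'
#' Great-circle distance from the release position to each particle's
#' surfacing position; summarised as median and standard deviation (km).
#'
#' @param traj A [backtrack()] result with at least one surfaced particle.
#' @return `list(median_km, sd_km, distances_km)`.
#' @export
catchment_radius <- function(traj) {
  s <- .surfaced(traj)
  if (nrow(s) == 0) {
    warning("no particles surfaced within the window")
    return(list(median_km = NA_real_, sd_km = NA_real_,
                distances_km = numeric()))
  }
  d <- gc_distance_km(traj$release$lon, traj$release$lat, s$surf_lon, s$surf_lat)
  list(median_km = stats::median(d), sd_km = stats::sd(d), distances_km = d)
}

#' Horizontal trajectory length of surfaced particles
#'
#' Sum of great-circle lengths between consecutive stored horizontal
#' positions per particle (the horizontal projection of the path; the
#' vertical leg is not included), summarised as median and standard
#' deviation (km).
#'
#' @param traj A [backtrack()] result with at least one surfaced particle.
#' @return `list(median_km, sd_km, lengths_km)`.
#' @export
trajectory_length <- function(traj) {
  s <- .surfaced(traj)
  if (nrow(s) == 0) {
    warning("no particles surfaced within the window")
    return(list(median_km = NA_real_, sd_km = NA_real_, lengths_km = numeric()))
  }
  lens <- vapply(s$particle, function(i) {
    p <- traj$paths[[i]]
    if (nrow(p) < 2) return(0)
    sum(gc_distance_km(p[-nrow(p), "lon"], p[-nrow(p), "lat"],
                       p[-1, "lon"], p[-1, "lat"]))
  }, numeric(1))
  list(median_km = stats::median(lens), sd_km = stats::sd(lens),
       lengths_km = lens)
}

#' Bin stored particle positions into a 3-D density
#'
#' Bins all stored positions into depth-by-lon-by-lat boxes (defaults 25 m by
#' 0.05 degrees) and normalises by the total number of stored positions, so
#' the fractions sum to 1.
#'
#' @param traj A [backtrack()] result.
#' @param depth_bin_m Depth bin size (m), default 25.
#' @param horiz_bin_deg Horizontal bin size (degrees), default 0.05.
#' @return `data.frame(lon_bin, lat_bin, depth_bin, fraction)` over occupied
#'   bins; bin coordinates are lower box edges.
#' @export
bin_density <- function(traj, depth_bin_m = 25, horiz_bin_deg = 0.05) {
  stopifnot(inherits(traj, "trajectory_ensemble"))
  .stopifnot_scalar_pos(depth_bin_m, "depth_bin_m")
  .stopifnot_scalar_pos(horiz_bin_deg, "horiz_bin_deg")
  pos <- do.call(rbind, traj$paths)
  if (is.null(pos) || nrow(pos) == 0) {
    warning("empty ensemble")
    return(data.frame(lon_bin = numeric(), lat_bin = numeric(),
                      depth_bin = numeric(), fraction = numeric()))
  }
  key <- paste(floor(pos[, "lon"] / horiz_bin_deg),
               floor(pos[, "lat"] / horiz_bin_deg),
               floor(pos[, "depth"] / depth_bin_m))
  tab <- table(key)
  parts <- do.call(rbind, strsplit(names(tab), " "))
  data.frame(lon_bin = as.numeric(parts[, 1]) * horiz_bin_deg,
             lat_bin = as.numeric(parts[, 2]) * horiz_bin_deg,
             depth_bin = as.numeric(parts[, 3]) * depth_bin_m,
             fraction = as.numeric(tab) / nrow(pos))
}

#' Count ice-covered days at a point
#'
#' Number of time slices within the window whose concentration at the
#' nearest grid cell is at or above the threshold.
#'
#' @param ice An [ice_series()].
#' @param lon,lat Point coordinates (must lie inside the grid).
#' @param window Numeric `c(first, last)` day, inside the series span.
#' @param params An [ice_params()].
#' @return Integer day count.
#' @export
count_ice_days <- function(ice, lon, lat, window = range(ice$time),
                           params = ice_params()) {
  stopifnot(inherits(ice, "ice_series"))
  if (lon < min(ice$lon) || lon > max(ice$lon) ||
      lat < min(ice$lat) || lat > max(ice$lat)) {
    stop("point outside the ice grid", call. = FALSE)
  }
  i <- .nearest_index(ice$lon, lon)
  j <- .nearest_index(ice$lat, lat)
  k <- which(ice$time >= window[1] & ice$time <= window[2])
  sum(ice$conc[i, j, k] >= params$threshold)
}

#' Distance from a point to the sea-ice edge (km)
#'
#' The edge is the set of grid cells at or above the threshold that have a
#' 4-neighbour below it. Returns the minimum great-circle distance from the
#' point to any edge-cell centre; 0 if the cell containing the point is
#' itself an edge cell; `NA` (with a warning) when no cell reaches the
#' threshold or the field is fully ice-covered (no edge exists).
#'
#' @param ice An [ice_series()].
#' @param lon,lat Point coordinates.
#' @param date Numeric day, inside the series span.
#' @param params An [ice_params()].
#' @return Distance in km, or `NA` if no edge exists.
#' @export
distance_to_ice_edge <- function(ice, lon, lat, date, params = ice_params()) {
  stopifnot(inherits(ice, "ice_series"))
  if (date < min(ice$time) || date > max(ice$time)) {
    stop("date outside the ice series span", call. = FALSE)
  }
  k <- .nearest_index(ice$time, date)
  mask <- ice$conc[, , k] >= params$threshold
  if (!any(mask)) {
    warning("no ice at or above the threshold anywhere; no edge")
    return(NA_real_)
  }
  nlon <- length(ice$lon); nlat <- length(ice$lat)
  open <- !mask
  nb_open <- matrix(FALSE, nlon, nlat)
  nb_open[-1, ] <- nb_open[-1, ] | open[-nlon, ]
  nb_open[-nlon, ] <- nb_open[-nlon, ] | open[-1, ]
  nb_open[, -1] <- nb_open[, -1] | open[, -nlat]
  nb_open[, -nlat] <- nb_open[, -nlat] | open[, -1]
  edge <- mask & nb_open
  if (!any(edge)) {
    warning("field fully ice-covered; no edge")
    return(NA_real_)
  }
  pi_ <- .nearest_index(ice$lon, lon)
  pj_ <- .nearest_index(ice$lat, lat)
  if (edge[pi_, pj_]) return(0)
  idx <- which(edge, arr.ind = TRUE)
  min(gc_distance_km(lon, lat, ice$lon[idx[, 1]], ice$lat[idx[, 2]]))
}
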