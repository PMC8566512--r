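test_that("field interpolation is exact at nodes and linear between them", {
  lon <- c(0, 1); lat <- c(70, 71); dep <- c(0, 100); tim <- c(0, 1)
  u <- array(0, c(2, 2, 2, 2)); u[1, 1, 1, 1] <- 1; u[2, 1, 1, 1] <- 3
  fld <- velocity_field(lon, lat, dep, tim, u, u * 0, u * 0)
  expect_equal(interpolate_field(fld, 0, 70, 0, 0)$u, 1)
  expect_equal(interpolate_field(fld, 1, 70, 0, 0)$u, 3)
  expect_equal(interpolate_field(fld, 0.5, 70, 0, 0)$u, 2)
  # constant field is constant everywhere inside the hull
  cf <- uniform_field(u = 0.3)
  q <- interpolate_field(cf, c(-3.2, 11.7), c(75.1, 80.9), c(40, 2000),
                         c(10, 350))
  expect_equal(q$u, c(0.3, 0.3))
  # outside the hull: NA signal
  expect_true(is.na(interpolate_field(cf, 100, 75, 40, 10)$u))
})

test_that("zero flow surfaces at the release point after depth/ws days", {
  fld <- uniform_field(u = 0, v = 0, w = 0)
  rel <- release_spec(2, 78, 2355, sinking_speed_m_d = 50,
                      release_offset = 5, release_dates = 200,
                      surfacing_window = c(0, 400))
  tr <- backtrack(fld, rel)
  s <- tr$summary
  expect_equal(s$status, "surfaced")
  expect_equal(s$surf_lon, 2)
  expect_equal(s$surf_lat, 78)
  # rises (2350 - 5) m at 50 m/d; travel time resolves to the 30-min step
  expect_equal(200 - s$surf_time, (2350 - 5) / 50, tolerance = 0.03)
  expect_equal(catchment_radius(tr)$median_km, 0)
  expect_equal(trajectory_length(tr)$median_km, 0)
})

test_that("uniform flow matches the closed-form advection displacement", {
  u0 <- 0.1; ws <- 52
  fld <- uniform_field(u = u0)
  rel <- release_spec(0, 79, 2355, ws, release_offset = 5,
                      release_dates = 200, surfacing_window = c(0, 400))
  tr <- backtrack(fld, rel)
  s <- tr$summary
  expect_equal(s$status, "surfaced")
  travel_d <- (2350 - 5) / ws
  disp_km <- u0 * travel_d * 86400 / 1000
  one_step_km <- u0 * 30 * 60 / 1000
  # zonal displacement measured along the parallel
  zonal <- abs(s$surf_lon - 0) * pi / 180 * 6371 * cos(79 * pi / 180)
  expect_lt(abs(zonal - disp_km), one_step_km + 1e-6)
  # straight path: trajectory length ~ catchment displacement
  expect_equal(trajectory_length(tr)$median_km, zonal, tolerance = 0.01)
  # reversibility: integrating back with the negated field returns home
  n_steps <- ceiling(travel_d * 48)
  fld_rev <- uniform_field(u = -u0)
  # mirrored vertical rate: the particle descends at ws in this formulation
  fld_rev$w <- fld_rev$w + 2 * ws / 86400
  rel2 <- release_spec(s$surf_lon, s$surf_lat, 305.99, ws,
                       release_offset = 300, release_dates = 100,
                       surfacing_window = c(0, 400),
                       max_steps = n_steps)
  tr2 <- backtrack(fld_rev, rel2)
  p2 <- tr2$paths[[1]]
  final <- p2[nrow(p2), ]
  # slack: one step of surfacing-time discretisation plus up to one storage
  # interval (4 steps) of unrecorded final displacement
  expect_lt(gc_distance_km(final["lon"], final["lat"], 0, 79),
            5 * one_step_km + 0.5)
})

test_that("halving the time step changes the surfacing position by < 1%", {
  fld <- uniform_field(u = 0.08, v = 0.03)
  mk_rel <- function(step) release_spec(0, 78, 2305, 45, release_offset = 5,
                                        release_dates = 180,
                                        time_step_min = step,
                                        surfacing_window = c(0, 400))
  s30 <- backtrack(fld, mk_rel(30))$summary
  s15 <- backtrack(fld, mk_rel(15))$summary
  disp <- gc_distance_km(0, 78, s30$surf_lon, s30$surf_lat)
  shift <- gc_distance_km(s30$surf_lon, s30$surf_lat, s15$surf_lon, s15$surf_lat)
  expect_lt(shift / disp, 0.01)
})

test_that("rotating flow gives a path strictly longer than the end-to-end distance", {
  cfg <- synthetic_config(seed = 1, current_speed_east = 1e-6,
                          current_speed_west = 1e-6,
                          eddy = list(lon0 = 0, lat0 = 79, radius_km = 300,
                                      speed = 0.15))
  fld <- make_velocity_field(cfg)$field
  rel <- release_spec(0.8, 79.3, 2305, 40, release_offset = 5,
                      release_dates = 300, surfacing_window = c(0, 400))
  tr <- backtrack(fld, rel)
  expect_equal(tr$summary$status, "surfaced")
  expect_gt(trajectory_length(tr)$lengths_km,
            1.05 * catchment_radius(tr)$distances_km)
})

test_that("origin classification applies the inclusive 15% threshold", {
  fld <- uniform_field(u = 0, lon = seq(-10, 10, 0.5), lat = seq(76, 82, 0.5))
  rel <- release_spec(c(-5), 79, 2355, 50, release_offset = 5,
                      release_dates = c(100, 150), surfacing_window = c(0, 400))
  tr <- backtrack(fld, rel)
  ice_hi <- edge_ice(edge_lon = 10.5, ice_w = 0.8, time = 0:160)
  expect_equal(classify_origin(tr, ice_hi)$pct_ice_covered, 100)
  ice_lo <- edge_ice(edge_lon = -10.5, ice_w = 0.8, ice_e = 0, time = 0:160)
  expect_equal(classify_origin(tr, ice_lo)$pct_ice_covered, 0)
  ice_edge15 <- edge_ice(edge_lon = 10.5, ice_w = 0.15, time = 0:160)
  res <- classify_origin(tr, ice_edge15)
  expect_equal(res$pct_ice_covered, 100)  # exactly at threshold counts
  expect_equal(res$labels[tr$summary$in_window], rep("ice-covered", 2))
})

test_that("catchment radius and trajectory medians behave on mixed ensembles", {
  # two particles with different travel (release dates in a drifting field
  # would differ; here identical -> sd 0)
  fld <- uniform_field(u = 0.05)
  rel <- release_spec(0, 79, 2355, 50, release_offset = 5,
                      release_dates = c(120, 160),
                      surfacing_window = c(0, 400))
  tr <- backtrack(fld, rel)
  cr <- catchment_radius(tr)
  expect_equal(length(cr$distances_km), 2)
  expect_equal(cr$sd_km, 0, tolerance = 1e-6)
  expect_equal(cr$median_km, stats::median(cr$distances_km))
})

test_that("bin density sums to one and isolates stationary particles", {
  fld0 <- uniform_field(u = 0, v = 0)
  rel <- release_spec(0, 79, 2355, 50, release_offset = 5,
                      release_dates = 100, surfacing_window = c(0, 400))
  tr <- backtrack(fld0, rel)
  bd <- bin_density(tr)
  # stationary in lon/lat: one horizontal column, many depth bins
  expect_equal(sum(bd$fraction), 1)
  expect_equal(unique(bd$lon_bin), 0)
  fld <- uniform_field(u = 0.09, v = 0.02)
  tr2 <- backtrack(fld, rel)
  bd2 <- bin_density(tr2)
  expect_equal(sum(bd2$fraction), 1)
  expect_true(all(bd2$fraction > 0))
})

test_that("ice-day counting and edge distances follow the grid geometry", {
  ice_half <- edge_ice(edge_lon = 0, ice_w = 0.5, time = 0:99)
  expect_equal(count_ice_days(ice_half, -5, 79, c(0, 99)), 100)
  ice_low <- edge_ice(edge_lon = 0, ice_w = 0.10, time = 0:99)
  expect_equal(count_ice_days(ice_low, -5, 79, c(0, 99)), 0)
  # edge sweeping past the point mid-window: covered for the first half
  lon <- seq(-10, 10, 0.5); lat <- seq(76, 82, 0.5); tim <- 0:99
  conc <- array(0, c(length(lon), length(lat), length(tim)))
  for (k in seq_along(tim)) {
    edge <- ifelse(tim[k] < 50, 1, -6)  # edge jumps west at day 50
    conc[lon < edge, , k] <- 0.9
  }
  ice_sweep <- ice_series(lon, lat, tim, conc)
  expect_equal(count_ice_days(ice_sweep, -5, 79, c(0, 99)), 50)
  expect_error(count_ice_days(ice_half, 50, 79), "outside")

  # meridional edge one degree of longitude away at 79N: ~21.2 km
  d <- distance_to_ice_edge(edge_ice(edge_lon = -0.75), lon = 0,
                            lat = 79, date = 0)
  expect_equal(d, 111.195 * cos(79 * pi / 180), tolerance = 0.01)
  # point inside an edge cell
  expect_equal(distance_to_ice_edge(edge_ice(edge_lon = -0.75), -1, 79, 0), 0)
  # fully ice-free: no-edge signal
  expect_warning(
    d0 <- distance_to_ice_edge(edge_ice(ice_w = 0, ice_e = 0), 0, 79, 0),
    "no ice")
  expect_true(is.na(d0))
})

test_that("release and field validation reject inconsistent setups", {
  expect_error(release_spec(0, 79, 200, 50), "release depth")
  expect_error(release_spec(0, 79, 2350, -5), "sinking_speed_m_d")
  fld <- uniform_field()
  expect_error(backtrack(fld, release_spec(100, 79, 2355, 50,
                                           release_dates = 10)),
               "outside")
  expect_error(velocity_field(c(1, 1), 1:2, 1:2, 1:2,
                              array(0, c(2, 2, 2, 2)),
                              array(0, c(2, 2, 2, 2)),
                              array(0, c(2, 2, 2, 2))),
               "monotonic")
  expect_error(ice_series(1:2, 1:2, 1:2, array(2, c(2, 2, 2))), "\\[0, 1\\]")
})
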