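# Synthetic inputs with known ground truth: velocity/ice fields, flux-distance
# series, ASV community suites and aggregate records, so every downstream
# stage is testable without external data.

#' Configuration for the synthetic-data generators
#'
#' Bundles the study conditions emulated by the generators: a two-region
#' domain (ice-covered western half with southward flow, ice-free eastern
#' half with northward flow, mirroring the East Greenland / West Spitzbergen
#' current geometry), an exponential particulate-organic-carbon flux versus
#' ice-edge-distance relation with multiplicative lognormal noise, layered
#' free-living source communities whose particle-associated sinks are known
#' mixtures plus an unknown component, planted depth-enriched ASVs, and
#' sediment communities seeded with a fixed fraction of PA-enriched reads.
#'
#' @param seed Integer seed; a fixed seed gives identical outputs.
#' @param domain List of axis vectors `lon` (deg), `lat` (deg), `depth`
#'   (m, positive down), `time` (days); each strictly monotonic.
#' @param current_speed_east,current_speed_west Meridional jet speeds (m/s)
#'   of the eastern (northward, v > 0) and western (southward, v < 0) halves.
#' @param vertical_velocity Background model vertical velocity (m/s, positive
#'   up), default 0.
#' @param eddy Optional solid-body eddy perturbation,
#'   `list(lon0, lat0, radius_km, speed)` with tangential speed in m/s.
#' @param ice_edge_lon0 Ice-edge longitude at time 0 (deg); ice lies west.
#' @param ice_edge_drift Edge drift (deg/day).
#' @param ice_ramp_deg Width (deg lon) of the smooth ramp from full ice to
#'   open water east of the edge.
#' @param ice_max Concentration west of the edge (>= 0.8).
#' @param flux_model `list(a, b, noise_sigma_log, dist_range)`: intercept
#'   (mg m^-2 d^-1), decay (1/km), lognormal noise sigma, distance range (km).
#'   Defaults follow the long-term trap regression `13.6 * exp(-0.015 x)`.
#' @param community Community-suite settings; see Details.
#' @param aggregates Aggregate/gel settings; see Details.
#'
#' @details
#' `community` fields: `n_asvs`; `layers` (source water layers); `regions`;
#' `stations_per_region`; `fractions` (subset of `"FL"`, `"PA"`);
#' `n_sediment` samples; `reads_range` (per-sample read depth is drawn
#' uniformly from this range, default 5000-30000 so rarefaction to 5000 is
#' always feasible); `profile_sdlog` (lognormal abundance spectrum sigma);
#' `sample_conc` (Dirichlet concentration of per-sample perturbation);
#' `gamma` (mixing matrix rows = sink groups `layer|region`, columns =
#' source layers plus `"Unknown"`, rows summing to 1; `NULL` installs a
#' default motivated by observed water-column source proportions);
#' `planted` = `list(n_per_contrast, lfc)` depth-enriched ASVs planted
#' between consecutive layers; `sediment_seed_fraction` (rho), the fraction
#' of sediment reads drawn from the planted PA-enriched pool.
#'
#' `aggregates` fields: named per-region `n`, `esd_mean_mm`, `esd_cv`,
#' `velocity_mean` (m/d), `velocity_sd`; `pixel_size_um` for gel rendering.
#'
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1,
                             domain = list(
                               lon = seq(-10, 10, by = 0.5),
                               lat = seq(72, 86, by = 0.5),
                               depth = c(5, seq(130, 2605, by = 165)),
                               time = seq(0, 364, by = 7)),
                             current_speed_east = 0.06,
                             current_speed_west = 0.055,
                             vertical_velocity = 0,
                             eddy = NULL,
                             ice_edge_lon0 = 0,
                             ice_edge_drift = 0,
                             ice_ramp_deg = 1,
                             ice_max = 0.95,
                             flux_model = list(a = 13.6, b = -0.015,
                                               noise_sigma_log = 0.3,
                                               dist_range = c(0, 90)),
                             community = list(),
                             aggregates = list()) {
  for (ax in c("lon", "lat", "depth", "time")) {
    if (!.is_strictly_monotonic(domain[[ax]])) {
      stop(sprintf("domain axis '%s' must be strictly monotonic with >= 2 values", ax),
           call. = FALSE)
    }
  }
  .stopifnot_scalar_pos(current_speed_east, "current_speed_east")
  .stopifnot_scalar_pos(current_speed_west, "current_speed_west")
  if (!is.numeric(flux_model$a) || flux_model$a <= 0) {
    stop("flux_model$a must be positive", call. = FALSE)
  }
  community_defaults <- list(
    n_asvs = 400,
    layers = c("surface", "epi", "meso", "bathy"),
    regions = c("ice-covered", "ice-free"),
    stations_per_region = 2,
    fractions = c("FL", "PA"),
    n_sediment = 4,
    reads_range = c(5000, 30000),
    profile_sdlog = 2,
    sample_conc = 400,
    gamma = NULL,
    planted = list(n_per_contrast = 5, lfc = 2, min_rel_abundance = 0.005),
    sediment_seed_fraction = 0.15)
  community <- utils::modifyList(community_defaults, community)
  aggregate_defaults <- list(
    n = c("ice-covered" = 36, "ice-free" = 24),
    esd_mean_mm = c("ice-covered" = 0.9, "ice-free" = 0.6),
    esd_cv = 0.15,
    velocity_mean = c("ice-covered" = 52.8, "ice-free" = 29.5),
    velocity_sd = c("ice-covered" = 5, "ice-free" = 4),
    pixel_size_um = 12)
  aggregates <- utils::modifyList(aggregate_defaults, aggregates)
  if (any(aggregates$esd_mean_mm <= 0) || any(aggregates$velocity_mean <= 0)) {
    stop("aggregate region means must be positive", call. = FALSE)
  }
  if (!is.null(community$gamma)) .check_gamma(community$gamma)
  if (is.list(community$planted) && !is.data.frame(community$planted) &&
      !is.finite(community$planted$lfc)) {
    stop("planted log2 fold changes must be finite", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), domain = domain,
                 current_speed_east = current_speed_east,
                 current_speed_west = current_speed_west,
                 vertical_velocity = vertical_velocity, eddy = eddy,
                 ice_edge_lon0 = ice_edge_lon0,
                 ice_edge_drift = ice_edge_drift,
                 ice_ramp_deg = ice_ramp_deg, ice_max = ice_max,
                 flux_model = flux_model, community = community,
                 aggregates = aggregates),
            class = "synthetic_config")
}

.check_gamma <- function(gamma) {
  if (is.null(colnames(gamma)) || !"Unknown" %in% colnames(gamma)) {
    stop("gamma needs source-layer columns plus an 'Unknown' column", call. = FALSE)
  }
  if (any(abs(rowSums(gamma) - 1) > 1e-8)) {
    stop("each gamma row must sum to 1", call. = FALSE)
  }
  if (any(gamma < 0)) stop("gamma entries must be non-negative", call. = FALSE)
  invisible(TRUE)
}

# Evaluate `code` under a fixed seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.rdirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) <= 0) g <- alpha  # degenerate all-zero draw: fall back to the mean
  g / sum(g)
}

#' Generate an analytic velocity field and sea-ice series
#'
#' Constructs two opposing meridional jets (northward in the eastern half of
#' the domain, southward in the western half) with an optional solid-body
#' eddy perturbation, and a sea-ice concentration series that is `ice_max`
#' west of a (possibly drifting) edge longitude, zero east of it, with a
#' linear ramp of width `ice_ramp_deg` in between. Incompressibility is not
#' enforced; the field is consumed only by trajectory integration.
#'
#' @param cfg A [synthetic_config()].
#' @return `list(field = velocity_field, ice = ice_series)`.
#' @export
make_velocity_field <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  d <- cfg$domain
  nlon <- length(d$lon); nlat <- length(d$lat)
  ndep <- length(d$depth); ntim <- length(d$time)
  lon_mid <- mean(range(d$lon))
  v_col <- ifelse(d$lon >= lon_mid, cfg$current_speed_east,
                  -cfg$current_speed_west)
  v <- array(rep(v_col, times = nlat * ndep * ntim),
             dim = c(nlon, nlat, ndep, ntim))
  u <- array(0, dim = dim(v))
  w <- array(cfg$vertical_velocity, dim = dim(v))
  if (!is.null(cfg$eddy)) {
    e <- cfg$eddy
    km_per_deg_lat <- pi / 180 * .EARTH_RADIUS_KM
    for (i in seq_len(nlon)) for (j in seq_len(nlat)) {
      dx <- (d$lon[i] - e$lon0) * km_per_deg_lat * cos(d$lat[j] * pi / 180)
      dy <- (d$lat[j] - e$lat0) * km_per_deg_lat
      r <- sqrt(dx^2 + dy^2)
      if (r > 0 && r <= e$radius_km) {
        # solid-body rotation: tangential speed grows linearly to `speed` at rim
        s <- e$speed * r / e$radius_km
        u[i, j, , ] <- u[i, j, , ] - s * dy / r
        v[i, j, , ] <- v[i, j, , ] + s * dx / r
      }
    }
  }
  field <- velocity_field(lon = d$lon, lat = d$lat, depth = d$depth,
                          time = d$time, u = u, v = v, w = w)
  ice_time <- seq(min(d$time), max(d$time), by = 1)
  conc <- array(0, dim = c(nlon, nlat, length(ice_time)))
  for (k in seq_along(ice_time)) {
    edge <- cfg$ice_edge_lon0 + cfg$ice_edge_drift * ice_time[k]
    prof <- pmin(pmax((edge + cfg$ice_ramp_deg - d$lon) / cfg$ice_ramp_deg,
                      0), 1) * cfg$ice_max
    conc[, , k] <- matrix(rep(prof, nlat), nrow = nlon)
  }
  ice <- ice_series(lon = d$lon, lat = d$lat, time = ice_time, conc = conc)
  list(field = field, ice = ice)
}

#' Generate a synthetic flux versus ice-edge-distance series
#'
#' Draws distances uniformly over `flux_model$dist_range` and fluxes from
#' `a * exp(b * x)` with multiplicative lognormal noise
#' (`exp(rnorm(0, noise_sigma_log))`).
#'
#' @param cfg A [synthetic_config()].
#' @param n Number of (distance, flux) pairs; `n >= 2`.
#' @param seed Seed (default `cfg$seed`).
#' @return `data.frame(distance_km, flux)` with strictly positive fluxes.
#' @export
make_flux_series <- function(cfg, n, seed = cfg$seed) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  fm <- cfg$flux_model
  if (fm$a <= 0) stop("flux_model$a must be positive", call. = FALSE)
  .with_seed(seed, {
    x <- stats::runif(n, fm$dist_range[1], fm$dist_range[2])
    noise <- if (fm$noise_sigma_log > 0) {
      exp(stats::rnorm(n, 0, fm$noise_sigma_log))
    } else rep(1, n)
    data.frame(distance_km = x, flux = fm$a * exp(fm$b * x) * noise)
  })
}

.default_gamma <- function(layers, regions) {
  src <- layers
  groups <- as.vector(outer(layers, regions, paste, sep = "|"))
  gamma <- matrix(0, nrow = length(groups), ncol = length(src) + 1,
                  dimnames = list(groups, c(src, "Unknown")))
  canonical <- identical(src, c("surface", "epi", "meso", "bathy"))
  for (g in groups) {
    parts <- strsplit(g, "|", fixed = TRUE)[[1]]
    layer <- parts[1]; region <- parts[2]
    if (canonical) {
      row <- switch(layer,
        surface = c(surface = 0.70, epi = 0.14, meso = 0, bathy = 0),
        epi     = c(surface = 0.42, epi = 0.42, meso = 0, bathy = 0),
        meso    = if (region == "ice-covered") {
          c(surface = 0.18, epi = 0.09, meso = 0.02, bathy = 0)
        } else c(surface = 0.075, epi = 0.035, meso = 0.02, bathy = 0),
        bathy   = if (region == "ice-covered") {
          c(surface = 0.18, epi = 0.09, meso = 0, bathy = 0.08)
        } else c(surface = 0.075, epi = 0.035, meso = 0, bathy = 0.08))
    } else {
      row <- stats::setNames(rep(0, length(src)), src)
      row[layer] <- 0.8
    }
    gamma[g, src] <- row
    gamma[g, "Unknown"] <- 1 - sum(row)
  }
  gamma
}

#' Generate an ASV community suite with known ground truth
#'
#' Builds free-living (FL) source communities with one heavy-tailed
#' (lognormal) baseline profile per water layer, particle-associated (PA)
#' sink communities that are known mixtures (rows of `gamma`) of those
#' sources plus an unknown component, and sediment communities drawing a
#' fraction `sediment_seed_fraction` of their reads from the planted
#' PA-enriched ASV pool. Every sample is a multinomial draw (at a uniformly
#' drawn read depth) from a per-sample Dirichlet perturbation of its mean
#' profile.
#'
#' @param cfg A [synthetic_config()].
#' @param seed Seed (default `cfg$seed`).
#' @return `list(table = asv_table, truth = list(gamma, planted, rho,
#'   profiles, unknown_profile))`; `truth$planted` is a data.frame with
#'   columns `asv`, `shallow`, `deep`, `lfc`.
#' @export
make_community_suite <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "synthetic_config"))
  cc <- cfg$community
  layers <- cc$layers
  regions <- cc$regions
  gamma <- if (is.null(cc$gamma)) .default_gamma(layers, regions) else cc$gamma
  .check_gamma(gamma)
  if (!all(layers %in% colnames(gamma))) {
    stop("gamma must have one column per source layer", call. = FALSE)
  }
  combos <- as.vector(outer(layers, regions, paste, sep = "|"))
  if (!all(combos %in% rownames(gamma))) {
    stop("gamma must have one 'layer|region' row per sink group", call. = FALSE)
  }

  .with_seed(seed, {
    n_asv <- cc$n_asvs
    asv_ids <- sprintf("asv_%04d", seq_len(n_asv))
    # per-layer lognormal abundance spectra (independent draws => distinct layers)
    profiles <- sapply(layers, function(l) {
      p <- stats::rlnorm(n_asv, meanlog = 0, sdlog = cc$profile_sdlog)
      p / sum(p)
    })
    rownames(profiles) <- asv_ids
    unknown_profile <- stats::rlnorm(n_asv, 0, cc$profile_sdlog)
    unknown_profile <- unknown_profile / sum(unknown_profile)

    # planted depth-enriched ASVs between consecutive layers. Effects are
    # planted on taxa above a relative-abundance floor in the shallow layer
    # (default 0.5%), mirroring the major particle-associated clades the
    # planted truth emulates and keeping it observable at the default read
    # depths; topped up from the most abundant remaining taxa if needed.
    planted <- data.frame(asv = character(), shallow = character(),
                          deep = character(), lfc = numeric())
    pl <- cc$planted
    if (is.data.frame(pl)) {
      planted <- pl
    } else if (length(layers) >= 2 && pl$n_per_contrast > 0) {
      floor_ra <- if (is.null(pl$min_rel_abundance)) 0.005 else pl$min_rel_abundance
      avail <- asv_ids
      for (i in seq_len(length(layers) - 1)) {
        sh <- layers[i]; dp <- layers[i + 1]
        pool <- avail[profiles[avail, sh] >= floor_ra]
        if (length(pool) < pl$n_per_contrast) {
          extra <- setdiff(avail[order(profiles[avail, sh],
                                       decreasing = TRUE)], pool)
          pool <- c(pool, utils::head(extra, pl$n_per_contrast - length(pool)))
        }
        # prefer the least abundant qualifying taxa so the boosted mass stays
        # a small share of the community even with several contrasts
        pool <- pool[order(profiles[pool, sh])]
        pool <- utils::head(pool, 2 * pl$n_per_contrast)
        pick <- sample(pool, min(pl$n_per_contrast, length(pool)))
        avail <- setdiff(avail, pick)
        planted <- rbind(planted, data.frame(asv = pick, shallow = sh,
                                             deep = dp, lfc = pl$lfc))
      }
    }
    if (nrow(planted) && any(!is.finite(planted$lfc))) {
      stop("planted log2 fold changes must be finite", call. = FALSE)
    }

    # PA mean profiles per (layer, region): gamma mixtures, then planted
    # enrichment imposed so that each planted ASV's relative abundance is
    # exactly 2^lfc times the previous layer's at its planted contrast and
    # carried unchanged into deeper layers; only the non-planted mass is
    # rescaled
    pa_profiles <- list()
    for (g in rownames(gamma)) {
      mix <- profiles[, layers, drop = FALSE] %*% gamma[g, layers] +
        gamma[g, "Unknown"] * unknown_profile
      pa_profiles[[g]] <- stats::setNames(as.vector(mix), asv_ids)
    }
    if (nrow(planted)) {
      deep_i <- match(planted$deep, layers)
      for (region in regions) {
        for (i in seq_along(layers)[-1]) {
          g_prev <- paste(layers[i - 1], region, sep = "|")
          g_cur <- paste(layers[i], region, sep = "|")
          act <- which(deep_i <= i)
          if (!length(act)) next
          target <- pa_profiles[[g_prev]][planted$asv[act]] *
            ifelse(deep_i[act] == i, 2^planted$lfc[act], 1)
          if (sum(target) >= 1) {
            stop("planted fold changes leave no probability mass for the rest of the community",
                 call. = FALSE)
          }
          cur <- pa_profiles[[g_cur]]
          others <- setdiff(asv_ids, planted$asv[act])
          cur[others] <- cur[others] * (1 - sum(target)) / sum(cur[others])
          cur[planted$asv[act]] <- target
          pa_profiles[[g_cur]] <- cur
        }
      }
    }

    draw_sample <- function(mean_profile) {
      depth <- round(stats::runif(1, cc$reads_range[1], cc$reads_range[2]))
      p <- if (is.finite(cc$sample_conc)) {
        .rdirichlet(cc$sample_conc * mean_profile + 1e-12)
      } else mean_profile
      as.integer(stats::rmultinom(1, depth, p))
    }

    counts <- list(); meta <- list()
    stations <- function(region) {
      paste0(toupper(substr(region, 1, 1)), seq_len(cc$stations_per_region))
    }
    for (region in regions) for (st in stations(region)) for (layer in layers) {
      if ("FL" %in% cc$fractions) {
        id <- sprintf("FL_%s_%s_%s", layer, region, st)
        counts[[id]] <- draw_sample(profiles[, layer])
        meta[[id]] <- data.frame(fraction = "FL", layer = layer,
                                 region = region, station = st)
      }
      if ("PA" %in% cc$fractions) {
        id <- sprintf("PA_%s_%s_%s", layer, region, st)
        counts[[id]] <- draw_sample(pa_profiles[[paste(layer, region, sep = "|")]])
        meta[[id]] <- data.frame(fraction = "PA", layer = layer,
                                 region = region, station = st)
      }
    }

    # sediment: background excludes the planted pool; rho of the mean profile
    # sits on the planted PA-enriched ASVs (proportional to deep-PA abundance)
    rho <- cc$sediment_seed_fraction
    if (cc$n_sediment > 0) {
      pool <- unique(planted$asv)
      bg <- stats::rlnorm(n_asv, 0, cc$profile_sdlog)
      names(bg) <- asv_ids
      bg[pool] <- 0
      bg <- bg / sum(bg)
      sed_profile <- (1 - rho) * bg
      if (length(pool) && rho > 0) {
        deep_group <- grep(paste0("^", layers[length(layers)], "\\|"),
                           names(pa_profiles), value = TRUE)[1]
        pw <- pa_profiles[[deep_group]][pool]
        sed_profile[pool] <- rho * pw / sum(pw)
      }
      sed_regions <- rep_len(regions, cc$n_sediment)
      for (i in seq_len(cc$n_sediment)) {
        id <- sprintf("SED_%s_%d", sed_regions[i], i)
        counts[[id]] <- draw_sample(sed_profile)
        meta[[id]] <- data.frame(fraction = "sediment", layer = "sediment",
                                 region = sed_regions[i],
                                 station = paste0("SED", i))
      }
    }

    cmat <- do.call(rbind, counts)
    rownames(cmat) <- names(counts)
    colnames(cmat) <- asv_ids
    mdf <- do.call(rbind, meta)
    rownames(mdf) <- names(counts)
    # arbitrary family labels, shared in blocks of ~8 ASVs; each contrast's
    # planted set is relabelled as one family (the planted "enriched clade")
    fam <- sprintf("family_%03d", ((seq_len(n_asv) - 1) %/% 8) + 1)
    names(fam) <- asv_ids
    if (nrow(planted)) {
      key <- paste(planted$shallow, planted$deep, sep = "-")
      fam[planted$asv] <- sprintf("family_planted_%02d",
                                  as.integer(factor(key, unique(key))))
    }
    tax <- data.frame(family = unname(fam),
                      class = sprintf("class_%02d", ((seq_len(n_asv) - 1) %/% 64) + 1),
                      row.names = asv_ids)
    list(table = asv_table(cmat, mdf, tax),
         truth = list(gamma = gamma, planted = planted, rho = rho,
                      profiles = profiles, unknown_profile = unknown_profile,
                      pa_profiles = pa_profiles))
  })
}

#' Generate synthetic aggregate records and a gel-trap image
#'
#' Draws per-region aggregate equivalent spherical diameters (ESD) from
#' lognormal distributions whose means keep ice-covered aggregates larger and
#' faster than ice-free ones, derives ellipsoid axes consistent with each
#' ESD, attaches sinking velocities, and renders the ice-covered draws as
#' disks in an 8-bit grayscale gel image at the configured pixel size.
#'
#' @param cfg A [synthetic_config()].
#' @param seed Seed (default `cfg$seed`).
#' @return `list(records = data.frame(x_mm, y_mm, z_mm, esd_mm,
#'   sinking_velocity_m_d, taxon, region), image, image_meta)`; `image` is a
#'   matrix in `[0, 1]` (write with [png::writePNG]).
#' @export
make_aggregates <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "synthetic_config"))
  ag <- cfg$aggregates
  if (any(ag$esd_mean_mm <= 0) || any(ag$velocity_mean <= 0)) {
    stop("aggregate region means must be positive", call. = FALSE)
  }
  .with_seed(seed, {
    recs <- list()
    for (region in names(ag$n)) {
      n <- ag$n[[region]]
      mu <- ag$esd_mean_mm[[region]]
      sdlog <- sqrt(log(1 + ag$esd_cv^2))
      esd <- stats::rlnorm(n, log(mu) - sdlog^2 / 2, sdlog)
      # mild prolate anisotropy; geometric mean of the axes equals the ESD
      s1 <- exp(stats::rnorm(n, 0, 0.1)); s2 <- exp(stats::rnorm(n, 0, 0.1))
      vel <- pmax(stats::rnorm(n, ag$velocity_mean[[region]],
                               ag$velocity_sd[[region]]), 0.1)
      recs[[region]] <- data.frame(
        x_mm = esd * s1, y_mm = esd * s2, z_mm = esd / (s1 * s2),
        esd_mm = esd, sinking_velocity_m_d = vel,
        taxon = if (region == "ice-covered") "diatom" else "Phaeocystis",
        region = region)
    }
    records <- do.call(rbind, recs)
    rownames(records) <- NULL
    img <- render_gel_image(records$esd_mm[records$region == "ice-covered"],
                            pixel_size_um = ag$pixel_size_um)
    list(records = records, image = img,
         image_meta = gel_image_meta(pixel_size_um = ag$pixel_size_um))
  })
}

#' Render particle ESDs as disks in a synthetic gel image
#'
#' Places one filled disk per ESD on a regular grid (well separated, no
#' randomness) over a zero background. Disk diameters in pixels equal
#' `esd_mm * 1000 / pixel_size_um`.
#'
#' @param esd_mm Vector of particle ESDs (mm); may be empty for a blank image.
#' @param pixel_size_um Pixel size (micrometres), default 12.
#' @param margin_px Spacing margin between disk bounding boxes, in pixels.
#' @return Grayscale matrix in `[0, 1]` (foreground 1, background 0).
#' @export
render_gel_image <- function(esd_mm, pixel_size_um = 12, margin_px = 8) {
  .stopifnot_scalar_pos(pixel_size_um, "pixel_size_um")
  if (length(esd_mm) == 0) return(matrix(0, nrow = 64, ncol = 64))
  r_px <- esd_mm * 1000 / pixel_size_um / 2
  cell <- ceiling(2 * max(r_px)) + margin_px
  ncol_grid <- ceiling(sqrt(length(esd_mm)))
  nrow_grid <- ceiling(length(esd_mm) / ncol_grid)
  img <- matrix(0, nrow = nrow_grid * cell, ncol = ncol_grid * cell)
  for (k in seq_along(esd_mm)) {
    gi <- (k - 1) %/% ncol_grid
    gj <- (k - 1) %% ncol_grid
    cy <- gi * cell + cell / 2
    cx <- gj * cell + cell / 2
    rr <- r_px[k]
    ys <- max(1, floor(cy - rr)):min(nrow(img), ceiling(cy + rr))
    xs <- max(1, floor(cx - rr)):min(ncol(img), ceiling(cx + rr))
    for (y in ys) {
      dx2 <- rr^2 - (y - 0.5 - cy)^2
      if (dx2 < 0) next
      hit <- xs[abs(xs - 0.5 - cx) <= sqrt(dx2)]
      img[y, hit] <- 1
    }
  }
  img
}
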