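# End-to-end orchestration of the synthetic demonstration: transport,
# flux, source-tracking, enrichment and community-statistics summaries in
# the layouts of the study's result tables.

#' Default run configuration
#'
#' Returns the demonstration configuration: a two-region synthetic domain
#' with one ice-covered station in the western (southward-flowing) half and
#' one ice-free station in the eastern (northward-flowing) half, three
#' sinking-velocity scenarios (regionally measured, hypothetical low 20 m/d,
#' hypothetical high 60 m/d), and the default community, flux and
#' enrichment settings. Override any element via `modifyList()`-style
#' nesting in [run_pipeline()].
#'
#' @param seed Global seed; every stochastic stage derives its seed from it.
#' @return Nested configuration list.
#' @export
default_run_config <- function(seed = 7) {
  list(
    seed = as.integer(seed),
    synthetic = list(ice_edge_lon0 = 0, ice_edge_drift = 0),
    transport = list(
      stations = data.frame(
        name = c("W1", "E1"),
        lon = c(-5, 5), lat = c(79, 79),
        seafloor_depth = c(2350, 2250),
        region = c("ice-covered", "ice-free")),
      scenarios = list(measured = c("ice-covered" = 52, "ice-free" = 29),
                       low = 20, high = 60),
      release_dates = seq(120, 204, by = 7),
      time_step_min = 30,
      surfacing_window = c(61, 213)),
    flux = list(n_series = 200, drifting_duration_d = 1,
                poc_mg = c("ice-covered" = 1.09, "ice-free" = 0.54),
                pon_mg = c("ice-covered" = 0.149, "ice-free" = 0.055)),
    mst = list(rarefaction_depth = 5000, alpha = 0.001, beta = 0.001,
               burn_in = 100, restarts = 10),
    enrichment = list(lfc_threshold = 1, padj_threshold = 0.1,
                      prevalence_min = 0.04, min_asvs_per_family = 3),
    stats = list(n_perm = 999))
}

#' Read a run configuration from YAML
#'
#' @param path Path to a YAML file with (a subset of) the structure of
#'   [default_run_config()].
#' @return Configuration list merged over the defaults.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_run_config(), user)
  if (!is.null(user$transport$stations)) {
    cfg$transport$stations <- user$transport$stations
  }
  if (!is.null(user$transport$scenarios)) {
    cfg$transport$scenarios <- user$transport$scenarios
  }
  if (!is.data.frame(cfg$transport$stations)) {
    cfg$transport$stations <- as.data.frame(cfg$transport$stations)
  }
  cfg
}

#' Run the end-to-end synthetic demonstration pipeline
#'
#' Generates all synthetic inputs, then produces: a trajectory summary
#' (median catchment radius, percent ice-covered origin, median trajectory
#' length per station and sinking-velocity scenario), a flux summary
#' (trap fluxes, molar C:N, aggregate sizes, the fitted exponential
#' flux-distance model and its 200 m power-law projection), a source-
#' tracking layer summary, an enriched-family table and footprint tables.
#' Every output TSV carries the seed and a configuration fingerprint in
#' header comments; the run is deterministic under a fixed seed.
#'
#' @param config Configuration list (see [default_run_config()]) or a path
#'   to a YAML file; partial lists are merged over the defaults.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with every summary table plus the paths
#'   written.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = tempfile("icesink_run_")) {
  if (is.character(config)) config <- read_run_config(config)
  user <- config
  config <- utils::modifyList(default_run_config(), config)
  # station tables and scenario sets are replaced wholesale, not merged
  if (!is.null(user$transport$stations)) {
    config$transport$stations <- user$transport$stations
  }
  if (!is.null(user$transport$scenarios)) {
    config$transport$scenarios <- user$transport$scenarios
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  hdr <- c(sprintf("seed: %d", seed),
           sprintf("config_md5: %s", .object_md5(config)))
  emit <- function(df, name) {
    .write_tsv_commented(df, file.path(out_dir, paste0(name, ".tsv")), hdr)
  }
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop(sprintf("[stage %s] %s (partial outputs preserved in %s)",
                   name, conditionMessage(e), out_dir), call. = FALSE)
    })
  }

  ## --- simulate -----------------------------------------------------------
  scfg <- stage("simulate", do.call(synthetic_config,
                                    c(list(seed = seed), config$synthetic)))
  fields <- stage("simulate", make_velocity_field(scfg))
  suite <- stage("simulate", make_community_suite(scfg, seed = seed + 1L))
  aggs <- stage("simulate", make_aggregates(scfg, seed = seed + 2L))
  flux_series <- stage("simulate",
                       make_flux_series(scfg, config$flux$n_series,
                                        seed = seed + 3L))

  ## --- transport ----------------------------------------------------------
  traj_summary <- stage("backtrack", {
    tc <- config$transport
    rows <- list()
    for (si in seq_len(nrow(tc$stations))) {
      st <- tc$stations[si, ]
      for (sc in names(tc$scenarios)) {
        ws <- tc$scenarios[[sc]]
        if (length(ws) > 1) ws <- ws[[st$region]]
        rel <- release_spec(st$lon, st$lat, st$seafloor_depth,
                            sinking_speed_m_d = ws,
                            release_dates = tc$release_dates,
                            time_step_min = tc$time_step_min,
                            surfacing_window = tc$surfacing_window)
        traj <- backtrack(fields$field, rel)
        orig <- suppressWarnings(classify_origin(traj, fields$ice))
        rad <- suppressWarnings(catchment_radius(traj))
        len <- suppressWarnings(trajectory_length(traj))
        ice_days <- count_ice_days(fields$ice, st$lon, st$lat)
        rows[[length(rows) + 1]] <- data.frame(
          station = st$name, region = st$region, scenario = sc,
          sinking_velocity_m_d = ws,
          n_released = nrow(traj$summary),
          n_surfaced_in_window = sum(traj$summary$in_window),
          median_catchment_radius_km = rad$median_km,
          sd_catchment_radius_km = rad$sd_km,
          pct_ice_covered_origin = orig$pct_ice_covered,
          median_trajectory_length_km = len$median_km,
          sd_trajectory_length_km = len$sd_km,
          ice_days = ice_days)
      }
    }
    do.call(rbind, rows)
  })
  emit(traj_summary, "trajectory_summary")

  ## --- flux ---------------------------------------------------------------
  flux_summary <- stage("flux", {
    fc <- config$flux
    rows <- list()
    for (region in unique(aggs$records$region)) {
      rec <- aggs$records[aggs$records$region == region, ]
      vol <- esd_from_axes(rec$x_mm, rec$y_mm, rec$z_mm)
      trap <- trap_sample("drifting", drifting_trap_area_m2(),
                          fc$drifting_duration_d,
                          poc_mg = fc$poc_mg[[region]],
                          pon_mg = fc$pon_mg[[region]],
                          particles = data.frame(volume_mm3 = vol$volume_mm3))
      fx <- flux_from_trap(trap)
      rows[[region]] <- data.frame(
        region = region, n_aggregates = nrow(rec),
        poc_flux = fx$poc_flux, pon_flux = fx$pon_flux,
        molar_cn = molar_cn(fx$poc_flux, fx$pon_flux),
        number_flux = fx$number_flux, volume_flux = fx$volume_flux,
        mean_esd_mm = mean(vol$esd_mm),
        mean_volume_mm3 = mean(vol$volume_mm3),
        mean_sinking_velocity_m_d = mean(rec$sinking_velocity_m_d),
        poc_flux_200m = attenuate_flux(fx$poc_flux, 100, 200))
    }
    do.call(rbind, c(rows, make.row.names = FALSE))
  })
  emit(flux_summary, "flux_summary")
  flux_fit <- stage("flux", fit_ice_distance_model(flux_series$distance_km,
                                                   flux_series$flux))
  emit(data.frame(a = flux_fit$a, b = flux_fit$b, r2 = flux_fit$r2,
                  n = flux_fit$n), "flux_distance_model")

  ## --- source tracking ----------------------------------------------------
  mst_summary <- stage("mst", {
    mc <- config$mst
    tab <- suite$table
    rar <- suppressWarnings(rarefy(tab, mc$rarefaction_depth, seed = seed + 4L))
    is_fl <- rar$sample_data$fraction == "FL"
    is_pa <- rar$sample_data$fraction == "PA"
    sources <- subset_asv_table(rar, samples = which(is_fl))
    sinks <- subset_asv_table(rar, samples = which(is_pa))
    cfg_mst <- mst_config(alpha = mc$alpha, beta = mc$beta,
                          burn_in = mc$burn_in, restarts = mc$restarts,
                          rarefaction_depth = mc$rarefaction_depth,
                          seed = seed + 5L)
    fit <- fit_sources(sinks, sources, cfg_mst)
    summarize_by_layer(fit, sinks$sample_data)
  })
  emit(mst_summary, "mst_layer_summary")

  ## --- enrichment ---------------------------------------------------------
  enr <- stage("enrich", {
    ec <- do.call(enrichment_config, config$enrichment)
    tab <- suite$table
    results <- list(); families <- list(); footprints <- list()
    for (region in unique(tab$sample_data$region)) {
      pa <- subset_asv_table(tab, samples = which(
        tab$sample_data$fraction == "PA" & tab$sample_data$region == region))
      pa <- prevalence_filter(pa, ec$prevalence_min)
      res <- run_contrasts(pa, ec)
      res$region <- region
      results[[region]] <- res
      fam <- family_summary(res, tab$taxonomy, ec)
      if (nrow(fam)) fam$region <- region
      families[[region]] <- fam
      enr_asvs <- unique(res$asv[res$enriched])
      target <- subset_asv_table(tab, samples = which(
        (tab$sample_data$fraction == "FL" & tab$sample_data$layer == "bathy" |
           tab$sample_data$fraction == "sediment") &
          tab$sample_data$region == region))
      footprints[[region]] <- enriched_footprint(enr_asvs, target)$summary
    }
    list(results = do.call(rbind, c(results, make.row.names = FALSE)),
         families = do.call(rbind, c(families, make.row.names = FALSE)),
         footprint = do.call(rbind, c(footprints, make.row.names = FALSE)))
  })
  emit(enr$results, "enrichment_results")
  emit(enr$families, "enriched_families")
  emit(enr$footprint, "footprint_summary")

  ## --- community stats ----------------------------------------------------
  stats_out <- stage("stats", {
    tab <- prevalence_filter(subset_asv_table(
      suite$table,
      samples = which(suite$table$sample_data$fraction %in% c("FL", "PA"))),
      config$enrichment$prevalence_min)
    vmat <- vst(tab)
    adiv <- alpha_diversity(tab)
    pc <- pca_communities(vmat)
    dmat <- stats::dist(vmat)
    pf <- permanova(dmat, tab$sample_data$fraction,
                    n_perm = config$stats$n_perm, seed = seed + 6L)
    pl <- permanova(dmat, tab$sample_data$layer,
                    n_perm = config$stats$n_perm, seed = seed + 7L)
    fp <- suppressWarnings(fl_pa_distance(vmat, tab$sample_data))
    tests <- data.frame(
      test = c("PERMANOVA fraction", "PERMANOVA layer"),
      f = c(pf$f, pl$f), r2 = c(pf$r2, pl$r2), p = c(pf$p, pl$p),
      df1 = c(pf$df[1], pl$df[1]), df2 = c(pf$df[2], pl$df[2]))
    list(alpha = adiv, tests = tests,
         pca_var = data.frame(axis = seq_along(pc$var_explained),
                              var_explained_pct = pc$var_explained),
         fl_pa = fp$pairs)
  })
  emit(stats_out$alpha, "alpha_diversity")
  emit(stats_out$tests, "tests_summary")
  emit(stats_out$pca_var, "pca_variance")
  emit(stats_out$fl_pa, "fl_pa_distances")

  bundle <- list(seed = seed,
                 trajectory_summary = traj_summary,
                 flux_summary = flux_summary,
                 flux_distance_model = list(a = flux_fit$a, b = flux_fit$b,
                                            r2 = flux_fit$r2),
                 mst_layer_summary = mst_summary,
                 enriched_families = enr$families,
                 footprint_summary = enr$footprint,
                 tests_summary = stats_out$tests)
  jsonlite::write_json(bundle, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(c(bundle, list(out_dir = out_dir)))
}
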