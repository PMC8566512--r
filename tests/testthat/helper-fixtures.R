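# Fixtures built in code: uniform velocity fields, tiny ASV tables, and
# small community-suite configurations reused across test files.

# spatially/temporally uniform velocity field over a wide polar box
uniform_field <- function(u = 0.1, v = 0, w = 0,
                          lon = seq(-40, 40, by = 2),
                          lat = seq(70, 86, by = 1),
                          depth = c(5, 1000, 2500),
                          time = c(0, 400)) {
  mk <- function(val) array(val, c(length(lon), length(lat), length(depth),
                                   length(time)))
  velocity_field(lon, lat, depth, time, mk(u), mk(v), mk(w))
}

# ice series with a fixed meridional edge: conc ice_w west of edge_lon,
# conc ice_e at and east of it
edge_ice <- function(edge_lon = 0, ice_w = 0.8, ice_e = 0,
                     lon = seq(-10, 10, by = 0.5),
                     lat = seq(76, 82, by = 0.5),
                     time = 0:10) {
  conc <- array(rep(ifelse(lon < edge_lon, ice_w, ice_e),
                    times = length(lat) * length(time)),
                dim = c(length(lon), length(lat), length(time)))
  ice_series(lon, lat, time, conc)
}

# minimal ASV table from a counts matrix and layer/fraction vectors
tiny_table <- function(counts, fraction, layer,
                       region = "ice-covered", station = "S1") {
  rownames(counts) <- sprintf("smp_%02d", seq_len(nrow(counts)))
  colnames(counts) <- sprintf("asv_%03d", seq_len(ncol(counts)))
  md <- data.frame(fraction = fraction, layer = layer, region = region,
                   station = station, row.names = rownames(counts))
  asv_table(counts, md)
}

# two-layer particle-associated suite used for enrichment simulations;
# identical mixture rows make the layers exchangeable apart from planted
# effects, so expected planted ratios are exactly 2^lfc
two_layer_cfg <- function(seed, n_planted = 0, lfc = 2, n_per_group = 6,
                          n_asvs = 100, depth = 10000) {
  synthetic_config(seed = seed, community = list(
    n_asvs = n_asvs, layers = c("epi", "meso"), regions = "ice-covered",
    stations_per_region = n_per_group, fractions = "PA", n_sediment = 0,
    reads_range = c(depth, depth), sample_conc = 400,
    gamma = matrix(c(1, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE,
                   dimnames = list(c("epi|ice-covered", "meso|ice-covered"),
                                   c("epi", "meso", "Unknown"))),
    planted = list(n_per_contrast = n_planted, lfc = lfc)))
}
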