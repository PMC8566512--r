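# Aggregate geometry, sinking velocities, sediment-trap fluxes, C:N, the
# exponential flux-vs-ice-distance model, and power-law flux attenuation.

# atomic masses (g/mol)
.C_MOLAR <- 12.011
.N_MOLAR <- 14.007

#' Ellipsoid volume and equivalent spherical diameter from measured axes
#'
#' Aggregates measured in the flow chamber are treated as ellipsoids:
#' `V = (pi/6) x y z`, and the ESD is the diameter of the sphere of equal
#' volume, `(6 V / pi)^(1/3)`, i.e. the geometric mean of the three axes.
#'
#' @param x,y,z Aggregate axes in mm (vectorised); all must be positive.
#' @return `data.frame(volume_mm3, esd_mm)`.
#' @export
#' @examples
#' esd_from_axes(1, 1, 1)        # sphere: V = 0.5236, ESD = 1
#' esd_from_axes(2, 1, 0.5)      # ESD = 1 (geometric mean)
esd_from_axes <- function(x, y, z) {
  if (any(c(x, y, z) <= 0) || !all(is.finite(c(x, y, z)))) {
    stop("all axes must be positive and finite", call. = FALSE)
  }
  v <- pi / 6 * x * y * z
  data.frame(volume_mm3 = v, esd_mm = (6 * v / pi)^(1 / 3))
}

#' Sinking velocity from flow-chamber measurements
#'
#' The sinking velocity equals the mean volumetric flow rate that keeps the
#' aggregate suspended, divided by the chamber cross-section, converted to
#' m/d.
#'
#' @param flows_ml_min One or more volumetric flow measurements (mL/min).
#' @param chamber_area_cm2 Chamber cross-section area (cm^2), > 0.
#' @return Sinking velocity in m/d.
#' @export
#' @examples
#' sinking_velocity_from_flow(c(1, 2, 3), 10)  # 2.88 m/d
sinking_velocity_from_flow <- function(flows_ml_min, chamber_area_cm2) {
  if (length(flows_ml_min) == 0) stop("need >= 1 flow measurement", call. = FALSE)
  .stopifnot_scalar_pos(chamber_area_cm2, "chamber_area_cm2")
  cm_per_min <- mean(flows_ml_min) / chamber_area_cm2  # mL/cm^2 = cm
  cm_per_min * 60 * 24 / 100
}

#' Construct a sediment-trap sample
#'
#' @param kind `"moored"`, `"drifting"` or `"gel"`.
#' @param area_m2 Collection area (m^2), > 0. The drifting-trap cylinders of
#'   inner diameter 10.4 cm have area `pi * 0.052^2` = 8.49e-3 m^2
#'   (see [drifting_trap_area_m2()]).
#' @param duration_d Collection duration (days), > 0.
#' @param poc_mg,pon_mg Collected particulate organic carbon / nitrogen (mg).
#' @param particles Optional data.frame of particle records with a
#'   `volume_mm3` column (e.g. from [gel_image_particles()] or
#'   [esd_from_axes()]).
#' @return An object of class `trap_sample`.
#' @export
trap_sample <- function(kind = c("moored", "drifting", "gel"), area_m2,
                        duration_d, poc_mg = NA_real_, pon_mg = NA_real_,
                        particles = NULL) {
  kind <- match.arg(kind)
  .stopifnot_scalar_pos(area_m2, "area_m2")
  .stopifnot_scalar_pos(duration_d, "duration_d")
  if (!is.na(poc_mg) && poc_mg < 0) stop("poc_mg must be >= 0", call. = FALSE)
  if (!is.na(pon_mg) && pon_mg < 0) stop("pon_mg must be >= 0", call. = FALSE)
  structure(list(kind = kind, area_m2 = area_m2, duration_d = duration_d,
                 poc_mg = poc_mg, pon_mg = pon_mg, particles = particles),
            class = "trap_sample")
}

#' Inner collection area of the drifting-trap cylinders
#'
#' @param inner_diameter_cm Cylinder inner diameter (cm), default 10.4.
#' @return Area in m^2.
#' @export
drifting_trap_area_m2 <- function(inner_diameter_cm = 10.4) {
  pi * (inner_diameter_cm / 200)^2
}

#' Fluxes from a trap sample
#'
#' Each flux is the collected quantity divided by collection area times
#' duration. Number and volume fluxes require particle records; the volume
#' flux uses the sum of particle volumes.
#'
#' @param t A [trap_sample()].
#' @return `list(poc_flux, pon_flux, number_flux, volume_flux)` in
#'   mg m^-2 d^-1, # m^-2 d^-1 and mm^3 m^-2 d^-1 (NA where the input is
#'   absent).
#' @export
flux_from_trap <- function(t) {
  stopifnot(inherits(t, "trap_sample"))
  denom <- t$area_m2 * t$duration_d
  n_flux <- v_flux <- NA_real_
  if (!is.null(t$particles)) {
    n_flux <- nrow(t$particles) / denom
    v_flux <- sum(t$particles$volume_mm3) / denom
  }
  list(poc_flux = t$poc_mg / denom, pon_flux = t$pon_mg / denom,
       number_flux = n_flux, volume_flux = v_flux)
}

#' Molar carbon-to-nitrogen ratio from mass fluxes
#'
#' `(POC / 12.011) / (PON / 14.007)`; both fluxes in the same mass-per-area-
#' per-time unit.
#'
#' @param poc,pon POC and PON fluxes (e.g. mg m^-2 d^-1); `pon` must be > 0.
#' @return Molar C:N ratio.
#' @export
#' @examples
#' molar_cn(63, 6.5)  # 11.3
molar_cn <- function(poc, pon) {
  if (any(pon <= 0)) stop("PON must be positive", call. = FALSE)
  (poc / .C_MOLAR) / (pon / .N_MOLAR)
}

#' Fit the exponential flux versus ice-edge-distance model
#'
#' Fits `flux = a * exp(b * distance)` by ordinary least squares on
#' `log(flux)` (closed-form slope/intercept), the standard linearisation for
#' multiplicative lognormal errors. R^2 is reported on the original flux
#' scale: `1 - SS_res / SS_tot` about the mean flux.
#'
#' @param distance_km Distances to the ice edge (km).
#' @param flux Fluxes (mg m^-2 d^-1), all > 0; at least 3 pairs.
#' @return An object of class `ice_flux_model` with `print`, `coef`,
#'   `predict` and `summary` methods; coefficients `a` (flux at zero
#'   distance) and `b` (decay, 1/km).
#' @seealso [predict_flux()]
#' @export
fit_ice_distance_model <- function(distance_km, flux) {
  if (length(flux) < 3) stop("need >= 3 (distance, flux) pairs", call. = FALSE)
  if (any(flux <= 0)) stop("fluxes must be positive", call. = FALSE)
  fit <- stats::lm(log(flux) ~ distance_km)
  a <- exp(unname(stats::coef(fit)[1]))
  b <- unname(stats::coef(fit)[2])
  pred <- a * exp(b * distance_km)
  ss_res <- sum((flux - pred)^2)
  ss_tot <- sum((flux - mean(flux))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 0
  structure(list(a = a, b = b, r2 = r2, n = length(flux), log_fit = fit),
            class = "ice_flux_model")
}

#' @export
print.ice_flux_model <- function(x, ...) {
  cat(sprintf("flux = %.3g * exp(%.4g * distance_km)   (R2 = %.2f, n = %d)\n",
              x$a, x$b, x$r2, x$n))
  invisible(x)
}

#' @export
coef.ice_flux_model <- function(object, ...) c(a = object$a, b = object$b)

#' @export
predict.ice_flux_model <- function(object, distance_km, ...) {
  predict_flux(object, distance_km)
}

#' @export
summary.ice_flux_model <- function(object, ...) {
  s <- summary(object$log_fit)
  out <- list(a = object$a, b = object$b, r2 = object$r2, n = object$n,
              b_se = s$coefficients[2, 2],
              log_a_se = s$coefficients[1, 2],
              b_p = s$coefficients[2, 4])
  class(out) <- "summary.ice_flux_model"
  out
}

#' @export
print.summary.ice_flux_model <- function(x, ...) {
  cat(sprintf("exponential flux-distance model (n = %d)\n", x$n))
  cat(sprintf("  a = %.4g  (log-scale SE of log a: %.3g)\n", x$a, x$log_a_se))
  cat(sprintf("  b = %.4g 1/km  (SE %.3g, p = %.3g)\n", x$b, x$b_se, x$b_p))
  cat(sprintf("  R2 (flux scale) = %.3f\n", x$r2))
  invisible(x)
}

#' Predict flux at a given ice-edge distance
#'
#' @param m An [fit_ice_distance_model()] result (or any list with `a`, `b`).
#' @param distance_km Distances (km), >= 0.
#' @return Predicted fluxes `a * exp(b * distance)`.
#' @export
predict_flux <- function(m, distance_km) {
  if (any(distance_km < 0)) stop("distances must be >= 0", call. = FALSE)
  m$a * exp(m$b * distance_km)
}

#' Power-law (Martin-type) flux attenuation
#'
#' `F(z) = F(z0) * (z / z0)^(-b)`: projects a flux measured at reference
#' depth `z0` to depth `z`. The default exponent 0.858 is a commonly used
#' open-ocean value and should be overridden where a regional estimate
#' exists.
#'
#' @param flux0 Flux at the reference depth.
#' @param z0 Reference depth (m), > 0.
#' @param z Target depth (m), > 0.
#' @param b_att Attenuation exponent (unitless), default 0.858.
#' @return Flux at depth `z`.
#' @export
#' @examples
#' attenuate_flux(128, 100, 200)  # ~70.6
attenuate_flux <- function(flux0, z0, z, b_att = 0.858) {
  if (any(c(z0, z) <= 0)) stop("depths must be positive", call. = FALSE)
  flux0 * (z / z0)^(-b_att)
}

#' Nutrient drawdown across the seasonal pycnocline
#'
#' The consumption proxy is the mean concentration between 50 and 100 m
#' minus the mean above 50 m; measurements below 100 m are excluded from
#' both strata.
#'
#' @param depth_m Measurement depths (m).
#' @param concentration Concentrations at those depths (any unit).
#' @return The drawdown delta (same unit as the input).
#' @export
nutrient_drawdown <- function(depth_m, concentration) {
  stopifnot(length(depth_m) == length(concentration))
  above <- concentration[depth_m > 0 & depth_m < 50]
  below <- concentration[depth_m >= 50 & depth_m <= 100]
  if (length(above) == 0 || length(below) == 0) {
    stop("need measurements both above 50 m and between 50 and 100 m",
         call. = FALSE)
  }
  mean(below) - mean(above)
}

#' Partition aggregates into size classes about a cut-off
#'
#' @param esd_mm Aggregate ESDs (mm).
#' @param region Region labels (same length as `esd_mm`).
#' @param cut_mm Size cut-off (mm), default 0.512; ESDs exactly at the cut
#'   count as "above" (inclusive convention).
#' @return `data.frame(region, n_below, n_above)`.
#' @export
size_class_summary <- function(esd_mm, region, cut_mm = 0.512) {
  if (length(esd_mm) == 0) stop("no aggregate records", call. = FALSE)
  stopifnot(length(esd_mm) == length(region))
  out <- do.call(rbind, lapply(split(esd_mm, region), function(e) {
    data.frame(n_below = sum(e < cut_mm), n_above = sum(e >= cut_mm))
  }))
  data.frame(region = rownames(out), out, row.names = NULL)
}
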