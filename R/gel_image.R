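# Gel-trap image analysis: thresholding, connected components, particle sizing.

#' Gel image metadata
#'
#' @param pixel_size_um Pixel size in micrometres, default 12.
#' @param threshold `"otsu"` (default) or a fixed numeric threshold in
#'   `[0, 1]`.
#' @param min_esd_mm Minimum particle ESD retained (mm), default 0.1.
#' @return An object of class `gel_image_meta`.
#' @export
gel_image_meta <- function(pixel_size_um = 12, threshold = "otsu",
                           min_esd_mm = 0.1) {
  .stopifnot_scalar_pos(pixel_size_um, "pixel_size_um")
  structure(list(pixel_size_um = pixel_size_um, threshold = threshold,
                 min_esd_mm = min_esd_mm),
            class = "gel_image_meta")
}

#' Detect and size particles in a gel-trap image
#'
#' Converts the image to grayscale if needed, removes the background by a
#' threshold (Otsu's method by default), labels connected foreground
#' components, and converts each component's calibrated pixel area (mm^2) to
#' an equivalent spherical diameter `ESD = 2 * sqrt(area / pi)`. Components
#' below `min_esd_mm` are dropped. Deterministic for a fixed threshold
#' method; an empty image yields zero particles (not an error).
#'
#' @param image Numeric matrix (grayscale, values in `[0, 1]`) or an array
#'   with a trailing channel dimension (averaged to grayscale), e.g. from
#'   [png::readPNG()].
#' @param meta A [gel_image_meta()].
#' @return `data.frame(particle, pixel_area, area_mm2, esd_mm, volume_mm3)`;
#'   the volume assumes a sphere of the measured ESD.
#' @export
gel_image_particles <- function(image, meta = gel_image_meta()) {
  stopifnot(inherits(meta, "gel_image_meta"))
  if (length(dim(image)) == 3) image <- apply(image, c(1, 2), mean)
  img <- EBImage::Image(image)
  thr <- if (identical(meta$threshold, "otsu")) {
    # Otsu needs both classes present; a blank image has no particles
    if (length(unique(as.vector(image))) < 2) Inf else EBImage::otsu(img)
  } else meta$threshold
  mask <- EBImage::Image(image > thr)
  labels <- EBImage::bwlabel(mask)
  n <- max(labels)
  if (n == 0) {
    return(data.frame(particle = integer(), pixel_area = numeric(),
                      area_mm2 = numeric(), esd_mm = numeric(),
                      volume_mm3 = numeric()))
  }
  px <- tabulate(as.integer(labels@.Data), nbins = n)
  mm_per_px <- meta$pixel_size_um / 1000
  area_mm2 <- px * mm_per_px^2
  esd_mm <- 2 * sqrt(area_mm2 / pi)
  keep <- esd_mm >= meta$min_esd_mm
  data.frame(particle = seq_len(sum(keep)),
             pixel_area = px[keep], area_mm2 = area_mm2[keep],
             esd_mm = esd_mm[keep],
             volume_mm3 = pi / 6 * esd_mm[keep]^3)
}
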