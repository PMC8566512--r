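# Shared helpers: spherical geometry, validation, deterministic table writing.

# Earth radius used throughout (km). All great-circle distances are haversine
# distances on a sphere of this radius.
.EARTH_RADIUS_KM <- 6371

#' Great-circle distance between points (km)
#'
#' Haversine distance on a sphere of radius 6371 km. Vectorised over points;
#' inputs are recycled to a common length.
#'
#' @param lon1,lat1 Coordinates of the first point(s), decimal degrees.
#' @param lon2,lat2 Coordinates of the second point(s), decimal degrees.
#' @return Numeric vector of distances in kilometres.
#' @export
#' @examples
#' gc_distance_km(0, 79, 1, 79)  # ~21.2 km at 79 degrees north
gc_distance_km <- function(lon1, lat1, lon2, lat2) {
  n <- max(length(lon1), length(lat1), length(lon2), length(lat2))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  geosphere::distHaversine(p1, p2, r = .EARTH_RADIUS_KM * 1000) / 1000
}

.stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("'%s' must be a single positive finite number", name),
         call. = FALSE)
  }
  invisible(TRUE)
}

.is_strictly_monotonic <- function(x) {
  length(x) >= 2L && (all(diff(x) > 0) || all(diff(x) < 0))
}

# Deterministic number formatting for on-disk tables: fixed notation, trailing
# zeros trimmed, so that identical inputs give byte-identical files.
.fmt_num <- function(x, digits = 6) {
  out <- formatC(x, digits = digits, format = "fg", flag = "#")
  out <- sub("\\.?0+$", "", out)
  out[!is.finite(x)] <- as.character(x[!is.finite(x)])
  out
}

# Write a data.frame as TSV with '# key: value' header comments.
.write_tsv_commented <- function(df, path, header = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  is_num <- vapply(df, is.numeric, logical(1))
  for (j in which(is_num)) df[[j]] <- .fmt_num(df[[j]])
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# md5 fingerprint of an arbitrary R object (via serialized tempfile).
.object_md5 <- function(x) {
  tf <- tempfile(fileext = ".yml")
  on.exit(unlink(tf))
  writeLines(yaml::as.yaml(x), tf)
  unname(tools::md5sum(tf))
}
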