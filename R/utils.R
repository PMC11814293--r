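#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used for the percentage columns of the
#' campaign summary tables. Base [round()] rounds half to even, which does
#' not reproduce printed survey tables.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @examples
#' round_half_up(16.5)   # 17, where round(16.5) gives 16
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## scalar positive-number check used across constructors
stopifnot_positive <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("'%s' must be a single positive finite number", what),
         call. = FALSE)
  }
  invisible(x)
}

stopifnot_prob <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single probability in [0, 1]", what),
         call. = FALSE)
  }
  invisible(x)
}

## derive a reproducible child seed from a parent seed and a stream label;
## kept below 2^31 so it is always a valid R integer seed
child_seed <- function(seed, stream) {
  offs <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 69069 + offs) %% 2147483647)
}

#' Convert planar metric coordinates to WGS84 longitude/latitude
#'
#' Local equirectangular mapping about a reference point in the western
#' Wadden Sea. Adequate for the tens-of-kilometres extents of synthetic
#' worlds; real deployments would substitute a projected CRS transform.
#'
#' @param x,y planar coordinates in metres (east, north of the origin).
#' @param origin numeric `c(lon, lat)` of the planar origin, decimal degrees.
#' @return data.frame with columns `lon`, `lat` (decimal degrees, WGS84).
#' @export
planar_to_wgs84 <- function(x, y, origin = c(lon = 4.9, lat = 53.0)) {
  m_per_deg <- 111320
  lat <- origin[[2]] + y / m_per_deg
  lon <- origin[[1]] + x / (m_per_deg * cos(lat * pi / 180))
  data.frame(lon = lon, lat = lat)
}
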