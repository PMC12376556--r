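#' Injury-spheroid geometry
#'
#' Describes the circular injury region: the spheroid center in the imaging
#' frame and the contact radius that defines "within the injury site". All
#' lengths are in micrometers.
#'
#' @param center_x,center_y Spheroid center coordinates (um).
#' @param radius Contact radius (um); must be > 0.
#'
#' @return An object of class `spheroid_geometry` with fields `center_x`,
#'   `center_y`, `radius`.
#' @examples
#' sph <- spheroid_geometry(100, 50, 75)
#' sph
#' @export
spheroid_geometry <- function(center_x, center_y, radius) {
  for (nm in c("center_x", "center_y", "radius")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      rmt_stop("validation_error", "spheroid_geometry: '%s' must be a single finite number", nm)
  }
  if (radius <= 0)
    rmt_stop("validation_error", "spheroid_geometry: 'radius' must be > 0 (got %g)", radius)
  structure(
    list(center_x = as.numeric(center_x), center_y = as.numeric(center_y),
         radius = as.numeric(radius)),
    class = "spheroid_geometry"
  )
}

#' @export
print.spheroid_geometry <- function(x, ...) {
  cat(sprintf("<spheroid_geometry> center (%g, %g) um, radius %g um\n",
              x$center_x, x$center_y, x$radius))
  invisible(x)
}

is_spheroid_geometry <- function(x) inherits(x, "spheroid_geometry")
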