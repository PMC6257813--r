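#' Wrap angles to the half-open interval (-180, 180]
#'
#' All azimuths in the package live on (-180, 180] degrees, with 0 dead
#' ahead and positive angles to the user's right.
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector of the same length, wrapped to (-180, 180].
#' @examples
#' wrap_angle(c(190, -180, 540))
#' @export
wrap_angle <- function(x) {
  x - 360 * ceiling((x - 180) / 360)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Circular mean and dispersion of angles in degrees
#'
#' The mean is the direction of the resultant vector; the circular standard
#' deviation is \eqn{\sqrt{-2\log \bar R}} converted to degrees. For
#' dispersions below ~30 degrees both coincide with their linear
#' counterparts to a fraction of a degree.
#'
#' @param x angles in degrees.
#' @return `circ_mean()`: mean direction in (-180, 180];
#'   `circ_sd()`: circular standard deviation in degrees;
#'   `mean_resultant_length()`: \eqn{\bar R \in [0, 1]}.
#' @export
circ_mean <- function(x) {
  r <- deg2rad(x)
  rad2deg(atan2(mean(sin(r)), mean(cos(r))))
}

#' @rdname circ_mean
#' @export
circ_sd <- function(x) {
  rbar <- mean_resultant_length(x)
  if (rbar <= 0) return(Inf)
  rad2deg(sqrt(-2 * log(rbar)))
}

#' @rdname circ_mean
#' @export
mean_resultant_length <- function(x) {
  r <- deg2rad(x)
  sqrt(mean(cos(r))^2 + mean(sin(r))^2)
}
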