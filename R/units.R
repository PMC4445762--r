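#' Unit helpers
#'
#' The model's public parameters follow the conventions of the glioma imaging
#' literature: the net invasion rate `D` in mm\eqn{^2}/year and the net
#' proliferation rate `rho` in 1/year. Internally all computation is done in
#' millimetres and days, because clinical scan intervals are naturally
#' expressed in days; conversion happens once at the interface.
#'
#' @name units
#' @keywords internal
NULL

# days per Julian year, used for every year <-> day conversion
DAYS_PER_YEAR <- 365.25

per_year_to_per_day <- function(x) x / DAYS_PER_YEAR
per_day_to_per_year <- function(x) x * DAYS_PER_YEAR

#' Equivalent spherical radius from a lesion volume
#'
#' Converts a segmented lesion volume to the radius of the sphere with the
#' same volume, \eqn{r = (3V/4\pi)^{1/3}} — the geometry in which all radii in
#' this package are expressed.
#'
#' @param volume_mm3 Lesion volume(s) in mm\eqn{^3}.
#' @return Equivalent spherical radius (mm), vectorised over `volume_mm3`.
#' @examples
#' radius_from_volume(4 / 3 * pi * 10^3) # 10 mm
#' @export
radius_from_volume <- function(volume_mm3) {
  stopifnot(is.numeric(volume_mm3), all(volume_mm3 >= 0))
  (3 * volume_mm3 / (4 * pi))^(1 / 3)
}
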