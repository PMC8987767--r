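#' Convert a nucleus diameter to a circular area
#'
#' Literature definitions of vaginal cell nuclei are given sometimes as
#' diameters (e.g. 7--11 µm for the intermediate-cell nucleus) and sometimes
#' as areas. Assuming a circular nucleus, a diameter `d` corresponds to an
#' area of `pi * (d / 2)^2`; the 7--11 µm range maps to approximately
#' 38.5--95.0 µm².
#'
#' @param diameter_um Numeric vector of diameters in µm; must be `>= 0`.
#' @return Numeric vector of areas in µm².
#' @examples
#' diameter_to_area(c(7, 11))
#' @seealso [area_to_diameter()]
#' @export
diameter_to_area <- function(diameter_um) {
  if (!is.numeric(diameter_um)) {
    abort("`diameter_um` must be numeric.", class = "cytovag_error_domain")
  }
  if (any(is.na(diameter_um)) || any(diameter_um < 0)) {
    abort("`diameter_um` must be non-negative and non-missing.",
          class = "cytovag_error_domain")
  }
  pi * (diameter_um / 2)^2
}

#' Convert a circular area back to a diameter
#'
#' Inverse of [diameter_to_area()]: `2 * sqrt(area / pi)`.
#'
#' @param area_um2 Numeric vector of areas in µm²; must be `>= 0`.
#' @return Numeric vector of equivalent-circle diameters in µm.
#' @export
area_to_diameter <- function(area_um2) {
  if (!is.numeric(area_um2)) {
    abort("`area_um2` must be numeric.", class = "cytovag_error_domain")
  }
  if (any(is.na(area_um2)) || any(area_um2 < 0)) {
    abort("`area_um2` must be non-negative and non-missing.",
          class = "cytovag_error_domain")
  }
  2 * sqrt(area_um2 / pi)
}
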