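#' Induced circular dichroism sign rule
#'
#' Qualitative sign of the ICD band induced in an achiral chromophore by a
#' cyclodextrin host, following the Harata-Kodaka rules: for a chromophore
#' \emph{inside} the cavity the band is positive when the electric
#' transition dipole moment is parallel to the CD symmetry axis and
#' negative when perpendicular, with the sign changing at the magic angle
#' 54.7 degrees; moving the chromophore \emph{outside} the cavity reverses
#' the sign for a fixed transition direction.  Angles within
#' \code{tolerance_deg} of 54.7 return \code{"near-zero"}, expressing the
#' vanishing band intensity at the node.
#'
#' @param location \code{"inside"} or \code{"outside"} the host cavity.
#' @param angle_deg Angle between the transition dipole moment and the CD
#'   axis, degrees in [0, 90].
#' @param tolerance_deg Half-width of the near-zero band around the magic
#'   angle (default 3 degrees).
#' @return One of \code{"positive"}, \code{"negative"}, \code{"near-zero"}.
#' @examples
#' icd_sign("inside", 0)    # parallel, inside: positive
#' icd_sign("inside", 90)   # perpendicular, inside: negative
#' icd_sign("outside", 0)   # reversed outside: negative
#' @export
icd_sign <- function(location = c("inside", "outside"), angle_deg,
                     tolerance_deg = 3) {
  location <- match.arg(location)
  if (length(angle_deg) != 1L || !is.finite(angle_deg) ||
      angle_deg < 0 || angle_deg > 90)
    stop("angle_deg must be a single value in [0, 90]")
  magic <- 54.7
  if (abs(angle_deg - magic) <= tolerance_deg) return("near-zero")
  inside_sign <- if (angle_deg < magic) "positive" else "negative"
  if (location == "inside") inside_sign
  else if (inside_sign == "positive") "negative" else "positive"
}
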