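#' N-localizer design specification
#'
#' Constructs the design constants of an N-localizer: two vertical rods
#' (A and C) joined by one diagonal rod (B), the three of them tracing the
#' letter "N". The section height is recovered by linear interpolation
#' between the two ends of the diagonal rod, so only the rod heights and the
#' horizontal rod separation matter.
#'
#' Defaults describe the classical frame: vertical rods 140 mm high and
#' 140 mm apart, with the frame base at z = 0. All lengths are millimetres.
#'
#' @param z_top z-coordinate of the top of rod A, in mm.
#' @param z_bottom z-coordinate of the bottom of rod C, in mm.
#' @param rod_spacing horizontal distance between the vertical rods A and C,
#'   in mm.
#' @return An object of class `n_localizer`.
#' @examples
#' n_localizer()
#' n_localizer(z_top = 120, rod_spacing = 120)
#' @export
n_localizer <- function(z_top = 140, z_bottom = 0, rod_spacing = 140) {
  stopifnot(is.numeric(z_top), is.numeric(z_bottom), is.numeric(rod_spacing),
            length(z_top) == 1L, length(z_bottom) == 1L,
            length(rod_spacing) == 1L)
  if (!all(is.finite(c(z_top, z_bottom, rod_spacing))))
    stop("n_localizer constants must be finite", call. = FALSE)
  if (z_top <= z_bottom)
    stop("z_top must exceed z_bottom", call. = FALSE)
  if (rod_spacing <= 0)
    stop("rod_spacing must be positive", call. = FALSE)
  structure(
    list(z_top = z_top, z_bottom = z_bottom, rod_spacing = rod_spacing),
    class = "n_localizer"
  )
}

#' Sturm-Pastyr localizer design specification
#'
#' Constructs the design constant of the V-shaped Sturm-Pastyr localizer:
#' two diagonal rods (A and C) meeting one vertical rod (B) at the apex of a
#' "V". The manufactured angle between each diagonal rod and the vertical
#' rod is `upsilon`; the classical device uses arctan(1/2) = 26.565 degrees.
#'
#' @param upsilon rod angle in degrees, strictly between 0 and 90.
#' @return An object of class `sturm_pastyr`.
#' @examples
#' sturm_pastyr()
#' @export
sturm_pastyr <- function(upsilon = atan(1 / 2) * 180 / pi) {
  stopifnot(is.numeric(upsilon), length(upsilon) == 1L)
  if (!is.finite(upsilon) || upsilon <= 0 || upsilon >= 90)
    stop("upsilon must lie strictly between 0 and 90 degrees", call. = FALSE)
  structure(list(upsilon = upsilon), class = "sturm_pastyr")
}

# Tilt-angle domain limits (degrees). The N-localizer blows up as
# cos(beta) -> 0; the Sturm-Pastyr geometry is singular at 90 - upsilon
# (63.435 degrees for the classical device), so its cap sits strictly below.
beta_max_n <- 85
beta_max_sp <- 60

#' Tilt angle of minimal diagonal-rod foreshortening
#'
#' For the Sturm-Pastyr localizer the image-plane distance from fiducial A
#' to fiducial B is minimized, at fixed section height, when the section
#' tilt equals the rod angle. Returns that tilt in degrees.
#'
#' @param spec a [sturm_pastyr()] specification.
#' @return Tilt angle in degrees (26.565 for the classical device).
#' @export
sp_optimal_beta <- function(spec = sturm_pastyr()) {
  stopifnot(inherits(spec, "sturm_pastyr"))
  spec$upsilon
}

#' Tilt angle at which the Sturm-Pastyr geometry degenerates
#'
#' The distance from fiducial B to fiducial C diverges as the section tilt
#' approaches 90 degrees minus the rod angle (63.435 degrees for the
#' classical device); beyond it the section no longer crosses rod C.
#'
#' @param spec a [sturm_pastyr()] specification.
#' @return Tilt angle in degrees.
#' @export
sp_divergence_beta <- function(spec = sturm_pastyr()) {
  stopifnot(inherits(spec, "sturm_pastyr"))
  90 - spec$upsilon
}

#' @export
print.n_localizer <- function(x, ...) {
  cat(sprintf(
    "N-localizer: rod height %g..%g mm, rod spacing %g mm\n",
    x$z_bottom, x$z_top, x$rod_spacing
  ))
  invisible(x)
}

#' @export
print.sturm_pastyr <- function(x, ...) {
  cat(sprintf(
    "Sturm-Pastyr localizer: rod angle %.4f deg (singular tilt %.4f deg)\n",
    x$upsilon, 90 - x$upsilon
  ))
  invisible(x)
}

# Resolve a localizer argument: accept a spec object or the strings
# "n" / "sp" / "sturm_pastyr" (case-insensitive) meaning the default device.
as_localizer <- function(localizer) {
  if (inherits(localizer, "n_localizer") || inherits(localizer, "sturm_pastyr"))
    return(localizer)
  if (is.character(localizer) && length(localizer) == 1L) {
    key <- tolower(localizer)
    if (key %in% c("n", "n_localizer")) return(n_localizer())
    if (key %in% c("sp", "sturm_pastyr", "sturm-pastyr"))
      return(sturm_pastyr())
  }
  stop("localizer must be an n_localizer/sturm_pastyr spec or one of ",
       '"n", "sp"', call. = FALSE)
}

localizer_label <- function(spec) {
  if (inherits(spec, "n_localizer")) "N" else "SturmPastyr"
}
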