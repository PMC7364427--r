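#' Fiducial triplet in the image plane
#'
#' The three fiducial points A, B, C that a localizer's rods leave in a
#' tomographic image, as (u, v) coordinates in millimetres. Unperturbed
#' triplets produced by the forward models lie on the u-axis (v = 0).
#'
#' @param a,b,c numeric length-2 vectors `c(u, v)` in mm.
#' @return An object of class `fiducial_triplet`.
#' @examples
#' fiducial_triplet(a = c(140, 0), b = c(20, 0), c = c(0, 0))
#' @export
fiducial_triplet <- function(a, b, c) {
  pts <- list(a = a, b = b, c = c)
  for (nm in names(pts)) {
    p <- pts[[nm]]
    if (!is.numeric(p) || length(p) != 2L || !all(is.finite(p)))
      stop("fiducial ", nm, " must be a finite numeric (u, v) pair",
           call. = FALSE)
  }
  structure(lapply(pts, as.numeric), class = "fiducial_triplet")
}

#' @export
print.fiducial_triplet <- function(x, ...) {
  cat(sprintf("fiducials (mm): A=(%g, %g)  B=(%g, %g)  C=(%g, %g)\n",
              x$a[1], x$a[2], x$b[1], x$b[2], x$c[1], x$c[2]))
  invisible(x)
}

#' Euclidean distance between two image points
#'
#' @param p,q numeric length-2 vectors `c(u, v)` in mm.
#' @return Distance in mm.
#' @examples
#' euclidean_distance(c(0, 0), c(3, 4)) # 5
#' @export
euclidean_distance <- function(p, q) {
  if (!is.numeric(p) || !is.numeric(q) || length(p) != 2L || length(q) != 2L)
    stop("p and q must be numeric (u, v) pairs", call. = FALSE)
  if (!all(is.finite(c(p, q))))
    stop("coordinates must be finite", call. = FALSE)
  sqrt((p[1] - q[1])^2 + (p[2] - q[2])^2)
}

#' Inter-fiducial distances of a triplet
#'
#' @param triplet a [fiducial_triplet()].
#' @return A named list with `d_ab`, `d_bc`, `d_ac` in mm (`d_ac` is
#'   meaningful for the N-localizer only).
#' @export
fiducial_distances <- function(triplet) {
  stopifnot(inherits(triplet, "fiducial_triplet"))
  list(
    d_ab = euclidean_distance(triplet$a, triplet$b),
    d_bc = euclidean_distance(triplet$b, triplet$c),
    d_ac = euclidean_distance(triplet$a, triplet$c)
  )
}

#' Section height from N-localizer fiducial distances
#'
#' Recovers the height z at which the diagonal rod crosses the tomographic
#' section by linear interpolation between the ends of the diagonal:
#' `z = z_bottom + (d_bc / d_ac) * (z_top - z_bottom)`. The ratio
#' `d_bc / d_ac` is dimensionless, so no pixel-size calibration is needed;
#' the result carries the units of the design constants (mm).
#'
#' @param d_bc distance from fiducial B to fiducial C.
#' @param d_ac distance from fiducial A to fiducial C (must be positive).
#' @param spec an [n_localizer()] specification.
#' @return Section height z in mm.
#' @examples
#' n_localizer_z(d_bc = 70, d_ac = 140) # 70
#' @export
n_localizer_z <- function(d_bc, d_ac, spec = n_localizer()) {
  stopifnot(inherits(spec, "n_localizer"), is.numeric(d_bc), is.numeric(d_ac))
  if (!all(is.finite(d_bc)) || !all(is.finite(d_ac)) ||
      any(d_bc < 0) || any(d_ac < 0))
    stop("distances must be finite and nonnegative", call. = FALSE)
  if (any(d_ac == 0))
    stop("degenerate geometry: d_ac must be positive", call. = FALSE)
  spec$z_bottom + (d_bc / d_ac) * (spec$z_top - spec$z_bottom)
}

#' Section height from Sturm-Pastyr fiducial distances
#'
#' Recovers the height z at which the vertical rod crosses the tomographic
#' section from the two diagonal-to-vertical fiducial distances:
#' `z = 4 d_ab d_bc / sqrt((d_bc + d_ab)^2 + 4 (d_bc - d_ab)^2)`.
#' Unlike the N-localizer ratio, this formula is homogeneous of degree one
#' in the distances, so they must already be calibrated to millimetres: the
#' image pixel size enters the reconstruction, and an incorrect pixel size
#' propagates directly into z. Valid for the classical rod angle
#' arctan(1/2). At the apex of the V both distances vanish and z = 0 (the
#' limit of the formula along any approach ray).
#'
#' @param d_ab distance from fiducial A to fiducial B, in mm.
#' @param d_bc distance from fiducial B to fiducial C, in mm.
#' @return Section height z in mm.
#' @examples
#' sturm_pastyr_z(10, 10) # 20, the parallel-section case z = d_ab + d_bc
#' @export
sturm_pastyr_z <- function(d_ab, d_bc) {
  if (!is.numeric(d_ab) || !is.numeric(d_bc) ||
      !all(is.finite(d_ab)) || !all(is.finite(d_bc)) ||
      any(d_ab < 0) || any(d_bc < 0))
    stop("distances must be finite and nonnegative", call. = FALSE)
  num <- 4 * d_ab * d_bc
  den <- sqrt((d_bc + d_ab)^2 + 4 * (d_bc - d_ab)^2)
  z <- ifelse(den == 0, 0, num / den)
  if (length(z) == 1L) z <- as.numeric(z)
  z
}

check_pose <- function(z, beta, beta_max, z_max = Inf) {
  stopifnot(is.numeric(z), length(z) == 1L, is.numeric(beta),
            length(beta) == 1L)
  if (!is.finite(z) || z < 0 || z > z_max)
    stop(sprintf("z must lie in [0, %g] mm", z_max), call. = FALSE)
  if (!is.finite(beta) || beta < 0 || beta > beta_max)
    stop(sprintf("beta must lie in [0, %g] degrees", beta_max),
         call. = FALSE)
  invisible(TRUE)
}

#' Forward model: N-localizer fiducials for a section pose
#'
#' Places the three fiducial points of an N-localizer for a section at
#' height `z` (mm, where the diagonal rod crosses the section) tilted by
#' `beta` (degrees) relative to the frame base. A tilted section stretches
#' in-plane distances by 1/cos(beta), so the fiducials sit at C = (0, 0),
#' B = (z / cos beta, 0), A = (rod_spacing / cos beta, 0). This is one of
#' the rigid placements consistent with the geometry; any other placement
#' yields identical inter-fiducial distances.
#'
#' @param z section height in mm, in `[0, z_top]`.
#' @param beta section tilt in degrees, in `[0, 85]`.
#' @param spec an [n_localizer()] specification.
#' @return A [fiducial_triplet()].
#' @examples
#' n_forward_fiducials(z = 20, beta = 0)
#' @export
n_forward_fiducials <- function(z, beta, spec = n_localizer()) {
  stopifnot(inherits(spec, "n_localizer"))
  check_pose(z, beta, beta_max = beta_max_n, z_max = spec$z_top)
  cb <- cos(beta * pi / 180)
  fiducial_triplet(
    a = c(spec$rod_spacing / cb, 0),
    b = c(z / cb, 0),
    c = c(0, 0)
  )
}

#' Forward model: Sturm-Pastyr inter-fiducial distances for a section pose
#'
#' For a section at height `z` (mm, where the vertical rod crosses the
#' section) tilted by `beta` (degrees), the diagonal-to-vertical distances
#' are `d_ab = z sin(upsilon) / sin(pi/2 + beta - upsilon)` and
#' `d_bc = z sin(upsilon) / sin(pi/2 - beta - upsilon)`. At `beta = 0` both
#' equal `z tan(upsilon)` (z/2 for the classical device). `d_bc` diverges as
#' `beta` approaches `90 - upsilon` degrees; tilts are capped at 60 degrees,
#' strictly below the classical singularity at 63.435 degrees.
#'
#' @param z section height in mm, nonnegative.
#' @param beta section tilt in degrees, in `[0, 60]`.
#' @param spec a [sturm_pastyr()] specification.
#' @return A named list with `d_ab` and `d_bc` in mm.
#' @examples
#' sp_forward_distances(z = 20, beta = 0) # d_ab = d_bc = 10
#' @export
sp_forward_distances <- function(z, beta, spec = sturm_pastyr()) {
  stopifnot(inherits(spec, "sturm_pastyr"))
  check_pose(z, beta, beta_max = min(beta_max_sp, 90 - spec$upsilon))
  if (beta >= 90 - spec$upsilon)
    stop("singular geometry: d_bc diverges as beta approaches ",
         sprintf("%g degrees", 90 - spec$upsilon), call. = FALSE)
  ups <- spec$upsilon * pi / 180
  b <- beta * pi / 180
  list(
    d_ab = z * sin(ups) / sin(pi / 2 + b - ups),
    d_bc = z * sin(ups) / sin(pi / 2 - b - ups)
  )
}

#' Forward model: Sturm-Pastyr fiducials for a section pose
#'
#' Places the fiducials on the image u-axis as A = (-d_ab, 0), B = (0, 0),
#' C = (d_bc, 0), with the distances from [sp_forward_distances()]. At the
#' apex (z = 0) all three points coincide at the origin.
#'
#' @inheritParams sp_forward_distances
#' @return A [fiducial_triplet()].
#' @examples
#' sp_forward_fiducials(z = 20, beta = 0)
#' @export
sp_forward_fiducials <- function(z, beta, spec = sturm_pastyr()) {
  d <- sp_forward_distances(z, beta, spec)
  fiducial_triplet(a = c(-d$d_ab, 0), b = c(0, 0), c = c(d$d_bc, 0))
}

# Unified forward + inverse pair used by the Monte Carlo engine.
# Returns the unperturbed triplet and a vectorized reconstruction taking
# the 6 x m perturbed-coordinate matrix (rows u_a, v_a, u_b, v_b, u_c, v_c).
localizer_model <- function(spec, z, beta) {
  if (inherits(spec, "n_localizer")) {
    triplet <- n_forward_fiducials(z, beta, spec)
    zspan <- spec$z_top - spec$z_bottom
    z0 <- spec$z_bottom
    reconstruct <- function(m) {
      d_bc <- sqrt((m[3, ] - m[5, ])^2 + (m[4, ] - m[6, ])^2)
      d_ac <- sqrt((m[1, ] - m[5, ])^2 + (m[2, ] - m[6, ])^2)
      z0 + (d_bc / d_ac) * zspan
    }
  } else {
    triplet <- sp_forward_fiducials(z, beta, spec)
    reconstruct <- function(m) {
      d_ab <- sqrt((m[1, ] - m[3, ])^2 + (m[2, ] - m[4, ])^2)
      d_bc <- sqrt((m[3, ] - m[5, ])^2 + (m[4, ] - m[6, ])^2)
      den <- sqrt((d_bc + d_ab)^2 + 4 * (d_bc - d_ab)^2)
      ifelse(den == 0, 0, 4 * d_ab * d_bc / den)
    }
  }
  list(triplet = triplet, reconstruct = reconstruct)
}

triplet_as_vector <- function(triplet) {
  c(u_a = triplet$a[1], v_a = triplet$a[2],
    u_b = triplet$b[1], v_b = triplet$b[2],
    u_c = triplet$c[1], v_c = triplet$c[2])
}
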