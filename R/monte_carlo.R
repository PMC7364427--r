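#' Root-mean-square of a vector of errors
#'
#' @param values nonempty numeric vector of errors in mm.
#' @return `sqrt(mean(values^2))`.
#' @examples
#' rms(c(1, 2, 2)) # sqrt(3)
#' @export
rms <- function(values) {
  if (!is.numeric(values) || length(values) == 0L)
    stop("values must be a nonempty numeric vector", call. = FALSE)
  if (!all(is.finite(values)))
    stop("values must be finite", call. = FALSE)
  sqrt(mean(values^2))
}

#' Deterministic per-cell substream seed
#'
#' Derives a 31-bit seed from a master seed and the Monte Carlo cell
#' parameters, so that sweep cells are reproducible independently of
#' evaluation order and each cell can be re-run in isolation.
#'
#' @param seed master seed (integer).
#' @param localizer label `"N"` or `"SturmPastyr"`, or a spec object.
#' @param z,beta,epsilon cell parameters (mm, degrees, mm).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
cell_seed <- function(seed, localizer, z, beta, epsilon) {
  if (!is.character(localizer))
    localizer <- localizer_label(as_localizer(localizer))
  key <- sprintf("%d|%s|%.10g|%.10g|%.10g",
                 as.integer(seed), localizer, z, beta, epsilon)
  m <- 2147483629 # largest prime below 2^31; keeps h*31 + c < 2^53
  h <- 0
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% m
  as.integer(h + 1)
}

# Run thunk with a private RNG stream; the caller's RNG state is untouched.
with_seed <- function(seed, thunk) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  thunk()
}

# Draw the raw perturbation matrix: 6 rows (u_a, v_a, u_b, v_b, u_c, v_c),
# one column per iteration. Column-major fill means each iteration consumes
# six consecutive uniforms, so results do not depend on how a run is split
# into blocks. Draws are U(-1, 1) scaled by epsilon, which makes a fixed
# seed give common random numbers across noise amplitudes.
draw_perturbations <- function(m, epsilon) {
  matrix(stats::runif(6L * m, -1, 1), nrow = 6L) * epsilon
}

#' Perturb a fiducial triplet with uniform image noise
#'
#' Shifts each of the six coordinates (u and v of all three fiducials)
#' independently by a uniform draw from `[-epsilon, +epsilon]` mm. The noise
#' emulates the displacement of a detected fiducial center by image noise;
#' the classical choice `epsilon = 1` mm corresponds to at most about two
#' pixels at typical stereotactic imaging resolution.
#'
#' @param triplet a [fiducial_triplet()].
#' @param epsilon uniform noise half-width in mm, nonnegative.
#' @param n number of perturbed copies to draw.
#' @return For `n = 1` a perturbed [fiducial_triplet()]; for `n > 1` a
#'   `6 x n` numeric matrix with rows `u_a, v_a, u_b, v_b, u_c, v_c`.
#' @examples
#' set.seed(1)
#' perturb(n_forward_fiducials(20, 0), epsilon = 0.5)
#' @export
perturb <- function(triplet, epsilon, n = 1L) {
  stopifnot(inherits(triplet, "fiducial_triplet"))
  if (!is.numeric(epsilon) || length(epsilon) != 1L || !is.finite(epsilon) ||
      epsilon < 0)
    stop("epsilon must be a finite nonnegative scalar", call. = FALSE)
  n <- as.integer(n)
  stopifnot(n >= 1L)
  base <- triplet_as_vector(triplet)
  m <- base + draw_perturbations(n, epsilon)
  rownames(m) <- names(base)
  if (n == 1L)
    return(fiducial_triplet(a = m[1:2, 1], b = m[3:4, 1], c = m[5:6, 1]))
  m
}

#' Monte Carlo error of z-reconstruction for one simulation cell
#'
#' Implements the noise-propagation experiment for a single cell
#' (localizer, z, beta, epsilon): generate the unperturbed fiducial triplet
#' with the forward model, perturb all six coordinates with i.i.d. uniform
#' noise of half-width `epsilon` mm, recompute the inter-fiducial distances,
#' reconstruct the section height, and accumulate the root-mean-square and
#' maximum absolute deviation of the reconstruction from the true z over
#' `n` iterations.
#'
#' Iterations are processed in blocks of `block_size`; the sum of squares is
#' combined across blocks with compensated (Kahan) summation, so results are
#' identical for any block size and stable at the default n = 2^25.
#'
#' @param localizer an [n_localizer()] or [sturm_pastyr()] spec, or `"n"` /
#'   `"sp"` for the default devices.
#' @param z section height in mm.
#' @param beta section tilt in degrees.
#' @param epsilon uniform noise half-width in mm.
#' @param n iterations (default `2^25`).
#' @param seed RNG seed for this cell.
#' @param block_size iterations per vectorized block.
#' @return A one-row data.frame of class `error_summary` with columns
#'   `localizer, z_mm, beta_deg, epsilon_mm, n, seed, rms_mm, max_mm`.
#' @examples
#' simulate_cell("n", z = 20, beta = 5, epsilon = 1, n = 2^16, seed = 1)
#' @export
simulate_cell <- function(localizer, z, beta, epsilon, n = 2^25,
                          seed = 1L, block_size = 2^20) {
  spec <- as_localizer(localizer)
  if (!is.numeric(epsilon) || length(epsilon) != 1L || !is.finite(epsilon) ||
      epsilon < 0)
    stop("epsilon must be a finite nonnegative scalar", call. = FALSE)
  n <- round(n)
  block_size <- round(block_size)
  if (n < 1 || block_size < 1)
    stop("n and block_size must be at least 1", call. = FALSE)
  if (n > 2^40)
    stop("n too large", call. = FALSE)

  model <- localizer_model(spec, z, beta)
  base <- triplet_as_vector(model$triplet)

  sums <- with_seed(seed, function() {
    ss <- 0; comp <- 0; mx <- 0
    done <- 0
    while (done < n) {
      m <- min(block_size, n - done)
      pert <- base + draw_perturbations(m, epsilon)
      err <- model$reconstruct(pert) - z
      y <- sum(err * err) - comp
      t <- ss + y
      comp <- (t - ss) - y
      ss <- t
      mx <- max(mx, max(abs(err)))
      done <- done + m
    }
    list(ss = ss, mx = mx)
  })

  out <- data.frame(
    localizer = localizer_label(spec),
    z_mm = z, beta_deg = beta, epsilon_mm = epsilon,
    n = n, seed = as.integer(seed),
    rms_mm = sqrt(sums$ss / n), max_mm = sums$mx,
    stringsAsFactors = FALSE
  )
  class(out) <- c("error_summary", "data.frame")
  out
}

#' @export
print.error_summary <- function(x, ...) {
  cat(sprintf(
    "%s localizer, z = %g mm, beta = %g deg, epsilon = %g mm (n = %s, seed %d)\n  RMS error %.6g mm, max error %.6g mm\n",
    x$localizer[1], x$z_mm[1], x$beta_deg[1], x$epsilon_mm[1],
    format(x$n[1], big.mark = ","), x$seed[1], x$rms_mm[1], x$max_mm[1]
  ))
  invisible(x)
}

#' First-order (delta-method) prediction of the RMS reconstruction error
#'
#' Linearizes the reconstruction in the six fiducial coordinates at the
#' unperturbed triplet and propagates the per-coordinate noise variance
#' `epsilon^2 / 3` of a uniform `[-epsilon, epsilon]` draw:
#' `rms = epsilon / sqrt(3) * ||gradient||`. The gradient is computed by
#' central finite differences. Accurate for small noise; the simulated RMS
#' exceeds this prediction at large `epsilon`, where curvature of the
#' distance and reconstruction formulas contributes second-order error.
#'
#' @inheritParams simulate_cell
#' @return Predicted RMS error in mm.
#' @examples
#' delta_method_rms("n", z = 20, beta = 5, epsilon = 0.25)
#' @export
delta_method_rms <- function(localizer, z, beta, epsilon) {
  spec <- as_localizer(localizer)
  model <- localizer_model(spec, z, beta)
  base <- triplet_as_vector(model$triplet)
  f <- function(x) model$reconstruct(matrix(x, nrow = 6L))
  grad <- vapply(seq_along(base), function(i) {
    h <- 1e-6 * max(1, abs(base[i]))
    hi <- base; hi[i] <- hi[i] + h
    lo <- base; lo[i] <- lo[i] - h
    (f(hi) - f(lo)) / (2 * h)
  }, numeric(1))
  epsilon / sqrt(3) * sqrt(sum(grad^2))
}
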