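#' @title Parameter sweeps of Monte Carlo reconstruction error
#'
#' @description
#' Each sweep runs [simulate_cell()] over a grid and binds the one-row
#' summaries into a table with columns
#' `localizer, z_mm, beta_deg, epsilon_mm, n, seed, rms_mm, max_mm`.
#' Per-cell seeds are derived deterministically from the master `seed` and
#' the cell parameters via [cell_seed()], so a sweep row is identical to an
#' independent [simulate_cell()] call with the same derived seed, and cells
#' may be recomputed in any order. Cells outside a localizer's valid domain
#' are skipped with a warning rather than dropped silently.
#'
#' @param localizer an [n_localizer()] or [sturm_pastyr()] spec, or `"n"` /
#'   `"sp"`.
#' @param z_values section heights in mm.
#' @param beta_values section tilts in degrees.
#' @param epsilon uniform noise half-width in mm.
#' @param n iterations per cell.
#' @param seed master seed for the sweep.
#' @param block_size iterations per vectorized block.
#' @return A data.frame with one row per valid cell.
#' @name sweeps
NULL

run_cells <- function(spec, cells, n, seed, block_size) {
  label <- localizer_label(spec)
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    z <- cells$z[i]; beta <- cells$beta[i]; eps <- cells$epsilon[i]
    row <- tryCatch(
      simulate_cell(spec, z = z, beta = beta, epsilon = eps, n = n,
                    seed = cell_seed(seed, label, z, beta, eps),
                    block_size = block_size),
      error = function(e) {
        warning(sprintf(
          "skipping invalid cell (%s, z=%g, beta=%g, epsilon=%g): %s",
          label, z, beta, eps, conditionMessage(e)), call. = FALSE)
        NULL
      }
    )
    rows[[i]] <- row
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    stop("no valid cells in sweep grid", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}

#' @rdname sweeps
#' @examples
#' sweep_error_vs_z("sp", z_values = c(5, 10, 20), beta_values = 0,
#'                  epsilon = 1, n = 2^14, seed = 1)
#' @export
sweep_error_vs_z <- function(localizer, z_values = seq(5, 140, by = 5),
                             beta_values = c(0, 5, 10, 15, 20),
                             epsilon = 1, n = 2^20, seed = 1L,
                             block_size = 2^20) {
  spec <- as_localizer(localizer)
  stopifnot(length(z_values) >= 1L, length(beta_values) >= 1L)
  cells <- expand.grid(z = z_values, beta = beta_values, epsilon = epsilon,
                       KEEP.OUT.ATTRS = FALSE)
  run_cells(spec, cells, n, seed, block_size)
}

#' @rdname sweeps
#' @export
sweep_error_vs_beta <- function(localizer, beta_values = 0:60,
                                z_values = 20, epsilon = 1, n = 2^20,
                                seed = 1L, block_size = 2^20) {
  spec <- as_localizer(localizer)
  stopifnot(length(z_values) >= 1L, length(beta_values) >= 1L)
  cells <- expand.grid(beta = beta_values, z = z_values, epsilon = epsilon,
                       KEEP.OUT.ATTRS = FALSE)
  run_cells(spec, cells, n, seed, block_size)
}

#' Noise-amplitude sweep for both localizers at a fixed pose
#'
#' Runs both the N-localizer and the Sturm-Pastyr localizer at one section
#' pose across a list of uniform noise half-widths. The default pose
#' (z = 20 mm, beta = 5 degrees) corresponds to a section near the frame
#' base and nearly parallel to it, as acquired for deep-brain targets; the
#' default half-widths span 0.25 to 3 mm.
#'
#' @param z section height in mm.
#' @param beta section tilt in degrees.
#' @param epsilon_values positive, increasing noise half-widths in mm.
#' @param n iterations per cell.
#' @param seed master seed.
#' @param localizers list of localizer specs (or `"n"` / `"sp"` strings).
#' @param block_size iterations per vectorized block.
#' @return A data.frame with one row per (localizer, epsilon).
#' @examples
#' sweep_error_vs_epsilon(z = 20, beta = 5, epsilon_values = c(0.5, 1),
#'                        n = 2^14, seed = 1)
#' @export
sweep_error_vs_epsilon <- function(z = 20, beta = 5,
                                   epsilon_values = c(0.25, 0.5, 1, 2, 3),
                                   n = 2^20, seed = 1L,
                                   localizers = list("n", "sp"),
                                   block_size = 2^20) {
  stopifnot(length(epsilon_values) >= 1L)
  if (any(epsilon_values < 0) || is.unsorted(epsilon_values, strictly = TRUE))
    stop("epsilon_values must be nonnegative and strictly increasing",
         call. = FALSE)
  out <- lapply(localizers, function(loc) {
    spec <- as_localizer(loc)
    cells <- data.frame(z = z, beta = beta, epsilon = epsilon_values)
    run_cells(spec, cells, n, seed, block_size)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Ordinary least-squares fit of error against noise amplitude
#'
#' Fits `y = intercept + slope * x` by ordinary least squares (with
#' intercept) and reports the Pearson correlation of the pairs. Used to
#' quantify how reconstruction error scales with the noise half-width.
#'
#' @param x,y numeric vectors of equal length (mm); at least two distinct
#'   `x` values and non-constant `y` are required.
#' @return An object of class `fit_result`: a list with `slope`,
#'   `intercept`, `pearson_r`.
#' @examples
#' linear_fit(1:5, 2 * (1:5) + 1)
#' @export
linear_fit <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y) || length(x) < 2L)
    stop("x and y must be equal-length vectors with at least 2 points",
         call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("x and y must be finite", call. = FALSE)
  if (length(unique(x)) < 2L || stats::sd(y) == 0)
    stop("degenerate fit: x must have >= 2 distinct values and y must vary",
         call. = FALSE)
  fit <- stats::lm(y ~ x)
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         pearson_r = stats::cor(x, y)),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("linear fit: slope %.6g, intercept %.6g, Pearson r %.6g\n",
              x$slope, x$intercept, x$pearson_r))
  invisible(x)
}

#' Tilt angle of maximal RMS reconstruction error
#'
#' Sweeps the RMS error over a tilt-angle grid at fixed section height and
#' noise amplitude and returns the grid angle with the largest RMS error.
#' The grid is evaluated in ascending order and ties are broken toward the
#' smaller angle. For the Sturm-Pastyr localizer at z = 20 mm and unit
#' noise this maximum falls near 40 degrees, between the foreshortening
#' minimum at the rod angle and the 63.435-degree singularity.
#'
#' @inheritParams sweeps
#' @param z section height in mm.
#' @param beta_grid tilt angles in degrees.
#' @return The maximizing tilt angle in degrees.
#' @export
find_beta_of_max_rms <- function(localizer, z = 20, beta_grid = 0:60,
                                 epsilon = 1, n = 2^20, seed = 1L,
                                 block_size = 2^20) {
  if (length(beta_grid) == 0L)
    stop("beta_grid must be nonempty", call. = FALSE)
  beta_grid <- sort(beta_grid)
  tab <- sweep_error_vs_beta(localizer, beta_values = beta_grid, z_values = z,
                             epsilon = epsilon, n = n, seed = seed,
                             block_size = block_size)
  if (all(tab$rms_mm == 0))
    stop("degenerate sweep: RMS error is zero everywhere (epsilon = 0?)",
         call. = FALSE)
  tab$beta_deg[which.max(tab$rms_mm)]
}
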