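#' Default initiation-rate grid
#'
#' Log-spaced points resolve the small-alpha region where physiological
#' initiation rates concentrate and where density inversion happens;
#' extra linear points densify `[0.01, 1]`.
#'
#' @param n_log number of log-spaced points between `from` and `to`
#'   (default 60).
#' @param n_lin number of extra linear points over `[0.01, 1]`
#'   (default 20).
#' @param from,to grid range in s^-1 (defaults 1e-3 and 5).
#' @return Strictly increasing numeric vector.
#' @export
default_alpha_grid <- function(n_log = 60, n_lin = 20, from = 1e-3, to = 5) {
  g <- exp(seq(log(from), log(to), length.out = n_log))
  if (n_lin > 0) g <- c(g, seq(0.01, min(1, to), length.out = n_lin))
  sort(unique(signif(g, 10)))
}

#' Sweep the initiation rate to obtain J(alpha) and rho(alpha)
#'
#' Runs one steady-state simulation per grid point (each with a seed
#' derived from `config$seed`, the gene id and the grid index, so a sweep
#' is reproducible and order-independent) and smooths the raw series with
#' a running average.
#'
#' @param profile a `rate_profile`.
#' @param grid strictly increasing alpha values, s^-1.
#' @param config a `sim_config`.
#' @param smooth_window running-average window (default 10; 1 disables
#'   smoothing).
#' @return A `response_curve`: list with `gene_id`, `alpha`, `J_raw`,
#'   `J_stderr`, `rho_raw`, `rho_stderr`, `J_smooth`, `rho_smooth`.
#' @export
sweep_alpha <- function(profile, grid = default_alpha_grid(),
                        config = sim_config(), smooth_window = 10) {
  stopifnot(inherits(profile, "rate_profile"))
  if (length(grid) == 0) stop("alpha grid must not be empty")
  if (is.unsorted(grid, strictly = TRUE)) stop("alpha grid must be strictly increasing")
  if (any(grid < 0)) stop("alpha values must be >= 0")
  runs <- lapply(seq_along(grid), function(i) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, paste0(profile$gene_id, "@", i))
    simulate_steady_state(profile, grid[i], cfg)
  })
  J <- vapply(runs, `[[`, 0, "J")
  rho <- vapply(runs, `[[`, 0, "rho")
  response_curve(gene_id = profile$gene_id, alpha = grid,
                 J_raw = J, J_stderr = vapply(runs, `[[`, 0, "J_stderr"),
                 rho_raw = rho,
                 rho_stderr = vapply(runs, `[[`, 0, "rho_stderr"),
                 smooth_window = smooth_window)
}

#' Assemble a response curve from tabulated series
#'
#' @param gene_id gene identifier.
#' @param alpha strictly increasing grid, s^-1.
#' @param J_raw,rho_raw raw current and density series.
#' @param J_stderr,rho_stderr Monte-Carlo standard errors (default 0).
#' @param smooth_window running-average window applied to both series.
#' @return A `response_curve` object.
#' @export
response_curve <- function(gene_id, alpha, J_raw, rho_raw,
                           J_stderr = rep(0, length(alpha)),
                           rho_stderr = rep(0, length(alpha)),
                           smooth_window = 10) {
  n <- length(alpha)
  stopifnot(length(J_raw) == n, length(rho_raw) == n,
            length(J_stderr) == n, length(rho_stderr) == n)
  if (is.unsorted(alpha, strictly = TRUE))
    stop("alpha grid must be strictly increasing")
  structure(list(gene_id = gene_id, alpha = alpha,
                 J_raw = J_raw, J_stderr = J_stderr,
                 rho_raw = rho_raw, rho_stderr = rho_stderr,
                 J_smooth = smooth_curve(J_raw, smooth_window),
                 rho_smooth = smooth_curve(rho_raw, smooth_window),
                 # the same running average applied to the abscissa: a
                 # smoothed value estimates the curve at the window-mean
                 # alpha, which on a log-spaced grid exceeds the grid
                 # point; pairing smoothed ordinates with smoothed
                 # abscissae removes that interpolation bias
                 alpha_s = smooth_curve(alpha, smooth_window),
                 smooth_window = smooth_window),
            class = "response_curve")
}

#' Running-average smoothing
#'
#' Centred moving average of half-width `floor(window / 2)`; near the
#' boundaries the window shrinks symmetrically (half-width
#' `min(i - 1, n - i)`), so output length equals input length, constants
#' are preserved, and on series shorter than the window the central
#' position averages the whole series.
#'
#' @param series numeric vector.
#' @param window nominal window size (default 10).
#' @return Smoothed numeric vector of the same length.
#' @export
smooth_curve <- function(series, window = 10) {
  n <- length(series)
  if (n == 0) stop("series must have length >= 1")
  h <- floor(window / 2)
  if (h == 0 || n == 1) return(series)
  cs <- cumsum(c(0, series))
  out <- numeric(n)
  for (i in seq_len(n)) {
    hi <- min(h, i - 1, n - i)
    out[i] <- (cs[i + hi + 1] - cs[i - hi]) / (2 * hi + 1)
  }
  out
}

#' Saturation values of a response curve
#'
#' The maximal (elongation-limited) current and density, defined as the
#' mean of the last five simulation points of the raw series, i.e. the
#' five largest initiation rates considered.
#'
#' @param curve a `response_curve` with at least 5 grid points.
#' @return List with `J_max` (s^-1) and `rho_max` (ribosomes/codon).
#' @export
saturation_values <- function(curve) {
  stopifnot(inherits(curve, "response_curve"))
  n <- length(curve$alpha)
  if (n < 5) stop("need at least 5 grid points to define saturation values")
  tail5 <- (n - 4):n
  list(J_max = mean(curve$J_raw[tail5]), rho_max = mean(curve$rho_raw[tail5]))
}

#' Linear interpolation of a smoothed series at an alpha value
#'
#' Smoothed series are paired with the smoothed abscissa; clamps at the
#' ends so that lookups over the raw grid range stay defined.
#' @keywords internal
.interp_curve <- function(curve, what, alpha) {
  x <- if (is.null(curve$alpha_s)) curve$alpha else curve$alpha_s
  approx(x, curve[[what]], xout = alpha, rule = 2)$y
}

#' Gearing factor: slope of J(alpha) at the physiological initiation rate
#'
#' Numerical derivative of the smoothed current with respect to alpha,
#' evaluated at `alpha_ph` by a central difference over the neighbouring
#' grid points (one-sided at the grid ends). It measures responsiveness:
#' how many extra proteins per second each extra entering ribosome per
#' second buys at the operating point.
#'
#' @param curve a `response_curve`.
#' @param alpha_ph evaluation point, within the grid range.
#' @return Dimensionless slope K.
#' @export
gearing_factor <- function(curve, alpha_ph) {
  stopifnot(inherits(curve, "response_curve"))
  if (alpha_ph < curve$alpha[1] || alpha_ph > curve$alpha[length(curve$alpha)])
    stop("alpha_ph = ", alpha_ph, " outside grid range [",
         curve$alpha[1], ", ", curve$alpha[length(curve$alpha)], "]")
  a <- if (is.null(curve$alpha_s)) curve$alpha else curve$alpha_s
  J <- curve$J_smooth
  i <- which.min(abs(a - alpha_ph))
  lo <- max(1, i - 1)
  hi <- min(length(a), i + 1)
  if (lo == hi) stop("grid must have >= 2 points")
  (J[hi] - J[lo]) / (a[hi] - a[lo])
}

#' @export
print.response_curve <- function(x, ...) {
  cat("<response_curve> ", x$gene_id, ": ", length(x$alpha),
      " alpha points in [", signif(min(x$alpha), 3), ", ",
      signif(max(x$alpha), 3), "] s^-1, J up to ",
      signif(max(x$J_smooth), 4), " s^-1\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.response_curve <- function(x, ...) {
  data.frame(alpha = x$alpha, J_raw = x$J_raw, J_stderr = x$J_stderr,
             rho_raw = x$rho_raw, rho_stderr = x$rho_stderr,
             J_smooth = x$J_smooth, rho_smooth = x$rho_smooth)
}
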