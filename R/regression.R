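#' Gaussian-process regression of a metric against baseline
#'
#' Fits a Gaussian process with a squared-exponential kernel plus an
#' observation-noise term to scattered (baseline, metric) points and
#' predicts on a uniform grid spanning the observed baseline range. The
#' three hyperparameters (signal variance, length-scale, noise variance)
#' are learned by maximising the log marginal likelihood with L-BFGS-B from
#' several seeded random restarts. A GP is used because the epoch baselines
#' are inhomogeneously distributed; it smooths without imposing a
#' parametric shape.
#'
#' @param x Baseline values (predictor).
#' @param y Metric values (response), same length.
#' @param grid_size Number of prediction grid points. Default 200.
#' @param n_restarts Optimiser restarts. Default 3.
#' @param seed Seed for the restart initialisations. Default 1.
#' @return A list of class `regression_curve`: `grid`, `mean`, `lower`,
#'   `upper` (pointwise +/- 2 posterior SD of the latent function),
#'   `smoothed` (`NULL` until [smooth_and_peak()]), `fitted` (posterior
#'   mean at the training points), and the learned `hyperparameters`.
#' @export
fit_gpr <- function(x, y, grid_size = 200, n_restarts = 3, seed = 1L) {
  stopifnot(length(x) == length(y))
  if (length(x) < 10) stop("need at least 10 points for GPR", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("x and y must be finite", call. = FALSE)
  if (stats::sd(x) < .Machine$double.eps)
    stop("degenerate x: all values equal", call. = FALSE)
  n <- length(x)

  # standardise internally; hyperparameters are reported on this scale
  mx <- mean(x); sx <- stats::sd(x)
  my <- mean(y); sy <- stats::sd(y)
  if (sy < .Machine$double.eps) sy <- 1 # constant response: fit residual 0
  xs <- (x - mx) / sx
  ys <- (y - my) / sy
  d2 <- outer(xs, xs, "-")^2

  nll <- function(theta) {
    sf2 <- exp(theta[1]); ell <- exp(theta[2]); sn2 <- exp(theta[3])
    K <- sf2 * exp(-0.5 * d2 / ell^2)
    diag(K) <- diag(K) + sn2 + 1e-10
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    alpha <- backsolve(ch, forwardsolve(t(ch), ys))
    0.5 * sum(ys * alpha) + sum(log(diag(ch))) + 0.5 * n * log(2 * pi)
  }

  set.seed(seed)
  inits <- rbind(c(0, 0, log(0.1)),
                 matrix(runif(3 * (n_restarts - 1), c(-1, -2, -6), c(1, 1, 0)),
                        ncol = 3, byrow = TRUE))
  best <- NULL
  for (i in seq_len(nrow(inits))) {
    fit <- tryCatch(
      stats::optim(inits[i, ], nll, method = "L-BFGS-B",
                   lower = c(-8, -4, -27), upper = c(6, 4, 4)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("GPR hyperparameter optimisation failed", call. = FALSE)
  sf2 <- exp(best$par[1]); ell <- exp(best$par[2]); sn2 <- exp(best$par[3])

  K <- sf2 * exp(-0.5 * d2 / ell^2)
  diag(K) <- diag(K) + sn2 + 1e-10
  ch <- chol(K)
  alpha <- backsolve(ch, forwardsolve(t(ch), ys))

  grid <- seq(min(x), max(x), length.out = grid_size)
  gs <- (grid - mx) / sx
  Ks <- sf2 * exp(-0.5 * outer(gs, xs, "-")^2 / ell^2)
  mean_s <- as.numeric(Ks %*% alpha)
  v <- forwardsolve(t(ch), t(Ks))
  var_s <- pmax(sf2 - colSums(v^2), 0)

  Kt <- sf2 * exp(-0.5 * d2 / ell^2)
  fitted <- my + sy * as.numeric(Kt %*% alpha)

  structure(list(grid = grid,
                 mean = my + sy * mean_s,
                 lower = my + sy * (mean_s - 2 * sqrt(var_s)),
                 upper = my + sy * (mean_s + 2 * sqrt(var_s)),
                 smoothed = NULL, fitted = fitted,
                 hyperparameters = c(signal_var = sf2, length_scale = ell,
                                     noise_var = sn2)),
            class = "regression_curve")
}

#' @export
print.regression_curve <- function(x, ...) {
  cat(sprintf("GPR curve on [%.3g, %.3g], %d grid points%s\n",
              min(x$grid), max(x$grid), length(x$grid),
              if (is.null(x$smoothed)) "" else " (smoothed)"))
  invisible(x)
}

# internal: centered moving average in x units with shrinking edge windows
moving_average <- function(values, grid, window) {
  hw <- window / 2
  vapply(seq_along(grid), function(i) {
    mean(values[abs(grid - grid[i]) <= hw + 1e-12])
  }, numeric(1))
}

#' Moving-average smoothing and peak extraction
#'
#' Applies a centered moving average (window in baseline units, truncated
#' at the grid edges) to a fitted regression curve and locates the maximum
#' of the smoothed curve — the top of the inverted-U profile. Ties are
#' broken to the lower index; for a curve symmetric about an interior grid
#' point the peak lands exactly on it.
#'
#' @param curve A [fit_gpr()] result.
#' @param window Moving-average window in baseline units; default 5% of
#'   the grid range.
#' @return A list of class `peak_summary` with `peak_location`,
#'   `peak_value`, `is_interior` (FALSE when the argmax sits on the first
#'   or last grid point), and `curve` — the input curve with its `smoothed`
#'   field filled in.
#' @export
smooth_and_peak <- function(curve, window = NULL) {
  stopifnot(inherits(curve, "regression_curve"))
  spacing <- diff(curve$grid[1:2])
  if (is.null(window)) window <- 0.05 * diff(range(curve$grid))
  if (window < spacing) stop("window must be at least the grid spacing",
                             call. = FALSE)
  curve$smoothed <- moving_average(curve$mean, curve$grid, window)
  i <- which.max(curve$smoothed)
  structure(list(peak_location = curve$grid[i],
                 peak_value = curve$smoothed[i],
                 is_interior = i != 1L && i != length(curve$grid),
                 curve = curve),
            class = "peak_summary")
}

#' @export
print.peak_summary <- function(x, ...) {
  cat(sprintf("Peak: %.4g at %.4g (%s)\n", x$peak_value, x$peak_location,
              if (x$is_interior) "interior" else "boundary"))
  invisible(x)
}
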