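#' Coupled-Lorenz parameters for the bilateral locus coeruleus
#'
#' Each locus coeruleus (LC) population is driven by a Lorenz system; the
#' two systems are diffusively coupled in their first variable with
#' strength `J`. The default set (`a = 10`, `lorenz_b = 8/3`, `c = 28`,
#' `J = 0.7`) produces weak bilateral synchronisation (correlation of the
#' two X variables around 0.165 over the analysis window). `lorenz_b` is
#' the Lorenz dissipation parameter, distinct from the LC baseline firing
#' rate `baseline_b` of [pathway_params()].
#'
#' @param a Lorenz sigma-like parameter. Default 10.
#' @param lorenz_b Lorenz dissipation parameter. Default 8/3.
#' @param c Lorenz drive parameter. Default 28.
#' @param J Inter-LC diffusive coupling. Default 0.7.
#' @param init1,init2 Initial `(X, Y, Z)` per side. Defaults
#'   `(0, 1, 1)` and `(0, 1.1, 1.1)`.
#' @return A list of class `lorenz_params`.
#' @export
lorenz_params <- function(a = 10, lorenz_b = 8 / 3, c = 28, J = 0.7,
                          init1 = c(0, 1, 1), init2 = c(0, 1.1, 1.1)) {
  stopifnot(all(is.finite(c(a, lorenz_b, c, J, init1, init2))),
            length(init1) == 3, length(init2) == 3)
  structure(list(a = a, lorenz_b = lorenz_b, c = c, J = J,
                 init1 = init1, init2 = init2),
            class = "lorenz_params")
}

#' Pathway parameters of the pupil controller
#'
#' Parameters of the maps from LC activity to pupil diameter. LC activity
#' is `x_i = L * zscore(X_i) + baseline_b` (baseline firing rate plus
#' scaled chaotic fluctuation). The parasympathetic arm passes the
#' inhibitory ipsi- and contralateral LC drive through the
#' Edinger-Westphal nucleus: `S_i = tanh(-w_ipsi x_i - w_c x_j + beta) + 1`
#' (sphincter activation, bounded in (0, 2)). The sympathetic arm is
#' linear: dilator drive `D_i = s * x_i`. Pupil diameter is
#' `P_i = D_i - S_i + P0`.
#'
#' @param baseline_b LC baseline firing rate (both sides).
#' @param w_c Contralateral LC-to-EWN inhibitory weight. Default 0.15.
#' @param beta Other (non-LC) input to the EWN, both sides. Default 2.0.
#' @param L Scale of LC fluctuation. Default 1.5.
#' @param w_ipsi Ipsilateral LC-to-EWN weight. Default 0.3.
#' @param s LC-to-superior-cervical-ganglion weight. Default 0.3.
#' @param P0 Base pupil diameter. Default 3.0.
#' @return A list of class `pathway_params`.
#' @export
pathway_params <- function(baseline_b = 4.8, w_c = 0.15, beta = 2.0,
                           L = 1.5, w_ipsi = 0.3, s = 0.3, P0 = 3.0) {
  stopifnot(w_c >= 0, w_ipsi >= 0, s >= 0, L > 0,
            all(is.finite(c(baseline_b, w_c, beta, L, w_ipsi, s, P0))))
  structure(list(baseline_b = baseline_b, w_c = w_c, beta = beta, L = L,
                 w_ipsi = w_ipsi, s = s, P0 = P0),
            class = "pathway_params")
}

#' Integrate the coupled Lorenz pair
#'
#' Fixed-step 4th-order Runge-Kutta integration of the six-dimensional
#' coupled Lorenz system from the configured initial values. Deterministic.
#'
#' @param params A [lorenz_params()] object.
#' @param t_end End of integration (model time). Default 300.
#' @param dt Integration step. Default 0.001.
#' @param sample_dt Interval at which the state is recorded (must be a
#'   multiple of `dt`). Default 0.05.
#' @return A data.frame with columns `t, X1, Y1, Z1, X2, Y2, Z2`.
#' @export
integrate_coupled_lorenz <- function(params = lorenz_params(), t_end = 300,
                                     dt = 0.001, sample_dt = 0.05) {
  stopifnot(dt > 0, t_end > dt)
  sample_every <- as.integer(round(sample_dt / dt))
  stopifnot(sample_every >= 1,
            abs(sample_every * dt - sample_dt) < 1e-9)
  m <- cpp_coupled_lorenz_rk4(params$a, params$lorenz_b, params$c, params$J,
                              params$init1, params$init2, t_end, dt,
                              sample_every)
  out <- as.data.frame(m)
  names(out) <- c("t", "X1", "Y1", "Z1", "X2", "Y2", "Z2")
  out
}

#' LC population activity from a Lorenz trajectory
#'
#' `x_i = L * zscore(X_i) + baseline_b`, with the z-score computed over the
#' supplied analysis window, so the activity has mean `baseline_b` and SD
#' `L` on that window.
#'
#' @param X Numeric vector, one side's Lorenz X over the analysis window.
#' @param L Fluctuation scale.
#' @param baseline_b Baseline firing rate.
#' @return Numeric vector of LC activity.
#' @export
lc_activity <- function(X, L, baseline_b) {
  L * zscore(X) + baseline_b
}

#' EWN-to-ciliary-ganglion output
#'
#' `S_i = tanh(-w_ipsi x_i - w_c x_j + beta) + 1`, strictly inside (0, 2).
#'
#' @param x1,x2 LC activity of this side and the opposite side.
#' @param params A [pathway_params()] object.
#' @return Numeric vector `S` for the side whose own activity is `x1`.
#' @export
ewn_output <- function(x1, x2, params) {
  tanh(-params$w_ipsi * x1 - params$w_c * x2 + params$beta) + 1
}

#' Pupil diameter from pathway activations
#'
#' Dilator drive `D = s * x`; pupil diameter `P = D - S + P0`.
#'
#' @param x LC activity (this side).
#' @param S Sphincter activation (this side).
#' @param params A [pathway_params()] object.
#' @return A list with `D` and `P`.
#' @export
pupil_output <- function(x, S, params) {
  D <- params$s * x
  list(D = D, P = D - S + params$P0)
}

#' Simulate the pupil-control model
#'
#' Runs the coupled Lorenz pair and applies the pathway maps to obtain LC
#' activity, sphincter and dilator drives, and bilateral pupil diameters.
#' The z-score in the LC-activity map is computed over the analysis window
#' `t_analysis[1] <= t <= t_analysis[2]` (the transient before it is
#' excluded from all statistics), and pathway outputs are reported on that
#' window.
#'
#' @param pathway A [pathway_params()] object.
#' @param lorenz A [lorenz_params()] object.
#' @param t_end,dt,sample_dt Integration settings, see
#'   [integrate_coupled_lorenz()].
#' @param t_analysis Analysis window, default `c(10, 300)`.
#' @param trajectory Optional precomputed output of
#'   [integrate_coupled_lorenz()] to reuse across parameter settings (the
#'   Lorenz trajectory does not depend on the pathway parameters).
#' @return A list of class `pupil_simulation` with `t`, and per side `X`,
#'   `x`, `S`, `D`, `P` (matrices with two columns, left and right),
#'   restricted to the analysis window.
#' @export
simulate_pupil_model <- function(pathway = pathway_params(),
                                 lorenz = lorenz_params(),
                                 t_end = 300, dt = 0.001, sample_dt = 0.05,
                                 t_analysis = c(10, 300),
                                 trajectory = NULL) {
  if (is.null(trajectory))
    trajectory <- integrate_coupled_lorenz(lorenz, t_end, dt, sample_dt)
  keep <- trajectory$t >= t_analysis[1] & trajectory$t <= t_analysis[2]
  X <- cbind(trajectory$X1[keep], trajectory$X2[keep])
  x <- cbind(lc_activity(X[, 1], pathway$L, pathway$baseline_b),
             lc_activity(X[, 2], pathway$L, pathway$baseline_b))
  S <- cbind(ewn_output(x[, 1], x[, 2], pathway),
             ewn_output(x[, 2], x[, 1], pathway))
  o1 <- pupil_output(x[, 1], S[, 1], pathway)
  o2 <- pupil_output(x[, 2], S[, 2], pathway)
  structure(list(t = trajectory$t[keep], X = X, x = x, S = S,
                 D = cbind(o1$D, o2$D), P = cbind(o1$P, o2$P),
                 pathway = pathway),
            class = "pupil_simulation")
}

#' @export
print.pupil_simulation <- function(x, ...) {
  cat(sprintf(paste0("Pupil-control simulation: %d samples, ",
                     "t in [%.2f, %.2f], b = %.2f, w_c = %.2f, beta = %.2f\n"),
              length(x$t), min(x$t), max(x$t), x$pathway$baseline_b,
              x$pathway$w_c, x$pathway$beta))
  invisible(x)
}

#' Sweep baseline LC activity
#'
#' For each baseline firing rate `b` on a grid, simulates the model (one
#' shared Lorenz trajectory; only the pathway maps depend on `b`), z-scores
#' the pupil outputs over the analysis window, and computes sample entropy
#' per side plus direction-averaged transfer entropy between the sides.
#' This maps the inverted-U profiles of complexity and symmetricity against
#' baseline LC activity.
#'
#' @param b_grid Numeric vector of baseline values (e.g. `seq(3, 7, 0.1)`).
#' @param w_c Contralateral weight for the sweep condition.
#' @param beta EWN external input for the sweep condition.
#' @param sampen A [sampen_params()] object.
#' @param tranen A [tranen_params()] object.
#' @param lorenz A [lorenz_params()] object.
#' @param t_end,dt,sample_dt,t_analysis Simulation settings.
#' @param seed Seed for the tie-breaking jitter inside the knn estimator;
#'   results are deterministic given the full configuration.
#' @param trajectory Optional precomputed Lorenz trajectory to reuse.
#' @return A data.frame of class `sweep_result` with columns `b`,
#'   `sampen_left`, `sampen_right`, `tranen_mean` and attributes `w_c`,
#'   `beta`.
#' @export
sweep_baseline <- function(b_grid, w_c = 0.15, beta = 2.0,
                           sampen = sampen_params(),
                           tranen = tranen_params(),
                           lorenz = lorenz_params(),
                           t_end = 300, dt = 0.001, sample_dt = 0.05,
                           t_analysis = c(10, 300), seed = 1L,
                           trajectory = NULL) {
  stopifnot(length(b_grid) >= 1)
  if (is.null(trajectory))
    trajectory <- integrate_coupled_lorenz(lorenz, t_end, dt, sample_dt)
  res <- lapply(b_grid, function(b) {
    sim <- simulate_pupil_model(
      pathway_params(baseline_b = b, w_c = w_c, beta = beta),
      lorenz, t_end, dt, sample_dt, t_analysis, trajectory = trajectory)
    pl <- zscore(sim$P[, 1])
    pr <- zscore(sim$P[, 2])
    set.seed(seed)
    te <- bilateral_symmetricity(list(left = pl, right = pr), tranen)
    c(sampen_left = sample_entropy(pl, sampen)$value,
      sampen_right = sample_entropy(pr, sampen)$value,
      tranen_mean = te$te_mean)
  })
  out <- data.frame(b = b_grid, do.call(rbind, res))
  attr(out, "w_c") <- w_c
  attr(out, "beta") <- beta
  class(out) <- c("sweep_result", "data.frame")
  out
}
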