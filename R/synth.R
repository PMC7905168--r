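#' Synthetic-cohort configuration
#'
#' Settings for the generator of realistic bilateral pupil recordings. Two
#' hippus sources are available: `"lcewn_model"` runs the pupil-control
#' simulation (nonlinear, deterministic — what the surrogate test should
#' detect) with the baseline firing rate mapped affinely from the drawn
#' baseline diameter, and `"linear_ar"` produces a bilaterally correlated
#' Gaussian AR(2) process (linear, stochastic — the surrogate-test null).
#' Blink gaps are carved at Poisson arrivals, simultaneously in both eyes,
#' and white measurement noise is added.
#'
#' @param n_recordings Number of recordings in a cohort. Default 17.
#' @param duration_s Recording length in seconds. Default 120.
#' @param fs Sampling frequency in Hz. Default 300.
#' @param baseline_range_mm Range the per-recording baseline diameters are
#'   drawn from. Default `c(2.5, 7.5)` mm.
#' @param hippus_source `"lcewn_model"` or `"linear_ar"`.
#' @param blink_rate_hz Blink arrivals per second. Default 0.2.
#' @param blink_dur_ms Blink-duration range in ms. Default `c(100, 400)`.
#' @param noise_sd_mm White measurement-noise SD. Default 0.02 mm.
#' @param amplitude_sd_mm SD of the hippus fluctuation in mm. Default 0.15.
#' @param ar_cor Innovation correlation between eyes for the AR source.
#'   Default 0.8.
#' @param seed Cohort seed. Default 1.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_recordings = 17, duration_s = 120, fs = 300,
                         baseline_range_mm = c(2.5, 7.5),
                         hippus_source = c("lcewn_model", "linear_ar"),
                         blink_rate_hz = 0.2, blink_dur_ms = c(100, 400),
                         noise_sd_mm = 0.02, amplitude_sd_mm = 0.15,
                         ar_cor = 0.8, seed = 1L) {
  hippus_source <- match.arg(hippus_source)
  stopifnot(n_recordings >= 1, duration_s > 0, fs > 0,
            length(baseline_range_mm) == 2,
            baseline_range_mm[1] < baseline_range_mm[2],
            baseline_range_mm[1] > 1, baseline_range_mm[2] < 9,
            blink_rate_hz >= 0, length(blink_dur_ms) == 2,
            blink_dur_ms[1] <= blink_dur_ms[2], blink_dur_ms[1] > 0,
            noise_sd_mm >= 0, amplitude_sd_mm > 0,
            ar_cor >= -1, ar_cor <= 1)
  structure(list(n_recordings = as.integer(n_recordings),
                 duration_s = duration_s, fs = fs,
                 baseline_range_mm = baseline_range_mm,
                 hippus_source = hippus_source,
                 blink_rate_hz = blink_rate_hz, blink_dur_ms = blink_dur_ms,
                 noise_sd_mm = noise_sd_mm,
                 amplitude_sd_mm = amplitude_sd_mm,
                 ar_cor = ar_cor, seed = as.integer(seed)),
            class = "synth_config")
}

# internal: map a baseline diameter in mm onto the model's baseline firing
# rate: [2.5, 7.5] mm -> [3, 7] (monotone link between pupil size and tonic
# LC activity)
baseline_to_b <- function(baseline_mm, range_mm = c(2.5, 7.5),
                          range_b = c(3, 7)) {
  range_b[1] + (baseline_mm - range_mm[1]) /
    diff(range_mm) * diff(range_b)
}

# internal: bilaterally correlated Gaussian AR(2), n x 2, unit-ish scale
ar2_bilateral <- function(n, phi = c(1.8, -0.81), cor_innov = 0.8,
                          burn = 500L) {
  m <- n + burn
  e1 <- rnorm(m)
  shared <- rnorm(m)
  e2 <- cor_innov * e1 + sqrt(1 - cor_innov^2) * rnorm(m)
  x <- matrix(0, m, 2)
  innov <- cbind(e1, e2)
  for (t in 3:m)
    x[t, ] <- phi[1] * x[t - 1, ] + phi[2] * x[t - 2, ] + innov[t, ]
  x[(burn + 1):m, , drop = FALSE]
}

#' Generate one synthetic bilateral recording
#'
#' Draws a baseline diameter, synthesises a bilaterally coupled hippus
#' signal from the configured source, rescales it to mm around the
#' baseline, adds white measurement noise, and carves blink gaps (missing
#' runs at Poisson arrival times, durations uniform in the configured
#' range, affecting both eyes simultaneously). Fully reproducible from the
#' seed.
#'
#' @param cfg A [synth_config()].
#' @param seed Seed for this recording.
#' @param baseline_mm Optional fixed baseline diameter; drawn uniformly
#'   from `cfg$baseline_range_mm` when `NULL`.
#' @return A list with `recording` (a [pupil_recording()]) and
#'   `ground_truth` (source, baseline, model/AR parameters, blink
#'   intervals, seed).
#' @export
generate_recording <- function(cfg = synth_config(), seed = cfg$seed,
                               baseline_mm = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(seed)
  n <- as.integer(round(cfg$duration_s * cfg$fs))
  if (is.null(baseline_mm))
    baseline_mm <- runif(1, cfg$baseline_range_mm[1], cfg$baseline_range_mm[2])

  if (cfg$hippus_source == "lcewn_model") {
    b <- baseline_to_b(baseline_mm, cfg$baseline_range_mm)
    sample_dt <- 0.05
    t_end <- 10 + n * sample_dt
    sim <- simulate_pupil_model(pathway_params(baseline_b = b),
                                t_end = t_end, sample_dt = sample_dt,
                                t_analysis = c(10, t_end))
    P <- sim$P[seq_len(n), , drop = FALSE]
    sc <- cfg$amplitude_sd_mm / mean(apply(P, 2, stats::sd))
    hippus <- baseline_mm + (P - mean(P)) * sc
    src_params <- list(baseline_b = b, sample_dt = sample_dt)
  } else {
    ar <- ar2_bilateral(n, cor_innov = cfg$ar_cor)
    sc <- cfg$amplitude_sd_mm / mean(apply(ar, 2, stats::sd))
    hippus <- baseline_mm + (ar - mean(ar)) * sc
    src_params <- list(phi = c(1.8, -0.81), ar_cor = cfg$ar_cor)
  }

  left <- hippus[, 1] + rnorm(n, 0, cfg$noise_sd_mm)
  right <- hippus[, 2] + rnorm(n, 0, cfg$noise_sd_mm)

  n_blinks <- stats::rpois(1, cfg$blink_rate_hz * cfg$duration_s)
  blink_start <- sort(runif(n_blinks, 0, cfg$duration_s))
  blink_dur <- runif(n_blinks, cfg$blink_dur_ms[1], cfg$blink_dur_ms[2]) / 1000
  for (k in seq_len(n_blinks)) {
    i0 <- max(1L, as.integer(floor(blink_start[k] * cfg$fs)) + 1L)
    i1 <- min(n, as.integer(ceiling((blink_start[k] + blink_dur[k]) * cfg$fs)))
    left[i0:i1] <- NA_real_
    right[i0:i1] <- NA_real_
  }

  rec <- pupil_recording(time = (seq_len(n) - 1) / cfg$fs,
                         left = left, right = right, fs = cfg$fs)
  list(recording = rec,
       ground_truth = list(seed = seed, source = cfg$hippus_source,
                           baseline_mm = baseline_mm,
                           source_params = src_params,
                           blink_start_s = blink_start,
                           blink_dur_s = blink_dur))
}

#' Generate a synthetic cohort on disk
#'
#' Writes `n_recordings` CSV recordings plus a `manifest.csv` linking each
#' file to its ground truth. Baselines are assigned on an evenly spaced
#' grid across `baseline_range_mm` (with a small seeded jitter), so the
#' pooled scatter covers the whole inverted-U domain.
#'
#' @param cfg A [synth_config()].
#' @param out_dir Output directory (created if absent).
#' @return The manifest data.frame, invisibly.
#' @export
generate_cohort <- function(cfg = synth_config(), out_dir) {
  stopifnot(inherits(cfg, "synth_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  nr <- cfg$n_recordings
  span <- diff(cfg$baseline_range_mm)
  targets <- if (nr == 1) mean(cfg$baseline_range_mm) else
    seq(cfg$baseline_range_mm[1] + 0.05 * span,
        cfg$baseline_range_mm[2] - 0.05 * span, length.out = nr)
  targets <- pmin(pmax(targets + runif(nr, -0.02, 0.02) * span,
                       cfg$baseline_range_mm[1]),
                  cfg$baseline_range_mm[2])
  seeds <- cfg$seed + seq_len(nr)
  rows <- vector("list", nr)
  for (i in seq_len(nr)) {
    g <- generate_recording(cfg, seed = seeds[i], baseline_mm = targets[i])
    fname <- sprintf("recording_%02d.csv", i)
    write_recording(g$recording, file.path(out_dir, fname))
    rows[[i]] <- data.frame(file = fname, seed = seeds[i],
                            source = g$ground_truth$source,
                            baseline_mm = g$ground_truth$baseline_mm)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
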