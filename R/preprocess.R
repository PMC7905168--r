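#' Preprocessing configuration
#'
#' Epoching and filtering settings for bilateral pupil recordings: epochs of
#' `epoch_s` seconds cut consecutively from the recording start, exclusion
#' of epochs missing strictly more than `max_missing_fraction` of their
#' samples in either eye, and zero-phase Butterworth low-pass filtering
#' with cutoff `lowpass_hz`.
#'
#' @param epoch_s Epoch length in seconds. Default 2.0.
#' @param max_missing_fraction Maximum tolerated per-eye missing fraction
#'   (exclusive bound). Default 0.10; an epoch missing exactly 10% is
#'   retained.
#' @param lowpass_hz Low-pass cutoff in Hz (must stay below the Nyquist
#'   frequency of the recording it is applied to). Default 50.
#' @param filter_order Butterworth order (applied forward-backward, so the
#'   effective attenuation is doubled). Default 4.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(epoch_s = 2.0, max_missing_fraction = 0.10,
                              lowpass_hz = 50, filter_order = 4) {
  stopifnot(epoch_s > 0,
            max_missing_fraction > 0, max_missing_fraction < 1,
            lowpass_hz > 0, filter_order >= 1)
  structure(list(epoch_s = epoch_s,
                 max_missing_fraction = max_missing_fraction,
                 lowpass_hz = lowpass_hz,
                 filter_order = as.integer(filter_order)),
            class = "preprocess_config")
}

#' Construct a bilateral pupil recording
#'
#' Container for a bilateral pupil-diameter trace on a uniform time grid.
#' Samples that are `NA` or non-positive are flagged missing (remote eye
#' trackers emit zeros on track loss) and stored as `NA`.
#'
#' @param time Time in seconds, uniform grid.
#' @param left,right Pupil diameters in mm.
#' @param fs Sampling frequency in Hz.
#' @return A list of class `pupil_recording` with elements `time`, `left`,
#'   `right`, `missing_left`, `missing_right`, `fs`.
#' @export
pupil_recording <- function(time, left, right, fs) {
  n <- length(time)
  if (length(left) != n || length(right) != n)
    stop("time, left and right must have equal length", call. = FALSE)
  stopifnot(is.numeric(fs), length(fs) == 1, fs > 0)
  missing_left <- is.na(left) | left <= 0
  missing_right <- is.na(right) | right <= 0
  left[missing_left] <- NA_real_
  right[missing_right] <- NA_real_
  structure(list(time = as.numeric(time), left = as.numeric(left),
                 right = as.numeric(right),
                 missing_left = missing_left,
                 missing_right = missing_right, fs = fs),
            class = "pupil_recording")
}

#' @export
print.pupil_recording <- function(x, ...) {
  cat(sprintf(paste0("Pupil recording: %d samples at %g Hz (%.1f s), ",
                     "missing %.1f%% (L) / %.1f%% (R)\n"),
              length(x$time), x$fs, length(x$time) / x$fs,
              100 * mean(x$missing_left), 100 * mean(x$missing_right)))
  invisible(x)
}

#' Read a bilateral pupil recording from CSV
#'
#' Expects a comma-separated file with header `time,left,right` (time in
#' seconds, diameters in mm). Missing samples may be encoded as an empty
#' field, `NaN`, `NA`, or a non-positive diameter; all are flagged in the
#' missing masks. The time column must be a uniform grid at `1/fs` within
#' 1e-6 s.
#'
#' @param path Path to the CSV file.
#' @param fs Sampling frequency in Hz.
#' @return A [pupil_recording()].
#' @export
read_recording <- function(path, fs) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character",
                        strip.white = TRUE)
  need <- c("time", "left", "right")
  if (!all(need %in% names(df)))
    stop("expected columns time,left,right in ", path, call. = FALSE)
  parse_col <- function(v, col) {
    blank <- v == "" | toupper(v) %in% c("NAN", "NA")
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!blank & is.na(out))
    if (length(bad))
      stop(sprintf("malformed value in column '%s' at line %d of %s",
                   col, bad[1] + 1L, path), call. = FALSE) # +1 for header
    out
  }
  time <- parse_col(df$time, "time")
  if (anyNA(time)) stop("missing values in time column of ", path, call. = FALSE)
  dt <- diff(time)
  if (length(dt) && max(abs(dt - 1 / fs)) > 1e-6)
    stop("time column is not a uniform 1/fs grid (tolerance 1e-6 s) in ",
         path, call. = FALSE)
  pupil_recording(time, parse_col(df$left, "left"),
                  parse_col(df$right, "right"), fs)
}

#' Write a pupil recording to CSV
#'
#' Inverse of [read_recording()]: columns `time,left,right`, missing
#' samples written as `NaN`.
#'
#' @param rec A [pupil_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  df <- data.frame(time = rec$time, left = rec$left, right = rec$right)
  utils::write.csv(df, path, row.names = FALSE, na = "NaN")
  invisible(path)
}

# internal: linear interpolation of NA runs, nearest-value fill at the ends
interpolate_gaps <- function(v) {
  ok <- which(!is.na(v))
  if (length(ok) == length(v)) return(v)
  if (length(ok) == 0) stop("cannot interpolate an all-missing segment",
                            call. = FALSE)
  if (length(ok) == 1) return(rep(v[ok], length(v)))
  stats::approx(ok, v[ok], xout = seq_along(v), method = "linear",
                rule = 2)$y
}

#' Segment a recording into preprocessed epochs
#'
#' Cuts non-overlapping consecutive epochs of `epoch_s` seconds from the
#' recording start (a trailing partial epoch is discarded). The per-eye
#' missing fraction is computed before interpolation; epochs missing
#' strictly more than `max_missing_fraction` of their length in either eye
#' are excluded. In retained epochs, interior gaps are linearly
#' interpolated from the flanking non-missing samples and leading/trailing
#' gaps are filled with the nearest non-missing value. Epochs are not yet
#' filtered; see [lowpass_epoch()].
#'
#' @param rec A [pupil_recording()].
#' @param cfg A [preprocess_config()].
#' @return A list of `pupil_epoch` objects (fields `left`, `right`, `fs`,
#'   `index`, `missing_fraction_left/right`, `baseline_left/right/mean`),
#'   with attribute `qc` — a data.frame describing every candidate epoch
#'   including the excluded ones.
#' @export
segment_epochs <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "pupil_recording"),
            inherits(cfg, "preprocess_config"))
  len <- as.integer(round(cfg$epoch_s * rec$fs))
  n <- length(rec$time)
  n_epochs <- n %/% len
  if (n_epochs == 0) {
    warning("recording shorter than one epoch; returning no epochs")
    out <- list()
    attr(out, "qc") <- data.frame(epoch_index = integer(),
                                  missing_frac_left = numeric(),
                                  missing_frac_right = numeric(),
                                  excluded = logical())
    return(out)
  }
  epochs <- list()
  qc <- data.frame(epoch_index = seq_len(n_epochs),
                   missing_frac_left = NA_real_,
                   missing_frac_right = NA_real_,
                   excluded = NA)
  for (e in seq_len(n_epochs)) {
    idx <- ((e - 1L) * len + 1L):(e * len)
    fl <- mean(rec$missing_left[idx])
    fr <- mean(rec$missing_right[idx])
    qc$missing_frac_left[e] <- fl
    qc$missing_frac_right[e] <- fr
    excl <- fl > cfg$max_missing_fraction || fr > cfg$max_missing_fraction
    qc$excluded[e] <- excl
    if (excl) next
    left <- interpolate_gaps(rec$left[idx])
    right <- interpolate_gaps(rec$right[idx])
    epochs[[length(epochs) + 1L]] <- structure(
      list(left = left, right = right, fs = rec$fs, index = e,
           missing_fraction_left = fl, missing_fraction_right = fr,
           baseline_left = mean(left), baseline_right = mean(right),
           baseline_mean = (mean(left) + mean(right)) / 2),
      class = "pupil_epoch")
  }
  attr(epochs, "qc") <- qc
  epochs
}

#' @export
print.pupil_epoch <- function(x, ...) {
  cat(sprintf(paste0("Pupil epoch #%d: %d samples at %g Hz, baseline ",
                     "%.2f mm (L %.2f / R %.2f)\n"),
              x$index, length(x$left), x$fs, x$baseline_mean,
              x$baseline_left, x$baseline_right))
  invisible(x)
}

# internal: zero-phase Butterworth low-pass with odd-reflection padding
zero_phase_lowpass <- function(v, fs, cutoff, order) {
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  n <- length(v)
  pad <- min(150L, n - 1L) # long enough for the zero-IC transient to die out
  ext <- c(2 * v[1] - v[(pad + 1L):2],
           v,
           2 * v[n] - v[(n - 1L):(n - pad)])
  y <- signal::filtfilt(bf, ext)
  y[(pad + 1L):(pad + n)]
}

#' Low-pass filter an epoch
#'
#' Applies a zero-phase (forward-backward) Butterworth low-pass filter
#' independently to each eye's series. The passband includes DC, so the
#' epoch mean is preserved (within edge effects, below 1%); baselines are
#' recomputed after filtering.
#'
#' @param e A `pupil_epoch`.
#' @param cfg A [preprocess_config()].
#' @return The filtered `pupil_epoch`.
#' @export
lowpass_epoch <- function(e, cfg = preprocess_config()) {
  stopifnot(inherits(e, "pupil_epoch"), inherits(cfg, "preprocess_config"))
  if (cfg$lowpass_hz >= e$fs / 2)
    stop("low-pass cutoff must be below the Nyquist frequency", call. = FALSE)
  e$left <- zero_phase_lowpass(e$left, e$fs, cfg$lowpass_hz, cfg$filter_order)
  e$right <- zero_phase_lowpass(e$right, e$fs, cfg$lowpass_hz, cfg$filter_order)
  e$baseline_left <- mean(e$left)
  e$baseline_right <- mean(e$right)
  e$baseline_mean <- (e$baseline_left + e$baseline_right) / 2
  e
}

#' Per-epoch baseline diameter
#'
#' The temporal mean diameter of each eye over the epoch, and their
#' average — the "baseline" against which complexity and symmetricity are
#' plotted.
#'
#' @param e A `pupil_epoch`.
#' @return A list with `left`, `right`, `mean` (mm).
#' @export
epoch_baseline <- function(e) {
  stopifnot(inherits(e, "pupil_epoch"))
  bl <- mean(e$left); br <- mean(e$right)
  list(left = bl, right = br, mean = (bl + br) / 2)
}

#' Summary table of a list of epochs
#'
#' @param epochs List of `pupil_epoch` objects (from [segment_epochs()]).
#' @return A data.frame with one row per retained epoch: index, baselines
#'   and missing fractions.
#' @export
epoch_summary <- function(epochs) {
  do.call(rbind, lapply(epochs, function(e)
    data.frame(epoch_index = e$index,
               baseline_left = e$baseline_left,
               baseline_right = e$baseline_right,
               baseline_mean = e$baseline_mean,
               missing_frac_left = e$missing_fraction_left,
               missing_frac_right = e$missing_fraction_right)))
}
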