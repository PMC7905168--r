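#' Composite run configuration
#'
#' Bundles every stage's settings for the two headline experiments: the
#' data analysis (preprocess, sample entropy, transfer entropy, surrogate
#' tests, GPR inverted-U extraction) and the model analysis (baseline
#' sweeps across contralateral-weight and external-input conditions).
#'
#' @param input_dir Directory of recording CSVs (data analysis).
#' @param out_dir Directory artifacts are written to.
#' @param fs Sampling frequency of the recordings in Hz. Default 300.
#' @param preprocess A [preprocess_config()].
#' @param sampen A [sampen_params()].
#' @param tranen A [tranen_params()].
#' @param surrogate A [surrogate_config()].
#' @param grid_size GPR prediction grid size. Default 200.
#' @param ma_window_frac Moving-average window as a fraction of the
#'   baseline range. Default 0.05.
#' @param b_grid Baseline grid for the model sweeps. Default
#'   `seq(3, 7, by = 0.1)`.
#' @param w_c_values Contralateral weights to sweep. Default
#'   `c(0.15, 0)`.
#' @param beta_values External EWN inputs to sweep at the first `w_c`.
#'   Default `c(2.0, 3.5, 5.0)`.
#' @param seed Global seed. Default 1.
#' @return A list of class `run_config`.
#' @export
run_config <- function(input_dir = NULL, out_dir = tempfile("pupilrun"),
                       fs = 300,
                       preprocess = preprocess_config(),
                       sampen = sampen_params(),
                       tranen = tranen_params(),
                       surrogate = surrogate_config(),
                       grid_size = 200, ma_window_frac = 0.05,
                       b_grid = seq(3, 7, by = 0.1),
                       w_c_values = c(0.15, 0),
                       beta_values = c(2.0, 3.5, 5.0),
                       seed = 1L) {
  structure(list(input_dir = input_dir, out_dir = out_dir, fs = fs,
                 preprocess = preprocess, sampen = sampen, tranen = tranen,
                 surrogate = surrogate, grid_size = grid_size,
                 ma_window_frac = ma_window_frac, b_grid = b_grid,
                 w_c_values = w_c_values, beta_values = beta_values,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full data analysis
#'
#' Reads every recording CSV in `cfg$input_dir`, preprocesses it (epoching,
#' interpolation, QC exclusion, low-pass filtering), computes per-epoch
#' sample entropy (per eye) and bilateral transfer entropy, runs the IAAFT
#' surrogate tests for both metrics, and fits GPR + moving-average curves
#' of each metric against baseline diameter with peak extraction. All
#' intermediate tables are written as CSV and the report as JSON under
#' `cfg$out_dir`.
#'
#' @param cfg A [run_config()] with `input_dir` set.
#' @return A list of class `pupil_report`: `epochs` (metric table),
#'   `surrogate_sampen`, `surrogate_tranen`, `peak_sampen`, `peak_tranen`,
#'   and `files` (paths of artifacts written).
#' @export
run_data_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$input_dir) || !dir.exists(cfg$input_dir))
    stop("input directory does not exist", call. = FALSE)
  files <- list.files(cfg$input_dir, pattern = "\\.csv$", full.names = TRUE)
  files <- files[basename(files) != "manifest.csv"]
  if (length(files) == 0)
    stop("no recording CSVs found in ", cfg$input_dir, call. = FALSE)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)

  rows <- list(); all_epochs <- list()
  for (f in files) {
    rec <- read_recording(f, cfg$fs)
    epochs <- segment_epochs(rec, cfg$preprocess)
    for (e in epochs) {
      e <- lowpass_epoch(e, cfg$preprocess)
      sl <- sample_entropy(e$left, cfg$sampen)
      sr <- sample_entropy(e$right, cfg$sampen)
      te <- bilateral_symmetricity(e, cfg$tranen)
      rows[[length(rows) + 1L]] <- data.frame(
        recording = basename(f), epoch_index = e$index,
        baseline_left = e$baseline_left, baseline_right = e$baseline_right,
        baseline_mean = e$baseline_mean,
        sampen_left = sl$value, sampen_right = sr$value,
        te_lr = te$te_lr, te_rl = te$te_rl, te_mean = te$te_mean)
      all_epochs[[length(all_epochs) + 1L]] <- e
    }
  }
  if (length(rows) == 0) stop("no epochs survived preprocessing", call. = FALSE)
  tab <- do.call(rbind, rows)

  surr_se <- surrogate_metric_test(all_epochs, "sampen", cfg$surrogate,
                                   cfg$sampen)
  surr_te <- surrogate_metric_test(all_epochs, "tranen", cfg$surrogate,
                                   cfg$tranen)

  window <- cfg$ma_window_frac * diff(range(tab$baseline_mean))
  fit_curve <- function(x, y) {
    pk <- smooth_and_peak(fit_gpr(x, y, cfg$grid_size, seed = cfg$seed),
                          window = window)
    pk
  }
  pk_se <- fit_curve(rep(tab$baseline_mean, 2),
                     c(tab$sampen_left, tab$sampen_right))
  pk_te <- fit_curve(tab$baseline_mean, tab$te_mean)

  paths <- c(
    epochs = file.path(cfg$out_dir, "epoch_metrics.csv"),
    curves = file.path(cfg$out_dir, "curves.csv"),
    report = file.path(cfg$out_dir, "report.json"))
  utils::write.csv(tab, paths["epochs"], row.names = FALSE)
  curve_tab <- rbind(
    data.frame(metric = "sampen", grid = pk_se$curve$grid,
               mean = pk_se$curve$mean, lower = pk_se$curve$lower,
               upper = pk_se$curve$upper, smoothed = pk_se$curve$smoothed),
    data.frame(metric = "tranen", grid = pk_te$curve$grid,
               mean = pk_te$curve$mean, lower = pk_te$curve$lower,
               upper = pk_te$curve$upper, smoothed = pk_te$curve$smoothed))
  utils::write.csv(curve_tab, paths["curves"], row.names = FALSE)
  report <- list(
    n_recordings = length(files), n_epochs = nrow(tab),
    surrogate_sampen = as.list(as.data.frame(surr_se)),
    surrogate_tranen = as.list(as.data.frame(surr_te)),
    peak_sampen = list(location = pk_se$peak_location,
                       value = pk_se$peak_value,
                       is_interior = pk_se$is_interior),
    peak_tranen = list(location = pk_te$peak_location,
                       value = pk_te$peak_value,
                       is_interior = pk_te$is_interior))
  jsonlite::write_json(report, paths["report"], auto_unbox = TRUE,
                       digits = NA)

  structure(list(epochs = tab, surrogate_sampen = surr_se,
                 surrogate_tranen = surr_te, peak_sampen = pk_se,
                 peak_tranen = pk_te, files = paths),
            class = "pupil_report")
}

#' Run the model analysis
#'
#' Sweeps baseline LC activity for every configured contralateral-weight
#' condition (at the first external input) and every external-input
#' condition (at the first weight), writing one sweep CSV per condition
#' and a JSON summary of the sample-entropy and transfer-entropy peaks.
#' The Lorenz trajectory is shared across conditions (it does not depend
#' on the pathway parameters), so the sweeps are mutually consistent.
#'
#' @param cfg A [run_config()].
#' @return A list of class `pupil_report` with `sweeps` (named list of
#'   [sweep_baseline()] results), `peaks` (data.frame of per-condition
#'   argmax and maxima), and `files`.
#' @export
run_model_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  traj <- integrate_coupled_lorenz()
  conds <- unique(rbind(
    data.frame(w_c = cfg$w_c_values, beta = cfg$beta_values[1]),
    data.frame(w_c = cfg$w_c_values[1], beta = cfg$beta_values)))
  sweeps <- list(); peak_rows <- list(); paths <- character()
  for (i in seq_len(nrow(conds))) {
    wc <- conds$w_c[i]; bt <- conds$beta[i]
    key <- sprintf("wc%g_beta%g", wc, bt)
    sw <- sweep_baseline(cfg$b_grid, w_c = wc, beta = bt,
                         sampen = cfg$sampen, tranen = cfg$tranen,
                         seed = cfg$seed, trajectory = traj)
    sweeps[[key]] <- sw
    p <- file.path(cfg$out_dir, paste0("sweep_", key, ".csv"))
    utils::write.csv(as.data.frame(sw), p, row.names = FALSE)
    paths <- c(paths, p)
    se <- (sw$sampen_left + sw$sampen_right) / 2
    peak_rows[[key]] <- data.frame(
      w_c = wc, beta = bt,
      sampen_max = max(se), sampen_argmax_b = sw$b[which.max(se)],
      tranen_max = max(sw$tranen_mean),
      tranen_argmax_b = sw$b[which.max(sw$tranen_mean)])
  }
  peaks <- do.call(rbind, peak_rows)
  pjson <- file.path(cfg$out_dir, "model_peaks.json")
  jsonlite::write_json(peaks, pjson, auto_unbox = TRUE, digits = NA)
  structure(list(sweeps = sweeps, peaks = peaks,
                 files = c(paths, pjson)),
            class = "pupil_report")
}

#' @export
print.pupil_report <- function(x, ...) {
  if (!is.null(x$epochs)) {
    cat(sprintf("Data-analysis report: %d epochs\n", nrow(x$epochs)))
    print(x$surrogate_sampen); print(x$surrogate_tranen)
    cat("SampEn "); print(x$peak_sampen)
    cat("TranEn "); print(x$peak_tranen)
  } else {
    cat("Model-analysis report:\n")
    print(x$peaks)
  }
  invisible(x)
}
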