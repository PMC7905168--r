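#' Surrogate-testing configuration
#'
#' @param n_iterations IAAFT iteration count. Default 50.
#' @param n_surrogates Number of surrogate series per original. Default 10.
#' @param seed Seed for the surrogate generator. Default 1.
#' @return A list of class `surrogate_config`.
#' @export
surrogate_config <- function(n_iterations = 50, n_surrogates = 10, seed = 1L) {
  stopifnot(n_iterations >= 1, n_surrogates >= 1)
  structure(list(n_iterations = as.integer(n_iterations),
                 n_surrogates = as.integer(n_surrogates),
                 seed = as.integer(seed)),
            class = "surrogate_config")
}

#' IAAFT surrogate of a series
#'
#' Iterative amplitude-adjusted Fourier-transform surrogate: a randomised
#' series that keeps the original's amplitude distribution exactly and its
#' power spectrum approximately, realising the null hypothesis of a linear
#' Gaussian stochastic process observed through a static monotone
#' nonlinearity. Starting from a random permutation of the series, each
#' iteration (i) imposes the original amplitude spectrum in the Fourier
#' domain while keeping the current phases, then (ii) rank-remaps the
#' result onto the original's sorted values. The final step is the
#' amplitude remap, so `sort(surrogate)` equals `sort(original)`
#' element-wise exactly.
#'
#' @param series Numeric vector, length >= 16, finite, non-constant.
#' @param n_iterations Number of iterations. Default 50 (no early stop).
#' @param seed Optional seed; if supplied, the result is reproducible
#'   independently of the session RNG state.
#' @return A numeric surrogate series of the same length.
#' @export
iaaft <- function(series, n_iterations = 50, seed = NULL) {
  n <- length(series)
  if (n < 16) stop("series too short for IAAFT (need >= 16 samples)",
                   call. = FALSE)
  if (!all(is.finite(series))) stop("series must be finite", call. = FALSE)
  if (stats::sd(series) < .Machine$double.eps)
    stop("constant series: IAAFT surrogate undefined", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  target_amp <- Mod(stats::fft(series))
  sorted_vals <- sort(series)
  s <- sample(series)
  for (it in seq_len(n_iterations)) {
    ph <- Arg(stats::fft(s))
    s <- Re(stats::fft(complex(modulus = target_amp, argument = ph),
                       inverse = TRUE)) / n
    s <- sorted_vals[rank(s, ties.method = "first")]
  }
  s
}

# internal: paired t summary of surrogate-minus-original differences.
# t > 0 means the surrogates score higher than the originals. Zero-variance
# differences are flagged degenerate (t = 0, p = 1 when all differences are
# zero; otherwise t undefined, reported NA).
paired_t <- function(original, surrogate) {
  d <- surrogate - original
  n <- length(d)
  if (stats::sd(d) < .Machine$double.eps) {
    if (all(d == 0)) return(list(t = 0, p = 1, degenerate = TRUE))
    return(list(t = NA_real_, p = NA_real_, degenerate = TRUE))
  }
  tt <- stats::t.test(surrogate, original, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value, degenerate = FALSE)
}

#' Surrogate test of nonlinear determinism
#'
#' For each epoch, compares a metric (sample entropy per eye, or bilateral
#' transfer entropy) on the original series against the mean of the same
#' metric over `n_surrogates` IAAFT surrogates, then runs a two-tailed
#' paired t-test across epochs. A significant result with surrogate values
#' exceeding the originals indicates that the original dynamics contain
#' nonlinear deterministic structure the surrogates destroyed. For sample
#' entropy, left and right eyes are tested separately (two result rows);
#' for transfer entropy the left and right surrogates are generated
#' independently (destroying cross-dependence as well as nonlinearity) and
#' one pooled bilateral test is reported.
#'
#' @param epochs List of `pupil_epoch` objects (or lists with `left` and
#'   `right` series).
#' @param metric `"sampen"` or `"tranen"`.
#' @param cfg A [surrogate_config()].
#' @param metric_params A [sampen_params()] or [tranen_params()] matching
#'   the metric; defaults to the metric's defaults.
#' @return A data.frame of class `surrogate_test_result` with one row per
#'   test (`eye` is `"left"`/`"right"` or `"bilateral"`): mean and SD of
#'   the original and surrogate metric across epochs, the paired t and p
#'   values (t > 0 when surrogates are higher), `n_epochs`, and a
#'   `degenerate` flag.
#' @export
surrogate_metric_test <- function(epochs, metric = c("sampen", "tranen"),
                                  cfg = surrogate_config(),
                                  metric_params = NULL) {
  metric <- match.arg(metric)
  stopifnot(inherits(cfg, "surrogate_config"), length(epochs) >= 2)
  if (is.null(metric_params))
    metric_params <- if (metric == "sampen") sampen_params() else tranen_params()
  set.seed(cfg$seed)

  metric_fun <- function(l, r) {
    if (metric == "sampen")
      c(left = sample_entropy(l, metric_params)$value,
        right = sample_entropy(r, metric_params)$value)
    else
      c(bilateral = bilateral_symmetricity(list(left = l, right = r),
                                           metric_params)$te_mean)
  }

  orig <- list(); surr <- list()
  dropped <- 0L
  for (e in epochs) {
    res <- tryCatch({
      o <- metric_fun(e$left, e$right)
      sv <- replicate(cfg$n_surrogates, {
        metric_fun(iaaft(e$left, cfg$n_iterations),
                   iaaft(e$right, cfg$n_iterations))
      })
      sm <- if (is.matrix(sv)) rowMeans(sv) else c(bilateral = mean(sv))
      if (any(!is.finite(o)) || any(!is.finite(sm))) stop("undefined metric")
      list(o = o, s = sm)
    }, error = function(err) NULL)
    if (is.null(res)) { dropped <- dropped + 1L; next }
    orig[[length(orig) + 1L]] <- res$o
    surr[[length(surr) + 1L]] <- res$s
  }
  if (dropped > 0)
    warning(sprintf("%d epoch(s) dropped: metric undefined", dropped))
  if (length(orig) < 2)
    stop("fewer than 2 epochs with a defined metric", call. = FALSE)
  om <- do.call(rbind, orig)
  sm <- do.call(rbind, surr)

  rows <- lapply(colnames(om), function(side) {
    tt <- paired_t(om[, side], sm[, side])
    data.frame(eye = side,
               mean_original = mean(om[, side]),
               sd_original = stats::sd(om[, side]),
               mean_surrogate = mean(sm[, side]),
               sd_surrogate = stats::sd(sm[, side]),
               t_value = tt$t, p_value = tt$p,
               n_epochs = nrow(om), degenerate = tt$degenerate)
  })
  out <- do.call(rbind, rows)
  attr(out, "metric") <- metric
  class(out) <- c("surrogate_test_result", "data.frame")
  out
}

#' @export
print.surrogate_test_result <- function(x, ...) {
  cat(sprintf("Surrogate test (%s), %d epochs:\n", attr(x, "metric"),
              x$n_epochs[1]))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-9s original %.3f (%.3f)  surrogate %.3f (%.3f)  t = %.2f (p = %.3g)\n",
                x$eye[i], x$mean_original[i], x$sd_original[i],
                x$mean_surrogate[i], x$sd_surrogate[i],
                x$t_value[i], x$p_value[i]))
  invisible(x)
}
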