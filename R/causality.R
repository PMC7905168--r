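#' Transfer-entropy parameters
#'
#' Settings for [transfer_entropy()]: the embedding delay `tau` (in samples;
#' 10 samples is 0.033 s at 300 Hz), source and target embedding dimensions
#' `dx` and `dy`, and the probability estimator. The k-nearest-neighbour
#' estimator (Kraskov-style conditional mutual information, Chebyshev
#' metric) is the default: with a few hundred usable points in an
#' 11-dimensional joint space it is the only statistically viable choice.
#' The equiquantal binned estimator is exact on low-dimensional discrete
#' problems and serves as a cross-check.
#'
#' @param tau Delay in samples, >= 1. Default 10.
#' @param dx,dy Source/target embedding dimensions, >= 1. Default 5.
#' @param estimator `"knn"` or `"binned"`.
#' @param k Neighbour count for the knn estimator. Default 4.
#' @param bins Per-dimension bin count for the binned estimator. Default 4.
#' @return A list of class `tranen_params`.
#' @export
tranen_params <- function(tau = 10, dx = 5, dy = 5,
                          estimator = c("knn", "binned"),
                          k = 4, bins = 4) {
  estimator <- match.arg(estimator)
  stopifnot(tau >= 1, dx >= 1, dy >= 1, k >= 1, bins >= 2)
  structure(list(tau = as.integer(tau), dx = as.integer(dx),
                 dy = as.integer(dy), estimator = estimator,
                 k = as.integer(k), bins = as.integer(bins)),
            class = "tranen_params")
}

#' Delay embedding of a series
#'
#' The delay vector at time `t` is
#' \eqn{(x_t, x_{t-\tau}, \dots, x_{t-(d-1)\tau})}; valid `t` run from
#' `(d-1)*tau + 1` to `N` (1-based).
#'
#' @param series Numeric vector.
#' @param d Embedding dimension.
#' @param tau Delay in samples.
#' @return A matrix with one delay vector per row and attribute `t_index`
#'   giving the time index of each row.
#' @export
delay_embed <- function(series, d, tau) {
  n <- length(series)
  t0 <- (d - 1) * tau + 1
  if (n < t0) stop("series too short for delay embedding", call. = FALSE)
  t_idx <- t0:n
  out <- matrix(0, nrow = length(t_idx), ncol = d)
  for (l in seq_len(d)) out[, l] <- series[t_idx - (l - 1L) * tau]
  attr(out, "t_index") <- t_idx
  out
}

# internal: equiquantal integer codes; series with few unique values keep
# their own values as categories (exact on finite alphabets)
equiquantal_codes <- function(x, bins) {
  ux <- unique(x)
  if (length(ux) <= bins) return(match(x, sort(ux)))
  qs <- stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                        names = FALSE, type = 8)
  qs <- unique(qs)
  findInterval(x, qs[-c(1, length(qs))]) + 1L
}

# internal: plug-in conditional mutual information I(y; x | z) in nats from
# integer code matrices/vectors
discrete_cmi <- function(y, xcodes, zcodes) {
  key <- function(m) apply(m, 1, paste, collapse = "\r")
  zk <- key(as.matrix(zcodes))
  xk <- key(as.matrix(xcodes))
  yk <- as.character(y)
  n <- length(yk)
  p_xyz <- table(paste(yk, xk, zk, sep = "\n")) / n
  p_yz <- table(paste(yk, zk, sep = "\n")) / n
  p_xz <- table(paste(xk, zk, sep = "\n")) / n
  p_z <- table(zk) / n
  # iterate over observed joint cells
  cells <- strsplit(names(p_xyz), "\n", fixed = TRUE)
  val <- 0
  for (i in seq_along(p_xyz)) {
    cl <- cells[[i]]
    pj <- as.numeric(p_xyz[i])
    py_z <- as.numeric(p_yz[paste(cl[1], cl[3], sep = "\n")])
    px_z <- as.numeric(p_xz[paste(cl[2], cl[3], sep = "\n")])
    pz <- as.numeric(p_z[cl[3]])
    val <- val + pj * log(pj * pz / (py_z * px_z))
  }
  val
}

#' Transfer entropy between two series
#'
#' Estimates the directed information flow \eqn{T_{X \to Y}}: the reduction
#' in uncertainty about \eqn{y_{t+\tau}} given the delay-embedded past of
#' `x`, beyond what `y`'s own past provides — the conditional mutual
#' information \eqn{I(y_{t+\tau}; x_t^{d_x} \mid y_t^{d_y})} over all valid
#' `t`. Both series are used as given (z-score upstream if scale invariance
#' is wanted; the knn estimator itself is invariant to monotone affine maps
#' of either input).
#'
#' The knn estimator can return small negative values by finite-sample
#' bias; they are reported as-is, not clipped, because clipping would bias
#' downstream surrogate comparisons. Exactly tied coordinates (possible on
#' interpolated flat segments) are broken with a seeded uniform jitter of
#' `1e-10` SD before the neighbour search.
#'
#' @param x Source series.
#' @param y Target series (same length as `x`).
#' @param params A [tranen_params()] object.
#' @return Transfer entropy in nats (a single number) with attribute
#'   `n_samples`, the count of valid embedded time points.
#' @export
transfer_entropy <- function(x, y, params = tranen_params()) {
  stopifnot(inherits(params, "tranen_params"))
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  n <- length(x)
  tau <- params$tau
  t0 <- (max(params$dx, params$dy) - 1L) * tau + 1L
  if (n < t0 + tau) stop("series too short for embedding plus tau-ahead target",
                         call. = FALSE)
  # valid t: both embeddings defined and y_{t+tau} observed
  t_valid <- t0:(n - tau)
  xe <- delay_embed(x, params$dx, tau)
  ye <- delay_embed(y, params$dy, tau)
  xe <- xe[match(t_valid, attr(xe, "t_index")), , drop = FALSE]
  ye <- ye[match(t_valid, attr(ye, "t_index")), , drop = FALSE]
  yf <- y[t_valid + tau]

  te <- if (params$estimator == "knn") {
    sx <- stats::sd(x); sy <- stats::sd(y)
    if (sx < .Machine$double.eps || sy < .Machine$double.eps)
      stop("constant series: knn transfer entropy undefined", call. = FALSE)
    # break exact ties (e.g. interpolated flat segments) with a seeded
    # sub-resolution jitter; untied data are left untouched so degenerate
    # cases (x identical to y) stay exact
    if (anyDuplicated(x) || anyDuplicated(y)) {
      jit <- function(m, s) m + matrix(runif(length(m), 0, 1e-10 * s), nrow(m))
      xe <- jit(xe, sx); ye <- jit(ye, sy)
      yf <- yf + runif(length(yf), 0, 1e-10 * sy)
    }
    cpp_cmi_knn(yf, xe, ye, params$k)
  } else {
    yb <- equiquantal_codes(yf, params$bins)
    xb <- apply(xe, 2, equiquantal_codes, bins = params$bins)
    zb <- apply(ye, 2, equiquantal_codes, bins = params$bins)
    discrete_cmi(yb, xb, zb)
  }
  structure(te, n_samples = length(t_valid))
}

#' Bilateral transfer-entropy symmetricity of an epoch
#'
#' Computes transfer entropy in both directions between the z-scored left
#' and right pupil series of an epoch and reports their average, the
#' per-epoch symmetricity measure. High values indicate strong mutual
#' left-right information flow (symmetric behaviour); values near zero
#' indicate asymmetry.
#'
#' @param epoch A `pupil_epoch` (see [segment_epochs()]) or any list with
#'   numeric `left` and `right` elements.
#' @param params A [tranen_params()] object.
#' @return A list of class `causality_result` with `te_lr`, `te_rl`,
#'   `te_mean` (nats) and `n_samples`.
#' @export
bilateral_symmetricity <- function(epoch, params = tranen_params()) {
  l <- zscore(epoch$left)
  r <- zscore(epoch$right)
  te_lr <- transfer_entropy(l, r, params)
  te_rl <- transfer_entropy(r, l, params)
  structure(list(te_lr = as.numeric(te_lr), te_rl = as.numeric(te_rl),
                 te_mean = (as.numeric(te_lr) + as.numeric(te_rl)) / 2,
                 n_samples = attr(te_lr, "n_samples")),
            class = "causality_result")
}

#' @export
print.causality_result <- function(x, ...) {
  cat(sprintf("TranEn L->R: %.4f  R->L: %.4f  mean: %.4f nats (n = %d)\n",
              x$te_lr, x$te_rl, x$te_mean, x$n_samples))
  invisible(x)
}
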