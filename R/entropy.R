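#' Sample-entropy parameters
#'
#' Bundle the embedding dimension `m` and the tolerance `r` used by
#' [sample_entropy()]. The tolerance is expressed in units of the standard
#' deviation of the z-scored series, so the default tolerance of 0.2 means
#' 0.2 SD exactly.
#'
#' @param m Embedding (template) length, an integer >= 1. Default 2.
#' @param r Match tolerance in SD units, > 0. Default 0.2.
#' @return A list of class `sampen_params`.
#' @export
sampen_params <- function(m = 2, r = 0.2) {
  stopifnot(is.numeric(m), length(m) == 1, m >= 1, m == round(m))
  stopifnot(is.numeric(r), length(r) == 1, r > 0)
  structure(list(m = as.integer(m), r = r), class = "sampen_params")
}

#' Overlapping embedding windows of a series
#'
#' Build the `N - m + 1` overlapping length-`m` windows
#' \eqn{x_i^m = (x_i, \dots, x_{i+m-1})} of a series, the template vectors
#' that sample entropy counts matches over.
#'
#' @param series Numeric vector of length `N >= m`.
#' @param m Window length.
#' @return A `(N - m + 1) x m` numeric matrix, one window per row.
#' @export
embed_series <- function(series, m) {
  n <- length(series)
  if (n < m) stop("series shorter than embedding dimension m", call. = FALSE)
  idx <- seq_len(n - m + 1)
  out <- matrix(0, nrow = length(idx), ncol = m)
  for (l in seq_len(m)) out[, l] <- series[idx + l - 1L]
  out
}

#' Sample entropy of a finite series
#'
#' Sample entropy (SampEn) is the negative log conditional probability that
#' two length-`m` templates matching within tolerance `r` (Chebyshev norm,
#' strict inequality) still match when extended to length `m + 1`. The series
#' is z-scored first, so the result is invariant to affine rescaling and `r`
#' is in SD units. Template pairs for both lengths run over the same index
#' range `1..N-m` (the standard Richman-Moorman convention), which makes
#' the ratio a valid conditional probability;
#' the raw ordered-pair match counts are returned so other normalisations
#' remain recoverable. The result is in nats.
#'
#' Perfectly periodic series give 0 (every m-match extends); white noise
#' scores high. A series with no m-matches at all has undefined entropy
#' (error); m-matches but no (m+1)-matches yields `Inf` with
#' `undefined = TRUE`.
#'
#' @param series Numeric vector, length >= m + 2, non-constant.
#' @param params A [sampen_params()] object.
#' @return A list of class `entropy_result` with elements `value` (nats),
#'   `n_matches_m`, `n_matches_m1` (ordered-pair counts), `N`, and
#'   `undefined`.
#' @export
sample_entropy <- function(series, params = sampen_params()) {
  stopifnot(inherits(params, "sampen_params"))
  n <- length(series)
  if (n < params$m + 2) stop("series too short for sample entropy", call. = FALSE)
  z <- zscore(series)
  counts <- cpp_sampen_counts(z, params$m, params$r)
  b <- counts[1]; a <- counts[2]
  if (b == 0)
    stop("no template matches at length m; sample entropy undefined",
         call. = FALSE)
  undefined <- a == 0
  value <- if (undefined) Inf else -log(a / b)
  structure(list(value = value, n_matches_m = b, n_matches_m1 = a,
                 N = n, undefined = undefined),
            class = "entropy_result")
}

#' @export
print.entropy_result <- function(x, ...) {
  cat(sprintf("SampEn: %.4f nats (N = %d, m-matches = %d, m+1-matches = %d)\n",
              x$value, x$N, x$n_matches_m, x$n_matches_m1))
  invisible(x)
}
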