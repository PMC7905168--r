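test_that("delay embedding lags and aligns correctly", {
  e <- delay_embed(1:10, d = 2, tau = 3)
  expect_equal(nrow(e), 7)
  expect_equal(attr(e, "t_index"), 4:10)
  expect_equal(e[1, ], c(4, 1))
  expect_equal(e[7, ], c(10, 7))
  x <- rnorm(30)
  expect_equal(as.numeric(delay_embed(x, 1, 5)), x)
  # default pupil settings: 560 embedded points, 550 usable triples
  expect_equal(nrow(delay_embed(rnorm(600), 5, 10)), 560)
  te <- transfer_entropy(rnorm(600), rnorm(600))
  expect_equal(attr(te, "n_samples"), 550)
  expect_error(delay_embed(1:5, d = 3, tau = 10), "short")
})

test_that("transfer entropy vanishes for identical and for independent series", {
  set.seed(11)
  x <- as.numeric(stats::filter(rnorm(600), c(1.2, -0.4), method = "recursive"))
  x <- (x - mean(x)) / sd(x)
  expect_lt(abs(as.numeric(transfer_entropy(x, x))), 0.02)
  vals <- vapply(1:10, function(s) {
    set.seed(100 + s)
    as.numeric(transfer_entropy(rnorm(600), rnorm(600)))
  }, 1)
  expect_true(all(abs(vals) < 0.1))
  expect_lt(mean(abs(vals)), 0.05)
})

test_that("binned estimator matches exact enumeration on a discrete Markov pair", {
  p1 <- matrix(c(0.2, 0.8,   # P(y'=1 | x=0, y=0), P(y'=1 | x=1, y=0)
                 0.3, 0.9),  # P(y'=1 | x=0, y=1), P(y'=1 | x=1, y=1)
               nrow = 2, byrow = FALSE)
  te_true <- markov_te_exact(p1)
  expect_gt(te_true, 0.05) # a substantial coupling, not a degenerate check
  sim <- simulate_markov_pair(50000, p1, seed = 21)
  p <- tranen_params(tau = 1, dx = 1, dy = 1, estimator = "binned")
  te_hat <- as.numeric(transfer_entropy(sim$x, sim$y, p))
  expect_equal(te_hat, te_true, tolerance = 0.05 * te_true)
})

test_that("binned estimator equals the plug-in sum over observed cells", {
  set.seed(3)
  x <- rbinom(400, 1, 0.5)
  y <- rbinom(400, 1, 0.5)
  p <- tranen_params(tau = 1, dx = 1, dy = 1, estimator = "binned")
  te <- as.numeric(transfer_entropy(x, y, p))
  # independent re-derivation: empirical plug-in CMI over the 8 outcomes
  yf <- y[2:400]; xs <- x[1:399]; yp <- y[1:399]
  n <- length(yf)
  ref <- 0
  for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
    pj <- sum(yf == a & xs == b & yp == cc) / n
    if (pj == 0) next
    ref <- ref + pj * log(pj * (sum(yp == cc) / n) /
                            ((sum(yf == a & yp == cc) / n) *
                             (sum(xs == b & yp == cc) / n)))
  }
  expect_equal(te, ref, tolerance = 1e-10)
})

test_that("unidirectional coupling is detected in the driven direction", {
  p <- tranen_params(tau = 1, dx = 1, dy = 1)
  hits <- 0
  n_seeds <- 25
  for (s in 1:n_seeds) {
    set.seed(400 + s)
    x <- rnorm(600)
    y <- numeric(600)
    for (t in 1:599) y[t + 1] <- 0.5 * y[t] + 0.5 * x[t] + rnorm(1, sd = 0.5)
    te_xy <- as.numeric(transfer_entropy(x, y, p))
    te_yx <- as.numeric(transfer_entropy(y, x, p))
    if (te_xy > te_yx) hits <- hits + 1
  }
  expect_gte(hits, n_seeds - 2)
})

test_that("the direction-averaged measure is symmetric and affine-invariant", {
  set.seed(5)
  l <- as.numeric(stats::filter(rnorm(600), 0.9, method = "recursive"))
  r <- as.numeric(stats::filter(rnorm(600), 0.9, method = "recursive")) +
    0.3 * l
  set.seed(77); a <- bilateral_symmetricity(list(left = l, right = r))
  set.seed(77); b <- bilateral_symmetricity(list(left = r, right = l))
  expect_equal(a$te_mean, b$te_mean, tolerance = 1e-9)
  # z-scoring makes the measure invariant to affine maps of either eye
  set.seed(77); c1 <- bilateral_symmetricity(list(left = 3 * l + 7, right = r))
  expect_equal(c1$te_mean, a$te_mean, tolerance = 1e-9)
  expect_equal(a$te_mean, (a$te_lr + a$te_rl) / 2)
})

test_that("identical eyes give near-zero bilateral symmetricity", {
  set.seed(9)
  x <- as.numeric(stats::filter(rnorm(600), c(1.2, -0.4), method = "recursive"))
  res <- bilateral_symmetricity(list(left = x, right = x))
  expect_lt(abs(res$te_mean), 0.02)
})

test_that("invalid transfer-entropy inputs are rejected", {
  expect_error(transfer_entropy(rnorm(100), rnorm(99)), "equal length")
  expect_error(transfer_entropy(rnorm(30), rnorm(30)), "short")
  expect_error(transfer_entropy(rep(1, 600), rnorm(600)), "constant")
})
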