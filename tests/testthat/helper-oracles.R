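# Independent oracles and shared fixtures for the test suite.

# Brute-force sample entropy: direct nested-loop pair counting over the
# z-scored series, templates i, j in 1..N-m for both lengths, Chebyshev
# norm, strict < r. Independent of the package's compiled path.
brute_sampen <- function(x, m = 2, r = 0.2) {
  z <- (x - mean(x)) / sd(x)
  n <- length(z)
  nt <- n - m
  b <- 0; a <- 0
  for (i in 1:(nt - 1)) {
    for (j in (i + 1):nt) {
      dm <- max(abs(z[i:(i + m - 1)] - z[j:(j + m - 1)]))
      if (dm < r) {
        b <- b + 1
        if (abs(z[i + m] - z[j + m]) < r) a <- a + 1
      }
    }
  }
  -log(a / b)
}

# Two-state Markov pair: x iid Bernoulli(0.5); y' depends on (x, y) through
# p1[x+1, y+1] = P(y' = 1 | x, y). Returns a length-n realisation.
simulate_markov_pair <- function(n, p1, seed) {
  set.seed(seed)
  x <- rbinom(n, 1, 0.5)
  y <- integer(n)
  y[1] <- rbinom(1, 1, 0.5)
  for (t in 1:(n - 1))
    y[t + 1] <- rbinom(1, 1, p1[x[t] + 1, y[t] + 1])
  list(x = x, y = y)
}

# Exact transfer entropy T_{x->y} (tau = 1, dx = dy = 1) for the chain
# above, by enumeration over the stationary joint distribution of (x, y).
markov_te_exact <- function(p1) {
  # transition on the joint state (x, y): x' iid, y' | (x, y)
  states <- expand.grid(x = 0:1, y = 0:1)
  P <- matrix(0, 4, 4)
  for (s in 1:4) for (sp in 1:4) {
    py1 <- p1[states$x[s] + 1, states$y[s] + 1]
    py <- if (states$y[sp] == 1) py1 else 1 - py1
    P[s, sp] <- 0.5 * py
  }
  pi_s <- rep(0.25, 4)
  for (it in 1:2000) pi_s <- as.numeric(pi_s %*% P)
  # T = sum_{x,y} pi(x,y) sum_{y'} p(y'|x,y) log( p(y'|x,y) / p(y'|y) )
  te <- 0
  for (yv in 0:1) {
    piy <- sum(pi_s[states$y == yv])
    for (yp in 0:1) {
      # p(y'|y) = sum_x pi(x|y) p(y'|x,y)
      pyp_y <- 0
      for (xv in 0:1) {
        s <- which(states$x == xv & states$y == yv)
        pyp_y <- pyp_y + pi_s[s] / piy *
          (if (yp == 1) p1[xv + 1, yv + 1] else 1 - p1[xv + 1, yv + 1])
      }
      for (xv in 0:1) {
        s <- which(states$x == xv & states$y == yv)
        pc <- if (yp == 1) p1[xv + 1, yv + 1] else 1 - p1[xv + 1, yv + 1]
        if (pc > 0) te <- te + pi_s[s] * pc * log(pc / pyp_y)
      }
    }
  }
  te
}

# Preprocessed epochs from a synthetic recording of the requested source.
make_epochs <- function(source, seed, duration_s = 30,
                        cfg_extra = list()) {
  cfg <- do.call(synth_config, c(list(n_recordings = 1,
                                      duration_s = duration_s,
                                      hippus_source = source,
                                      seed = seed), cfg_extra))
  rec <- generate_recording(cfg, seed = seed)$recording
  pre <- preprocess_config()
  lapply(segment_epochs(rec, pre), lowpass_epoch, cfg = pre)
}

# Cached full-scale baseline sweeps shared by the acceptance tests (the
# Lorenz trajectory and each condition's sweep are deterministic, so they
# are computed once per test run).
.sweep_cache <- new.env(parent = emptyenv())

acceptance_sweep <- function(w_c, beta) {
  key <- sprintf("wc%g_beta%g", w_c, beta)
  if (is.null(.sweep_cache[[key]])) {
    if (is.null(.sweep_cache$traj))
      .sweep_cache$traj <- integrate_coupled_lorenz()
    .sweep_cache[[key]] <- sweep_baseline(seq(3, 7, by = 0.1),
                                          w_c = w_c, beta = beta,
                                          seed = 1L,
                                          trajectory = .sweep_cache$traj)
  }
  .sweep_cache[[key]]
}
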