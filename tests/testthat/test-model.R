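test_that("strong inter-LC coupling synchronises the Lorenz pair", {
  traj <- integrate_coupled_lorenz(lorenz_params(J = 50), t_end = 60)
  late <- traj$t >= 30
  expect_lt(max(abs(traj$X1[late] - traj$X2[late])), 1e-3)
})

test_that("uncoupled chaotic trajectories decorrelate", {
  traj <- integrate_coupled_lorenz(lorenz_params(J = 0))
  keep <- traj$t >= 10
  expect_lt(abs(cor(traj$X1[keep], traj$X2[keep])), 0.1)
})

test_that("swapping the sides' initial conditions swaps the output traces", {
  p1 <- lorenz_params()
  p2 <- lorenz_params(init1 = p1$init2, init2 = p1$init1)
  a <- integrate_coupled_lorenz(p1, t_end = 20)
  b <- integrate_coupled_lorenz(p2, t_end = 20)
  expect_identical(a$X1, b$X2)
  expect_identical(a$Z2, b$Z1)
})

test_that("a divergent integration is reported with its time", {
  expect_error(integrate_coupled_lorenz(lorenz_params(), t_end = 10, dt = 0.5,
                                        sample_dt = 0.5),
               "diverged at t")
})

test_that("LC activity has exactly the configured mean and SD", {
  traj <- integrate_coupled_lorenz(t_end = 60)
  X <- traj$X1[traj$t >= 10]
  x <- lc_activity(X, L = 1.5, baseline_b = 4.8)
  expect_equal(mean(x), 4.8, tolerance = 1e-10)
  expect_equal(sd(x), 1.5, tolerance = 1e-10)
})

test_that("EWN output follows the shifted tanh and stays inside (0, 2)", {
  p <- pathway_params(w_ipsi = 0.3, w_c = 0.15, beta = 2)
  expect_equal(ewn_output(0, 0, pathway_params(beta = 0)), 1.0)
  expect_equal(ewn_output(c(2, 4), c(3, 5), p),
               tanh(-0.3 * c(2, 4) - 0.15 * c(3, 5) + 2) + 1)
  expect_lt(ewn_output(1e3, 1e3, p), 1e-6)       # strong LC inhibition
  expect_gt(ewn_output(0, 0, pathway_params(beta = 1e3)), 2 - 1e-6)
  sim <- simulate_pupil_model(pathway_params(baseline_b = 4.8), t_end = 60,
                              t_analysis = c(10, 60))
  expect_true(all(sim$S > 0 & sim$S < 2))
})

test_that("pupil diameter combines dilator and sphincter drives linearly", {
  p <- pathway_params(s = 0.3, P0 = 3.0)
  out <- pupil_output(0, 1, p)
  expect_equal(out$P, 2.0)
  # D identical to S cancels to the base diameter
  x <- rnorm(50)
  S <- p$s * x
  expect_equal(pupil_output(x, S, p)$P, rep(3.0, 50))
  # the sympathetic arm scales proportionally with s
  x <- rnorm(100) + 5
  Sfix <- rep(1, 100)
  p1 <- pathway_params(s = 0.3); p2 <- pathway_params(s = 0.6)
  d1 <- pupil_output(x, Sfix, p1)$P - (-Sfix + p1$P0)
  d2 <- pupil_output(x, Sfix, p2)$P - (-Sfix + p2$P0)
  expect_equal(d2, 2 * d1)
})

test_that("sphincter variability peaks at intermediate baseline activity", {
  traj <- integrate_coupled_lorenz()
  sims <- lapply(c(1.5, 4.8, 9), function(b)
    simulate_pupil_model(pathway_params(baseline_b = b), trajectory = traj))
  sds <- vapply(sims, function(s) sd(s$S[, 1]), 1)
  means <- vapply(sims, function(s) mean(s$S[, 1]), 1)
  expect_gt(sds[2], sds[1])   # saturated near 2 at small b
  expect_gt(sds[2], sds[3])
  expect_gt(means[1], 1.8)    # small b: output saturated high
  expect_lt(means[3], 0.2)    # large b: output driven to zero
})

test_that("baseline sweeps carry aligned metric profiles and their condition", {
  traj <- integrate_coupled_lorenz()
  sw <- sweep_baseline(c(4.5, 4.8), w_c = 0.15, beta = 2, trajectory = traj)
  expect_s3_class(sw, "sweep_result")
  expect_equal(sw$b, c(4.5, 4.8))
  expect_true(all(is.finite(sw$sampen_left)))
  expect_true(all(is.finite(sw$tranen_mean)))
  expect_equal(attr(sw, "w_c"), 0.15)
  # deterministic given the configuration
  sw2 <- sweep_baseline(c(4.5, 4.8), w_c = 0.15, beta = 2, trajectory = traj)
  expect_identical(sw$sampen_left, sw2$sampen_left)
  expect_identical(sw$tranen_mean, sw2$tranen_mean)
})
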