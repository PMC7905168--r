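make_csv <- function(df) {
  f <- tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE, na = "NaN")
  f
}

test_that("read_recording parses a recording and flags missing samples", {
  fs <- 300
  n <- 1500
  t <- (0:(n - 1)) / fs
  left <- rep(4, n); right <- rep(5, n)
  gap <- 201:350 # a 150-sample blink
  left[gap] <- NA; right[gap] <- NA
  rec <- read_recording(make_csv(data.frame(time = t, left, right)), fs)
  expect_s3_class(rec, "pupil_recording")
  expect_length(rec$left, n)
  expect_identical(which(rec$missing_left), gap)
  expect_identical(which(rec$missing_right), gap)
  # non-positive diameters are treated as track loss
  left2 <- rep(4, n); left2[10] <- 0; left2[11] <- -1
  rec2 <- read_recording(make_csv(data.frame(time = t, left = left2, right)), fs)
  expect_true(all(rec2$missing_left[10:11]))
  expect_true(is.na(rec2$left[10]))
})

test_that("a two-minute 300 Hz file yields 36,000 samples per eye", {
  g <- generate_recording(synth_config(duration_s = 120, fs = 300,
                                       hippus_source = "linear_ar"),
                          seed = 3)
  f <- tempfile(fileext = ".csv")
  write_recording(g$recording, f)
  rec <- read_recording(f, 300)
  expect_length(rec$left, 36000)
  expect_length(rec$right, 36000)
})

test_that("malformed rows and non-uniform time grids are rejected", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("time,left,right", "0,4.0,4.1", "0.00333333333,4.x,4.1"), f)
  expect_error(read_recording(f, 300), "line 3")
  t <- (0:99) / 300
  t[50] <- t[50] + 1e-3
  expect_error(read_recording(make_csv(data.frame(time = t, left = 4,
                                                  right = 4)), 300),
               "uniform")
})

test_that("epochs are 600 samples at 2 s x 300 Hz, consecutive and non-overlapping", {
  g <- generate_recording(synth_config(duration_s = 21, fs = 300,
                                       hippus_source = "linear_ar",
                                       blink_rate_hz = 0), seed = 1)
  eps <- segment_epochs(g$recording, preprocess_config())
  expect_length(eps, 10) # trailing 1 s partial epoch discarded
  expect_true(all(vapply(eps, function(e) length(e$left), 1L) == 600))
  expect_identical(vapply(eps, function(e) e$index, 1L), 1:10)
  # epoch 2 is exactly samples 601:1200 of the recording
  expect_identical(eps[[2]]$left, g$recording$left[601:1200])
})

test_that("missing-fraction QC uses a strict 10% bound, per eye, pre-interpolation", {
  fs <- 300
  n <- 1200 # two epochs
  left <- rep(4, n) + sin(2 * pi * (1:n) / 300) * 0.1
  right <- rep(5, n) + cos(2 * pi * (1:n) / 300) * 0.1
  left[1:61] <- NA          # epoch 1: 61/600 = 10.17% -> excluded
  left[601:660] <- NA       # epoch 2: exactly 60/600 = 10% -> retained
  rec <- pupil_recording((0:(n - 1)) / fs, left, right, fs)
  eps <- segment_epochs(rec, preprocess_config())
  expect_length(eps, 1)
  expect_identical(eps[[1]]$index, 2L)
  qc <- attr(eps, "qc")
  expect_identical(qc$excluded, c(TRUE, FALSE))
  expect_equal(qc$missing_frac_left, c(61, 60) / 600)
  # one failing eye is enough to exclude
  right2 <- right; right2[601:700] <- NA
  eps2 <- segment_epochs(pupil_recording((0:(n - 1)) / fs, left, right2, fs),
                         preprocess_config())
  expect_length(eps2, 0)
})

test_that("gaps are linearly interpolated, ends filled with nearest values", {
  fs <- 3
  cfg <- preprocess_config(epoch_s = 1, max_missing_fraction = 0.7)
  rec <- pupil_recording((0:2) / fs, c(1, NA, 3), c(NA, 2, NA), fs)
  e <- segment_epochs(rec, cfg)[[1]]
  expect_equal(e$left, c(1, 2, 3))   # interior midpoint
  expect_equal(e$right, c(2, 2, 2))  # leading/trailing nearest fill
})

test_that("interpolation is idempotent on gap-free epochs", {
  g <- generate_recording(synth_config(duration_s = 4, fs = 300,
                                       hippus_source = "linear_ar",
                                       blink_rate_hz = 0), seed = 7)
  eps <- segment_epochs(g$recording, preprocess_config())
  expect_identical(eps[[1]]$left, g$recording$left[1:600])
})

test_that("lowering the missing tolerance never increases surviving epochs", {
  for (seed in 1:5) {
    g <- generate_recording(synth_config(duration_s = 30,
                                         hippus_source = "linear_ar",
                                         blink_rate_hz = 0.5), seed = seed)
    counts <- vapply(c(0.30, 0.20, 0.10, 0.05, 0.02), function(mmf)
      length(segment_epochs(g$recording,
                            preprocess_config(max_missing_fraction = mmf))),
      1L)
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("a recording shorter than one epoch yields no epochs, with a warning", {
  rec <- pupil_recording((0:299) / 300, rep(4, 300), rep(4, 300), 300)
  expect_warning(eps <- segment_epochs(rec, preprocess_config()), "shorter")
  expect_length(eps, 0)
})

make_epoch_from <- function(left, right = left, fs = 300) {
  n <- length(left)
  rec <- pupil_recording((0:(n - 1)) / fs, left, right, fs)
  segment_epochs(rec, preprocess_config(epoch_s = n / fs))[[1]]
}

test_that("low-pass filter passes the band, kills 120 Hz, and is zero-phase", {
  fs <- 300
  tt <- (0:599) / fs
  cfg <- preprocess_config()
  # 10 Hz tone: in the passband, attenuation < 1%
  e10 <- make_epoch_from(4 + sin(2 * pi * 10 * tt))
  f10 <- lowpass_epoch(e10, cfg)
  core <- 100:500 # away from epoch edges
  amp_ratio <- sd(f10$left[core] - mean(f10$left[core])) /
    sd(e10$left[core] - mean(e10$left[core]))
  expect_gt(amp_ratio, 0.99)
  # 120 Hz tone: attenuated by > 90%
  e120 <- make_epoch_from(4 + sin(2 * pi * 120 * tt))
  f120 <- lowpass_epoch(e120, cfg)
  expect_lt(sd(f120$left[core]) / sd(e120$left[core] - 4), 0.1)
  # constant series unchanged
  ec <- make_epoch_from(rep(4, 600))
  expect_equal(lowpass_epoch(ec, cfg)$left, rep(4, 600), tolerance = 1e-10)
  # mean preserved within 1%
  eg <- make_epoch_from(4 + cumsum(rnorm(600, sd = 0.01)))
  expect_equal(mean(lowpass_epoch(eg, cfg)$left), mean(eg$left),
               tolerance = 0.01)
  # zero-phase: a symmetric pulse filters to a symmetric output
  sym <- 4 + exp(-((1:599) - 300)^2 / 200) # symmetric about its center
  filt <- pupilkinetics:::zero_phase_lowpass(sym, fs, 50, 4)
  asym <- max(abs(filt - rev(filt))) / max(abs(filt))
  expect_lt(asym, 1e-8)
  # cutoff at or above Nyquist is a configuration error
  expect_error(lowpass_epoch(e10, preprocess_config(lowpass_hz = 150)),
               "Nyquist")
})

test_that("epoch baselines are temporal means and their average", {
  e <- make_epoch_from(rep(3, 600), rep(5, 600))
  b <- epoch_baseline(e)
  expect_equal(b$left, 3)
  expect_equal(b$right, 5)
  expect_equal(b$mean, 4)
  expect_equal(e$baseline_mean, 4)
  # generated epoch: baseline equals the direct summation oracle
  ep <- make_epochs("linear_ar", seed = 9, duration_s = 4)[[1]]
  expect_equal(epoch_baseline(ep)$left, sum(ep$left) / length(ep$left),
               tolerance = 1e-12)
})
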