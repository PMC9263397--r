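test_that("initial-volume discard keeps the right frames", {
  m <- matrix(seq_len(250 * 2), nrow = 250)
  b <- bold_from_matrix(m)
  out <- discard_initial(b, 10L)
  expect_equal(dim(out$data)[4], 240L)
  expect_equal(out$data[1, 1, 1, 1], m[11, 1])
  expect_identical(discard_initial(b, 0L), b)
  expect_error(discard_initial(b, 250L), class = "gfcmap_input_error")
  expect_equal(nrow(trim_motion(motion_trace(matrix(0, 250, 6)), 10)$params),
               240L)
})

test_that("motion QC applies strict 2 mm / 2 degree limits from frame 0", {
  zero <- motion_trace(matrix(0, 20, 6))
  expect_true(motion_qc(zero)$pass)

  p <- matrix(0, 20, 6); p[7, 2] <- 2.5
  qc <- motion_qc(motion_trace(p))
  expect_false(qc$pass)
  expect_equal(qc$offending_frames, 7L)

  # 0.0349 rad = 1.99949 degrees: inside the strict limit
  p <- matrix(0, 20, 6); p[5, 4] <- 0.0349
  expect_true(motion_qc(motion_trace(p))$pass)
  # exactly 2 degrees is still a pass (strict inequality)
  p[5, 4] <- 2 * pi / 180
  expect_true(motion_qc(motion_trace(p))$pass)
  p[5, 4] <- 2.0001 * pi / 180
  expect_false(motion_qc(motion_trace(p))$pass)
})

test_that("frame-wise displacement follows the 50 mm sphere formula", {
  const <- motion_trace(matrix(1, 30, 6))
  fd <- compute_fd(const)
  expect_equal(fd$fd, rep(0, 30))
  expect_equal(fd$mean_fd, 0)

  p <- matrix(0, 2, 6)
  p[2, 1:3] <- 0.1
  p[2, 4:6] <- 0.001
  fd <- compute_fd(motion_trace(p))
  expect_equal(fd$fd[2], 0.3 + 50 * 0.003, tolerance = 1e-12)
  expect_equal(fd$fd[1], 0)

  set.seed(1)
  p <- matrix(cumsum(rnorm(60 * 6, 0, 0.05)), 60, 6)
  fd1 <- compute_fd(motion_trace(p))
  fd2 <- compute_fd(motion_trace(p[sample(60), ]))
  expect_false(isTRUE(all.equal(fd1$fd, fd2$fd)))
  expect_error(compute_fd(motion_trace(p[1, , drop = FALSE])),
               class = "gfcmap_input_error")
})

test_that("linear detrending removes exact lines and is an idempotent projection", {
  nt <- 50
  tt <- seq_len(nt)
  m <- cbind(2 + 3 * tt, rnorm(nt))
  b <- bold_from_matrix(m)
  d1 <- detrend_linear(b)
  expect_lt(max(abs(d1$data[1, 1, 1, ])), 1e-9)
  for (v in 1:2) {
    r <- d1$data[v, 1, 1, ]
    expect_lt(abs(sum(r)), 1e-8)
    expect_lt(abs(sum(r * tt)), 1e-8)
  }
  d2 <- detrend_linear(d1)
  expect_equal(d2$data, d1$data, tolerance = 1e-12)
})

test_that("ideal band-pass keeps in-band tones and removes out-of-band power", {
  nt <- 250; tr <- 2  # 0.04 Hz and 0.2 Hz fall on exact FFT bins
  tt <- (seq_len(nt) - 1) * tr
  inband <- sin(2 * pi * 0.04 * tt)
  outband <- sin(2 * pi * 0.2 * tt)
  b <- bold_from_matrix(cbind(inband, outband), tr = tr)
  f <- bandpass(b)
  kept <- f$data[1, 1, 1, ]
  expect_lt(abs(max(abs(kept)) - max(abs(inband))) / max(abs(inband)), 0.05)
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(rms(f$data[2, 1, 1, ]) / rms(outband), 0.01)

  # spectrum strictly outside [0.01, 0.08] Hz is exactly zero
  set.seed(5)
  noise <- rnorm(nt)
  fn <- bandpass(bold_from_matrix(cbind(noise), tr = tr))
  spec <- Mod(fft(fn$data[1, 1, 1, ]))
  freq <- (seq_len(nt) - 1) / (nt * tr)
  freq <- pmin(freq, 1 / tr - freq)
  outside <- freq < 0.01 - 1e-9 | freq > 0.08 + 1e-9
  expect_lt(max(spec[outside]), 1e-8)

  expect_error(bandpass(b, 0.01, 0.3), class = "gfcmap_config_error")
})

test_that("Butterworth option attenuates out-of-band tones", {
  skip_if_not_installed("signal")
  nt <- 240; tr <- 2
  tt <- (seq_len(nt) - 1) * tr
  b <- bold_from_matrix(cbind(sin(2 * pi * 0.2 * tt)), tr = tr)
  f <- bandpass(b, method = "butterworth")
  expect_lt(sqrt(mean(f$data[1, 1, 1, ]^2)) / sqrt(0.5), 0.05)
})

test_that("Friston-24 expansion has the documented structure", {
  zero <- motion_trace(matrix(0, 25, 6))
  expect_true(all(friston24(zero) == 0))
  set.seed(2)
  m <- motion_trace(matrix(rnorm(25 * 6, 0, 0.1), 25, 6))
  X <- friston24(m)
  expect_equal(ncol(X), 24L)
  expect_equal(X[, 13:18], X[, 1:6]^2, ignore_attr = TRUE)
  expect_equal(X[, 19:24], X[, 7:12]^2, ignore_attr = TRUE)
  expect_equal(X[2:25, 7:12], m$params[1:24, ], ignore_attr = TRUE)
  expect_equal(X[1, 7:12], rep(0, 6), ignore_attr = TRUE)
})

test_that("compartment means are masked frame-wise averages", {
  arr <- array(rnorm(4 * 4 * 4 * 10), dim = c(4, 4, 4, 10))
  b <- bold4d(arr)
  single <- array(FALSE, dim = c(4, 4, 4)); single[2, 3, 1] <- TRUE
  expect_equal(extract_compartment_mean(b, single), arr[2, 3, 1, ])
  const <- bold4d(array(7, dim = c(4, 4, 4, 10)))
  full <- array(TRUE, dim = c(4, 4, 4))
  expect_equal(extract_compartment_mean(const, full), rep(7, 10))
  two <- array(FALSE, dim = c(4, 4, 4)); two[1, 1, 1] <- TRUE; two[4, 4, 4] <- TRUE
  expect_equal(extract_compartment_mean(b, two),
               (arr[1, 1, 1, ] + arr[4, 4, 4, ]) / 2)
  expect_error(extract_compartment_mean(b, array(FALSE, dim = c(4, 4, 4))),
               class = "gfcmap_input_error")
})

test_that("nuisance regression orthogonalizes against the design", {
  nt <- 40
  set.seed(3)
  X <- cbind(intercept = 1, a = rnorm(nt), b = rnorm(nt))
  m <- cbind(X[, "a"], rnorm(nt), rnorm(nt) + 5)
  b4 <- bold_from_matrix(m)
  out <- nuisance_regress(b4, X)
  expect_lt(max(abs(out$data[1, 1, 1, ])), 1e-10)
  for (v in 1:3) for (j in 1:3)
    expect_lt(abs(sum(out$data[v, 1, 1, ] * X[, j])), 1e-8)

  demean <- nuisance_regress(b4, matrix(1, nt, 1,
                                        dimnames = list(NULL, "intercept")))
  expect_equal(demean$data[3, 1, 1, ], m[, 3] - mean(m[, 3]),
               tolerance = 1e-12)

  Xbad <- cbind(intercept = 1, a = X[, "a"], dup = X[, "a"])
  expect_error(nuisance_regress(b4, Xbad), "dup")
})

test_that("the full chain preserves shape and produces no NaN", {
  cfg <- small_cohort_config(seed = 8, n_per_group = c(1L, 1L, 1L),
                             n_volumes = 40L)
  b <- generate_cohort(cfg)
  p <- preprocess_bold(b$images[[1]], b$motion[[1]], b$template,
                       n_discard = 5L)
  expect_equal(dim(p$bold$data), c(12, 12, 12, 35))
  expect_true(all(is.finite(p$bold$data)))
  expect_equal(nrow(p$motion$params), 35L)
  expect_equal(length(p$fd$fd), 35L)
  expect_equal(length(p$params$nuisance_columns), 27L)
})
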