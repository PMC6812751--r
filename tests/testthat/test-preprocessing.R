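test_that("rereference subtracts the mean of the reference channels", {
  chans <- c("TP9", "TP10", "Cz", "Oz")
  data <- array(0, c(2, 4, 10))
  data[, 1, ] <- 1; data[, 2, ] <- 3; data[, 3, ] <- 2; data[, 4, ] <- 7
  ep <- make_epochs(data, chans)
  out <- rereference(ep)
  expect_equal(unname(out$data[, "Cz", ]), matrix(0, 2, 10))
  expect_equal(unname(out$data[, "Oz", ]), matrix(5, 2, 10))
  # reference mean is zero everywhere after the operation
  expect_equal(unname((out$data[, "TP9", ] + out$data[, "TP10", ]) / 2),
               matrix(0, 2, 10))

  zero <- make_epochs(array(0, c(2, 4, 10)), chans)
  expect_equal(rereference(zero)$data, zero$data)

  expect_error(rereference(make_epochs(array(0, c(1, 2, 5)), c("A", "B"))),
               "missing reference")
})

test_that("artifact rejection uses a strict threshold and keeps content", {
  chans <- c("TP9", "TP10", "Cz")
  data <- array(0, c(4, 3, 20))
  data[2, 3, 7] <- 151    # removed: exceeds
  data[3, 2, 5] <- 150    # kept: boundary is not an excursion
  data[4, 1, 1] <- -151   # removed: negative excursion
  ep <- make_epochs(data, chans)
  res <- reject_artifacts(ep, 150)
  expect_equal(res$report$removed, 2)
  expect_equal(res$report$kept, 2)
  expect_equal(res$removed, c(2L, 4L))
  expect_false(res$report$all_removed)
  expect_equal(res$epochs$data, ep$data[c(1, 3), , , drop = FALSE])

  allz <- reject_artifacts(make_epochs(array(0, c(3, 3, 5)), chans), 150)
  expect_equal(allz$report$removed, 0)

  gone <- reject_artifacts(make_epochs(array(200, c(2, 3, 5)), chans), 150)
  expect_true(gone$report$all_removed)
})

test_that("rejection is permutation-invariant over trials", {
  set.seed(42)
  for (rep in 1:5) {
    data <- array(rnorm(10 * 3 * 30, sd = 80), c(10, 3, 30))
    ep <- make_epochs(data, c("A", "B", "C"))
    perm <- sample(10)
    ep_p <- make_epochs(data[perm, , , drop = FALSE], c("A", "B", "C"))
    r1 <- reject_artifacts(ep, 150)
    r2 <- reject_artifacts(ep_p, 150)
    expect_equal(r1$report$removed, r2$report$removed)
    # surviving trials identical as sets
    kept1 <- setdiff(seq_len(10), r1$removed)
    expect_setequal(perm[setdiff(seq_len(10), r2$removed)], kept1)
  }
})

test_that("low-pass filter is zero-phase and preserves DC", {
  const <- matrix(5, 1, 400)
  out <- lowpass(const, 25, 500)
  expect_equal(as.numeric(out), rep(5, 400), tolerance = 1e-9)

  tt <- seq_len(400)
  pulse <- exp(-((tt - 200)^2) / (2 * 15^2))
  filt <- lowpass(pulse, 25, 500)
  expect_equal(which.max(filt), 200)

  expect_error(lowpass(matrix(0, 1, 50), 25, 500), "too short")
  expect_error(lowpass(matrix(0, 1, 400), 300, 500), "Nyquist")
})

test_that("50 Hz attenuation matches the kernel's frequency response", {
  tt <- seq_len(2000)
  x <- sin(2 * pi * 50 * tt / 500)
  y <- lowpass(x, 25, 500)
  core <- 300:1700  # avoid edge effects
  att <- sqrt(mean(y[core]^2)) / sqrt(mean(x[core]^2))
  h <- fir_lowpass_kernel(25, 500)
  oracle <- fir_response(h, 50, 500)
  expect_gt(att / oracle, 0.8)
  expect_lt(att / oracle, 1.25)
  expect_lt(att, 0.01)   # deep stopband at twice the cutoff
  # passband is flat
  expect_equal(fir_response(h, c(0, 5, 10), 500), rep(1, 3), tolerance = 0.01)
})

test_that("baseline correction zeroes the window mean", {
  times <- seq(-100, 698, by = 2)
  x <- matrix(7, 2, length(times))
  out <- baseline_correct(x, times, c(-60, 40))
  expect_equal(out, matrix(0, 2, length(times)))

  set.seed(1)
  y <- matrix(rnorm(length(times)), 1, length(times))
  y1 <- baseline_correct(y, times, c(-60, 40))
  expect_equal(baseline_correct(y1, times, c(-60, 40)), y1)

  z <- ifelse(times >= -60 & times <= 40, 2, 5)
  z1 <- baseline_correct(z, times, c(-60, 40))
  expect_equal(unique(z1[times >= -60 & times <= 40]), 0)
  expect_equal(unique(z1[times > 40]), 3)

  expect_error(baseline_correct(y, times, c(-200, 40)), "outside")
})

test_that("ms/sample conversion rounds to the nearest sample", {
  expect_identical(ms_to_sample(20, 500, 0L), 10L)
  expect_identical(ms_to_sample(0, 123, 7L), 7L)
  for (t_ms in c(-100, -31, 0, 13, 250.4, 799)) {
    idx <- ms_to_sample(t_ms, 500, 51L)
    expect_lte(abs(sample_to_ms(idx, 500, 51L) - t_ms), 1)  # half a period = 1 ms
  }
  expect_error(ms_to_sample(900, 500, 51L, n_samples = 451), "outside")
})
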