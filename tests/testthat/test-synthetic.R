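test_that("noiseless forward model plants templates exactly", {
  fn <- component_template("FN", 160, 30, -5, c(Fz = 1))
  spec <- noiseless_spec(templates_shared = list(fn), n_trials = 3)
  eps <- generate_subject(spec, MONTAGE, 1)
  rev <- eps$passive.reversal; stab <- eps$passive.stability
  k <- which(rev$times == 160)
  expect_equal(unname(rev$data[, "Fz", k]), rep(-5, 3))
  expect_equal(unname(stab$data[, "Fz", k]), rep(0, 3))
  # topography weight 0 elsewhere
  expect_equal(max(abs(rev$data[, "Oz", ])), 0)
})

test_that("generation is deterministic under a fixed seed", {
  spec <- tiny_spec(seed = 11)
  a <- generate_subject(spec, MONTAGE, 2)
  b <- generate_subject(spec, MONTAGE, 2)
  expect_identical(a, b)
  spec2 <- tiny_spec(seed = 12)
  c <- generate_subject(spec2, MONTAGE, 2)
  expect_false(identical(a$passive.reversal$data, c$passive.reversal$data))
})

test_that("cohort emits one epoch set per subject x experiment x condition", {
  spec <- noiseless_spec(n_med = 12, n_ctl = 15, n_trials = 1)
  cohort <- generate_cohort(spec, MONTAGE)
  expect_length(cohort, 27)
  expect_true(all(vapply(cohort, length, integer(1)) == 4L))
  groups <- vapply(cohort, function(s) s[[1]]$group, character(1))
  expect_equal(sum(groups == "meditator"), 12)
  expect_equal(sum(groups == "non_meditator"), 15)
})

test_that("inject_artifacts honours rate, magnitude and seed", {
  spec <- noiseless_spec(n_trials = 8)
  ep <- generate_subject(spec, MONTAGE, 1)$passive.reversal

  forced <- inject_artifacts(ep, rate = 1, magnitude_uv = 200, seed = 3)
  expect_equal(forced$n_modified, 8)
  for (t in seq_len(8)) {
    expect_gte(max(abs(forced$epochs$data[t, , ] - ep$data[t, , ])), 200)
  }

  noop <- inject_artifacts(ep, rate = 0, magnitude_uv = 200, seed = 3)
  expect_identical(noop$epochs$data, ep$data)
  expect_equal(noop$n_modified, 0)

  r1 <- inject_artifacts(ep, rate = 0.5, magnitude_uv = 200, seed = 99)
  r2 <- inject_artifacts(ep, rate = 0.5, magnitude_uv = 200, seed = 99)
  expect_identical(r1$epochs$data, r2$epochs$data)
  expect_identical(r1$trials, r2$trials)
})

test_that("noiseless dERP equals the sum of reversal-only templates (linearity)", {
  rp <- component_template("RP", 140, 25, 3, c(Oz = 1, O1 = 0.5))
  fn <- component_template("FN", 160, 30, -4, c(Fz = 1, Oz = 0.2))
  p1 <- component_template("P1", 100, 20, 8, c(Oz = 1), conditions = "both")
  spec <- noiseless_spec(templates_shared = list(rp, fn, p1), n_trials = 5)
  eps <- generate_subject(spec, MONTAGE, 1)
  avg <- function(e) {
    d <- dim(e$data)
    matrix(colMeans(matrix(e$data, d[1], d[2] * d[3])), d[2], d[3],
           dimnames = list(channel_labels(e), NULL))
  }
  derp <- avg(eps$hold.reversal) - avg(eps$hold.stability)
  times <- eps$hold.reversal$times
  g <- function(lat, wid) exp(-((times - lat)^2) / (2 * wid^2))
  expected_oz <- 3 * g(140, 25) + (-4) * 0.2 * g(160, 30)  # P1 cancels
  expect_equal(unname(derp["Oz", ]), expected_oz, tolerance = 1e-12)
  expect_equal(unname(derp["Fz", ]), -4 * g(160, 30), tolerance = 1e-12)
})

test_that("1/f noise has a monotonically decreasing average power spectrum", {
  set.seed(5)
  n <- 256
  x <- onseterp:::.pink_noise(n, 150, 1, 500)   # 150 realizations
  pw <- rowMeans(Mod(stats::mvfft(x))^2)[2:(n / 2)]
  freqs <- (1:(n / 2 - 1)) * 500 / n
  # average power in octave bands must decrease monotonically
  bands <- split(pw, cut(log2(freqs), breaks = 6))
  bandmeans <- vapply(bands, mean, numeric(1))
  expect_true(all(diff(bandmeans) < 0))
  # variance calibrated to the requested SD
  expect_equal(stats::sd(as.numeric(x)), 1, tolerance = 0.05)
})

test_that("paper fixture encodes the study's design constants", {
  spec <- paper_fixture()
  expect_equal(spec$n_meditators, 12)
  expect_equal(spec$n_non_meditators, 15)
  shared <- vapply(spec$templates_shared, `[[`, "", "name")
  medonly <- vapply(spec$templates_meditator_only, `[[`, "", "name")
  expect_true("FN" %in% medonly)
  expect_false("FN" %in% shared)
  tc <- spec$trial_counts
  expect_equal(tc$mean[tc$group == "non_meditator" & tc$experiment == "passive"], 78.7)
  expect_equal(tc$mean[tc$group == "meditator" & tc$experiment == "hold"], 43.3)
  widths <- vapply(c(spec$templates_shared, spec$templates_meditator_only),
                   `[[`, numeric(1), "width_ms")
  expect_true(all(widths > 0))
  # planted chain latencies are the reported ones
  lat <- vapply(c(spec$templates_shared, spec$templates_meditator_only),
                `[[`, numeric(1), "latency_ms")
  names(lat) <- c(shared, medonly)
  expect_equal(unname(lat[c("RP", "RN", "PP_parietal", "PP_frontal", "FN")]),
               c(140, 260, 540, 480, 160))
})

test_that("cohort_spec validates its inputs", {
  counts <- data.frame(group = "meditator", experiment = "passive",
                       mean = 10, sd = 0, floor = 1)
  expect_error(cohort_spec(0, 5, counts), "group sizes")
  expect_error(cohort_spec(2, 2, counts, noise_white_sd = -1), ">= 0")
  expect_error(cohort_spec(2, 2, transform(counts, floor = 0)), "floor")
  expect_error(component_template("X", 100, 0, 1, c(Cz = 1)), "width")
  expect_error(component_template("X", 100, 10, 1, c(Cz = 0)), "nonzero")
})
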