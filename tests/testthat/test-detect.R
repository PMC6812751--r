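test_that("running t-tests match the closed-form oracle", {
  derps <- constant_derps(c(1, 2, 3))
  tt <- running_ttests(derps, "Oz", c(0, 98))
  n <- 3; mu <- 2; s <- 1
  t_oracle <- mu / (s / sqrt(n))
  p_oracle <- 2 * (1 - stats::pt(t_oracle, n - 1))
  expect_equal(tt$t, rep(t_oracle, length(tt$t)))
  expect_equal(tt$p, rep(p_oracle, length(tt$p)))
  expect_false(any(tt$degenerate))

  # subject order invariance
  tt2 <- running_ttests(rev(derps), "Oz", c(0, 98))
  expect_equal(tt$p, tt2$p)
})

test_that("degenerate variance flags and sets p as specified", {
  zeros <- constant_derps(c(0, 0, 0))
  tt <- running_ttests(zeros, "Oz", c(0, 98))
  expect_true(all(tt$degenerate))
  expect_equal(tt$p, rep(1, length(tt$p)))

  same <- constant_derps(c(2, 2, 2))
  tt2 <- running_ttests(same, "Oz", c(0, 98))
  expect_true(all(tt2$degenerate))
  expect_equal(tt2$p, rep(0, length(tt2$p)))

  expect_error(running_ttests(constant_derps(c(1, 2)), "Oz", c(0, 98)),
               "at least 3")
})

test_that("find_runs matches a brute-force enumerator", {
  times <- seq(0, by = 2, length.out = 60)
  # hand cases: exactly 10, exactly 9, two separated stretches
  p10 <- rep(1, 60); p10[11:20] <- 0.001
  expect_equal(nrow(find_runs(p10, times)), 1)
  expect_equal(find_runs(p10, times)$start_ms, times[11])
  expect_equal(find_runs(p10, times)$end_ms, times[20])

  p9 <- rep(1, 60); p9[11:19] <- 0.001
  expect_equal(nrow(find_runs(p9, times)), 0)

  p2 <- rep(1, 60); p2[5:16] <- 0.001; p2[30:44] <- 0.001
  r2 <- find_runs(p2, times)
  expect_equal(nrow(r2), 2)
  expect_equal(r2$length, c(12, 15))

  set.seed(31)
  for (i in 1:200) {
    p <- ifelse(runif(60) < 0.35, 0.001, 0.5)
    min_len <- sample(1:12, 1)
    got <- find_runs(p, times, alpha = 0.01, min_run_samples = min_len)
    want <- brute_runs(p < 0.01, min_len)
    expect_equal(nrow(got), length(want))
    if (length(want)) {
      expect_equal(got$start_idx, vapply(want, `[`, integer(1), 1))
      expect_equal(got$end_idx, vapply(want, `[`, integer(1), 2))
    }
  }
})

test_that("confirmatory presence is a disjunction over ROI electrodes", {
  # one electrode with a strong deflection, others flat noise-free zero
  set.seed(2)
  times <- seq(-100, 800, by = 2)
  mk <- function(subj, amp) {
    m <- matrix(rnorm(6 * length(times), sd = 0.05), 6, length(times))
    bump <- amp * exp(-((times - 150)^2) / (2 * 25^2))
    m[1, ] <- m[1, ] + bump
    make_derp(m, c("Oz", "O1", "O2", "P3", "Pz", "P4"), subject = subj)
  }
  derps <- lapply(sprintf("s%02d", 1:8), mk, amp = 5)
  pr <- presence_confirmatory(derps, ROIS$RP)
  expect_true(pr$met)
  expect_gt(nrow(pr$runs$Oz), 0)

  flat <- constant_derps(rep(0, 5), channels = ROIS$RP$electrodes,
                         n_samples = length(times))
  flat <- lapply(flat, function(d) { d$times <- times; d })
  expect_false(presence_confirmatory(flat, ROIS$RP)$met)

  # monotonicity: removing the qualifying electrode flips the verdict,
  # adding it back cannot
  roi_wo <- roi_spec("RP", c("O1", "O2"), 80, 250, "positive")
  expect_false(presence_confirmatory(derps, roi_wo)$met)
})

test_that("exploratory presence needs overlapping runs at neighbouring electrodes", {
  times <- seq(-100, 800, by = 2)
  chans <- c("F3", "Fz", "Oz", "O1")
  mk <- function(subj, on) {
    m <- matrix(0, length(chans), length(times))
    rownames(m) <- chans
    bump <- -5 * exp(-((times - 160)^2) / (2 * 30^2))
    for (el in on) m[el, ] <- bump
    set.seed(match(subj, sprintf("s%02d", 1:10)) + 77)
    m <- m + matrix(rnorm(length(m), sd = 0.05), nrow(m))
    make_derp(m, chans, subject = subj)
  }
  subs <- sprintf("s%02d", 1:8)
  # F3 and Fz are neighbours: met
  both <- lapply(subs, mk, on = c("F3", "Fz"))
  pr <- presence_exploratory(both, MONTAGE, c(80, 250), chans)
  expect_true(pr$met)
  expect_true(all(pr$pairs$a == "F3" & pr$pairs$b == "Fz"))

  # Fz and Oz are not neighbours: not met
  apart <- lapply(subs, mk, on = c("Fz", "Oz"))
  expect_false(presence_exploratory(apart, MONTAGE, c(80, 250), chans)$met)

  # brute-force cross-check of the pair search
  pr2 <- presence_exploratory(both, MONTAGE, c(80, 250), chans,
                              component = "FN")
  found <- FALSE
  for (a in chans) for (b in chans) {
    if (a < b && are_neighbors(MONTAGE, a, b)) {
      ra <- pr2$runs[[a]]; rb <- pr2$runs[[b]]
      if (nrow(ra) && nrow(rb)) {
        for (i in seq_len(nrow(ra))) for (j in seq_len(nrow(rb))) {
          if (max(ra$start_idx[i], rb$start_idx[j]) <=
              min(ra$end_idx[i], rb$end_idx[j])) found <- TRUE
        }
      }
    }
  }
  expect_equal(pr2$met, found)

  expect_error(presence_exploratory(both, MONTAGE, c(80, 250), c("Fz", "XX")),
               "outside montage")
})

test_that("pick_peak follows the largest-local-extremum-with-fallback rule", {
  times <- seq(0, by = 2, length.out = 5)
  up <- pick_peak(c(0, 1, 3, 2, 1), times, c(0, 8), "positive")
  expect_equal(up$amplitude_uv, 3)
  expect_equal(up$latency_ms, times[3])
  expect_false(up$fallback)

  ramp <- pick_peak(c(1, 2, 3, 4, 5), times, c(0, 8), "positive")
  expect_true(ramp$fallback)
  expect_equal(ramp$amplitude_uv, 3)
  expect_true(is.na(ramp$latency_ms))

  dn <- pick_peak(c(0, -1, -4, -2, 0), times, c(0, 8), "negative")
  expect_equal(dn$amplitude_uv, -4)
  expect_equal(dn$latency_ms, times[3])

  # tie-break: earliest of two equal extrema
  tie <- pick_peak(c(0, 5, 0, 5, 0), times, c(0, 8), "positive")
  expect_equal(tie$latency_ms, times[2])

  # window endpoints are never peaks
  edge <- pick_peak(c(9, 1, 2, 1, 9), times, c(0, 8), "positive")
  expect_equal(edge$amplitude_uv, 2)
})

test_that("pick_peak agrees with the exhaustive-scan oracle", {
  set.seed(9)
  times <- seq(0, by = 2, length.out = 30)
  for (i in 1:300) {
    w <- round(rnorm(30), 1)  # rounding provokes ties
    pol <- sample(c("positive", "negative"), 1)
    got <- pick_peak(w, times, c(0, 58), pol)
    want <- brute_peak(w, pol == "positive")
    expect_equal(got$fallback, want$fallback)
    expect_equal(got$amplitude_uv, want$amplitude)
    if (!want$fallback) {
      # same amplitude; our rule additionally breaks ties to the earliest
      cand <- which(w == want$amplitude)
      expect_true(got$latency_ms <= times[max(cand)])
    }
  }
})

test_that("measure_component yields one row per subject x electrode", {
  fn <- component_template("FN", 160, 30, -5, c(Fz = 1, F3 = 0.8, Cz = 0.8))
  spec <- noiseless_spec(templates_med = list(fn), n_med = 3, n_ctl = 2,
                         n_trials = 3)
  cohort <- generate_cohort(spec, MONTAGE)
  pp <- preproc_config()
  derps <- unlist(lapply(cohort, function(s) {
    lapply(c("passive", "hold"), function(e) {
      suppressWarnings(
        compute_derp(average_erp(s[[paste0(e, ".reversal")]], pp),
                     average_erp(s[[paste0(e, ".stability")]], pp)))
    })
  }), recursive = FALSE)
  tab <- measure_component(derps, ROIS$FN)
  expect_equal(nrow(tab), length(derps) * 8)
  med <- tab[tab$group == "meditator" & tab$electrode == "Fz", ]
  expect_equal(med$latency_ms, rep(160, nrow(med)))  # no jitter planted
  expect_equal(med$amplitude_uv, rep(-5, nrow(med)), tolerance = 0.02)
  # controls carry no FN: flat traces have no local extremum -> fallback
  ctl <- tab[tab$group == "non_meditator", ]
  expect_true(all(ctl$fallback))
  expect_true(all(is.na(ctl$latency_ms)))
})

test_that("confirmatory criterion false-positive rate is liberal on smooth noise", {
  # dERP-level white noise, 12 subjects, RP ROI; filtered (autocorrelated)
  # noise inflates the family-wise false-detection rate well beyond the
  # nominal per-test alpha, unfiltered noise keeps it near zero.
  set.seed(123)
  n_sim <- 200
  times <- seq(-100, 800, by = 2)
  els <- ROIS$RP$electrodes
  hits <- c(filtered = 0, unfiltered = 0)
  for (s in 1:n_sim) {
    raw <- lapply(1:12, function(i) {
      matrix(rnorm(6 * length(times), sd = 2), 6, length(times))
    })
    for (variant in names(hits)) {
      derps <- lapply(seq_along(raw), function(i) {
        m <- raw[[i]]
        if (variant == "filtered") {
          m <- baseline_correct(lowpass(m, 25, 500), times)
        }
        make_derp(m, els, subject = sprintf("s%02d", i))
      })
      if (presence_confirmatory(derps, ROIS$RP)$met) {
        hits[variant] <- hits[variant] + 1
      }
    }
  }
  rate <- hits / n_sim
  # the criterion is admittedly liberal: family-wise rate on smooth noise
  # clearly exceeds the per-test alpha of 0.01 (simulation count scaled to
  # 200 to keep the default run fast; the estimate is coarse but the gap
  # between the rates and alpha is large)
  expect_gt(rate[["filtered"]], 0.01,
            label = sprintf("measured false-detection rate on filtered noise (%.3f)",
                            rate[["filtered"]]))
  expect_gte(rate[["filtered"]], rate[["unfiltered"]],
             label = sprintf("filtered rate %.3f vs unfiltered rate %.3f",
                             rate[["filtered"]], rate[["unfiltered"]]))
})
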