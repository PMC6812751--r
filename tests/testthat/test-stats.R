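test_that("partial eta squared follows its definition", {
  expect_equal(partial_eta_sq(1, 1), 0.5)
  expect_equal(partial_eta_sq(0, 5), 0)
  expect_equal(partial_eta_sq(3, 1), 0.75)
  expect_error(partial_eta_sq(0, 0), "undefined")
  expect_error(partial_eta_sq(-1, 1), ">= 0")
})

test_that("mixed ANOVA agrees with the explicit sums-of-squares oracle", {
  # hand-sized designs, balanced and unbalanced groups
  for (cfg in list(c(3, 3, 2, 101), c(4, 6, 3, 202), c(5, 5, 6, 303))) {
    df <- random_measures(cfg[1:2], cfg[3], seed = cfg[4], group_shift = 0.5)
    df$value <- df$amplitude_uv
    got <- mixed_anova(df, "amplitude")
    want <- anova_ss_oracle(df)
    got <- got[match(want$effect, got$effect), ]
    expect_equal(got$F, want$F, tolerance = 1e-10)
    expect_equal(got$df1, want$df1)
    expect_equal(got$df2, want$df2)
    expect_equal(got$pes, want$pes, tolerance = 1e-10)
  }
})

test_that("mixed ANOVA degenerate and error paths behave", {
  # identical data in both groups: zero between-group variance
  df <- random_measures(c(3, 3), 2, seed = 5)
  base <- df[df$group == "meditator", ]
  mirror <- base
  mirror$subject <- sub("s0", "t0", mirror$subject)
  mirror$group <- "non_meditator"
  both <- rbind(base, mirror)
  both$amplitude_uv <- rep(base$amplitude_uv, 2)
  out <- mixed_anova(both, "amplitude")
  expect_lt(out$F[out$effect == "GROUP"], 1e-20)

  # fallback rows are dropped for latency; incomplete subjects go listwise
  df2 <- random_measures(c(4, 4), 2, seed = 9)
  df2$fallback[df2$subject == "s01"][1] <- TRUE
  expect_message(out2 <- mixed_anova(df2, "latency"), "dropped listwise")
  expect_equal(attr(out2, "n_dropped"), 1)

  df3 <- random_measures(c(1, 4), 2, seed = 10)
  expect_error(mixed_anova(df3, "amplitude"), "at least 2 subjects")
})

test_that("Greenhouse-Geisser columns are sane", {
  df <- random_measures(c(5, 5), 4, seed = 77)
  out <- mixed_anova(df, "amplitude", gg = TRUE)
  ee <- out[out$effect == "ELECTRODE", ]
  expect_gte(ee$epsilon, 1 / (4 - 1) - 1e-9)
  expect_lte(ee$epsilon, 1 + 1e-9)
  expect_true(ee$p_gg > 0 && ee$p_gg <= 1)
  # a 2-level within factor needs no correction
  xx <- out[out$effect == "EXPERIMENT", ]
  expect_equal(xx$epsilon, 1, tolerance = 1e-9)
  expect_equal(xx$p_gg, xx$p, tolerance = 1e-9)
})

test_that("Wilcoxon post-hoc matches the exact signed-rank null", {
  b <- c(1, 2, 3, 1, 4, 5)
  a <- b + c(1, 2, 3, 4, 5, 6)   # all-positive, tie-free differences
  wt <- wilcoxon_posthoc(a, b)
  expect_equal(wt$p, 2 / 64)
  expect_true(wt$exact)
  expect_equal(wt$statistic, 21)

  swapped <- wilcoxon_posthoc(b, a)
  expect_equal(swapped$p, wt$p)

  expect_error(wilcoxon_posthoc(a, a), "all differences are zero")
  expect_error(wilcoxon_posthoc(c(1, 2, 3, 4), c(0, 1, 2, 3)), "fewer than 5")

  # n > 25 switches to the normal approximation
  set.seed(4)
  big <- rnorm(30) + 0.5
  wt2 <- wilcoxon_posthoc(big, rep(0, 30))
  expect_false(wt2$exact)
  expect_true(wt2$p > 0 && wt2$p <= 1)
})

test_that("Holm correction matches the step-down formula", {
  expect_equal(holm_correct(c(0.04, 0.01)), c(0.04, 0.02))
  expect_equal(holm_correct(0.2), 0.2)
  expect_equal(holm_correct(c(0.01, 0.01, 0.01)), c(0.03, 0.03, 0.03))
  expect_error(holm_correct(c(0.1, 0)), "0, 1")

  set.seed(12)
  for (i in 1:50) {
    p <- runif(sample(1:8, 1))
    got <- holm_correct(p)
    expect_equal(got, stats::p.adjust(p, method = "holm"))
    expect_true(all(got >= p))
    o <- order(p)
    expect_true(all(diff(got[o]) >= -1e-12))
  }
})

test_that("corrected/uncorrected pairs are validated", {
  row <- report_corrected_pair(0.002, 0.02)
  expect_equal(row$p_raw, 0.002)
  expect_equal(row$p_corrected, 0.02)
  expect_error(report_corrected_pair(0.05, 0.04), "cannot be smaller")
  expect_equal(report_corrected_pair(0.01, 0.01)$p_corrected, 0.01)
})

test_that("post-hoc contrasts report Holm-corrected pairs", {
  set.seed(21)
  els <- c("O1", "Oz", "O2", "P3", "Pz", "P4")
  subs <- sprintf("s%02d", 1:10)
  df <- expand.grid(subject = subs, experiment = c("passive", "hold"),
                    electrode = els, stringsAsFactors = FALSE)
  df$group <- "meditator"
  occ <- df$electrode %in% c("O1", "Oz", "O2")
  df$amplitude_uv <- rnorm(nrow(df), mean = ifelse(occ, 3, 1), sd = 0.5)
  df$latency_ms <- 150; df$fallback <- FALSE; df$component <- "RP"
  out <- posthoc_contrasts(df, builtin_contrasts("RP"), "amplitude")
  expect_equal(nrow(out), 2)
  expect_true(all(out$p_corrected >= out$p_raw))
  expect_lt(out$p_raw[out$contrast == "occipital_vs_parietal"], 0.01)
})
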