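# Shared fixtures: all synthetic, built in code at test time.

MONTAGE <- standard_montage_32()
ROIS <- builtin_rois()

# Small, fast cohort: 3 + 3 subjects, fixed trial counts.
tiny_spec <- function(seed = 7L, n_trials = 15, noise_white = 4,
                      noise_pink = 4, artifact_rate = 0,
                      templates_shared = NULL, templates_med = NULL,
                      latency_jitter = 0, amp_jitter = 0) {
  if (is.null(templates_shared)) {
    templates_shared <- list(
      component_template("RP", 140, 25, 3,
                         c(Oz = 1, O1 = 0.9, O2 = 0.9, Pz = 0.6)))
  }
  if (is.null(templates_med)) {
    templates_med <- list(
      component_template("FN", 160, 30, -4, c(Fz = 1, F3 = 0.8, Cz = 0.8)))
  }
  counts <- expand.grid(group = c("meditator", "non_meditator"),
                        experiment = c("passive", "hold"),
                        stringsAsFactors = FALSE)
  counts$mean <- n_trials; counts$sd <- 0; counts$floor <- 1
  cohort_spec(3, 3, counts,
              templates_shared = templates_shared,
              templates_meditator_only = templates_med,
              noise_white_sd = noise_white, noise_pink_sd = noise_pink,
              latency_jitter_sd = latency_jitter, amp_scale_sd = amp_jitter,
              artifact_rate = artifact_rate, seed = seed)
}

# Fully deterministic spec: no noise, no jitter, no artifacts.
noiseless_spec <- function(templates_shared = list(),
                           templates_med = list(), n_med = 1, n_ctl = 1,
                           n_trials = 4, seed = 1L) {
  counts <- expand.grid(group = c("meditator", "non_meditator"),
                        experiment = c("passive", "hold"),
                        stringsAsFactors = FALSE)
  counts$mean <- n_trials; counts$sd <- 0; counts$floor <- 1
  cohort_spec(n_med, n_ctl, counts,
              templates_shared = templates_shared,
              templates_meditator_only = templates_med,
              noise_white_sd = 0, noise_pink_sd = 0,
              latency_jitter_sd = 0, amp_scale_sd = 0,
              artifact_rate = 0, seed = seed)
}

# Hand-built epoch set: values array [trials, channels, samples].
make_epochs <- function(data, channels, srate = 500,
                        times = NULL, subject = "s01", group = "meditator",
                        experiment = "passive", condition = "reversal") {
  if (is.null(times)) times <- seq(0, by = 1000 / srate,
                                   length.out = dim(data)[3])
  dimnames(data) <- list(NULL, channels, NULL)
  epoch_set(data, subject, group, experiment, condition, srate, times)
}

# Hand-built dERP trace from a channels x samples matrix.
make_derp <- function(mat, channels, subject = "s01", group = "meditator",
                      experiment = "passive", srate = 500, times = NULL) {
  if (is.null(times)) times <- seq(0, by = 1000 / srate, length.out = ncol(mat))
  rownames(mat) <- channels
  derp_trace(mat, subject, group, experiment, n_reversal = 10,
             n_stability = 10, srate = srate, times = times)
}

# A set of constant-valued dERPs (one value per subject) on one electrode
# grid; useful for exact t-test checks.
constant_derps <- function(values, channels = c("Oz", "O1"), n_samples = 50) {
  lapply(seq_along(values), function(i) {
    make_derp(matrix(values[i], length(channels), n_samples), channels,
              subject = sprintf("s%02d", i))
  })
}

# Brute-force oracle: maximal runs of TRUE with length >= min_len.
brute_runs <- function(mask, min_len) {
  out <- list()
  i <- 1
  n <- length(mask)
  while (i <= n) {
    if (mask[i]) {
      j <- i
      while (j < n && mask[j + 1]) j <- j + 1
      if (j - i + 1 >= min_len) out[[length(out) + 1]] <- as.integer(c(i, j))
      i <- j + 1
    } else i <- i + 1
  }
  out
}

# Brute-force oracle for pick_peak: scan all interior samples.
brute_peak <- function(w, positive) {
  n <- length(w)
  best <- NULL
  if (n >= 3) {
    for (i in 2:(n - 1)) {
      ok <- if (positive) w[i] > w[i - 1] && w[i] > w[i + 1]
            else w[i] < w[i - 1] && w[i] < w[i + 1]
      if (ok) {
        if (is.null(best) ||
            (positive && w[i] > w[best]) || (!positive && w[i] < w[best])) {
          best <- i
        }
      }
    }
  }
  if (is.null(best)) list(amplitude = mean(w), idx = NA_integer_, fallback = TRUE)
  else list(amplitude = w[best], idx = best, fallback = FALSE)
}

# Explicit sums-of-squares oracle for the mixed GROUP x EXPERIMENT x
# ELECTRODE design (complete within-subject cells; groups may be unequal).
anova_ss_oracle <- function(df) {
  df$subject <- as.character(df$subject)
  gm <- mean(df$value)
  E <- sort(unique(df$experiment)); L <- sort(unique(df$electrode))
  nE <- length(E); nL <- length(L)
  subj <- unique(df[, c("subject", "group")])
  mean_by <- function(...) tapply(df$value, lapply(list(...), function(f) df[[f]]), mean)
  drop1 <- function(a) setNames(as.vector(a), names(a))
  m_s <- drop1(tapply(df$value, df$subject, mean))
  m_g <- drop1(tapply(df$value, df$group, mean))
  m_e <- drop1(tapply(df$value, df$experiment, mean))
  m_l <- drop1(tapply(df$value, df$electrode, mean))
  m_ge <- mean_by("group", "experiment")
  m_gl <- mean_by("group", "electrode")
  m_el <- mean_by("experiment", "electrode")
  m_gel <- mean_by("group", "experiment", "electrode")
  m_se <- mean_by("subject", "experiment")
  m_sl <- mean_by("subject", "electrode")
  Ng <- table(subj$group)
  gs <- subj$group; names(gs) <- subj$subject

  ss_G <- nE * nL * sum(Ng * (m_g - gm)^2)
  ss_subj <- nE * nL * sum((m_s - m_g[gs[names(m_s)]])^2)
  ss_E <- nL * nrow(subj) * sum((m_e - gm)^2)
  ss_GE <- nL * sum(rep(Ng, nE) *
                    (t(t(m_ge) - m_e) - (m_g - gm))^2)
  # error strata
  err_E <- 0
  for (s in names(m_s)) for (e in E) {
    err_E <- err_E + nL * (m_se[s, e] - m_s[s] - m_ge[gs[s], e] + m_g[gs[s]])^2
  }
  ss_L <- nE * nrow(subj) * sum((m_l - gm)^2)
  ss_GL <- nE * sum(rep(Ng, nL) * (t(t(m_gl) - m_l) - (m_g - gm))^2)
  err_L <- 0
  for (s in names(m_s)) for (l in L) {
    err_L <- err_L + nE * (m_sl[s, l] - m_s[s] - m_gl[gs[s], l] + m_g[gs[s]])^2
  }
  ss_EL <- nrow(subj) *
    sum((sweep(sweep(m_el, 1, m_e), 2, m_l) + gm)^2)
  ss_GEL <- 0
  for (g in names(Ng)) for (e in E) for (l in L) {
    ss_GEL <- ss_GEL + Ng[[g]] *
      (m_gel[g, e, l] - m_ge[g, e] - m_gl[g, l] - m_el[e, l] +
         m_g[g] + m_e[e] + m_l[l] - gm)^2
  }
  err_EL <- 0
  for (i in seq_len(nrow(df))) {
    s <- df$subject[i]; e <- df$experiment[i]; l <- df$electrode[i]; g <- gs[s]
    fit <- m_se[s, e] + m_sl[s, l] - m_s[s] +
      m_gel[g, e, l] - m_ge[g, e] - m_gl[g, l] + m_g[g]
    err_EL <- err_EL + (df$value[i] - fit)^2
  }
  nS <- nrow(subj); nGr <- length(Ng)
  mkrow <- function(effect, ss, df1, ss_err, df2) {
    data.frame(effect = effect, df1 = df1, df2 = df2,
               F = (ss / df1) / (ss_err / df2),
               pes = ss / (ss + ss_err), stringsAsFactors = FALSE)
  }
  rbind(
    mkrow("GROUP", ss_G, nGr - 1, ss_subj, nS - nGr),
    mkrow("EXPERIMENT", ss_E, nE - 1, err_E, (nS - nGr) * (nE - 1)),
    mkrow("GROUP:EXPERIMENT", ss_GE, (nGr - 1) * (nE - 1), err_E,
          (nS - nGr) * (nE - 1)),
    mkrow("ELECTRODE", ss_L, nL - 1, err_L, (nS - nGr) * (nL - 1)),
    mkrow("GROUP:ELECTRODE", ss_GL, (nGr - 1) * (nL - 1), err_L,
          (nS - nGr) * (nL - 1)),
    mkrow("EXPERIMENT:ELECTRODE", ss_EL, (nE - 1) * (nL - 1), err_EL,
          (nS - nGr) * (nE - 1) * (nL - 1)),
    mkrow("GROUP:EXPERIMENT:ELECTRODE", ss_GEL, (nGr - 1) * (nE - 1) * (nL - 1),
          err_EL, (nS - nGr) * (nE - 1) * (nL - 1))
  )
}

# Random complete-design measures table for ANOVA checks.
random_measures <- function(n_per_group, n_electrodes, seed,
                            group_shift = 0, subject_sd = 1, noise_sd = 1) {
  set.seed(seed)
  electrodes <- sprintf("e%02d", seq_len(n_electrodes))
  subjects <- sprintf("s%02d", seq_len(sum(n_per_group)))
  groups <- rep(c("meditator", "non_meditator"), n_per_group)
  df <- expand.grid(subject = subjects, experiment = c("passive", "hold"),
                    electrode = electrodes, stringsAsFactors = FALSE)
  df$group <- groups[match(df$subject, subjects)]
  b_s <- stats::rnorm(length(subjects), 0, subject_sd)
  names(b_s) <- subjects
  df$amplitude_uv <- b_s[df$subject] + stats::rnorm(nrow(df), 0, noise_sd) +
    ifelse(df$group == "meditator", group_shift, 0)
  df$latency_ms <- df$amplitude_uv + 100
  df$fallback <- FALSE
  df$component <- "X"
  df
}
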