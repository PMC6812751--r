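#' Synthetic Onset-Paradigm cohorts
#'
#' The generator emits trial-level stimulus-locked EEG for a two-group
#' (meditator / non-meditator), two-experiment (passive / hold),
#' two-condition (reversal / stability) design.  Reversal-related components
#' are planted as Gaussian time-course templates with fixed scalp
#' topographies; templates marked `conditions = "both"` model
#' stimulus-evoked activity shared by both conditions and cancel exactly in
#' the reversal-minus-stability difference.  Trial noise is white plus
#' 1/f-shaped (pink) noise, and between-subject variability is a Gaussian
#' additive latency shift plus a Gaussian multiplicative amplitude scale.
#'
#' @name synthetic_data
NULL

#' Define a planted ERP component template
#'
#' @param name component name.
#' @param latency_ms peak latency in ms post stimulus onset.
#' @param width_ms temporal half-width: the standard deviation of the
#'   Gaussian time course, in ms.  Must be positive.
#' @param amplitude_uv signed peak amplitude in microvolts at the
#'   maximally-weighted electrode.
#' @param topography named numeric vector of electrode weights in [-1, 1];
#'   electrodes not listed get weight 0.  At least one weight must be
#'   nonzero.
#' @param conditions `"reversal"` (injected into reversal trials only, so it
#'   survives the dERP subtraction) or `"both"` (injected into both
#'   conditions, cancelling in the dERP).
#' @return An object of class `component_template`.
#' @export
component_template <- function(name, latency_ms, width_ms, amplitude_uv,
                               topography, conditions = c("reversal", "both")) {
  conditions <- match.arg(conditions)
  if (!(is.numeric(width_ms) && width_ms > 0)) stop("width_ms must be > 0")
  if (is.null(names(topography)) || !any(topography != 0)) {
    stop("topography must be a named vector with at least one nonzero weight")
  }
  if (any(abs(topography) > 1)) stop("topography weights must lie in [-1, 1]")
  structure(list(name = name, latency_ms = latency_ms, width_ms = width_ms,
                 amplitude_uv = amplitude_uv, topography = topography,
                 conditions = conditions),
            class = "component_template")
}

#' Define a synthetic cohort
#'
#' @param n_meditators,n_non_meditators group sizes (>= 1).
#' @param trial_counts data.frame with columns `group`, `experiment`,
#'   `mean`, `sd`, `floor`: the per-subject trial-count distribution for
#'   each experiment (the same distribution is used for the reversal and
#'   the stability condition of that experiment).  Counts are drawn as
#'   `round(rnorm(mean, sd))` clamped below at `floor` (>= 1).
#' @param templates_shared list of [component_template] objects planted in
#'   every subject.
#' @param templates_meditator_only list of templates planted only in
#'   meditators.
#' @param noise_white_sd,noise_pink_sd per-sample standard deviations (uV)
#'   of the white and the 1/f noise added to every trial.
#' @param latency_jitter_sd between-subject SD of the additive latency
#'   shift (ms), drawn once per subject x component.
#' @param amp_scale_sd between-subject SD of the multiplicative amplitude
#'   scale (mean 1), drawn once per subject x component and truncated below
#'   at 0.05.
#' @param artifact_rate,artifact_magnitude_uv Bernoulli rate and excursion
#'   magnitude (uV) of injected large-amplitude artifacts (see
#'   [inject_artifacts()]).
#' @param window_ms epoch window (ms relative to stimulus onset).
#' @param srate sampling rate in Hz.
#' @param seed integer random seed for the whole cohort.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_meditators, n_non_meditators, trial_counts,
                        templates_shared = list(),
                        templates_meditator_only = list(),
                        noise_white_sd = 8, noise_pink_sd = 8,
                        latency_jitter_sd = 10, amp_scale_sd = 0.2,
                        artifact_rate = 0.1, artifact_magnitude_uv = 300,
                        window_ms = c(-100, 800), srate = 500, seed = 1L) {
  if (n_meditators < 1 || n_non_meditators < 1) stop("group sizes must be >= 1")
  req <- c("group", "experiment", "mean", "sd", "floor")
  if (!all(req %in% names(trial_counts))) {
    stop("trial_counts needs columns: ", paste(req, collapse = ", "))
  }
  if (any(trial_counts$floor < 1)) stop("trial floor must be >= 1")
  if (any(trial_counts$sd < 0) || noise_white_sd < 0 || noise_pink_sd < 0 ||
      latency_jitter_sd < 0 || amp_scale_sd < 0) {
    stop("standard deviations must be >= 0")
  }
  if (artifact_rate < 0 || artifact_rate > 1) stop("artifact_rate must be in [0, 1]")
  structure(list(n_meditators = n_meditators,
                 n_non_meditators = n_non_meditators,
                 trial_counts = trial_counts,
                 templates_shared = templates_shared,
                 templates_meditator_only = templates_meditator_only,
                 noise_white_sd = noise_white_sd, noise_pink_sd = noise_pink_sd,
                 latency_jitter_sd = latency_jitter_sd,
                 amp_scale_sd = amp_scale_sd,
                 artifact_rate = artifact_rate,
                 artifact_magnitude_uv = artifact_magnitude_uv,
                 window_ms = window_ms, srate = srate, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Subject roster of a cohort spec
#' @param spec a [cohort_spec].
#' @return data.frame with columns `subject` and `group`.
#' @export
cohort_subjects <- function(spec) {
  data.frame(
    subject = c(sprintf("med%02d", seq_len(spec$n_meditators)),
                sprintf("ctl%02d", seq_len(spec$n_non_meditators))),
    group = rep(c("meditator", "non_meditator"),
                c(spec$n_meditators, spec$n_non_meditators)),
    stringsAsFactors = FALSE
  )
}

#' The shipped default cohort
#'
#' Both groups carry the reversal-related chain templates (Reversal
#' Positivity at 140 ms, Reversal Negativity at 260 ms, and the late
#' positivity split into a parietal part peaking at 540 ms and a
#' frontal/frontopolar part peaking at 480 ms) plus two stimulus-evoked
#' templates injected into both conditions; only the meditator group
#' additionally carries the anterior Frontal Negativity at 160 ms.  Group
#' sizes (12 meditators, 15 non-meditators) and per-experiment trial-count
#' distributions follow the study's trial bookkeeping.
#'
#' @param seed integer seed stored in the spec.
#' @return A [cohort_spec].
#' @examples
#' spec <- paper_fixture()
#' spec$n_meditators + spec$n_non_meditators
#' @export
paper_fixture <- function(seed = 1L) {
  rp <- component_template("RP", 140, 25, 3,
    c(Oz = 1, O1 = 0.9, O2 = 0.9, POz = 0.8, Pz = 0.6, P3 = 0.5, P4 = 0.5,
      P7 = 0.3, P8 = 0.3))
  rn <- component_template("RN", 260, 45, -4,
    c(Oz = 1, O1 = 0.9, O2 = 0.9, POz = 0.9, Pz = 0.8, P3 = 0.7, P4 = 0.7,
      P7 = 0.4, P8 = 0.4, CP1 = 0.3, CP2 = 0.3))
  ppp <- component_template("PP_parietal", 540, 60, 7,
    c(Pz = 1, CP1 = 0.8, CP2 = 0.8, P3 = 0.8, P4 = 0.8, Cz = 0.7,
      POz = 0.6, C3 = 0.4, C4 = 0.4))
  ppf <- component_template("PP_frontal", 480, 60, 6,
    c(Fpz = 1, Fp1 = 0.9, Fp2 = 0.9, Fz = 0.7, F3 = 0.5, F4 = 0.5, Cz = 0.2))
  fn <- component_template("FN", 160, 30, -4,
    c(Fz = 1, F3 = 0.8, F4 = 0.8, Cz = 0.8, Fp1 = 0.7, Fp2 = 0.7, C3 = 0.6,
      C4 = 0.6, FC1 = 0.5, FC2 = 0.5))
  # stimulus-evoked activity present in both conditions (cancels in dERP)
  p1 <- component_template("P1", 100, 20, 8,
    c(Oz = 1, O1 = 0.9, O2 = 0.9, POz = 0.7, Pz = 0.4), conditions = "both")
  n1 <- component_template("N1", 170, 25, -6,
    c(P7 = 1, P8 = 1, O1 = 0.8, O2 = 0.8, POz = 0.5), conditions = "both")
  counts <- data.frame(
    group = c("meditator", "meditator", "non_meditator", "non_meditator"),
    experiment = c("passive", "hold", "passive", "hold"),
    mean = c(65.8, 43.3, 78.7, 61),
    sd = c(34.6, 25.4, 26.2, 28.4),
    floor = c(12, 13, 34, 26),
    stringsAsFactors = FALSE
  )
  cohort_spec(12, 15, counts,
              templates_shared = list(rp, rn, ppp, ppf, p1, n1),
              templates_meditator_only = list(fn),
              noise_white_sd = 6, noise_pink_sd = 3,
              seed = seed)
}

# deterministic per-subject seed below 2^31
.subject_seed <- function(seed, i) {
  (abs(seed) + i * 1000003L) %% 2147483647L
}

# 1/f-shaped noise: S x ncol matrix, unit-variance columns scaled to sd.
# White noise is shaped in the frequency domain with H(f) ~ f^(-1/2)
# (power ~ 1/f); DC is removed; H is normalised so the per-sample variance
# equals sd^2 exactly in expectation.  Synthesis runs at the next power of
# two >= n_samples (then truncates) so the FFT length is always composite.
.pink_noise <- function(n_samples, ncol, sd, srate) {
  if (sd == 0) return(matrix(0, n_samples, ncol))
  n <- 2^ceiling(log2(n_samples))
  k <- seq_len(n) - 1
  f <- pmin(k, n - k) * srate / n
  h <- ifelse(f > 0, 1 / sqrt(f), 0)
  h <- h / sqrt(mean(h^2))
  w <- matrix(stats::rnorm(n * ncol), n, ncol)
  x <- Re(stats::mvfft(stats::mvfft(w) * h, inverse = TRUE)) / n
  x[seq_len(n_samples), , drop = FALSE] * sd
}

# Gaussian time course evaluated on the time axis
.template_course <- function(times, latency_ms, width_ms) {
  exp(-((times - latency_ms)^2) / (2 * width_ms^2))
}

# Add artifacts using the current RNG stream; returns list(data, n, trials)
.add_artifacts <- function(data, rate, magnitude) {
  d <- dim(data)
  hit <- which(stats::runif(d[1]) < rate)
  for (t in hit) {
    ch <- sample.int(d[2], 1)
    sm <- sample.int(d[3], 1)
    data[t, ch, sm] <- data[t, ch, sm] + sample(c(-1, 1), 1) * magnitude
  }
  list(data = data, n = length(hit), trials = hit)
}

#' Generate all epoch sets for one subject
#'
#' Deterministic given `spec$seed` and the subject index: the subject's
#' per-component latency shifts and amplitude scales are drawn first, then
#' the four experiment x condition cells are generated in a fixed order.
#'
#' @param spec a [cohort_spec].
#' @param montage a [montage] giving the channel set and order.
#' @param i subject index (1..n_meditators first, then non-meditators).
#' @return Named list of four [epoch_set] objects
#'   (`passive.reversal`, `passive.stability`, `hold.reversal`,
#'   `hold.stability`).
#' @export
generate_subject <- function(spec, montage, i) {
  roster <- cohort_subjects(spec)
  stopifnot(i >= 1, i <= nrow(roster))
  subject <- roster$subject[i]
  group <- roster$group[i]
  templates <- spec$templates_shared
  if (group == "meditator") {
    templates <- c(templates, spec$templates_meditator_only)
  }
  labels <- montage$labels
  times <- seq(spec$window_ms[1], spec$window_ms[2], by = 1000 / spec$srate)
  S <- length(times)
  C <- length(labels)

  set.seed(.subject_seed(spec$seed, i))
  # subject-level variability, one draw per component
  shifts <- stats::rnorm(length(templates), 0, spec$latency_jitter_sd)
  scales <- pmax(0.05, stats::rnorm(length(templates), 1, spec$amp_scale_sd))

  # channels x samples signal for each condition
  sig <- list(reversal = matrix(0, C, S), stability = matrix(0, C, S))
  for (j in seq_along(templates)) {
    tp <- templates[[j]]
    topo <- numeric(C)
    idx <- match(names(tp$topography), labels)
    if (anyNA(idx)) {
      stop("template ", tp$name, " references electrodes outside the montage")
    }
    topo[idx] <- tp$topography
    course <- .template_course(times, tp$latency_ms + shifts[j], tp$width_ms)
    g <- (tp$amplitude_uv * scales[j]) * (topo %o% course)
    sig$reversal <- sig$reversal + g
    if (tp$conditions == "both") sig$stability <- sig$stability + g
  }

  out <- list()
  for (experiment in c("passive", "hold")) {
    row <- spec$trial_counts[spec$trial_counts$group == group &
                            spec$trial_counts$experiment == experiment, ]
    if (nrow(row) != 1) stop("trial_counts must have one row per group x experiment")
    for (condition in c("reversal", "stability")) {
      n <- max(row$floor, round(stats::rnorm(1, row$mean, row$sd)), 1)
      x <- array(stats::rnorm(n * C * S, 0, spec$noise_white_sd),
                 dim = c(n, C, S))
      if (spec$noise_pink_sd > 0) {
        pk <- .pink_noise(S, n * C, spec$noise_pink_sd, spec$srate)
        x <- x + aperm(array(pk, c(S, n, C)), c(2, 3, 1))
      }
      # broadcast the channels x samples signal over trials
      x <- x + aperm(array(sig[[condition]], c(C, S, n)), c(3, 1, 2))
      if (spec$artifact_rate > 0) {
        x <- .add_artifacts(x, spec$artifact_rate, spec$artifact_magnitude_uv)$data
      }
      dimnames(x) <- list(NULL, labels, NULL)
      out[[paste(experiment, condition, sep = ".")]] <-
        epoch_set(x, subject, group, experiment, condition,
                  srate = spec$srate, times = times)
    }
  }
  out
}

#' Generate a full cohort of epoch sets
#'
#' @param spec a [cohort_spec].
#' @param montage a [montage].
#' @return Named list with one element per subject (`<subject>` ->
#'   list of four [epoch_set]s as returned by [generate_subject()]).
#'   Identical spec and seed give bit-identical output.
#' @export
generate_cohort <- function(spec, montage) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(montage, "montage"))
  roster <- cohort_subjects(spec)
  out <- lapply(seq_len(nrow(roster)), function(i) generate_subject(spec, montage, i))
  names(out) <- roster$subject
  out
}

#' Inject large-amplitude artifacts into an epoch set
#'
#' A Bernoulli(`rate`) subset of trials receives an added excursion of
#' +/- `magnitude_uv` at one random channel and sample, emulating the
#' transient artifacts targeted by the +/-150 uV rejection rule.
#'
#' @param epochs an [epoch_set].
#' @param rate per-trial injection probability in [0, 1].
#' @param magnitude_uv excursion magnitude in microvolts (> 0).
#' @param seed optional integer seed; fixed seed gives identical injections.
#' @return List with elements `epochs` (modified [epoch_set]), `n_modified`
#'   and `trials` (indices of modified trials).
#' @export
inject_artifacts <- function(epochs, rate, magnitude_uv, seed = NULL) {
  stopifnot(inherits(epochs, "epoch_set"), rate >= 0, rate <= 1)
  if (magnitude_uv <= 0) stop("magnitude_uv must be > 0")
  if (!is.null(seed)) set.seed(seed)
  res <- .add_artifacts(epochs$data, rate, magnitude_uv)
  epochs$data <- res$data
  list(epochs = epochs, n_modified = res$n, trials = res$trials)
}

#' Write a cohort spec as structured-text (JSON) config
#' @param spec a [cohort_spec].
#' @param path output file path.
#' @export
write_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  x <- unclass(spec)
  as_obj <- function(tl) lapply(tl, function(tp) {
    tp <- unclass(tp)
    tp$topography <- as.list(tp$topography)  # keep electrode names in JSON
    tp
  })
  x$templates_shared <- as_obj(x$templates_shared)
  x$templates_meditator_only <- as_obj(x$templates_meditator_only)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(path)
}

#' Read a cohort spec written by [write_cohort_spec()]
#' @param path file path.
#' @return A validated [cohort_spec].
#' @export
read_cohort_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  mk_templates <- function(tl) {
    lapply(tl, function(tp) {
      component_template(tp$name, tp$latency_ms, tp$width_ms, tp$amplitude_uv,
                         unlist(tp$topography), tp$conditions)
    })
  }
  counts <- do.call(rbind, lapply(x$trial_counts, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  cohort_spec(x$n_meditators, x$n_non_meditators, counts,
              templates_shared = mk_templates(x$templates_shared),
              templates_meditator_only = mk_templates(x$templates_meditator_only),
              noise_white_sd = x$noise_white_sd, noise_pink_sd = x$noise_pink_sd,
              latency_jitter_sd = x$latency_jitter_sd,
              amp_scale_sd = x$amp_scale_sd,
              artifact_rate = x$artifact_rate,
              artifact_magnitude_uv = x$artifact_magnitude_uv,
              window_ms = x$window_ms, srate = x$srate, seed = x$seed)
}
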