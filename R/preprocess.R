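#' Preprocessing: re-referencing, artifact rejection, filtering, baseline
#'
#' The fixed preprocessing order is: re-reference to the mastoid-adjacent
#' electrodes (TP9/TP10) -> reject trials with amplitude excursions beyond
#' the threshold (evaluated on the re-referenced signal over the full epoch
#' window) -> average -> zero-phase low-pass filter -> baseline-correct.
#' Rejection uses a strict inequality: a trial is removed iff any channel at
#' any sample has |value| strictly greater than the threshold.
#'
#' @name preprocessing
NULL

#' Preprocessing configuration
#'
#' @param reference character vector of reference electrode labels
#'   (default TP9, TP10; their per-trial, per-sample mean is subtracted).
#' @param reject_uv rejection threshold in microvolts (default 150; strict
#'   inequality).
#' @param lowpass_hz low-pass cutoff in Hz (default 25).
#' @param baseline_ms baseline window in ms relative to stimulus onset
#'   (default -60..+40).
#' @param min_trials minimum trial count per condition below which a
#'   subject's average is flagged for exclusion (default 10).
#' @return An object of class `preproc_config`.
#' @export
preproc_config <- function(reference = c("TP9", "TP10"), reject_uv = 150,
                           lowpass_hz = 25, baseline_ms = c(-60, 40),
                           min_trials = 10) {
  if (reject_uv <= 0) stop("reject_uv must be > 0")
  if (lowpass_hz <= 0) stop("lowpass_hz must be > 0")
  stopifnot(length(baseline_ms) == 2, baseline_ms[1] < baseline_ms[2])
  structure(list(reference = reference, reject_uv = reject_uv,
                 lowpass_hz = lowpass_hz, baseline_ms = baseline_ms,
                 min_trials = min_trials),
            class = "preproc_config")
}

#' Re-reference an epoch set
#'
#' Subtracts, per trial and sample, the mean of the reference channels
#' (computed before any subtraction) from every channel.
#'
#' @param epochs an [epoch_set].
#' @param refs reference electrode labels (default TP9 and TP10).
#' @return The re-referenced [epoch_set].
#' @export
rereference <- function(epochs, refs = c("TP9", "TP10")) {
  stopifnot(inherits(epochs, "epoch_set"))
  labels <- channel_labels(epochs)
  idx <- match(refs, labels)
  if (anyNA(idx)) {
    stop("missing reference channel(s): ", paste(refs[is.na(idx)], collapse = ", "))
  }
  d <- dim(epochs$data)
  refmean <- epochs$data[, idx[1], , drop = TRUE]
  if (length(idx) > 1) {
    for (k in idx[-1]) refmean <- refmean + epochs$data[, k, , drop = TRUE]
    refmean <- refmean / length(idx)
  }
  refmean <- array(refmean, c(d[1], d[3]))  # trials x samples
  epochs$data <- epochs$data - aperm(array(refmean, c(d[1], d[3], d[2])), c(1, 3, 2))
  epochs
}

#' Reject trials with large amplitude excursions
#'
#' A trial is removed iff any channel at any sample satisfies
#' `|value| > threshold_uv` (strict).  Surviving trials are untouched.
#'
#' @param epochs an [epoch_set].
#' @param threshold_uv rejection threshold in microvolts (> 0).
#' @return List with `epochs` (kept trials), `report` (one-row data.frame
#'   with total/kept/removed counts and an `all_removed` flag) and
#'   `removed` (indices of removed trials).
#' @export
reject_artifacts <- function(epochs, threshold_uv = 150) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (threshold_uv <= 0) stop("threshold_uv must be > 0")
  d <- dim(epochs$data)
  m <- matrix(abs(epochs$data), d[1], d[2] * d[3])
  peak <- m[cbind(seq_len(d[1]), max.col(m, ties.method = "first"))]
  keep <- peak <= threshold_uv
  report <- data.frame(subject = epochs$subject, group = epochs$group,
                       experiment = epochs$experiment,
                       condition = epochs$condition,
                       total = d[1], kept = sum(keep),
                       removed = sum(!keep),
                       all_removed = !any(keep),
                       stringsAsFactors = FALSE)
  epochs$data <- epochs$data[keep, , , drop = FALSE]
  list(epochs = epochs, report = report, removed = which(!keep))
}

#' Symmetric FIR low-pass kernel (Hamming-windowed sinc)
#'
#' Odd-length, symmetric (hence exactly zero-phase when applied centred),
#' normalised to unit DC gain.  The default transition width of 10 Hz gives
#' a 165-tap kernel at 500 Hz with stopband attenuation of about -53 dB.
#'
#' @param cutoff_hz cutoff frequency in Hz.
#' @param rate_hz sampling rate in Hz; `cutoff_hz` must be below Nyquist.
#' @param transition_hz transition bandwidth in Hz.
#' @return Numeric vector of filter taps (odd length).
#' @export
fir_lowpass_kernel <- function(cutoff_hz, rate_hz, transition_hz = 10) {
  if (cutoff_hz >= rate_hz / 2) stop("cutoff must be below Nyquist")
  L <- ceiling(3.3 * rate_hz / transition_hz)
  if (L %% 2 == 0) L <- L + 1
  m <- (L - 1) / 2
  n <- seq(-m, m)
  fc <- cutoff_hz / rate_hz
  h <- ifelse(n == 0, 2 * fc, sin(2 * pi * fc * n) / (pi * n))
  h <- h * (0.54 + 0.46 * cos(pi * n / m))  # Hamming window
  h / sum(h)
}

#' Frequency response magnitude of a FIR kernel
#' @param h filter taps.
#' @param f_hz frequencies at which to evaluate.
#' @param rate_hz sampling rate in Hz.
#' @return `|H(f)|` at the requested frequencies.
#' @export
fir_response <- function(h, f_hz, rate_hz) {
  n <- seq_along(h) - (length(h) + 1) / 2
  vapply(f_hz, function(f) {
    Mod(sum(h * exp(-2i * pi * f * n / rate_hz)))
  }, numeric(1))
}

#' Zero-phase low-pass filter a channels x samples trace
#'
#' Applies the symmetric FIR kernel from [fir_lowpass_kernel()] with
#' reflection padding at the epoch edges.  Being symmetric and applied
#' centred, the filter is latency-neutral: a symmetric pulse keeps its peak
#' sample and the DC level is preserved.
#'
#' @param trace numeric matrix, channels x samples (a single channel may be
#'   passed as a vector).
#' @param cutoff_hz cutoff frequency in Hz (< rate/2).
#' @param rate_hz sampling rate in Hz.
#' @param transition_hz transition bandwidth in Hz.
#' @return Filtered trace with the same shape.
#' @export
lowpass <- function(trace, cutoff_hz, rate_hz, transition_hz = 10) {
  vec <- is.null(dim(trace))
  x <- if (vec) matrix(trace, nrow = 1) else trace
  h <- fir_lowpass_kernel(cutoff_hz, rate_hz, transition_hz)
  m <- (length(h) - 1) / 2
  S <- ncol(x)
  if (S <= m) {
    stop("epoch too short (", S, " samples) for filter edge handling (needs > ",
         m, ")")
  }
  out <- x
  for (ch in seq_len(nrow(x))) {
    padded <- c(rev(x[ch, seq_len(m) + 1]), x[ch, ],
                rev(x[ch, seq(S - m, S - 1)]))
    f <- stats::filter(padded, h, method = "convolution", sides = 2)
    out[ch, ] <- as.numeric(f[(m + 1):(m + S)])
  }
  if (vec) drop(out) else out
}

#' Baseline-correct a channels x samples trace
#'
#' Subtracts, per channel, the mean amplitude over the baseline window.
#'
#' @param trace numeric matrix channels x samples (or a vector).
#' @param times time axis in ms (length = number of samples).
#' @param window_ms two-element window (ms); must lie within the time axis.
#' @return Corrected trace; the post-hoc mean over the window is 0 per
#'   channel.
#' @export
baseline_correct <- function(trace, times, window_ms = c(-60, 40)) {
  vec <- is.null(dim(trace))
  x <- if (vec) matrix(trace, nrow = 1) else trace
  stopifnot(length(times) == ncol(x))
  if (window_ms[1] < min(times) || window_ms[2] > max(times)) {
    stop("baseline window outside epoch span")
  }
  sel <- times >= window_ms[1] & times <= window_ms[2]
  if (!any(sel)) stop("baseline window contains no samples")
  x <- x - rowMeans(x[, sel, drop = FALSE])
  if (vec) drop(x) else x
}

#' Convert a post-onset time to a sample index
#'
#' Nearest-sample rounding.  With a 500 Hz rate, 20 ms corresponds to 10
#' samples.
#'
#' @param t_ms time in ms relative to stimulus onset.
#' @param rate_hz sampling rate in Hz.
#' @param onset_index index of the sample at t = 0 (any integer origin).
#' @param n_samples optional epoch length; if given, out-of-range results
#'   raise an error (range is `onset_index - offset .. n_samples` for a
#'   1-based axis starting at index 1).
#' @return Integer sample index `onset_index + round(t_ms * rate_hz / 1000)`.
#' @export
ms_to_sample <- function(t_ms, rate_hz, onset_index = 0L, n_samples = NULL) {
  idx <- onset_index + as.integer(round(t_ms * rate_hz / 1000))
  if (!is.null(n_samples) && (any(idx < 1) || any(idx > n_samples))) {
    stop("time ", t_ms, " ms falls outside the epoch")
  }
  idx
}

#' Convert a sample index back to time in ms
#' @inheritParams ms_to_sample
#' @param index sample index.
#' @return Time in ms relative to onset.
#' @export
sample_to_ms <- function(index, rate_hz, onset_index = 0L) {
  (index - onset_index) * 1000 / rate_hz
}
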