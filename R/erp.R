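#' Selective averaging and difference-ERP computation
#'
#' Clean epochs are averaged per subject x experiment x condition to
#' event-related potentials (ERPs); stability-condition ERPs are then
#' subtracted from reversal-condition ERPs to form difference traces
#' (dERPs) in which activity common to both conditions cancels and only
#' reversal-related components survive.  Grand means are unweighted
#' averages over subjects.
#'
#' @name derp_pipeline
NULL

#' Construct an ERP trace
#'
#' @param data numeric matrix channels x samples (uV), rownames =
#'   electrode labels.
#' @param subject,group,experiment,condition metadata.
#' @param n_trials number of trials averaged.
#' @param srate sampling rate (Hz).
#' @param times time axis (ms).
#' @param low_trials logical flag: trial count below the configured minimum.
#' @return An object of class `erp_trace`.
#' @export
erp_trace <- function(data, subject, group, experiment, condition, n_trials,
                      srate, times, low_trials = FALSE) {
  stopifnot(is.matrix(data), !is.null(rownames(data)),
            length(times) == ncol(data))
  structure(list(data = data, subject = subject, group = group,
                 experiment = experiment, condition = condition,
                 n_trials = n_trials, srate = srate,
                 times = as.numeric(times), low_trials = low_trials),
            class = "erp_trace")
}

#' @export
print.erp_trace <- function(x, ...) {
  cat(sprintf("<erp_trace> %s %s/%s/%s: %d channels x %d samples (n = %d%s)\n",
              x$subject, x$group, x$experiment, x$condition, nrow(x$data),
              ncol(x$data), x$n_trials,
              if (isTRUE(x$low_trials)) ", LOW TRIALS" else ""))
  invisible(x)
}

#' Average clean epochs to a per-subject ERP
#'
#' Per-channel mean over trials, followed by zero-phase low-pass filtering
#' and baseline correction (filtering is applied to the average, not to
#' single trials).  A trial count below `preproc$min_trials` sets the
#' `low_trials` flag (the subject becomes excludable downstream).
#'
#' @param epochs an [epoch_set] of artifact-free trials.
#' @param preproc a [preproc_config].
#' @return An [erp_trace].
#' @export
average_erp <- function(epochs, preproc = preproc_config()) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  if (d[1] < 1) stop("cannot average an epoch set with zero trials")
  avg <- matrix(colMeans(matrix(epochs$data, d[1], d[2] * d[3])), d[2], d[3])
  rownames(avg) <- channel_labels(epochs)
  avg <- lowpass(avg, preproc$lowpass_hz, epochs$srate)
  avg <- baseline_correct(avg, epochs$times, preproc$baseline_ms)
  low <- d[1] < preproc$min_trials
  if (low) {
    warning(sprintf("%s %s/%s: only %d trials (minimum %d)", epochs$subject,
                    epochs$experiment, epochs$condition, d[1],
                    preproc$min_trials))
  }
  erp_trace(avg, epochs$subject, epochs$group, epochs$experiment,
            epochs$condition, n_trials = d[1], srate = epochs$srate,
            times = epochs$times, low_trials = low)
}

#' Construct a dERP trace
#' @param data channels x samples matrix (uV).
#' @param subject,group,experiment metadata.
#' @param n_reversal,n_stability trial counts of the source ERPs.
#' @param srate sampling rate (Hz).
#' @param times time axis (ms).
#' @return An object of class `derp_trace`.
#' @export
derp_trace <- function(data, subject, group, experiment, n_reversal,
                       n_stability, srate, times) {
  stopifnot(is.matrix(data), !is.null(rownames(data)),
            length(times) == ncol(data))
  structure(list(data = data, subject = subject, group = group,
                 experiment = experiment, n_reversal = n_reversal,
                 n_stability = n_stability, srate = srate,
                 times = as.numeric(times)),
            class = "derp_trace")
}

#' @export
print.derp_trace <- function(x, ...) {
  cat(sprintf("<derp_trace> %s %s/%s: %d channels x %d samples (rev n = %d, stab n = %d)\n",
              x$subject, x$group, x$experiment, nrow(x$data), ncol(x$data),
              x$n_reversal, x$n_stability))
  invisible(x)
}

#' Reversal-minus-stability difference ERP
#'
#' @param reversal,stability [erp_trace]s of the same subject, experiment
#'   and shape.
#' @return A [derp_trace] with `data = reversal$data - stability$data`.
#' @export
compute_derp <- function(reversal, stability) {
  stopifnot(inherits(reversal, "erp_trace"), inherits(stability, "erp_trace"))
  if (reversal$condition != "reversal" || stability$condition != "stability") {
    stop("arguments must be a reversal and a stability ERP, in that order")
  }
  if (!identical(reversal$subject, stability$subject) ||
      !identical(reversal$experiment, stability$experiment)) {
    stop("ERPs must come from the same subject and experiment")
  }
  if (!identical(dim(reversal$data), dim(stability$data)) ||
      !identical(rownames(reversal$data), rownames(stability$data)) ||
      !isTRUE(all.equal(reversal$times, stability$times))) {
    stop("ERPs must have identical shape, channels and time axis")
  }
  derp_trace(reversal$data - stability$data, reversal$subject,
             reversal$group, reversal$experiment,
             n_reversal = reversal$n_trials, n_stability = stability$n_trials,
             srate = reversal$srate, times = reversal$times)
}

#' Grand mean over subject dERPs
#'
#' Unweighted mean (each selected trace contributes equally, regardless of
#' its trial counts).
#'
#' @param derps list of [derp_trace] objects.
#' @param group optional group selector (`"meditator"`/`"non_meditator"`;
#'   NULL = all).
#' @param experiment optional experiment selector (NULL = all).
#' @return channels x samples matrix with a `times` attribute and an `n`
#'   attribute (number of traces averaged).
#' @export
grand_mean <- function(derps, group = NULL, experiment = NULL) {
  sel <- vapply(derps, function(d) {
    (is.null(group) || d$group == group) &&
      (is.null(experiment) || d$experiment == experiment)
  }, logical(1))
  if (!any(sel)) stop("no dERP traces match the selection")
  picked <- derps[sel]
  acc <- picked[[1]]$data
  if (length(picked) > 1) {
    for (d in picked[-1]) acc <- acc + d$data
  }
  out <- acc / length(picked)
  attr(out, "times") <- picked[[1]]$times
  attr(out, "n") <- length(picked)
  out
}

#' Write an ERP or dERP trace (binary array + JSON sidecar)
#'
#' Same container scheme as [write_epochs()]: float64 samples in
#' `<prefix>.dat`, metadata in `<prefix>.json`.
#'
#' @param trace an [erp_trace] or [derp_trace].
#' @param prefix output path prefix.
#' @return The prefix, invisibly.
#' @export
write_trace <- function(trace, prefix) {
  stopifnot(inherits(trace, "erp_trace") || inherits(trace, "derp_trace"))
  meta <- unclass(trace)
  meta$data <- NULL
  meta$.class <- class(trace)[1]
  meta$channels <- rownames(trace$data)
  meta$dim <- dim(trace$data)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(paste0(prefix, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(trace$data), con, size = 8, endian = "little")
  invisible(prefix)
}

#' Read a trace written by [write_trace()]
#' @param prefix path prefix.
#' @return An [erp_trace] or [derp_trace].
#' @export
read_trace <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  con <- file(paste0(prefix, ".dat"), "rb")
  on.exit(close(con))
  x <- readBin(con, "double", n = prod(meta$dim), size = 8, endian = "little")
  if (length(x) != prod(meta$dim)) stop("truncated trace data file: ", prefix)
  data <- matrix(x, meta$dim[1], meta$dim[2],
                 dimnames = list(meta$channels, NULL))
  if (meta$.class == "erp_trace") {
    erp_trace(data, meta$subject, meta$group, meta$experiment, meta$condition,
              meta$n_trials, meta$srate, meta$times,
              low_trials = isTRUE(meta$low_trials))
  } else {
    derp_trace(data, meta$subject, meta$group, meta$experiment,
               meta$n_reversal, meta$n_stability, meta$srate, meta$times)
  }
}
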