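#' Component presence testing and ROI peak measurement
#'
#' A component counts as present (confirmatory criterion) when, at at least
#' one ROI electrode, the running one-sample t-test of the subjects' dERP
#' amplitudes against zero stays below alpha = 0.01 for at least 10
#' successive samples (20 ms at 500 Hz) inside the temporal ROI.  The
#' exploratory variant additionally requires qualifying runs at two
#' neighbouring electrodes whose runs overlap in time by at least one
#' sample.  Peaks are the largest strict interior local extremum of the ROI
#' polarity; if the window contains no such extremum, the amplitude falls
#' back to the window mean and the latency is undefined.
#'
#' @name component_analysis
NULL

# subjects x samples matrix of dERP values at one electrode within a window
.derp_window_matrix <- function(derps, electrode, window_ms) {
  stopifnot(length(derps) >= 1)
  times <- derps[[1]]$times
  sel <- which(times >= window_ms[1] & times <= window_ms[2])
  if (!length(sel)) stop("window contains no samples")
  m <- t(vapply(derps, function(d) {
    if (!electrode %in% rownames(d$data)) {
      stop("electrode ", electrode, " not present in dERP trace")
    }
    d$data[electrode, sel]
  }, numeric(length(sel))))
  list(m = m, times = times[sel], idx = sel)
}

#' Running one-sample t-tests of dERPs against zero
#'
#' At each sample inside the window, the subjects' dERP amplitudes at the
#' given electrode are tested against zero (two-tailed by default).  With
#' zero across-subject variance the p-value degenerates: 0 if the mean is
#' nonzero, 1 otherwise, with a degeneracy flag.
#'
#' @param derps list of per-subject [derp_trace]s (one group x experiment
#'   cell; at least 3).
#' @param electrode electrode label.
#' @param window_ms two-element window in ms.
#' @param tail `"two"` (default) or `"one"` (one-tailed in the direction of
#'   the observed mean is not meaningful for a presence test, so the
#'   one-tailed variant halves the two-tailed p).
#' @return List with `times`, `t`, `p`, `degenerate` (logical), `n`.
#' @export
running_ttests <- function(derps, electrode, window_ms, tail = c("two", "one")) {
  tail <- match.arg(tail)
  if (length(derps) < 3) stop("need at least 3 subjects for running t-tests")
  w <- .derp_window_matrix(derps, electrode, window_ms)
  n <- nrow(w$m)
  mu <- colMeans(w$m)
  s <- sqrt(colSums(sweep(w$m, 2, mu)^2) / (n - 1))
  degenerate <- s == 0
  tval <- ifelse(degenerate, 0, mu / (s / sqrt(n)))
  p <- 2 * stats::pt(-abs(tval), df = n - 1)
  if (tail == "one") p <- p / 2
  p[degenerate] <- ifelse(mu[degenerate] != 0, 0, 1)
  tval[degenerate & mu != 0] <- Inf * sign(mu[degenerate & mu != 0])
  list(times = w$times, t = tval, p = p, degenerate = degenerate, n = n)
}

#' Find qualifying sub-alpha runs in a p-value series
#'
#' Maximal consecutive stretches with `p < alpha` of length at least
#' `min_run_samples`.
#'
#' @param p numeric vector of p-values.
#' @param times time axis (ms) matching `p`.
#' @param alpha significance threshold (default 0.01; strict inequality).
#' @param min_run_samples minimum run length in samples (default 10,
#'   i.e. 20 ms at 500 Hz).
#' @return data.frame with columns `start_ms`, `end_ms`, `start_idx`,
#'   `end_idx`, `length` (zero rows when no run qualifies).
#' @export
find_runs <- function(p, times, alpha = 0.01, min_run_samples = 10) {
  stopifnot(length(p) == length(times), min_run_samples >= 1)
  r <- rle(p < alpha)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  qual <- which(r$values & r$lengths >= min_run_samples)
  data.frame(start_ms = times[starts[qual]], end_ms = times[ends[qual]],
             start_idx = starts[qual], end_idx = ends[qual],
             length = r$lengths[qual])
}

.presence_result <- function(component, group, experiment, variant,
                             electrodes, p_series, runs, met, pairs = NULL) {
  structure(list(component = component, group = group,
                 experiment = experiment, variant = variant,
                 electrodes = electrodes, p_series = p_series, runs = runs,
                 met = met, pairs = pairs),
            class = "presence_result")
}

#' @export
print.presence_result <- function(x, ...) {
  nr <- sum(vapply(x$runs, nrow, integer(1)))
  cat(sprintf("<presence_result> %s [%s] %s/%s: %s (%d qualifying run%s)\n",
              x$component, x$variant, x$group, x$experiment,
              if (x$met) "PRESENT" else "not present", nr,
              if (nr == 1) "" else "s"))
  invisible(x)
}

#' Confirmatory component-presence criterion
#'
#' The component is present iff at least one ROI electrode shows a
#' qualifying run (p < alpha for >= `min_run_samples` successive samples
#' within the temporal ROI).
#'
#' @param derps list of per-subject [derp_trace]s from one group x
#'   experiment cell.
#' @param roi a [roi_spec].
#' @param alpha significance threshold (default 0.01).
#' @param min_run_samples minimum run length (default 10 samples).
#' @param tail passed to [running_ttests()].
#' @return A `presence_result`.
#' @export
presence_confirmatory <- function(derps, roi, alpha = 0.01,
                                  min_run_samples = 10, tail = "two") {
  stopifnot(inherits(roi, "roi_spec"))
  win <- c(roi$start_ms, roi$end_ms)
  p_series <- list(); runs <- list()
  for (el in roi$electrodes) {
    tt <- running_ttests(derps, el, win, tail = tail)
    p_series[[el]] <- tt
    runs[[el]] <- find_runs(tt$p, tt$times, alpha, min_run_samples)
  }
  met <- any(vapply(runs, nrow, integer(1)) > 0)
  .presence_result(roi$name, derps[[1]]$group, derps[[1]]$experiment,
                   "confirmatory", roi$electrodes, p_series, runs, met)
}

#' Exploratory component-presence criterion
#'
#' The criterion is met iff there exist two neighbouring electrodes (per
#' montage adjacency) that both show qualifying runs overlapping in time by
#' at least one sample.
#'
#' @inheritParams presence_confirmatory
#' @param montage a [montage] (supplies the adjacency).
#' @param window_ms temporal window scanned, in ms.
#' @param electrodes electrode subset scanned (must be in the montage).
#' @param component name used in the result (default "scan").
#' @return A `presence_result`; `pairs` lists the qualifying electrode
#'   pairs with the overlap window.
#' @export
presence_exploratory <- function(derps, montage, window_ms, electrodes,
                                 alpha = 0.01, min_run_samples = 10,
                                 tail = "two", component = "scan") {
  stopifnot(inherits(montage, "montage"))
  bad <- setdiff(electrodes, montage$labels)
  if (length(bad)) stop("electrodes outside montage: ", paste(bad, collapse = ", "))
  p_series <- list(); runs <- list()
  for (el in electrodes) {
    tt <- running_ttests(derps, el, window_ms, tail = tail)
    p_series[[el]] <- tt
    runs[[el]] <- find_runs(tt$p, tt$times, alpha, min_run_samples)
  }
  pairs <- list()
  adj <- montage$adjacency
  for (k in seq_len(nrow(adj))) {
    a <- adj$a[k]; b <- adj$b[k]
    if (!(a %in% electrodes && b %in% electrodes)) next
    ra <- runs[[a]]; rb <- runs[[b]]
    if (!nrow(ra) || !nrow(rb)) next
    for (i in seq_len(nrow(ra))) for (j in seq_len(nrow(rb))) {
      lo <- max(ra$start_idx[i], rb$start_idx[j])
      hi <- min(ra$end_idx[i], rb$end_idx[j])
      if (lo <= hi) {
        pairs[[length(pairs) + 1]] <- data.frame(
          a = a, b = b,
          overlap_start_ms = p_series[[a]]$times[lo],
          overlap_end_ms = p_series[[a]]$times[hi],
          stringsAsFactors = FALSE)
      }
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else NULL
  .presence_result(component, derps[[1]]$group, derps[[1]]$experiment,
                   "exploratory", electrodes, p_series, runs,
                   met = !is.null(pairs), pairs = pairs)
}

#' Pick the ROI peak of a single-channel trace
#'
#' Among interior samples of the window that are strict local extrema of
#' the ROI polarity (strictly greater/less than both immediate
#' neighbours; window endpoints are never peaks), returns the one with the
#' largest amplitude in the polarity direction; ties break to the earliest
#' latency.  If the window contains no such extremum, the amplitude falls
#' back to the mean over the whole window, the latency is `NA` and the
#' fallback flag is set.  Amplitudes are measured as-is (polarity is not
#' enforced on the returned value).
#'
#' @param x numeric vector (one channel's dERP trace).
#' @param times time axis (ms) matching `x`.
#' @param window_ms two-element window in ms.
#' @param polarity `"positive"` (look for maxima) or `"negative"` (minima).
#' @return List with `amplitude_uv`, `latency_ms` (NA on fallback) and
#'   `fallback`.
#' @export
pick_peak <- function(x, times, window_ms, polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  stopifnot(length(x) == length(times))
  sel <- which(times >= window_ms[1] & times <= window_ms[2])
  if (length(sel) < 1) stop("window contains no samples")
  w <- x[sel]
  n <- length(w)
  if (n >= 3) {
    i <- 2:(n - 1)
    is_ext <- if (polarity == "positive") {
      w[i] > w[i - 1] & w[i] > w[i + 1]
    } else {
      w[i] < w[i - 1] & w[i] < w[i + 1]
    }
    ext <- i[is_ext]
  } else {
    ext <- integer(0)
  }
  if (!length(ext)) {
    return(list(amplitude_uv = mean(w), latency_ms = NA_real_, fallback = TRUE))
  }
  val <- w[ext]
  best <- if (polarity == "positive") ext[which.max(val)] else ext[which.min(val)]
  list(amplitude_uv = w[best], latency_ms = times[sel][best], fallback = FALSE)
}

#' Measure a component for every subject and ROI electrode
#'
#' Applies [pick_peak()] to each subject's dERP at each ROI electrode.
#'
#' @param derps list of per-subject [derp_trace]s (may span both
#'   experiments; each trace yields its own rows).
#' @param roi a [roi_spec].
#' @return data.frame with one row per trace x electrode: `subject`,
#'   `group`, `experiment`, `electrode`, `component`, `amplitude_uv`,
#'   `latency_ms`, `fallback`.
#' @export
measure_component <- function(derps, roi) {
  stopifnot(inherits(roi, "roi_spec"))
  win <- c(roi$start_ms, roi$end_ms)
  rows <- lapply(derps, function(d) {
    do.call(rbind, lapply(roi$electrodes, function(el) {
      pk <- pick_peak(d$data[el, ], d$times, win, roi$polarity)
      data.frame(subject = d$subject, group = d$group,
                 experiment = d$experiment, electrode = el,
                 component = roi$name, amplitude_uv = pk$amplitude_uv,
                 latency_ms = pk$latency_ms, fallback = pk$fallback,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
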