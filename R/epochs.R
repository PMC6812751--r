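#' Trial-level stimulus-locked EEG epochs
#'
#' An `epoch_set` holds one subject x experiment x condition block of
#' stimulus-locked EEG trials as a numeric array of dimension
#' trials x channels x samples (microvolts), together with a time axis in
#' milliseconds anchored at stimulus onset.
#'
#' @param data numeric array, trials x channels x samples, in microvolts.
#'   Channel dimnames must be electrode labels.
#' @param subject subject identifier.
#' @param group `"meditator"` or `"non_meditator"`.
#' @param experiment `"passive"` or `"hold"`.
#' @param condition `"reversal"` or `"stability"`.
#' @param srate sampling rate in Hz (default 500).
#' @param times numeric vector of sample times in ms (0 = stimulus onset);
#'   length must equal `dim(data)[3]`.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, subject, group, experiment, condition,
                      srate = 500, times) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (length(times) != dim(data)[3]) stop("times must match sample dimension")
  if (is.null(dimnames(data)[[2]])) stop("channel dimension must be named")
  group <- match.arg(group, c("meditator", "non_meditator"))
  experiment <- match.arg(experiment, c("passive", "hold"))
  condition <- match.arg(condition, c("reversal", "stability"))
  structure(list(data = data, subject = subject, group = group,
                 experiment = experiment, condition = condition,
                 srate = srate, times = as.numeric(times)),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %s %s/%s/%s: %d trials x %d channels x %d samples @ %g Hz\n",
              x$subject, x$group, x$experiment, x$condition,
              d[1], d[2], d[3], x$srate))
  invisible(x)
}

#' Number of trials in an epoch set
#' @param epochs an [epoch_set].
#' @return Integer trial count.
#' @export
n_trials <- function(epochs) dim(epochs$data)[1]

#' Channel labels of an epoch set or ERP trace
#' @param x an [epoch_set], `erp_trace` or `derp_trace`.
#' @return Character vector of electrode labels.
#' @export
channel_labels <- function(x) {
  if (inherits(x, "epoch_set")) dimnames(x$data)[[2]] else rownames(x$data)
}

#' Write an epoch set to disk (binary array + JSON sidecar)
#'
#' The samples are stored as little-endian float64 in `<prefix>.dat`
#' (trial-major order) and the metadata (subject, group, experiment,
#' condition, sampling rate, time axis, channel labels, dimensions) in
#' `<prefix>.json`.
#'
#' @param epochs an [epoch_set].
#' @param prefix output path prefix.
#' @return The prefix, invisibly.
#' @export
write_epochs <- function(epochs, prefix) {
  stopifnot(inherits(epochs, "epoch_set"))
  meta <- list(subject = epochs$subject, group = epochs$group,
               experiment = epochs$experiment, condition = epochs$condition,
               srate = epochs$srate, times = epochs$times,
               channels = channel_labels(epochs), dim = dim(epochs$data))
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(paste0(prefix, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(epochs$data), con, size = 8, endian = "little")
  invisible(prefix)
}

#' Read an epoch set written by [write_epochs()]
#' @param prefix path prefix.
#' @return An [epoch_set].
#' @export
read_epochs <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  n <- prod(meta$dim)
  con <- file(paste0(prefix, ".dat"), "rb")
  on.exit(close(con))
  x <- readBin(con, "double", n = n, size = 8, endian = "little")
  if (length(x) != n) stop("truncated epoch data file: ", prefix, ".dat")
  data <- array(x, dim = meta$dim,
                dimnames = list(NULL, meta$channels, NULL))
  epoch_set(data, meta$subject, meta$group, meta$experiment, meta$condition,
            srate = meta$srate, times = meta$times)
}
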