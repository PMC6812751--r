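#' BrainVision recordings (header + marker + binary data triplet)
#'
#' Minimal reader/writer for the BrainVision Core format as produced by
#' Brain Products amplifiers: an INI-style `.vhdr` header, a `.vmrk` marker
#' file, and a raw binary `.eeg` data file.  Supported layout:
#' multiplexed orientation with IEEE_FLOAT_32 or INT_16 binary format
#' (INT_16 is scaled by the per-channel resolution).  Units are
#' microvolts.
#'
#' @name brainvision
NULL

.bv_parse_ini <- function(lines) {
  out <- list(); section <- ""
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      out[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1])
      out[[section]][[key]] <- trimws(paste(kv[-1], collapse = "="))
    }
  }
  out
}

#' Read a BrainVision recording
#'
#' Parses the header, the marker stream and the binary samples into a
#' continuous-recording object.
#'
#' @param header_path path to the `.vhdr` header file; the marker and data
#'   files are resolved relative to it.
#' @return A list of class `bv_recording` with `data` (channels x samples
#'   matrix, uV, rownames = labels), `srate` (Hz), and `markers`
#'   (data.frame with `type`, `description`, `position` (1-based sample)).
#' @export
read_brainvision <- function(header_path) {
  if (!file.exists(header_path)) stop("header file not found: ", header_path)
  hdr <- .bv_parse_ini(readLines(header_path, warn = FALSE))
  ci <- hdr[["Common Infos"]]
  if (is.null(ci)) stop("header missing [Common Infos] section")
  for (fld in c("DataFile", "MarkerFile", "NumberOfChannels", "SamplingInterval")) {
    if (is.null(ci[[fld]])) stop("header missing field: ", fld)
  }
  if (!is.null(ci$DataFormat) && toupper(ci$DataFormat) != "BINARY") {
    stop("unsupported DataFormat: ", ci$DataFormat)
  }
  if (!is.null(ci$DataOrientation) &&
      toupper(ci$DataOrientation) != "MULTIPLEXED") {
    stop("unsupported DataOrientation: ", ci$DataOrientation)
  }
  nchan <- as.integer(ci$NumberOfChannels)
  srate <- 1e6 / as.numeric(ci$SamplingInterval)  # SamplingInterval is in us
  binfmt <- toupper(hdr[["Binary Infos"]]$BinaryFormat %||% "IEEE_FLOAT_32")
  chinfo <- hdr[["Channel Infos"]]
  if (is.null(chinfo) || length(chinfo) != nchan) {
    stop("header field NumberOfChannels (", nchan,
         ") inconsistent with [Channel Infos] (", length(chinfo), " entries)")
  }
  labels <- character(nchan); resolution <- rep(1, nchan)
  for (k in seq_len(nchan)) {
    parts <- strsplit(chinfo[[paste0("Ch", k)]], ",", fixed = TRUE)[[1]]
    labels[k] <- parts[1]
    if (length(parts) >= 3 && nzchar(parts[3])) {
      resolution[k] <- as.numeric(parts[3])
    }
  }
  dir <- dirname(header_path)
  data_path <- file.path(dir, ci$DataFile)
  marker_path <- file.path(dir, ci$MarkerFile)
  if (!file.exists(data_path)) stop("data file not found: ", data_path)
  if (!file.exists(marker_path)) stop("marker file not found: ", marker_path)

  bytes <- file.size(data_path)
  elsize <- if (binfmt == "IEEE_FLOAT_32") 4L else if (binfmt == "INT_16") 2L
            else stop("unsupported BinaryFormat: ", binfmt)
  if (bytes %% (elsize * nchan) != 0) {
    stop("truncated binary data file: size ", bytes,
         " not a multiple of frame size ", elsize * nchan)
  }
  n_samples <- bytes / (elsize * nchan)
  con <- file(data_path, "rb")
  on.exit(close(con))
  raw_vals <- if (binfmt == "IEEE_FLOAT_32") {
    readBin(con, "double", n = nchan * n_samples, size = 4, endian = "little")
  } else {
    readBin(con, "integer", n = nchan * n_samples, size = 2, signed = TRUE,
            endian = "little")
  }
  data <- matrix(raw_vals, nrow = nchan)  # multiplexed: channel fastest
  if (binfmt == "INT_16") data <- data * resolution
  rownames(data) <- labels

  mk <- .bv_parse_ini(readLines(marker_path, warn = FALSE))[["Marker Infos"]]
  markers <- data.frame(type = character(0), description = character(0),
                        position = integer(0), stringsAsFactors = FALSE)
  if (!is.null(mk)) {
    rows <- lapply(mk, function(v) {
      parts <- strsplit(v, ",", fixed = TRUE)[[1]]
      data.frame(type = parts[1], description = parts[2],
                 position = as.integer(parts[3]), stringsAsFactors = FALSE)
    })
    markers <- do.call(rbind, rows)
    rownames(markers) <- NULL
    if (any(markers$position < 1 | markers$position > n_samples)) {
      stop("marker position outside the recording")
    }
  }
  structure(list(data = data, srate = srate, markers = markers),
            class = "bv_recording")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a BrainVision recording (for round trips and testing)
#'
#' @param data channels x samples matrix (uV) with rownames.
#' @param srate sampling rate in Hz.
#' @param markers data.frame with `type`, `description`, `position`.
#' @param prefix output path prefix (writes `<prefix>.vhdr`,
#'   `<prefix>.vmrk`, `<prefix>.eeg`).
#' @return The header path, invisibly.
#' @export
write_brainvision <- function(data, srate, markers, prefix) {
  stopifnot(is.matrix(data), !is.null(rownames(data)))
  base <- basename(prefix)
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nrow(data)),
    paste0("SamplingInterval=", format(1e6 / srate, scientific = FALSE)),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1", seq_len(nrow(data)), rownames(data))
  )
  writeLines(hdr, paste0(prefix, ".vhdr"))
  mrk <- c(
    "Brain Vision Data Exchange Marker File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", base, ".eeg"),
    "[Marker Infos]",
    if (nrow(markers)) {
      sprintf("Mk%d=%s,%s,%d,1,0", seq_len(nrow(markers)), markers$type,
              markers$description, markers$position)
    }
  )
  writeLines(mrk, paste0(prefix, ".vmrk"))
  con <- file(paste0(prefix, ".eeg"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(data), con, size = 4, endian = "little")
  invisible(paste0(prefix, ".vhdr"))
}

#' Cut stimulus-locked epochs from a continuous recording
#'
#' Epochs are cut around stimulus markers whose description appears in
#' `condition_map`; markers too close to the recording edges for the full
#' window are skipped.
#'
#' @param rec a `bv_recording` from [read_brainvision()].
#' @param condition_map named character vector mapping marker descriptions
#'   to conditions, e.g. `c("S 10" = "reversal", "S 20" = "stability")`.
#' @param subject,group,experiment metadata for the resulting epoch sets.
#' @param window_ms epoch window in ms relative to the marker.
#' @return Named list of [epoch_set]s, one per condition present.
#' @export
epochs_from_continuous <- function(rec, condition_map, subject, group,
                                   experiment, window_ms = c(-100, 800)) {
  stopifnot(inherits(rec, "bv_recording"))
  S <- ncol(rec$data)
  pre <- round(-window_ms[1] * rec$srate / 1000)
  post <- round(window_ms[2] * rec$srate / 1000)
  times <- seq(-pre, post) * 1000 / rec$srate
  stim <- rec$markers[rec$markers$description %in% names(condition_map), ]
  out <- list()
  for (cond in unique(condition_map)) {
    descs <- names(condition_map)[condition_map == cond]
    pos <- stim$position[stim$description %in% descs]
    pos <- pos[pos - pre >= 1 & pos + post <= S]
    if (!length(pos)) next
    arr <- array(NA_real_, c(length(pos), nrow(rec$data), pre + post + 1),
                 dimnames = list(NULL, rownames(rec$data), NULL))
    for (i in seq_along(pos)) {
      arr[i, , ] <- rec$data[, (pos[i] - pre):(pos[i] + post)]
    }
    out[[cond]] <- epoch_set(arr, subject, group, experiment, cond,
                             srate = rec$srate, times = times)
  }
  out
}
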