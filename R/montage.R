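#' Electrode montage and spatio-temporal regions of interest
#'
#' The analysis operates on a fixed 32-channel extended 10-20 montage that
#' includes the mastoid-adjacent reference electrodes TP9 and TP10 and the
#' frontopolar midline electrode Fpz.  Electrode adjacency is defined by a
#' static shipped table following a conventional nearest-neighbour scheme
#' (lateral and anterior-posterior neighbours within one ring/step); the 2D
#' positions are a standard polar projection onto the unit disc and are used
#' for plotting only, never for statistics.
#'
#' @name montage
NULL

.onseterp_extdata <- function(file) {
  path <- system.file("extdata", file, package = "onseterp")
  if (!nzchar(path)) stop("shipped data file not found: ", file)
  path
}

#' Construct a montage object
#'
#' @param positions data.frame with columns `label`, `x`, `y` (unit-disc
#'   coordinates, x towards the right ear, y towards the nasion).
#' @param adjacency data.frame with columns `a`, `b`, one row per unordered
#'   neighbour pair.  Stored symmetrically.
#' @return An object of class `montage` with elements `labels`, `positions`
#'   and `adjacency`.
#' @export
montage <- function(positions, adjacency) {
  stopifnot(is.data.frame(positions), all(c("label", "x", "y") %in% names(positions)))
  stopifnot(is.data.frame(adjacency), all(c("a", "b") %in% names(adjacency)))
  labels <- as.character(positions$label)
  if (anyDuplicated(labels)) stop("electrode labels must be unique")
  bad <- setdiff(unique(c(adjacency$a, adjacency$b)), labels)
  if (length(bad)) stop("adjacency refers to unknown electrodes: ", paste(bad, collapse = ", "))
  if (any(adjacency$a == adjacency$b)) stop("adjacency must be irreflexive")
  # symmetrize and deduplicate
  pairs <- unique(data.frame(
    a = pmin(as.character(adjacency$a), as.character(adjacency$b)),
    b = pmax(as.character(adjacency$a), as.character(adjacency$b)),
    stringsAsFactors = FALSE
  ))
  deg <- table(factor(c(pairs$a, pairs$b), levels = labels))
  if (any(deg == 0)) {
    stop("electrodes without neighbours: ", paste(labels[deg == 0], collapse = ", "))
  }
  out <- list(labels = labels,
              positions = data.frame(label = labels, x = positions$x,
                                     y = positions$y, stringsAsFactors = FALSE),
              adjacency = pairs)
  class(out) <- "montage"
  out
}

#' The standard 32-channel extended 10-20 montage
#'
#' Returns the fixed montage used throughout the pipeline: 32 electrodes of
#' the extended 10-20 system (including TP9, TP10 and Fpz) with unit-disc
#' positions and the shipped nearest-neighbour adjacency table.
#'
#' @return A [montage] object with 32 electrodes.
#' @examples
#' m <- standard_montage_32()
#' length(m$labels)
#' neighbors(m, "Oz")
#' @export
standard_montage_32 <- function() {
  pos <- utils::read.delim(.onseterp_extdata("montage32_electrodes.tsv"),
                           stringsAsFactors = FALSE)
  adj <- utils::read.delim(.onseterp_extdata("montage32_adjacency.tsv"),
                           stringsAsFactors = FALSE)
  m <- montage(pos, adj)
  if (length(m$labels) != 32L) stop("internal: montage must have 32 electrodes")
  m
}

#' Neighbours of an electrode
#'
#' @param montage a [montage] object.
#' @param electrode electrode label.
#' @return Character vector of neighbouring electrode labels.
#' @export
neighbors <- function(montage, electrode) {
  stopifnot(inherits(montage, "montage"))
  if (!electrode %in% montage$labels) {
    stop("unknown electrode label: ", electrode)
  }
  adj <- montage$adjacency
  sort(unique(c(adj$b[adj$a == electrode], adj$a[adj$b == electrode])))
}

#' Test whether two electrodes are neighbours
#' @inheritParams neighbors
#' @param a,b electrode labels.
#' @return Logical scalar.
#' @export
are_neighbors <- function(montage, a, b) {
  b %in% neighbors(montage, a)
}

#' @export
print.montage <- function(x, ...) {
  cat("<montage> ", length(x$labels), " electrodes, ",
      nrow(x$adjacency), " neighbour pairs\n", sep = "")
  cat(" ", paste(x$labels, collapse = " "), "\n")
  invisible(x)
}

#' Construct a spatio-temporal region of interest
#'
#' A RoiSpec names an ERP component and gives the electrode set, the
#' post-onset time window in milliseconds, and the expected polarity of the
#' deflection.
#'
#' @param name component name (e.g. "RP", "RN", "PP", "FN").
#' @param electrodes character vector of electrode labels.
#' @param start_ms,end_ms window bounds in ms post stimulus onset,
#'   `0 <= start_ms < end_ms`.
#' @param polarity `"positive"` or `"negative"`.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(name, electrodes, start_ms, end_ms, polarity) {
  polarity <- match.arg(polarity, c("positive", "negative"))
  stopifnot(is.character(electrodes), length(electrodes) >= 1)
  if (!(is.numeric(start_ms) && is.numeric(end_ms) &&
        start_ms >= 0 && start_ms < end_ms)) {
    stop("need 0 <= start_ms < end_ms")
  }
  structure(list(name = name, electrodes = electrodes,
                 start_ms = start_ms, end_ms = end_ms, polarity = polarity),
            class = "roi_spec")
}

#' @export
print.roi_spec <- function(x, ...) {
  cat(sprintf("<roi_spec> %s: %g-%g ms, %s, [%s]\n", x$name, x$start_ms,
              x$end_ms, x$polarity, paste(x$electrodes, collapse = ", ")))
  invisible(x)
}

#' The built-in component ROIs
#'
#' The four spatio-temporal regions of interest of the analysis: the
#' Reversal Positivity (RP, 80-250 ms, occipito-parietal, positive), the
#' Reversal Negativity (RN, 150-350 ms, same electrodes, negative), the
#' Parietal/Frontopolar Positivity (PP, 250-700 ms, Pz/Cz/Fpz, positive)
#' and the anterior Frontal Negativity (FN, 80-250 ms, negative).
#'
#' @param path optional path to an ROI table overriding the shipped one
#'   (TSV with columns name, electrodes (comma separated), start_ms,
#'   end_ms, polarity).
#' @return Named list of [roi_spec] objects.
#' @examples
#' builtin_rois()$RN$start_ms
#' @export
builtin_rois <- function(path = NULL) {
  if (is.null(path)) path <- .onseterp_extdata("rois.tsv")
  read_rois(path)
}

#' Read an ROI table from a TSV file
#' @param path file path (columns name, electrodes, start_ms, end_ms, polarity).
#' @return Named list of [roi_spec] objects.
#' @export
read_rois <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(tab)), function(i) {
    roi_spec(tab$name[i],
             trimws(strsplit(tab$electrodes[i], ",")[[1]]),
             tab$start_ms[i], tab$end_ms[i], tab$polarity[i])
  })
  names(out) <- tab$name
  out
}

#' Write ROIs to a TSV file
#' @param rois list of [roi_spec] objects.
#' @param path output file path.
#' @export
write_rois <- function(rois, path) {
  tab <- do.call(rbind, lapply(rois, function(r) {
    data.frame(name = r$name, electrodes = paste(r$electrodes, collapse = ","),
               start_ms = r$start_ms, end_ms = r$end_ms, polarity = r$polarity,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a montage to a pair of TSV files
#'
#' @param montage a [montage] object.
#' @param electrodes_path,adjacency_path output file paths.
#' @export
write_montage <- function(montage, electrodes_path, adjacency_path) {
  stopifnot(inherits(montage, "montage"))
  utils::write.table(montage$positions, electrodes_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(montage$adjacency, adjacency_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Read a montage from a pair of TSV files
#' @param electrodes_path,adjacency_path file paths as written by
#'   [write_montage()].
#' @return A [montage] object.
#' @export
read_montage <- function(electrodes_path, adjacency_path) {
  montage(utils::read.delim(electrodes_path, stringsAsFactors = FALSE),
          utils::read.delim(adjacency_path, stringsAsFactors = FALSE))
}
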