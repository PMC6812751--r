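#' Generic source-statistics stage on vertex point clouds
#'
#' Operates on arbitrary 3D point clouds carrying per-subject contrast
#' values (synthetic vertex fields stand in for a cortical mesh): one
#' two-tailed one-sample t-test per vertex, thresholding at a predefined
#' alpha, and grouping of the suprathreshold vertices by repeated k-means
#' with elbow selection per hemisphere.  Hemispheres are split at x = 0
#' (x <= 0 is left).  Only vertex coordinates are clustered, optionally
#' weighted.
#'
#' @name source_clustering
NULL

#' Construct a vertex field
#'
#' @param coords numeric matrix n x 3 of vertex coordinates (mm; the sign
#'   of x encodes the hemisphere, x <= 0 left).
#' @param values numeric matrix n x m of per-subject contrast values (one
#'   column per subject, m >= 2).
#' @return An object of class `vertex_field`.
#' @export
vertex_field <- function(coords, values) {
  coords <- as.matrix(coords); values <- as.matrix(values)
  if (ncol(coords) != 3) stop("coords must be n x 3")
  if (nrow(values) != nrow(coords)) stop("one value row per vertex required")
  if (ncol(values) < 2) stop("need >= 2 subjects for t-tests")
  structure(list(coords = coords, values = values), class = "vertex_field")
}

#' Per-vertex one-sample t-tests
#'
#' Two-tailed t-test of each vertex's subject values against zero.  Zero
#' across-subject variance degenerates as in [running_ttests()]: p = 0 if
#' the mean is nonzero, 1 otherwise, with a flag.
#'
#' @param field a [vertex_field].
#' @return data.frame with `t`, `p`, `degenerate` per vertex.
#' @export
vertex_ttest <- function(field) {
  stopifnot(inherits(field, "vertex_field"))
  v <- field$values
  n <- ncol(v)
  mu <- rowMeans(v)
  s <- sqrt(rowSums((v - mu)^2) / (n - 1))
  degenerate <- s == 0
  tval <- ifelse(degenerate, ifelse(mu != 0, Inf, 0) * sign(mu + (mu == 0)),
                 mu / (s / sqrt(n)))
  p <- 2 * stats::pt(-abs(tval), df = n - 1)
  p[degenerate] <- ifelse(mu[degenerate] != 0, 0, 1)
  data.frame(t = tval, p = p, degenerate = degenerate)
}

#' Threshold a statistical map
#'
#' @param t,p per-vertex statistics (as from [vertex_ttest()]).
#' @param alpha threshold in (0, 1); vertices with `p < alpha` are kept.
#' @return Integer vector of suprathreshold vertex indices.
#' @export
threshold_map <- function(t, p, alpha = 0.05) {
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  which(p < alpha)
}

# explained-variance ratio of a k-means partition, relative to the
# uncentred total sum of squares of the coordinates.  With the uncentred
# total, a single compact cluster far from the origin is almost fully
# explained by one centroid, which is what makes the elbow rule pick k = 1
# for one tight cloud.
.explained_uncentred <- function(coords, wss) {
  tss0 <- sum(coords^2)
  if (tss0 == 0) return(1)
  1 - wss / tss0
}

#' Repeated k-means with elbow selection, per hemisphere
#'
#' For each hemisphere (split at x = 0, x <= 0 left), k-means is run for
#' k = 1..`max_k_per_hemisphere` with `reps` random restarts each; the
#' chosen k is the smallest whose explained-variance ratio (one minus the
#' within-cluster sum of squares over the uncentred total sum of squares of
#' the vertex coordinates) reaches `elbow_cutoff`.  If no k reaches the
#' cutoff, the maximum is used; the cluster count per hemisphere therefore
#' never exceeds `max_k_per_hemisphere`.  Deterministic under a fixed seed.
#'
#' @param vertices numeric matrix n x 3 of suprathreshold vertex
#'   coordinates (mm).
#' @param reps number of k-means restarts per k (default 1000).
#' @param elbow_cutoff explained-variance cutoff (default 0.95).
#' @param max_k_per_hemisphere maximum clusters per hemisphere (default 8).
#' @param t,p optional per-vertex statistics carried into the output
#'   (cluster peak = member with largest |t|).
#' @param seed optional integer seed.
#' @return data.frame of class `cluster_result`, one row per cluster:
#'   `hemisphere`, `cluster`, `n_vertices`, `x`, `y`, `z` (centroid),
#'   `peak_t`, `peak_p`; the member indices (into `vertices`) are stored in
#'   the `members` attribute (a list).
#' @export
cluster_sources <- function(vertices, reps = 1000, elbow_cutoff = 0.95,
                            max_k_per_hemisphere = 8, t = NULL, p = NULL,
                            seed = NULL) {
  vertices <- as.matrix(vertices)
  if (!nrow(vertices)) stop("empty suprathreshold vertex set")
  if (!is.null(seed)) set.seed(seed)
  hemi <- ifelse(vertices[, 1] <= 0, "L", "R")
  rows <- list(); members <- list()
  for (h in c("L", "R")) {
    idx <- which(hemi == h)
    if (!length(idx)) next  # empty hemisphere: zero clusters, not an error
    xs <- vertices[idx, , drop = FALSE]
    kmax <- min(max_k_per_hemisphere, nrow(unique(xs)))
    fits <- vector("list", kmax)
    ev <- numeric(kmax)
    for (k in seq_len(kmax)) {
      fits[[k]] <- if (k == 1) {
        ctr <- colMeans(xs)
        list(cluster = rep(1L, nrow(xs)),
             centers = matrix(ctr, 1, 3),
             tot.withinss = sum(sweep(xs, 2, ctr)^2))
      } else {
        stats::kmeans(xs, centers = k, nstart = reps, iter.max = 100)
      }
      ev[k] <- .explained_uncentred(xs, fits[[k]]$tot.withinss)
    }
    k_sel <- if (any(ev >= elbow_cutoff)) min(which(ev >= elbow_cutoff)) else kmax
    fit <- fits[[k_sel]]
    for (k in seq_len(k_sel)) {
      mem <- idx[fit$cluster == k]
      peak_t <- NA_real_; peak_p <- NA_real_
      if (!is.null(t)) {
        j <- mem[which.max(abs(t[mem]))]
        peak_t <- t[j]
        if (!is.null(p)) peak_p <- p[j]
      }
      rows[[length(rows) + 1]] <- data.frame(
        hemisphere = h, cluster = k, n_vertices = length(mem),
        x = fit$centers[k, 1], y = fit$centers[k, 2], z = fit$centers[k, 3],
        peak_t = peak_t, peak_p = peak_p, stringsAsFactors = FALSE)
      members[[length(members) + 1]] <- mem
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "members") <- members
  class(out) <- c("cluster_result", class(out))
  out
}

#' Read a vertex field from a TSV file
#'
#' Expected columns: `x`, `y`, `z`, then one column per subject.
#'
#' @param path file path.
#' @return A [vertex_field].
#' @export
read_vertex_field <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("x", "y", "z") %in% names(tab))) stop("need columns x, y, z")
  vertex_field(as.matrix(tab[, c("x", "y", "z")]),
               as.matrix(tab[, setdiff(names(tab), c("x", "y", "z")), drop = FALSE]))
}

#' Write a vertex field to a TSV file
#' @param field a [vertex_field].
#' @param path output path.
#' @export
write_vertex_field <- function(field, path) {
  stopifnot(inherits(field, "vertex_field"))
  tab <- data.frame(field$coords, field$values)
  names(tab) <- c("x", "y", "z",
                  sprintf("s%02d", seq_len(ncol(field$values))))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
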