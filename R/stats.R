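#' Mixed-design ANOVA, effect sizes and nonparametric post-hocs
#'
#' Peak measures are analysed with a univariate mixed-model
#' sums-of-squares decomposition: between-subject factor GROUP, within
#' subject factors EXPERIMENT and ELECTRODE.  Effect sizes are partial eta
#' squared.  Post-hoc electrode contrasts use paired Wilcoxon signed-rank
#' tests with Bonferroni-Holm step-down correction, reporting corrected and
#' uncorrected p-values side by side.  No sphericity correction is applied
#' by default; Greenhouse-Geisser adjustment is available behind a flag.
#'
#' @name group_stats
NULL

#' Partial eta squared
#'
#' `ss_effect / (ss_effect + ss_error)`.
#'
#' @param ss_effect,ss_error sums of squares (>= 0, not both zero).
#' @return Numeric value in [0, 1].
#' @export
partial_eta_sq <- function(ss_effect, ss_error) {
  if (ss_effect < 0 || ss_error < 0) stop("sums of squares must be >= 0")
  if (ss_effect + ss_error == 0) stop("partial eta squared undefined: both SS zero")
  ss_effect / (ss_effect + ss_error)
}

# orthonormal Helmert-style contrast matrix, k x (k-1)
.ortho_contrasts <- function(k) {
  qr.Q(qr(cbind(1, stats::contr.helmert(k))))[, -1, drop = FALSE]
}

# Greenhouse-Geisser epsilon for one within effect.
# wide: subjects x cells matrix (cells ordered electrode-within-experiment),
# groups: group factor per subject; C: cells x df contrast matrix.
.gg_epsilon <- function(wide, groups, C) {
  centred <- do.call(rbind, lapply(split.data.frame(wide, groups), function(m) {
    sweep(m, 2, colMeans(m))
  }))
  S <- crossprod(centred) / (nrow(wide) - length(unique(groups)))
  M <- t(C) %*% S %*% C
  d <- ncol(C)
  (sum(diag(M))^2) / (d * sum(M^2))
}

#' Mixed-design ANOVA on peak measures
#'
#' Fits the full GROUP x EXPERIMENT x ELECTRODE decomposition with subject
#' as the random blocking factor (strata: subject, subject:experiment,
#' subject:electrode, subject:experiment:electrode).  Latency analyses
#' exclude fallback rows (their latency is undefined); subjects left with
#' incomplete cells are dropped listwise with a message.
#'
#' @param measures data.frame as produced by [measure_component()]
#'   (columns subject, group, experiment, electrode, amplitude_uv,
#'   latency_ms, fallback).
#' @param dv dependent variable, `"amplitude"` or `"latency"`.
#' @param gg if `TRUE`, add Greenhouse-Geisser adjusted columns
#'   (`epsilon`, `p_gg`) for within-subject effects.
#' @return data.frame of class `anova_table`: one row per effect with
#'   `effect`, `df1`, `df2`, `ss_effect`, `ss_error`, `F`, `p`, `pes`
#'   (partial eta squared), plus an attribute `n_dropped` (listwise-deleted
#'   subjects).
#' @export
mixed_anova <- function(measures, dv = c("amplitude", "latency"), gg = FALSE) {
  dv <- match.arg(dv)
  df <- measures
  df$value <- if (dv == "amplitude") df$amplitude_uv else df$latency_ms
  if (dv == "latency") df <- df[!df$fallback & !is.na(df$value), ]
  if (!nrow(df)) stop("no usable rows for dv = ", dv)

  experiments <- sort(unique(df$experiment))
  electrodes <- sort(unique(df$electrode))
  cells_needed <- length(experiments) * length(electrodes)
  counts <- table(df$subject)
  complete <- names(counts)[counts == cells_needed]
  n_dropped <- length(counts) - length(complete)
  if (n_dropped > 0) {
    message(n_dropped, " subject(s) dropped listwise (incomplete cells) for dv = ", dv)
  }
  df <- df[df$subject %in% complete, ]
  groups_per_subj <- unique(df[, c("subject", "group")])
  if (any(table(groups_per_subj$group) < 2)) {
    stop("need at least 2 subjects per group after exclusions")
  }

  df$subject <- factor(df$subject)
  df$group <- factor(df$group)
  df$experiment <- factor(df$experiment, levels = experiments)
  df$electrode <- factor(df$electrode, levels = electrodes)

  fit <- stats::aov(value ~ group * experiment * electrode +
                      Error(subject / (experiment * electrode)), data = df)
  sm <- summary(fit)

  # map each effect to its error stratum
  strata <- list(
    "Error: subject" = c("group"),
    "Error: subject:experiment" = c("experiment", "group:experiment"),
    "Error: subject:electrode" = c("electrode", "group:electrode"),
    "Error: subject:experiment:electrode" =
      c("experiment:electrode", "group:experiment:electrode")
  )
  rows <- list()
  for (stratum in names(strata)) {
    tab <- sm[[stratum]][[1]]
    rn <- trimws(rownames(tab))
    res_i <- match("Residuals", rn)
    ss_err <- tab[res_i, "Sum Sq"]
    df_err <- tab[res_i, "Df"]
    for (eff in strata[[stratum]]) {
      i <- match(eff, rn)
      if (is.na(i)) next
      ss <- tab[i, "Sum Sq"]
      rows[[eff]] <- data.frame(
        effect = toupper(eff), df1 = tab[i, "Df"], df2 = df_err,
        ss_effect = ss, ss_error = ss_err,
        F = tab[i, "F value"], p = tab[i, "Pr(>F)"],
        pes = partial_eta_sq(ss, ss_err),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL

  if (gg) {
    # wide subject x cell matrix, electrode varying fastest
    df$cell <- interaction(df$electrode, df$experiment, lex.order = FALSE)
    wide <- stats::xtabs(value ~ subject + cell, data = df)
    wide <- matrix(wide, nrow(wide), ncol(wide))
    grp <- groups_per_subj$group[match(sort(unique(as.character(df$subject))),
                                       groups_per_subj$subject)]
    kE <- length(experiments); kL <- length(electrodes)
    cE <- .ortho_contrasts(kE); cL <- .ortho_contrasts(kL)
    oE <- matrix(1 / sqrt(kE), kE, 1); oL <- matrix(1 / sqrt(kL), kL, 1)
    Cmats <- list(
      EXPERIMENT = kronecker(cE, oL), `GROUP:EXPERIMENT` = kronecker(cE, oL),
      ELECTRODE = kronecker(oE, cL), `GROUP:ELECTRODE` = kronecker(oE, cL),
      `EXPERIMENT:ELECTRODE` = kronecker(cE, cL),
      `GROUP:EXPERIMENT:ELECTRODE` = kronecker(cE, cL))
    out$epsilon <- NA_real_
    out$p_gg <- NA_real_
    for (eff in names(Cmats)) {
      i <- match(eff, out$effect)
      if (is.na(i)) next
      eps <- .gg_epsilon(wide, grp, Cmats[[eff]])
      out$epsilon[i] <- eps
      out$p_gg[i] <- stats::pf(out$F[i], out$df1[i] * eps, out$df2[i] * eps,
                               lower.tail = FALSE)
    }
  }
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("anova_table", class(out))
  out
}

#' @export
print.anova_table <- function(x, ...) {
  for (i in seq_len(nrow(x))) {
    cat(sprintf("%-28s p = %.4g, F(%d,%d) = %.3g, eta2p = %.3g\n",
                x$effect[i], x$p[i], x$df1[i], x$df2[i], x$F[i], x$pes[i]))
  }
  invisible(x)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-tailed signed-rank test on paired samples; zero differences are
#' dropped first.  The exact null distribution is used for n <= 25 (when
#' free of ties), the normal approximation above.
#'
#' @param a,b equal-length paired numeric vectors.
#' @return List with `statistic` (V), `p`, `n` (nonzero differences) and
#'   `exact`.
#' @export
wilcoxon_posthoc <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[d != 0]
  if (!length(d)) stop("all differences are zero: no information")
  if (length(d) < 5) stop("fewer than 5 nonzero differences")
  exact <- length(d) <= 25
  wt <- suppressWarnings(stats::wilcox.test(d, exact = exact))
  list(statistic = unname(wt$statistic), p = wt$p.value, n = length(d),
       exact = exact)
}

#' Bonferroni-Holm step-down correction
#'
#' Sorts the p-values, multiplies the k-th smallest by (m - k + 1),
#' enforces monotonicity by a cumulative maximum, caps at 1, and returns
#' the adjusted values in the input order.
#'
#' @param p numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values, same order as the input.
#' @export
holm_correct <- function(p) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, cummax((m - seq_len(m) + 1) * p[o]))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Pair a raw p-value with its corrected counterpart
#'
#' Mirrors the dual corrected/uncorrected reporting style; a correction can
#' never decrease a p-value.
#'
#' @param raw_p uncorrected p-value.
#' @param corrected_p corrected p-value (must be >= `raw_p`).
#' @return One-row data.frame with `p_raw` and `p_corrected`.
#' @export
report_corrected_pair <- function(raw_p, corrected_p) {
  if (corrected_p < raw_p) {
    stop("corrected p-value cannot be smaller than the raw p-value")
  }
  data.frame(p_raw = raw_p, p_corrected = corrected_p)
}

#' Built-in post-hoc electrode contrasts
#'
#' Named electrode groupings behind the reported contrasts: occipital vs
#' parietal and right vs left for the posterior components, central vs
#' peripheral and parietal vs central/frontopolar for the late positivity,
#' frontal vs central for the Frontal Negativity.  The exact pooling is a
#' package choice (configurable): the contrasts are named in the analysis
#' style but the groupings are not uniquely specified there.
#'
#' @param component one of "RP", "RN", "PP", "FN".
#' @return Named list of `list(a = electrodes, b = electrodes)` contrasts.
#' @export
builtin_contrasts <- function(component = c("RP", "RN", "PP", "FN")) {
  component <- match.arg(component)
  posterior <- list(
    occipital_vs_parietal = list(a = c("O1", "Oz", "O2"), b = c("P3", "Pz", "P4")),
    right_vs_left = list(a = c("O2", "P4"), b = c("O1", "P3")))
  switch(component,
    RP = posterior,
    RN = posterior,
    PP = list(
      central_vs_peripheral = list(a = "Cz", b = c("Pz", "Fpz")),
      parietal_vs_central = list(a = "Pz", b = "Cz"),
      parietal_vs_frontopolar = list(a = "Pz", b = "Fpz")),
    FN = list(
      frontal_vs_central = list(a = c("F3", "Fz", "F4"), b = c("C3", "Cz", "C4"))))
}

#' Run post-hoc electrode contrasts with Holm correction
#'
#' For each contrast, the dependent variable is averaged per subject over
#' experiments and over each electrode pool, then compared with a paired
#' Wilcoxon test across all subjects.  Holm correction is applied over the
#' set of contrasts tested in this call; corrected and uncorrected p-values
#' are reported side by side.
#'
#' @param measures data.frame from [measure_component()].
#' @param contrasts named list as returned by [builtin_contrasts()].
#' @param dv `"amplitude"` or `"latency"`.
#' @return data.frame with one row per contrast: `contrast`, `n`,
#'   `statistic`, `p_raw`, `p_corrected`.
#' @export
posthoc_contrasts <- function(measures, contrasts, dv = c("amplitude", "latency")) {
  dv <- match.arg(dv)
  df <- measures
  df$value <- if (dv == "amplitude") df$amplitude_uv else df$latency_ms
  if (dv == "latency") df <- df[!df$fallback & !is.na(df$value), ]
  rows <- list()
  for (nm in names(contrasts)) {
    ct <- contrasts[[nm]]
    per_side <- function(els) {
      sub <- df[df$electrode %in% els, ]
      tapply(sub$value, sub$subject, mean)
    }
    a <- per_side(ct$a); b <- per_side(ct$b)
    common <- intersect(names(a)[!is.na(a)], names(b)[!is.na(b)])
    wt <- wilcoxon_posthoc(as.numeric(a[common]), as.numeric(b[common]))
    rows[[nm]] <- data.frame(contrast = nm, n = wt$n, statistic = wt$statistic,
                             p_raw = wt$p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_corrected <- holm_correct(out$p_raw)
  for (i in seq_len(nrow(out))) {
    report_corrected_pair(out$p_raw[i], out$p_corrected[i])  # invariant check
  }
  rownames(out) <- NULL
  out
}
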