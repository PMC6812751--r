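#' End-to-end pipeline from a single configuration
#'
#' `run_pipeline()` executes the full analysis in a fixed stage order:
#' generate (or load) trial-level epochs -> re-reference -> artifact
#' rejection -> selective averaging -> dERP computation -> component
#' presence (confirmatory for RP/RN/PP, exploratory anterior scan for FN)
#' -> ROI peak measurement -> mixed ANOVAs -> Wilcoxon/Holm post-hocs.
#' Every table plus the exact configuration and seed are written to the
#' output directory when one is given, so a run can be reproduced
#' bit-identically.
#'
#' @name cli_reporting
NULL

#' Pipeline configuration
#'
#' @param cohort a [cohort_spec] describing the synthetic cohort (or the
#'   epochs already loaded; see `epochs`).
#' @param epochs optional pre-built cohort (named list of per-subject lists
#'   of [epoch_set]s, as from [generate_cohort()] or BrainVision epoching);
#'   when given, `cohort` is only used for bookkeeping.
#' @param preproc a [preproc_config].
#' @param rois named list of [roi_spec]s (default [builtin_rois()]).
#' @param alpha running t-test significance threshold (default 0.01).
#' @param min_run_ms minimum significant run length in ms (default 20, i.e.
#'   10 samples at 500 Hz).
#' @param exploratory_component name of the ROI (in `rois`) used for the
#'   exploratory anterior scan (default "FN").
#' @param gg apply Greenhouse-Geisser correction columns in ANOVAs.
#' @param seed overrides the cohort seed when not `NULL`.
#' @param out_dir optional output directory.
#' @param figures write PNG figures (dERP grid, peak scatter) to `out_dir`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = paper_fixture(), epochs = NULL,
                            preproc = preproc_config(), rois = builtin_rois(),
                            alpha = 0.01, min_run_ms = 20,
                            exploratory_component = "FN", gg = FALSE,
                            seed = NULL, out_dir = NULL, figures = FALSE) {
  stopifnot(inherits(cohort, "cohort_spec"), inherits(preproc, "preproc_config"))
  if (!is.null(seed)) cohort$seed <- as.integer(seed)
  if (!is.null(epochs) && !length(epochs)) {
    stop("pipeline config: empty cohort (no epoch sets)")
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (!exploratory_component %in% names(rois)) {
    stop("exploratory_component must name an entry of rois")
  }
  structure(list(cohort = cohort, epochs = epochs, preproc = preproc,
                 rois = rois, alpha = alpha, min_run_ms = min_run_ms,
                 exploratory_component = exploratory_component, gg = gg,
                 out_dir = out_dir, figures = figures),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' @param config a [pipeline_config].
#' @return A results bundle (list) with elements `derps` (per subject x
#'   experiment [derp_trace]s), `trial_report` (Table-1-style bookkeeping),
#'   `grand_means`, `presence` (data.frame: component x group x experiment
#'   with `met`), `presence_detail` (the `presence_result` objects),
#'   `measures` (peak tables per component), `anovas`, `posthocs`,
#'   `chain_latencies` (grand-mean peak latencies of the component chain)
#'   and `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  montage <- standard_montage_32()
  spec <- config$cohort
  preproc <- config$preproc
  rois <- config$rois
  min_run <- max(1L, as.integer(round(config$min_run_ms * spec$srate / 1000)))

  roster <- cohort_subjects(spec)
  if (!is.null(config$epochs) && !length(config$epochs)) {
    stop("pipeline config: empty cohort")
  }
  derps <- list()
  report_rows <- list()
  .stage("preprocess", for (i in seq_len(nrow(roster))) {
    subj_epochs <- if (is.null(config$epochs)) {
      generate_subject(spec, montage, i)
    } else {
      config$epochs[[roster$subject[i]]]
    }
    for (experiment in c("passive", "hold")) {
      erps <- list()
      for (condition in c("reversal", "stability")) {
        ep <- subj_epochs[[paste(experiment, condition, sep = ".")]]
        ep <- rereference(ep, preproc$reference)
        rej <- reject_artifacts(ep, preproc$reject_uv)
        report_rows[[length(report_rows) + 1]] <- rej$report
        if (rej$report$all_removed) {
          stop("all trials rejected for ", ep$subject, " ", experiment, "/",
               condition)
        }
        erps[[condition]] <- suppressWarnings(average_erp(rej$epochs, preproc))
      }
      derps[[paste(roster$subject[i], experiment, sep = ".")]] <-
        compute_derp(erps$reversal, erps$stability)
    }
  })
  trial_counts <- do.call(rbind, report_rows)

  # Table-1-style bookkeeping per group x experiment
  trial_report <- do.call(rbind, lapply(split(
    trial_counts, list(trial_counts$group, trial_counts$experiment)),
    function(d) data.frame(
      group = d$group[1], experiment = d$experiment[1],
      mean_total = mean(d$total), sd_total = stats::sd(d$total),
      mean_kept = mean(d$kept), sd_kept = stats::sd(d$kept),
      max_kept = max(d$kept), min_kept = min(d$kept),
      stringsAsFactors = FALSE)))
  rownames(trial_report) <- NULL

  cells <- expand.grid(group = c("meditator", "non_meditator"),
                       experiment = c("passive", "hold"),
                       stringsAsFactors = FALSE)
  sel_cell <- function(g, e) {
    Filter(function(d) d$group == g && d$experiment == e, derps)
  }

  grand_means <- .stage("grand_mean", {
    gm <- list(pooled = grand_mean(derps))
    for (j in seq_len(nrow(cells))) {
      gm[[paste(cells$group[j], cells$experiment[j], sep = ".")]] <-
        grand_mean(derps, cells$group[j], cells$experiment[j])
    }
    gm
  })

  confirmatory <- setdiff(names(rois), config$exploratory_component)
  presence_detail <- list()
  presence <- list()
  .stage("presence", {
    for (comp in confirmatory) {
      for (j in seq_len(nrow(cells))) {
        pr <- presence_confirmatory(sel_cell(cells$group[j], cells$experiment[j]),
                                    rois[[comp]], config$alpha, min_run)
        presence_detail[[length(presence_detail) + 1]] <- pr
        presence[[length(presence) + 1]] <- data.frame(
          component = comp, variant = "confirmatory", group = cells$group[j],
          experiment = cells$experiment[j], met = pr$met,
          stringsAsFactors = FALSE)
      }
    }
    fn_roi <- rois[[config$exploratory_component]]
    for (j in seq_len(nrow(cells))) {
      pr <- presence_exploratory(sel_cell(cells$group[j], cells$experiment[j]),
                                 montage, c(fn_roi$start_ms, fn_roi$end_ms),
                                 fn_roi$electrodes, config$alpha, min_run,
                                 component = fn_roi$name)
      presence_detail[[length(presence_detail) + 1]] <- pr
      presence[[length(presence) + 1]] <- data.frame(
        component = fn_roi$name, variant = "exploratory",
        group = cells$group[j], experiment = cells$experiment[j], met = pr$met,
        stringsAsFactors = FALSE)
    }
  })
  presence <- do.call(rbind, presence)

  measures <- .stage("peaks", {
    out <- lapply(rois, function(roi) measure_component(derps, roi))
    names(out) <- names(rois)
    out
  })

  anovas <- list(); posthocs <- list()
  .stage("stats", for (comp in names(rois)) {
    for (dv in c("amplitude", "latency")) {
      key <- paste(comp, dv, sep = ".")
      anovas[[key]] <- tryCatch(
        suppressMessages(mixed_anova(measures[[comp]], dv, gg = config$gg)),
        error = function(e) e$message)
      if (comp %in% c("RP", "RN", "PP", "FN")) {
        posthocs[[key]] <- tryCatch(
          posthoc_contrasts(measures[[comp]], builtin_contrasts(comp), dv),
          error = function(e) e$message)
      }
    }
  })

  chain <- .stage("chain_latencies", chain_latencies(derps, rois))

  bundle <- list(derps = derps, trial_counts = trial_counts,
                 trial_report = trial_report, grand_means = grand_means,
                 presence = presence, presence_detail = presence_detail,
                 measures = measures, anovas = anovas, posthocs = posthocs,
                 chain_latencies = chain, config = config)
  class(bundle) <- "derp_bundle"
  if (!is.null(config$out_dir)) .stage("write", write_bundle(bundle, config$out_dir))
  bundle
}

#' Grand-mean peak latencies of the component chain
#'
#' Measures, on grand-mean dERPs, the peak latency of each chain component
#' at its characteristic site: RP on the occipital electrodes (O1/Oz/O2,
#' positive), RN on its full occipito-parietal ROI (negative), the late
#' positivity separately at the parietal midline electrode (Pz) and over
#' the frontal/frontopolar electrodes (Fpz/Fp1/Fp2/Fz), and FN on its
#' anterior ROI in the meditator group only (negative).  RP/RN/PP pool
#' both groups and experiments; FN uses the meditator grand mean.
#'
#' @param derps list of per-subject [derp_trace]s.
#' @param rois named list of [roi_spec]s containing RP, RN, PP and FN.
#' @return Named numeric vector (ms): `RP`, `RN`, `PP_parietal`,
#'   `PP_frontal`, `FN`.
#' @export
chain_latencies <- function(derps, rois = builtin_rois()) {
  gm_all <- grand_mean(derps)
  times <- attr(gm_all, "times")
  peak_at <- function(gm, electrodes, roi) {
    x <- colMeans(gm[electrodes, , drop = FALSE])
    pick_peak(x, times, c(roi$start_ms, roi$end_ms), roi$polarity)$latency_ms
  }
  out <- c(
    RP = peak_at(gm_all, c("O1", "Oz", "O2"), rois$RP),
    RN = peak_at(gm_all, rois$RN$electrodes, rois$RN),
    PP_parietal = peak_at(gm_all, "Pz", rois$PP),
    PP_frontal = peak_at(gm_all, c("Fpz", "Fp1", "Fp2", "Fz"), rois$PP)
  )
  has_med <- any(vapply(derps, function(d) d$group == "meditator", logical(1)))
  out["FN"] <- if (has_med) {
    gm_med <- grand_mean(derps, group = "meditator")
    peak_at(gm_med, rois$FN$electrodes, rois$FN)
  } else NA_real_
  out
}

#' @export
print.derp_bundle <- function(x, ...) {
  cat("<derp_bundle>\n")
  cat("  subjects: ", length(unique(vapply(x$derps, `[[`, "", "subject"))),
      ", dERP traces: ", length(x$derps), "\n", sep = "")
  cat("  presence:\n")
  p <- x$presence
  for (i in seq_len(nrow(p))) {
    cat(sprintf("    %-3s %-13s %-13s %-7s %s\n", p$component[i], p$variant[i],
                p$group[i], p$experiment[i],
                if (p$met[i]) "present" else "-"))
  }
  cat("  chain latencies (ms): ",
      paste(names(x$chain_latencies),
            round(x$chain_latencies), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write a results bundle to a directory
#'
#' Writes the configuration (JSON), the trial bookkeeping, presence,
#' peak-measure, ANOVA and post-hoc tables (TSV), the grand-mean traces,
#' and optional figures.
#'
#' @param bundle a `derp_bundle` from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  cfg <- bundle$config
  cfg$epochs <- NULL
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  w(bundle$trial_counts, "trial_counts.tsv")
  w(bundle$trial_report, "trial_report.tsv")
  w(bundle$presence, "presence.tsv")
  w(do.call(rbind, bundle$measures), "peaks.tsv")
  for (key in names(bundle$anovas)) {
    if (is.data.frame(bundle$anovas[[key]])) {
      w(bundle$anovas[[key]], paste0("anova_", key, ".tsv"))
    }
  }
  ph <- bundle$posthocs[vapply(bundle$posthocs, is.data.frame, logical(1))]
  if (length(ph)) {
    tab <- do.call(rbind, Map(function(d, k) cbind(analysis = k, d), ph, names(ph)))
    w(tab, "posthocs.tsv")
  }
  chain <- data.frame(component = names(bundle$chain_latencies),
                      latency_ms = as.numeric(bundle$chain_latencies))
  w(chain, "chain_latencies.tsv")
  for (nm in names(bundle$grand_means)) {
    gm <- bundle$grand_means[[nm]]
    tab <- data.frame(time_ms = attr(gm, "times"), t(gm), check.names = FALSE)
    w(tab, paste0("grand_mean_", nm, ".tsv"))
  }
  if (isTRUE(bundle$config$figures)) {
    montage <- standard_montage_32()
    grDevices::png(file.path(out_dir, "derp_grid.png"), 1600, 1200)
    plot_derp_grid(bundle$grand_means, montage)
    grDevices::dev.off()
    grDevices::png(file.path(out_dir, "peak_scatter.png"), 1200, 800)
    plot_peak_scatter(do.call(rbind, bundle$measures))
    grDevices::dev.off()
  }
  invisible(out_dir)
}

#' Detection pattern of a results bundle
#'
#' Convenience summary of whether the expected pattern holds: RP, RN and PP
#' present (confirmatory) in both groups and both experiments, and the
#' exploratory component detected in meditators only.
#'
#' @param bundle a `derp_bundle`.
#' @return List with `table` (the presence data.frame), `confirmatory_all`
#'   (logical), `fn_meditators_only` (logical).
#' @export
detection_pattern <- function(bundle) {
  p <- bundle$presence
  conf <- p[p$variant == "confirmatory", ]
  expl <- p[p$variant == "exploratory", ]
  list(table = p,
       confirmatory_all = all(conf$met),
       fn_meditators_only = all(expl$met[expl$group == "meditator"]) &&
         !any(expl$met[expl$group == "non_meditator"]))
}
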