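#' Analysis configuration
#'
#' Collects the knobs of the end-to-end analysis: the five baseline
#' binarization cutoffs (fixed defaults, or recomputed from the cohort at
#' hand as integer-rounded medians), which parameter pairs get a concordance
#' score, the Spearman independence threshold, the confidence level, and
#' whether the multivariate Cox models use binarized (default) or continuous
#' covariates. Fixed cutoffs are the default so that reports from different
#' cohorts are comparable.
#'
#' @param cutoffs Named cutoff vector over the five parameters
#'   ([default_cutoffs()]).
#' @param cutoff_mode `"fixed"` uses `cutoffs` as given; `"median"`
#'   recomputes every cutoff except the NLR (which keeps its conventional
#'   value) from the cohort via [median_integer_cutoff()].
#' @param concordance_pairs List of parameter pairs to score.
#' @param independence_threshold Spearman threshold (default 0.8).
#' @param conf_level Confidence level (default 0.95).
#' @param cox_covariates `"binarized"` or `"continuous"`.
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(cutoffs = default_cutoffs(),
                            cutoff_mode = c("fixed", "median"),
                            concordance_pairs = list(c("volume", "nlr"),
                                                     c("recist_sum", "nlr")),
                            independence_threshold = 0.8,
                            conf_level = 0.95,
                            cox_covariates = c("binarized", "continuous")) {
  cutoff_mode <- match.arg(cutoff_mode)
  cox_covariates <- match.arg(cox_covariates)
  stopifnot(all(PARAMETERS %in% names(cutoffs)), all(cutoffs > 0))
  for (pair in concordance_pairs) {
    if (length(pair) != 2L || !all(pair %in% PARAMETERS)) {
      stop("each concordance pair must name two of: ",
           paste(PARAMETERS, collapse = ", "))
    }
  }
  structure(list(cutoffs = cutoffs, cutoff_mode = cutoff_mode,
                 concordance_pairs = concordance_pairs,
                 independence_threshold = independence_threshold,
                 conf_level = conf_level, cox_covariates = cox_covariates),
            class = "analysis_config")
}

#' Run the full tumor-burden survival analysis
#'
#' Executes the pipeline end to end: read and validate the inputs, compute
#' per-lesion shape features, apply the lesion-inclusion rules, build the
#' per-patient biomarker table, then run for both endpoints (OS and PFS)
#' the baseline univariate Kaplan-Meier / log-rank analyses per parameter,
#' the baseline Spearman screen and multivariate Cox model, the same for the
#' percent variations, and the concordance analyses with pairwise log-rank
#' tests. Analyses that are undefined on a given cohort (a one-sided split,
#' no observed events, a separated Cox model) are recorded in the report as
#' named notes instead of aborting the run.
#'
#' @param annotations Path to an annotations `.jsonl` file, or a list of
#'   [lesion_annotation] objects.
#' @param blood_recist Path to the per-timepoint CSV, or a data.frame
#'   ([read_blood_recist()] schema).
#' @param outcomes Path to the outcome CSV, or a data.frame
#'   ([read_outcomes()] schema).
#' @param config An [analysis_config()].
#' @param out_dir Optional output directory; when given, writes
#'   `biomarker_table.csv`, `report.json`, `report.txt` and `rejects.csv`.
#' @return List of class `run_report`.
#' @export
run_pipeline <- function(annotations, blood_recist, outcomes,
                         config = analysis_config(), out_dir = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.character(annotations)) annotations <- read_annotations(annotations)
  if (is.character(blood_recist)) blood_recist <- read_blood_recist(blood_recist)
  if (is.character(outcomes)) outcomes <- read_outcomes(outcomes)

  annotation_rejects <- attr(annotations, "rejects")
  warn <- character(0)
  withCallingHandlers({
    feats <- lesion_features(annotations)
    feats <- filter_lesions(feats)
    dropped <- attr(feats, "n_dropped")

    biomarkers <- build_biomarker_table(feats, blood_recist,
                                        cutoffs = config$cutoffs)
  }, warning = function(w) {
    warn <<- c(warn, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  cutoffs <- config$cutoffs
  if (config$cutoff_mode == "median") {
    for (p in setdiff(PARAMETERS, "nlr")) {
      cutoffs[[p]] <- median_integer_cutoff(biomarkers[[paste0(p, "_baseline")]])
      biomarkers[[paste0(p, "_baseline_class")]] <-
        binarize_baseline(biomarkers[[paste0(p, "_baseline")]], cutoffs[[p]])
    }
  }

  # align biomarker rows with outcomes; patients must appear in both
  patient_rejects <- attr(biomarkers, "rejects")
  common <- intersect(biomarkers$patient_id, outcomes$patient_id)
  only_bio <- setdiff(biomarkers$patient_id, common)
  # patients already rejected upstream are not double-counted here
  only_out <- setdiff(setdiff(outcomes$patient_id, common),
                      patient_rejects$patient_id)
  extra_rejects <- data.frame(
    patient_id = c(only_bio, only_out),
    reason = c(rep("no outcome record", length(only_bio)),
               rep("no biomarker record (missing annotations or timepoint)",
                   length(only_out))),
    stringsAsFactors = FALSE)
  rejects <- rbind(patient_rejects, extra_rejects)
  biomarkers <- biomarkers[match(common, biomarkers$patient_id), , drop = FALSE]
  outcomes <- outcomes[match(common, outcomes$patient_id), , drop = FALSE]
  if (nrow(biomarkers) < 2L) {
    stop("stage survival_analysis: fewer than 2 analyzable patients; ",
         "no groups to compare")
  }

  endpoints <- list(os = list(time = outcomes$os_months,
                              event = outcomes$os_event),
                    pfs = list(time = outcomes$pfs_months,
                               event = outcomes$pfs_event))

  baseline <- .univariate_block(biomarkers, endpoints, suffix = "_baseline_class",
                                levels = c("low", "high"),
                                conf_level = config$conf_level)
  baseline$screen <- .try_note(
    spearman_screen(stats::setNames(
      biomarkers[paste0(PARAMETERS, "_baseline")], PARAMETERS),
      config$independence_threshold))
  baseline$cox <- .cox_block(biomarkers, endpoints, config, mode = "baseline")

  variation <- .univariate_block(biomarkers, endpoints, suffix = "_direction",
                                 levels = c("decrease", "increase"),
                                 conf_level = config$conf_level)
  variation$screen <- .try_note(
    spearman_screen(stats::setNames(
      biomarkers[paste0(PARAMETERS, "_variation")], PARAMETERS),
      config$independence_threshold))
  variation$cox <- .cox_block(biomarkers, endpoints, config, mode = "variation")

  concordance <- list()
  for (pair in config$concordance_pairs) {
    col <- if (identical(sort(pair), sort(c("volume", "nlr")))) {
      "concordance_vol_nlr"
    } else if (identical(sort(pair), sort(c("recist_sum", "nlr")))) {
      "concordance_recist_nlr"
    } else {
      tmp <- concordance_category(
        biomarkers[[paste0(pair[1L], "_direction")]],
        biomarkers[[paste0(pair[2L], "_direction")]])
      biomarkers[[paste0("concordance_", pair[1L], "_", pair[2L])]] <- tmp
      paste0("concordance_", pair[1L], "_", pair[2L])
    }
    concordance[[paste(pair, collapse = "_x_")]] <-
      .concordance_block(biomarkers[[col]], endpoints, config$conf_level)
  }

  tumor_counts <- sort(table(outcomes$tumor_type), decreasing = TRUE)
  report <- structure(list(
    cohort = list(
      n_patients = nrow(biomarkers),
      n_rejected = nrow(rejects),
      n_annotation_rejects = if (is.null(annotation_rejects)) 0L
                             else nrow(annotation_rejects),
      tumor_types = as.list(tumor_counts),
      median_age = if ("age" %in% names(outcomes)) {
        stats::median(outcomes$age)
      },
      n_lesions_retained = nrow(feats),
      n_lesions_dropped_by_rule = as.list(dropped),
      os_events = sum(outcomes$os_event),
      pfs_events = sum(outcomes$pfs_event)),
    cutoffs = as.list(cutoffs),
    cutoff_mode = config$cutoff_mode,
    baseline = baseline,
    variation = variation,
    concordance = concordance,
    rejects = rejects,
    warnings = warn),
    class = "run_report")
  attr(report, "biomarker_table") <- biomarkers

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_biomarker_table(biomarkers, file.path(out_dir, "biomarker_table.csv"))
    write_report(report, out_dir)
    utils::write.csv(rejects, file.path(out_dir, "rejects.csv"),
                     row.names = FALSE)
  }
  report
}

.try_note <- function(expr) {
  tryCatch(expr, error = function(e) list(note = conditionMessage(e)))
}

# per-parameter two-group univariate analysis for both endpoints
.univariate_block <- function(biomarkers, endpoints, suffix, levels,
                              conf_level) {
  out <- list()
  for (p in PARAMETERS) {
    cls <- biomarkers[[paste0(p, suffix)]]
    ok <- !is.na(cls)
    entry <- list(group_sizes = as.list(table(factor(cls[ok], levels = levels))),
                  n_excluded = sum(!ok))
    for (ep in names(endpoints)) {
      time <- endpoints[[ep]]$time[ok]
      event <- endpoints[[ep]]$event[ok]
      grp <- factor(cls[ok], levels = levels)
      entry[[ep]] <- if (length(unique(grp)) < 2L) {
        list(note = "only one group present; log-rank not applicable")
      } else {
        .try_note({
          lr <- logrank_test(time, event, grp)
          med <- lapply(levels, function(lv) {
            km <- km_estimate(time[grp == lv], event[grp == lv], conf_level)
            attr(km, "median")
          })
          names(med) <- levels
          list(logrank_chi_square = lr$chi_square, logrank_p = lr$p_value,
               median_survival = med)
        })
      }
    }
    out[[p]] <- entry
  }
  out
}

.cox_block <- function(biomarkers, endpoints, config, mode) {
  x <- sapply(PARAMETERS, function(p) {
    if (config$cox_covariates == "binarized") {
      if (mode == "baseline") {
        as.numeric(biomarkers[[paste0(p, "_baseline_class")]] == "high")
      } else {
        as.numeric(biomarkers[[paste0(p, "_direction")]] == "increase")
      }
    } else {
      if (mode == "baseline") {
        scale(biomarkers[[paste0(p, "_baseline")]])[, 1L]
      } else {
        scale(biomarkers[[paste0(p, "_variation")]])[, 1L]
      }
    }
  })
  colnames(x) <- paste0(PARAMETERS, if (mode == "baseline") "_baseline"
                                    else "_variation")
  complete <- stats::complete.cases(x)
  out <- list()
  for (ep in names(endpoints)) {
    out[[ep]] <- .try_note({
      fit <- cox_fit(x[complete, , drop = FALSE],
                     endpoints[[ep]]$time[complete],
                     endpoints[[ep]]$event[complete],
                     conf_level = config$conf_level)
      list(n = fit$n, n_events = fit$n_events, converged = fit$converged,
           table = fit$coefficients)
    })
  }
  out$n_excluded <- sum(!complete)
  out
}

.concordance_block <- function(category, endpoints, conf_level) {
  lev <- c("mutual_decrease", "discordant", "mutual_increase")
  ok <- !is.na(category)
  grp <- factor(category[ok], levels = lev)
  entry <- list(group_sizes = as.list(table(grp)), n_excluded = sum(!ok))
  present <- levels(droplevels(grp))
  for (ep in names(endpoints)) {
    time <- endpoints[[ep]]$time[ok]
    event <- endpoints[[ep]]$event[ok]
    entry[[ep]] <- if (length(present) < 2L) {
      list(note = "fewer than 2 concordance categories present")
    } else {
      .try_note({
        pw <- pairwise_logrank(time, event, droplevels(grp))
        med <- lapply(present, function(lv) {
          km <- km_estimate(time[grp == lv], event[grp == lv], conf_level)
          attr(km, "median")
        })
        names(med) <- present
        list(pairwise_p = pw$p_value, median_survival = med)
      })
    }
  }
  entry
}

#' Write a run report to disk
#'
#' Emits `report.json` (machine-readable, field-ordered, no timestamps — so
#' identical runs give byte-identical files) and `report.txt` (a human
#' summary).
#'
#' @param report A `run_report`.
#' @param dir Output directory.
#' @return Invisibly, the two file paths.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  json_path <- file.path(dir, "report.json")
  txt_path <- file.path(dir, "report.txt")
  jsonlite::write_json(.jsonable(unclass(report)), json_path,
                       auto_unbox = TRUE, digits = I(10), na = "null")
  writeLines(utils::capture.output(print(report)), txt_path)
  invisible(c(json = json_path, txt = txt_path))
}

# matrices -> named row lists so the JSON is stable and self-describing
.jsonable <- function(x) {
  if (is.matrix(x)) {
    rows <- lapply(seq_len(nrow(x)), function(i) as.list(x[i, ]))
    names(rows) <- rownames(x)
    return(rows)
  }
  if (inherits(x, c("correlation_screen", "logrank_test", "pairwise_logrank"))) {
    x <- unclass(x)
  }
  if (is.list(x)) return(lapply(x, .jsonable))
  x
}

#' @export
print.run_report <- function(x, ...) {
  cat("Tumor-burden survival analysis report\n")
  cat("=====================================\n")
  cat("Patients analyzed:", x$cohort$n_patients,
      "| rejected:", x$cohort$n_rejected, "\n")
  cat("Lesions retained:", x$cohort$n_lesions_retained,
      "(dropped by rules:", paste(names(x$cohort$n_lesions_dropped_by_rule),
                                  unlist(x$cohort$n_lesions_dropped_by_rule),
                                  collapse = ", "), ")\n")
  cat("Events: OS", x$cohort$os_events, "| PFS", x$cohort$pfs_events, "\n")
  cat("Cutoffs (", x$cutoff_mode, "): ",
      paste(names(x$cutoffs), unlist(x$cutoffs), sep = "=", collapse = ", "),
      "\n\n", sep = "")
  for (block in c("baseline", "variation")) {
    cat("--", block, "univariate log-rank p-values --\n")
    for (p in PARAMETERS) {
      e <- x[[block]][[p]]
      fmt <- function(ep) {
        if (!is.null(e[[ep]]$logrank_p)) sprintf("%.4g", e[[ep]]$logrank_p)
        else "n/a"
      }
      cat(sprintf("  %-12s groups %s | OS p=%s PFS p=%s\n", p,
                  paste(unlist(e$group_sizes), collapse = "/"),
                  fmt("os"), fmt("pfs")))
    }
  }
  cat("\n-- concordance analyses --\n")
  for (nm in names(x$concordance)) {
    e <- x$concordance[[nm]]
    cat(sprintf("  %s: sizes %s\n", nm,
                paste(names(e$group_sizes), unlist(e$group_sizes),
                      sep = "=", collapse = ", ")))
    for (ep in c("os", "pfs")) {
      if (!is.null(e[[ep]]$pairwise_p)) {
        pm <- e[[ep]]$pairwise_p
        cat(sprintf("    %s pairwise p: %s\n", toupper(ep),
                    paste(apply(which(upper.tri(pm), arr.ind = TRUE), 1L,
                                function(ij) {
                                  sprintf("%s vs %s %.3g",
                                          rownames(pm)[ij[1L]],
                                          colnames(pm)[ij[2L]],
                                          pm[ij[1L], ij[2L]])
                                }), collapse = "; ")))
      }
    }
  }
  if (length(x$warnings)) {
    cat("\nWarnings:\n")
    for (w in x$warnings) cat("  -", w, "\n")
  }
  invisible(x)
}
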