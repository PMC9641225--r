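#' @name biomarkers
#' @title Patient-level burden parameters
#'
#' @description Five parameters summarise a patient's tumor burden at each
#' CT examination: total tumor volume (cm^3, the sum of approximate per-lesion
#' 3D volumes), the RECIST 1.1 sum of target-lesion diameters (mm), the
#' neutrophil-to-lymphocyte ratio (NLR), the total number of lesions, and the
#' number of distinct organs involved. Each is studied both at baseline and
#' as its percent variation between baseline and the first evaluation.
NULL

PARAMETERS <- c("volume", "recist_sum", "nlr", "n_lesions", "n_organs")

#' Default binarization cutoffs for the baseline parameters
#'
#' Total volume 90 cm^3 (a single sphere about 5.6 cm across), RECIST sum
#' 55 mm, NLR 5 (the conventional prognostic threshold), 10 lesions and
#' 3 involved organs. All but the NLR cutoff are integer-rounded cohort
#' medians; they can be recomputed for a new cohort with
#' [median_integer_cutoff()].
#'
#' @return Named numeric vector over the five parameters.
#' @export
default_cutoffs <- function() {
  c(volume = 90, recist_sum = 55, nlr = 5, n_lesions = 10, n_organs = 3)
}

#' Total tumor volume of a set of lesions
#'
#' Sums per-lesion approximate 3D volumes (mm^3) and converts to cm^3.
#'
#' @param volumes_mm3 Numeric vector of lesion volumes in mm^3.
#' @return Total volume in cm^3; 0 for an empty vector.
#' @export
total_volume <- function(volumes_mm3) {
  if (any(volumes_mm3 < 0)) stop("lesion volumes must be >= 0")
  sum(volumes_mm3) / 1000
}

#' Number of distinct organs involved
#'
#' @param organs Character vector of organ labels, one per lesion.
#' @return Count of distinct labels.
#' @export
organ_count <- function(organs) length(unique(organs))

#' Neutrophil-to-lymphocyte ratio
#'
#' @param neutrophils,lymphocytes Absolute counts (10^9 cells/L); vectorised.
#' @param patient_id Optional identifier(s) used in the error message.
#' @return `neutrophils / lymphocytes`.
#' @export
compute_nlr <- function(neutrophils, lymphocytes, patient_id = NULL) {
  bad <- !is.na(lymphocytes) & lymphocytes <= 0
  if (any(bad)) {
    who <- if (is.null(patient_id)) which(bad) else patient_id[bad]
    stop("NLR undefined (lymphocytes <= 0) for: ",
         paste(unique(who), collapse = ", "))
  }
  neutrophils / lymphocytes
}

#' Percent variation between baseline and first evaluation
#'
#' \deqn{\mathrm{variation} = \frac{x_{E1} - x_{BL}}{x_{BL}} \times 100}
#' A zero baseline leaves the variation undefined; such patients are excluded
#' from that parameter's variation analysis, so the function returns `NA`
#' there (with a warning) rather than an infinity.
#'
#' @param baseline,eval1 Parameter values at the two timepoints; vectorised.
#' @return Percent change; `NA` where `baseline == 0`.
#' @export
variation <- function(baseline, eval1) {
  out <- (eval1 - baseline) / baseline * 100
  undef <- !is.na(baseline) & baseline == 0
  if (any(undef)) {
    warning(sum(undef), " variation value(s) undefined (zero baseline), set to NA")
    out[undef] <- NA_real_
  }
  out
}

#' Binarize a variation into increase vs decrease
#'
#' Only the sign of the variation is analysed: `"increase"` if strictly
#' positive, `"decrease"` otherwise. An exactly zero variation is pooled with
#' the decreases — "no increase" is the conservative assignment for a risk
#' marker — and flagged with a warning so ties are never silent.
#'
#' @param variation_percent Numeric vector of percent variations.
#' @return Character vector of `"increase"` / `"decrease"` (`NA` preserved).
#' @export
direction <- function(variation_percent) {
  zero <- !is.na(variation_percent) & variation_percent == 0
  if (any(zero)) {
    warning(sum(zero), " exactly-zero variation(s) grouped with 'decrease'")
  }
  ifelse(is.na(variation_percent), NA_character_,
         ifelse(variation_percent > 0, "increase", "decrease"))
}

#' Binarize a baseline parameter at its cutoff
#'
#' `"high"` strictly above the cutoff, `"low"` at or below it.
#'
#' @param value Numeric vector of baseline parameter values.
#' @param cutoff Scalar cutoff on the same scale.
#' @return Character vector of `"low"` / `"high"` (`NA` preserved).
#' @export
binarize_baseline <- function(value, cutoff) {
  ifelse(is.na(value), NA_character_, ifelse(value > cutoff, "high", "low"))
}

#' Integer-rounded median cutoff
#'
#' The cohort median (mean of the middle two values for even n), rounded half
#' away from zero to the nearest integer — the rule used to set the default
#' baseline cutoffs for every parameter except the NLR.
#'
#' @param values Numeric vector (NAs dropped); at least one finite value.
#' @return Integer-valued cutoff.
#' @export
median_integer_cutoff <- function(values) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("no finite values to take a median of")
  m <- stats::median(values)
  sign(m) * floor(abs(m) + 0.5)
}

#' Concordance category of two variation directions
#'
#' Collapses the joint movement of two parameters into three categories:
#' both increase (`mutual_increase`), both decrease (`mutual_decrease`), or
#' one of each (`discordant`). Symmetric in its arguments.
#'
#' @param direction_a,direction_b `"increase"`/`"decrease"` vectors.
#' @return Character vector of categories (`NA` if either input is `NA`).
#' @export
concordance_category <- function(direction_a, direction_b) {
  ifelse(is.na(direction_a) | is.na(direction_b), NA_character_,
         ifelse(direction_a == "increase" & direction_b == "increase",
                "mutual_increase",
                ifelse(direction_a == "decrease" & direction_b == "decrease",
                       "mutual_decrease", "discordant")))
}

#' Read the per-timepoint blood count / RECIST table
#'
#' CSV with columns `patient_id`, `timepoint`, `neutrophils`, `lymphocytes`
#' and either `recist_sum_mm` or per-target diameter columns
#' `target1_mm ... target5_mm` (summed on read, at most 5 targets).
#'
#' @param path CSV path.
#' @return data.frame with a `recist_sum_mm` column.
#' @export
read_blood_recist <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "timepoint", "neutrophils", "lymphocytes")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!"recist_sum_mm" %in% names(tab)) {
    target_cols <- grep("^target[0-9]+_mm$", names(tab), value = TRUE)
    if (!length(target_cols)) {
      stop("need recist_sum_mm or target<i>_mm columns")
    }
    if (length(target_cols) > 5L) stop("RECIST 1.1 allows at most 5 target lesions")
    tab$recist_sum_mm <- rowSums(tab[target_cols], na.rm = TRUE)
  }
  tab$timepoint <- as.character(tab$timepoint)
  if (!all(tab$timepoint %in% TIMEPOINTS)) {
    stop("timepoint must be one of: ", paste(TIMEPOINTS, collapse = ", "))
  }
  tab
}

#' Read the patient-level outcome table
#'
#' CSV with columns `patient_id`, `os_months`, `os_event`, `pfs_months`,
#' `pfs_event` and optionally `tumor_type`, `age`, `sex`, `treatment`.
#' Overall survival (OS) runs from the first immunotherapy injection to death
#' from any cause; progression-free survival (PFS) to RECIST progression or
#' death, whichever comes first; `*_event = 0` marks right-censoring.
#'
#' @param path CSV path.
#' @return data.frame, one row per patient.
#' @export
read_outcomes <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "os_months", "os_event", "pfs_months", "pfs_event")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$patient_id)) stop("duplicate patient_id in outcomes")
  for (col in c("os_months", "pfs_months")) {
    if (any(!is.finite(tab[[col]]) | tab[[col]] <= 0)) {
      stop(col, " must be finite and > 0")
    }
  }
  for (col in c("os_event", "pfs_event")) {
    if (!all(tab[[col]] %in% c(0, 1))) stop(col, " must be 0/1")
  }
  tab
}

#' Build the per-patient biomarker table
#'
#' Aggregates filtered lesions and the blood/RECIST table into one row per
#' patient: the five parameters at baseline and first evaluation, their
#' percent variations, the increase/decrease directions, baseline low/high
#' classes at the supplied cutoffs, and the two concordance categories
#' (volume x NLR and RECIST x NLR).
#'
#' Patients missing either timepoint in the blood/RECIST table are excluded
#' and listed in the `"rejects"` attribute. A patient with no retained lesion
#' at a timepoint legitimately has zero volume and counts there; zero
#' baselines then propagate `NA` through that parameter's variation,
#' direction and any concordance using it.
#'
#' @param lesion_table Filtered lesion feature table ([filter_lesions()]).
#' @param blood_recist Per-timepoint table ([read_blood_recist()]).
#' @param cutoffs Named cutoff vector, as [default_cutoffs()].
#' @return data.frame of class `biomarker_table`, one row per patient, with
#'   attribute `rejects` (data.frame `patient_id`, `reason`).
#' @export
build_biomarker_table <- function(lesion_table, blood_recist,
                                  cutoffs = default_cutoffs()) {
  stopifnot(all(PARAMETERS %in% names(cutoffs)))
  patients <- sort(unique(blood_recist$patient_id))
  rejects <- list()
  rows <- list()
  for (pid in patients) {
    sub <- blood_recist[blood_recist$patient_id == pid, , drop = FALSE]
    have <- TIMEPOINTS %in% sub$timepoint
    if (!all(have)) {
      rejects[[length(rejects) + 1L]] <- data.frame(
        patient_id = pid,
        reason = paste("missing timepoint:",
                       paste(TIMEPOINTS[!have], collapse = ", ")),
        stringsAsFactors = FALSE)
      next
    }
    if (any(duplicated(sub$timepoint))) {
      rejects[[length(rejects) + 1L]] <- data.frame(
        patient_id = pid, reason = "duplicated timepoint rows",
        stringsAsFactors = FALSE)
      next
    }
    ps <- lapply(TIMEPOINTS, function(tp) {
      les <- lesion_table[lesion_table$patient_id == pid &
                            lesion_table$timepoint == tp, , drop = FALSE]
      bl <- sub[sub$timepoint == tp, ]
      c(volume = total_volume(les$volume),
        recist_sum = bl$recist_sum_mm,
        nlr = compute_nlr(bl$neutrophils, bl$lymphocytes, pid),
        n_lesions = nrow(les),
        n_organs = organ_count(les$organ))
    })
    names(ps) <- TIMEPOINTS
    rows[[length(rows) + 1L]] <- c(list(patient_id = pid),
                                   as.list(ps$baseline),
                                   as.list(ps$eval1))
  }
  if (!length(rows)) stop("no patient has both timepoints; empty cohort")
  tab <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  names(tab) <- c("patient_id",
                  paste0(PARAMETERS, "_baseline"),
                  paste0(PARAMETERS, "_eval1"))

  for (p in PARAMETERS) {
    tab[[paste0(p, "_variation")]] <-
      variation(tab[[paste0(p, "_baseline")]], tab[[paste0(p, "_eval1")]])
    tab[[paste0(p, "_direction")]] <-
      direction(tab[[paste0(p, "_variation")]])
    tab[[paste0(p, "_baseline_class")]] <-
      binarize_baseline(tab[[paste0(p, "_baseline")]], cutoffs[[p]])
  }
  tab$concordance_vol_nlr <-
    concordance_category(tab$volume_direction, tab$nlr_direction)
  tab$concordance_recist_nlr <-
    concordance_category(tab$recist_sum_direction, tab$nlr_direction)

  rownames(tab) <- NULL
  attr(tab, "rejects") <- if (length(rejects)) {
    do.call(rbind, rejects)
  } else {
    data.frame(patient_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  }
  attr(tab, "cutoffs") <- cutoffs
  class(tab) <- c("biomarker_table", "data.frame")
  tab
}

#' Write a biomarker table as CSV
#'
#' Fixed column order, missing values as empty fields; byte-stable for a
#' given table, so identical runs produce identical files.
#'
#' @param table A `biomarker_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_biomarker_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  invisible(path)
}
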