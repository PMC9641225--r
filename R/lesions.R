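#' Recognised organ labels
#'
#' The closed set of 16 anatomical locations a lesion annotation may carry.
#' Unknown labels are rejected at parse time.
#'
#' @return Character vector of the 16 labels.
#' @export
organ_labels <- function() {
  c("heart", "lung", "liver", "lymph_node", "bone", "spleen", "kidney",
    "carcinosis", "ovary", "pancreas", "skin_soft_tissue", "adrenal",
    "brain", "muscle", "bowels", "other")
}

TIMEPOINTS <- c("baseline", "eval1")

#' One annotated lesion
#'
#' Bundles a contour with its identity: which patient, which of the two
#' CT examinations (baseline, before immunotherapy, or `eval1`, the first
#' radiological evaluation), and which organ.
#'
#' @param patient_id,lesion_id Identifier strings.
#' @param timepoint `"baseline"` or `"eval1"`.
#' @param organ One of [organ_labels()].
#' @param polygon A [polygon2d] contour in mm.
#' @return An object of class `lesion_annotation`.
#' @export
lesion_annotation <- function(patient_id, timepoint, lesion_id, organ, polygon) {
  timepoint <- match.arg(timepoint, TIMEPOINTS)
  if (!organ %in% organ_labels()) {
    stop("unknown organ label '", organ, "' (lesion ", lesion_id,
         ", patient ", patient_id, ")")
  }
  if (!inherits(polygon, "polygon2d")) polygon <- polygon2d(polygon)
  structure(list(patient_id = as.character(patient_id),
                 timepoint = timepoint,
                 lesion_id = as.character(lesion_id),
                 organ = organ,
                 polygon = polygon),
            class = "lesion_annotation")
}

#' Read lesion annotations from a JSON-lines file
#'
#' One lesion per line:
#' `{"patient_id", "timepoint": "baseline"|"eval1", "lesion_id", "organ",
#' "vertices_mm": [[x,y],...]}`. A pixel dialect with `"vertices_px"` plus
#' `"pixel_spacing_mm"` is also accepted and converted to mm on read
#' (`mm = px * spacing`).
#'
#' Records that fail validation (unknown organ, bad timepoint, malformed or
#' missing vertices, duplicate `(patient, timepoint, lesion)` key) are
#' collected rather than aborting the read; they are returned in the
#' `"rejects"` attribute as a data.frame with the line number and the reason.
#'
#' @param path Path to a `.jsonl` file.
#' @return List of [lesion_annotation] objects with attribute `rejects`.
#' @export
read_annotations <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  rejects <- list()
  seen <- new.env(hash = TRUE, parent = emptyenv())
  kept <- 0L
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                    error = function(e) NULL)
    reason <- .validate_annotation_record(rec)
    if (is.null(reason)) {
      key <- paste(rec$patient_id, rec$timepoint, rec$lesion_id, sep = "\r")
      if (!is.null(seen[[key]])) {
        reason <- "duplicate (patient_id, timepoint, lesion_id)"
      } else {
        assign(key, TRUE, envir = seen)
      }
    }
    if (!is.null(reason)) {
      rejects[[length(rejects) + 1L]] <- data.frame(
        line = i, reason = reason, stringsAsFactors = FALSE)
      next
    }
    verts <- if (!is.null(rec$vertices_mm)) {
      matrix(as.numeric(rec$vertices_mm), ncol = 2L)
    } else {
      matrix(as.numeric(rec$vertices_px), ncol = 2L) * rec$pixel_spacing_mm
    }
    kept <- kept + 1L
    out[[kept]] <- lesion_annotation(rec$patient_id, rec$timepoint,
                                     rec$lesion_id, rec$organ,
                                     polygon2d(verts))
  }
  out <- out[seq_len(kept)]
  attr(out, "rejects") <- if (length(rejects)) {
    do.call(rbind, rejects)
  } else {
    data.frame(line = integer(), reason = character(), stringsAsFactors = FALSE)
  }
  out
}

.validate_annotation_record <- function(rec) {
  if (is.null(rec)) return("unparseable JSON")
  for (f in c("patient_id", "timepoint", "lesion_id", "organ")) {
    if (is.null(rec[[f]]) || !nzchar(as.character(rec[[f]])[1L])) {
      return(paste0("missing field '", f, "'"))
    }
  }
  if (!rec$timepoint %in% TIMEPOINTS) {
    return(paste0("unknown timepoint '", rec$timepoint, "'"))
  }
  if (!rec$organ %in% organ_labels()) {
    return(paste0("unknown organ '", rec$organ, "'"))
  }
  has_mm <- !is.null(rec$vertices_mm)
  has_px <- !is.null(rec$vertices_px)
  if (!has_mm && !has_px) return("no vertices")
  if (has_px && !has_mm && is.null(rec$pixel_spacing_mm)) {
    return("vertices_px without pixel_spacing_mm")
  }
  verts <- if (has_mm) rec$vertices_mm else rec$vertices_px
  if (length(verts) < 6L || length(verts) %% 2L != 0L ||
      any(!is.finite(as.numeric(verts)))) {
    return("malformed vertices")
  }
  NULL
}

#' Write lesion annotations to a JSON-lines file
#'
#' Inverse of [read_annotations()]; always writes the mm dialect.
#'
#' @param annotations List of [lesion_annotation] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  lines <- vapply(annotations, function(a) {
    jsonlite::toJSON(list(patient_id = a$patient_id, timepoint = a$timepoint,
                          lesion_id = a$lesion_id, organ = a$organ,
                          vertices_mm = unname(a$polygon$vertices)),
                     auto_unbox = TRUE, digits = I(10))
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Per-lesion shape feature table
#'
#' Computes the four shape features of every annotated lesion and returns
#' them as one data.frame row per lesion. Lesions whose contour is degenerate
#' (zero enclosed area) are dropped with a warning: they carry no measurable
#' burden and would otherwise contribute spurious zero-size lesions to the
#' lesion and organ counts.
#'
#' @param annotations List of [lesion_annotation] objects.
#' @return data.frame with columns `patient_id`, `timepoint`, `lesion_id`,
#'   `organ`, `surface` (mm^2), `major_axis` (mm), `minor_axis` (mm),
#'   `volume` (mm^3).
#' @export
lesion_features <- function(annotations) {
  n <- length(annotations)
  feats <- matrix(0, nrow = n, ncol = 4L,
                  dimnames = list(NULL, c("surface", "major_axis",
                                          "minor_axis", "volume")))
  for (i in seq_len(n)) {
    feats[i, ] <- .shape_features_mat(annotations[[i]]$polygon$vertices)
  }
  tab <- data.frame(
    patient_id = vapply(annotations, `[[`, "", "patient_id"),
    timepoint = vapply(annotations, `[[`, "", "timepoint"),
    lesion_id = vapply(annotations, `[[`, "", "lesion_id"),
    organ = vapply(annotations, `[[`, "", "organ"),
    feats,
    stringsAsFactors = FALSE
  )
  degenerate <- tab$surface <= 0
  if (any(degenerate)) {
    warning(sum(degenerate), " degenerate (zero-area) lesion contour(s) dropped")
    tab <- tab[!degenerate, , drop = FALSE]
    rownames(tab) <- NULL
  }
  tab
}

#' Apply the lesion-inclusion rules
#'
#' Two inclusion rules mirror how the annotations are meant to be read:
#' lymph nodes count as lesions only when their smallest (minor) axis exceeds
#' 10 mm — the RECIST short-axis convention for pathological nodes — and
#' pulmonary micronodules are annotated only above 3 mm, applied here to the
#' major axis. Both thresholds are strict: a lesion exactly at the threshold
#' is dropped. All other organs are retained unconditionally and row order
#' is preserved.
#'
#' @param lesion_table data.frame as returned by [lesion_features()].
#' @param lymph_node_min_minor_mm,lung_min_major_mm Rule thresholds in mm.
#' @return The retained subset, with attribute `n_dropped` giving the counts
#'   per rule.
#' @export
filter_lesions <- function(lesion_table,
                           lymph_node_min_minor_mm = 10,
                           lung_min_major_mm = 3) {
  drop_node <- lesion_table$organ == "lymph_node" &
    lesion_table$minor_axis <= lymph_node_min_minor_mm
  drop_lung <- lesion_table$organ == "lung" &
    lesion_table$major_axis <= lung_min_major_mm
  kept <- lesion_table[!(drop_node | drop_lung), , drop = FALSE]
  rownames(kept) <- NULL
  attr(kept, "n_dropped") <- c(lymph_node = sum(drop_node),
                               lung = sum(drop_lung))
  kept
}
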