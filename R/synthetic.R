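#' Configuration of the synthetic cohort generator
#'
#' Describes the cohort the generator emulates: 61 patients with metastatic
#' mismatch-repair-deficient tumors of mixed origin, two CT examinations
#' (baseline and first evaluation, about two months apart), roughly 35
#' annotated lesions per patient (about 2100 lesions cohort-wide), blood
#' counts at both timepoints, and right-censored overall and
#' progression-free survival driven by planted proportional-hazards effects
#' on three binary covariates: high baseline total volume, increasing total
#' volume, and increasing NLR.
#'
#' Lesion mean radii are log-normal; contours are star-convex polygons with
#' mean-preserving radial noise. Each patient is latently a responder
#' (lesions shrink, NLR drifts down) or progressor (lesions grow, new
#' lesions may appear, NLR drifts up); the responder fraction defaults to
#' 51%. Survival times are exponential with rate
#' `baseline_hazard * exp(linear predictor)` and independent exponential
#' censoring.
#'
#' @param n_patients Cohort size.
#' @param tumor_type_weights Named sampling weights over tumor types
#'   (normalised internally).
#' @param lesion_count_mu,lesion_count_size Negative-binomial mean and size
#'   for baseline lesions per patient (truncated at 1).
#' @param lesion_radius_meanlog,lesion_radius_sdlog Log-normal mean radius
#'   (mm) of a lesion contour.
#' @param polygon_vertices,polygon_irregularity Contour resolution and
#'   radial noise amplitude (fraction of the mean radius).
#' @param responder_fraction Latent probability of the responder class.
#' @param responder_growth_meanlog,responder_growth_sdlog,
#'   progressor_growth_meanlog,progressor_growth_sdlog Log-normal per-patient
#'   lesion-volume multipliers between baseline and first evaluation.
#' @param lesion_growth_sdlog Per-lesion log-normal scatter around the
#'   patient multiplier.
#' @param new_lesion_mean Poisson mean of new lesions at first evaluation
#'   (progressors only).
#' @param new_lesion_radius_meanlog,new_lesion_radius_sdlog Size of newly
#'   appeared lesions.
#' @param neutrophils_meanlog,neutrophils_sdlog,lymphocytes_meanlog,
#'   lymphocytes_sdlog Baseline blood counts (10^9 cells/L).
#' @param responder_nlr_drift_meanlog,responder_nlr_drift_sdlog,
#'   progressor_nlr_drift_meanlog,progressor_nlr_drift_sdlog Log-normal
#'   multiplicative NLR drift by class.
#' @param recist_measure_sdlog Log-normal measurement noise a simulated
#'   independent reader adds to every target diameter at each timepoint.
#' @param log_hr Named planted log hazard ratios for
#'   `volume_baseline_high`, `nlr_increase`, `volume_increase`.
#' @param volume_baseline_cutoff_cm3 Cutoff defining the planted
#'   high-baseline-volume covariate.
#' @param baseline_hazard_os,baseline_hazard_pfs Exponential baseline event
#'   rates (per month).
#' @param censor_rate_os,censor_rate_pfs Exponential censoring rates (per
#'   month), chosen so that roughly half of OS records are censored.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(
    n_patients = 61L,
    tumor_type_weights = c(colorectal = 26, endometrial = 13, gastric = 7,
                           small_intestine = 5, prostate = 2, ovarian = 2,
                           esophagus = 2, pancreas = 2, adrenal_gland = 1,
                           uterine_cervix = 1),
    lesion_count_mu = 35, lesion_count_size = 0.5,
    lesion_radius_meanlog = log(7.5), lesion_radius_sdlog = 0.6,
    polygon_vertices = 32L, polygon_irregularity = 0.25,
    responder_fraction = 0.51,
    responder_growth_meanlog = log(0.55), responder_growth_sdlog = 0.35,
    progressor_growth_meanlog = log(1.8), progressor_growth_sdlog = 0.35,
    lesion_growth_sdlog = 0.5,
    new_lesion_mean = 2,
    new_lesion_radius_meanlog = log(4), new_lesion_radius_sdlog = 0.5,
    neutrophils_meanlog = log(4.5), neutrophils_sdlog = 0.35,
    lymphocytes_meanlog = log(1.4), lymphocytes_sdlog = 0.35,
    responder_nlr_drift_meanlog = log(0.75), responder_nlr_drift_sdlog = 0.35,
    progressor_nlr_drift_meanlog = log(1.4), progressor_nlr_drift_sdlog = 0.35,
    recist_measure_sdlog = 0.10,
    log_hr = c(volume_baseline_high = log(3.2), nlr_increase = log(2.9),
               volume_increase = log(2.0)),
    volume_baseline_cutoff_cm3 = 90,
    baseline_hazard_os = 0.012, baseline_hazard_pfs = 0.030,
    censor_rate_os = 0.050, censor_rate_pfs = 0.090) {
  if (abs(sum(tumor_type_weights)) < .Machine$double.eps) {
    stop("tumor_type_weights must not sum to zero")
  }
  if (any(tumor_type_weights < 0)) stop("tumor_type_weights must be >= 0")
  need_hr <- c("volume_baseline_high", "nlr_increase", "volume_increase")
  if (!all(need_hr %in% names(log_hr))) {
    stop("log_hr must name: ", paste(need_hr, collapse = ", "))
  }
  cfg <- as.list(environment())
  cfg$tumor_type_weights <- tumor_type_weights / sum(tumor_type_weights)
  structure(cfg, class = "cohort_config")
}

# base sampling weights over the 16 organ labels; the tumor type's typical
# dissemination sites get an extra boost before renormalisation
.base_organ_weights <- function() {
  c(heart = 0.005, lung = 0.14, liver = 0.18, lymph_node = 0.22, bone = 0.07,
    spleen = 0.02, kidney = 0.02, carcinosis = 0.12, ovary = 0.01,
    pancreas = 0.03, skin_soft_tissue = 0.02, adrenal = 0.03, brain = 0.015,
    muscle = 0.01, bowels = 0.05, other = 0.05)
}

.tumor_type_organ_boost <- list(
  colorectal = c("liver", "carcinosis"),
  endometrial = c("carcinosis", "ovary"),
  gastric = c("liver", "carcinosis"),
  small_intestine = c("carcinosis", "bowels"),
  prostate = c("bone", "lymph_node"),
  ovarian = c("ovary", "carcinosis"),
  esophagus = c("lymph_node", "liver"),
  pancreas = c("pancreas", "liver"),
  adrenal_gland = c("adrenal", "lung"),
  uterine_cervix = c("lymph_node", "carcinosis")
)

.organ_weights_for <- function(tumor_type) {
  w <- .base_organ_weights()
  boost <- .tumor_type_organ_boost[[tumor_type]]
  if (!is.null(boost)) w[boost] <- w[boost] + 0.15
  w / sum(w)
}

#' Generate one star-convex lesion contour
#'
#' Emulates a freehand circumscribed annotation as a star-convex polygon:
#' vertices at equally spaced angles with radii
#' `mean_radius * (1 + irregularity * u)`, `u ~ Uniform(-1, 1)`. The radial
#' noise is mean-preserving, so over many draws the mean enclosed area stays
#' close to `pi * mean_radius^2` (up to the usual n-gon deficit).
#'
#' @param center `(x, y)` center in mm.
#' @param mean_radius Mean radius in mm (> 0).
#' @param irregularity Noise amplitude in `[0, 1)`; 0 gives a regular n-gon.
#' @param n_vertices Number of vertices (>= 8).
#' @param seed Optional integer; when given, the polygon is a pure function
#'   of the arguments and the caller's RNG state is left untouched.
#' @return A [polygon2d].
#' @export
generate_lesion_polygon <- function(center = c(0, 0), mean_radius,
                                    irregularity = 0.25, n_vertices = 32L,
                                    seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  polygon2d(.lesion_polygon_mat(center, mean_radius, irregularity, n_vertices))
}

.lesion_polygon_mat <- function(center, mean_radius, irregularity, n_vertices) {
  stopifnot(mean_radius > 0, irregularity >= 0, irregularity < 1,
            n_vertices >= 8L)
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  r <- mean_radius * (1 + irregularity * stats::runif(n_vertices, -1, 1))
  cbind(center[1L] + r * cos(theta), center[2L] + r * sin(theta))
}

#' Simulate right-censored proportional-hazards survival
#'
#' Event times are exponential with rate
#' `baseline_rate * exp(linear_predictor)`; censoring times are independent
#' exponential with rate `censor_rate` (`0` disables censoring). The
#' observed time is the minimum, the event indicator marks whether the event
#' came first.
#'
#' @param linear_predictor Numeric vector, one value per subject.
#' @param baseline_rate Baseline hazard (> 0), events per month.
#' @param censor_rate Censoring hazard (>= 0), per month.
#' @return data.frame with columns `time` (months) and `event` (0/1).
#' @export
simulate_survival <- function(linear_predictor, baseline_rate, censor_rate = 0) {
  stopifnot(baseline_rate > 0, censor_rate >= 0)
  n <- length(linear_predictor)
  event_time <- stats::rexp(n, rate = baseline_rate * exp(linear_predictor))
  censor_time <- if (censor_rate > 0) stats::rexp(n, rate = censor_rate) else Inf
  data.frame(time = pmin(event_time, censor_time),
             event = as.integer(event_time <= censor_time))
}

#' Generate a synthetic two-timepoint cohort
#'
#' Draws a full cohort under `config`: per-patient lesions with polygonal
#' contours at baseline, the same lesions rescaled by the patient's latent
#' growth multiplier at first evaluation (plus possible new lesions for
#' progressors), blood counts with class-linked NLR drift, RECIST target
#' diameter sums (up to 5 largest lesions by major axis, at most 2 per
#' organ, selected at baseline and re-measured at first evaluation), and
#' OS/PFS outcomes from an exponential proportional-hazards model whose
#' linear predictor applies the planted log hazard ratios to the binarized
#' covariates actually derivable from the generated data.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; the cohort is a pure function of
#'   `(config, seed)` and the caller's RNG state is restored afterwards.
#' @param out_dir Optional directory; when given the cohort is also written
#'   via [write_cohort()].
#' @return List of class `synthetic_cohort` with elements `annotations`
#'   (list of [lesion_annotation]), `blood_recist`, `outcomes`,
#'   `ground_truth` (all data.frames), `config`, `seed`.
#' @export
generate_cohort <- function(config = cohort_config(), seed, out_dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (missing(seed)) stop("a seed is mandatory for cohort generation")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  cfg <- config
  n <- cfg$n_patients
  pids <- sprintf("P%03d", seq_len(n))
  tumor_types <- sample(names(cfg$tumor_type_weights), n, replace = TRUE,
                        prob = cfg$tumor_type_weights)
  responder <- stats::runif(n) < cfg$responder_fraction
  growth <- ifelse(responder,
                   stats::rlnorm(n, cfg$responder_growth_meanlog,
                                 cfg$responder_growth_sdlog),
                   stats::rlnorm(n, cfg$progressor_growth_meanlog,
                                 cfg$progressor_growth_sdlog))

  annotations <- vector("list", 8L * n * ceiling(cfg$lesion_count_mu))
  n_ann <- 0L
  add_ann <- function(a) {
    n_ann <<- n_ann + 1L
    if (n_ann > length(annotations)) {
      length(annotations) <<- 2L * n_ann
    }
    annotations[[n_ann]] <<- a
  }

  blood_rows <- vector("list", n)
  truth_rows <- vector("list", n)

  for (i in seq_len(n)) {
    pid <- pids[i]
    organ_w <- .organ_weights_for(tumor_types[i])
    k <- max(1L, stats::rnbinom(1L, mu = cfg$lesion_count_mu,
                                size = cfg$lesion_count_size))
    organs <- sample(names(organ_w), k, replace = TRUE, prob = organ_w)
    radii <- stats::rlnorm(k, cfg$lesion_radius_meanlog, cfg$lesion_radius_sdlog)
    centers <- matrix(stats::runif(2L * k, 0, 400), ncol = 2L)
    # per-lesion volume multipliers scatter around the patient multiplier;
    # contours scale linearly by the cube root
    vol_mult <- growth[i] * stats::rlnorm(k, 0, cfg$lesion_growth_sdlog)
    lin_scale <- vol_mult^(1 / 3)
    for (j in seq_len(k)) {
      lid <- sprintf("L%03d", j)
      v_bl <- .lesion_polygon_mat(centers[j, ], radii[j],
                                  cfg$polygon_irregularity,
                                  cfg$polygon_vertices)
      ctr <- .polygon_centroid(v_bl)
      v_e1 <- cbind(ctr[1L] + (v_bl[, 1L] - ctr[1L]) * lin_scale[j],
                    ctr[2L] + (v_bl[, 2L] - ctr[2L]) * lin_scale[j])
      add_ann(structure(list(patient_id = pid, timepoint = "baseline",
                             lesion_id = lid, organ = organs[j],
                             polygon = structure(list(vertices = v_bl),
                                                 class = "polygon2d")),
                        class = "lesion_annotation"))
      add_ann(structure(list(patient_id = pid, timepoint = "eval1",
                             lesion_id = lid, organ = organs[j],
                             polygon = structure(list(vertices = v_e1),
                                                 class = "polygon2d")),
                        class = "lesion_annotation"))
    }
    if (!responder[i]) {
      k_new <- stats::rpois(1L, cfg$new_lesion_mean)
      if (k_new > 0L) {
        organs_new <- sample(names(organ_w), k_new, replace = TRUE,
                             prob = organ_w)
        radii_new <- stats::rlnorm(k_new, cfg$new_lesion_radius_meanlog,
                                   cfg$new_lesion_radius_sdlog)
        for (j in seq_len(k_new)) {
          v_new <- .lesion_polygon_mat(stats::runif(2L, 0, 400), radii_new[j],
                                       cfg$polygon_irregularity,
                                       cfg$polygon_vertices)
          add_ann(structure(list(patient_id = pid, timepoint = "eval1",
                                 lesion_id = sprintf("N%03d", j),
                                 organ = organs_new[j],
                                 polygon = structure(list(vertices = v_new),
                                                     class = "polygon2d")),
                            class = "lesion_annotation"))
        }
      }
    }

    ne_bl <- stats::rlnorm(1L, cfg$neutrophils_meanlog, cfg$neutrophils_sdlog)
    ly_bl <- stats::rlnorm(1L, cfg$lymphocytes_meanlog, cfg$lymphocytes_sdlog)
    drift <- if (responder[i]) {
      stats::rlnorm(1L, cfg$responder_nlr_drift_meanlog,
                    cfg$responder_nlr_drift_sdlog)
    } else {
      stats::rlnorm(1L, cfg$progressor_nlr_drift_meanlog,
                    cfg$progressor_nlr_drift_sdlog)
    }
    ly_e1 <- ly_bl * stats::rlnorm(1L, 0, 0.10)
    ne_e1 <- ne_bl * drift
    blood_rows[[i]] <- data.frame(
      patient_id = pid, timepoint = TIMEPOINTS,
      neutrophils = round(c(ne_bl, ne_e1), 3),
      lymphocytes = round(c(ly_bl, ly_e1), 3),
      stringsAsFactors = FALSE)
    truth_rows[[i]] <- data.frame(
      patient_id = pid, tumor_type = tumor_types[i],
      responder = responder[i], growth_multiplier = growth[i],
      nlr_drift = drift, stringsAsFactors = FALSE)
  }
  annotations <- annotations[seq_len(n_ann)]
  blood_recist <- do.call(rbind, blood_rows)
  truth <- do.call(rbind, truth_rows)

  # derive the planted covariates from the data actually generated
  feats <- suppressWarnings(lesion_features(annotations))
  feats <- filter_lesions(feats)
  key <- paste(feats$patient_id, feats$timepoint)
  vol_by <- tapply(feats$volume, key, sum) / 1000
  vol_of <- function(pid, tp) {
    v <- vol_by[paste(pid, tp)]
    ifelse(is.na(v), 0, v)
  }
  vol_bl <- as.numeric(vol_of(pids, "baseline"))
  vol_e1 <- as.numeric(vol_of(pids, "eval1"))
  nlr_tab <- blood_recist$neutrophils / blood_recist$lymphocytes
  nlr_bl <- nlr_tab[blood_recist$timepoint == "baseline"]
  nlr_e1 <- nlr_tab[blood_recist$timepoint == "eval1"]

  # RECIST target selection at baseline: top 5 by major axis, <= 2 per organ
  recist <- matrix(0, n, 2L)
  for (i in seq_len(n)) {
    bl <- feats[feats$patient_id == pids[i] & feats$timepoint == "baseline", ]
    bl <- bl[order(-bl$major_axis), ]
    keep <- integer(0)
    for (r in seq_len(nrow(bl))) {
      org <- bl$organ[r]
      if (sum(bl$organ[keep] == org) < 2L) keep <- c(keep, r)
      if (length(keep) == 5L) break
    }
    targets <- bl[keep, , drop = FALSE]
    n_t <- nrow(targets)
    # an independent reader re-measures each target diameter at both
    # timepoints with multiplicative log-normal measurement noise
    noise <- stats::rlnorm(2L * n_t, 0, cfg$recist_measure_sdlog)
    recist[i, 1L] <- sum(targets$major_axis * noise[seq_len(n_t)])
    e1 <- feats[feats$patient_id == pids[i] & feats$timepoint == "eval1", ]
    m <- match(targets$lesion_id, e1$lesion_id)
    # a target that shrank below the inclusion rules is re-measured on its
    # eval1 contour when present, otherwise contributes its baseline size
    e1_major <- ifelse(is.na(m), targets$major_axis, e1$major_axis[m])
    recist[i, 2L] <- sum(e1_major * noise[n_t + seq_len(n_t)])
  }
  # rows are ordered (patient, baseline), (patient, eval1)
  blood_recist$recist_sum_mm <- round(c(rbind(recist[, 1L], recist[, 2L])), 2)

  cov_vol_high <- as.integer(vol_bl > cfg$volume_baseline_cutoff_cm3)
  cov_vol_inc <- as.integer(vol_e1 > vol_bl)
  cov_nlr_inc <- as.integer(nlr_e1 > nlr_bl)
  lp <- cfg$log_hr[["volume_baseline_high"]] * cov_vol_high +
    cfg$log_hr[["nlr_increase"]] * cov_nlr_inc +
    cfg$log_hr[["volume_increase"]] * cov_vol_inc

  os <- simulate_survival(lp, cfg$baseline_hazard_os, cfg$censor_rate_os)
  pfs <- simulate_survival(lp, cfg$baseline_hazard_pfs, cfg$censor_rate_pfs)

  outcomes <- data.frame(
    patient_id = pids,
    os_months = pmax(round(os$time, 2), 0.01), os_event = os$event,
    pfs_months = pmax(round(pfs$time, 2), 0.01), pfs_event = pfs$event,
    tumor_type = tumor_types,
    age = pmin(pmax(round(stats::rnorm(n, 64, 11)), 25), 92),
    sex = ifelse(stats::runif(n) < 32 / 61, "F", "M"),
    treatment = ifelse(stats::runif(n) < 26 / 61, "anti-PD-1", "anti-PD-L1"),
    stringsAsFactors = FALSE)

  truth <- cbind(truth, data.frame(
    volume_baseline_cm3 = vol_bl, volume_eval1_cm3 = vol_e1,
    nlr_baseline = nlr_bl, nlr_eval1 = nlr_e1,
    volume_baseline_high = cov_vol_high, volume_increase = cov_vol_inc,
    nlr_increase = cov_nlr_inc, linear_predictor = as.numeric(lp)))

  cohort <- structure(list(annotations = annotations,
                           blood_recist = blood_recist,
                           outcomes = outcomes,
                           ground_truth = truth,
                           config = cfg, seed = seed),
                      class = "synthetic_cohort")
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort: ", nrow(x$outcomes), " patients, ",
      length(x$annotations), " lesion annotations (seed ", x$seed, ")\n",
      sep = "")
  invisible(x)
}

#' Write a synthetic cohort in the pipeline's input formats
#'
#' Emits `annotations.jsonl`, `blood_recist.csv`, `outcomes.csv` and
#' `ground_truth.json` into `dir`. Output is byte-identical for identical
#' `(config, seed)`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if absent).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(annotations = file.path(dir, "annotations.jsonl"),
             blood_recist = file.path(dir, "blood_recist.csv"),
             outcomes = file.path(dir, "outcomes.csv"),
             ground_truth = file.path(dir, "ground_truth.json"))
  write_annotations(cohort$annotations, paths[["annotations"]])
  utils::write.csv(cohort$blood_recist, paths[["blood_recist"]],
                   row.names = FALSE)
  utils::write.csv(cohort$outcomes, paths[["outcomes"]], row.names = FALSE)
  jsonlite::write_json(
    list(seed = cohort$seed,
         config = unclass(cohort$config),
         patients = cohort$ground_truth),
    paths[["ground_truth"]], auto_unbox = TRUE, digits = I(10))
  invisible(paths)
}
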