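test_that("total_volume sums lesion volumes in cm^3", {
  sphere <- (4 / 3) * pi * 10^3  # mm^3
  expect_equal(total_volume(c(sphere, sphere)), 8.378, tolerance = 1e-3)
  expect_equal(total_volume(numeric(0)), 0)
  expect_equal(total_volume(90000), 90)
  expect_error(total_volume(c(10, -1)), ">= 0")
  # additive and monotone under adding a lesion
  set.seed(3)
  vols <- runif(20, 0, 5000)
  expect_equal(total_volume(vols), sum(vols) / 1000)
  expect_gt(total_volume(c(vols, 1)), total_volume(vols))
})

test_that("organ_count counts distinct labels", {
  expect_equal(organ_count(c("liver", "liver", "lung")), 2L)
  expect_equal(organ_count(character(0)), 0L)
  expect_equal(organ_count(organ_labels()), 16L)
})

test_that("compute_nlr divides counts and guards the denominator", {
  expect_equal(compute_nlr(5, 1), 5)
  expect_equal(compute_nlr(3.3, 1.1), 3)
  expect_error(compute_nlr(2, 0, patient_id = "P007"), "P007")
})

test_that("variation is the percent change from baseline", {
  expect_equal(variation(100, 150), 50)
  expect_equal(variation(80, 80), 0)
  expect_equal(variation(200, 50), -75)
  expect_warning(v <- variation(c(0, 10), c(5, 20)), "zero baseline")
  expect_true(is.na(v[1]))
  expect_equal(v[2], 100)
  # identities
  x <- c(3, 17, 250)
  expect_equal(variation(x, x), rep(0, 3))
  expect_equal(variation(x, 2 * x), rep(100, 3))
})

test_that("direction splits on the sign of the variation, ties to decrease", {
  expect_equal(direction(0.1), "increase")
  expect_equal(direction(-0.1), "decrease")
  expect_warning(d <- direction(0), "zero")
  expect_equal(d, "decrease")
  expect_true(is.na(direction(NA_real_)))
})

test_that("baseline binarization is strict at the cutoff", {
  expect_equal(binarize_baseline(90, 90), "low")
  expect_equal(binarize_baseline(5.1, 5), "high")
  expect_equal(binarize_baseline(11, 10), "high")
  expect_equal(binarize_baseline(10, 10), "low")
})

test_that("median_integer_cutoff rounds the median half away from zero", {
  expect_equal(median_integer_cutoff(c(1, 2, 3, 4)), 3)  # median 2.5
  expect_equal(median_integer_cutoff(c(7, 7, 7)), 7)
  expect_equal(median_integer_cutoff(c(89.6, 90.2, 90.4)), 90)
  expect_equal(median_integer_cutoff(c(-1, -2, -3, -4)), -3)
  expect_error(median_integer_cutoff(c(NA, Inf)), "finite")
})

test_that("median cutoff splits a cohort near-evenly up to ties", {
  set.seed(11)
  for (n in c(20, 61)) {
    x <- round(rlnorm(n, 3, 0.8))
    cut <- median_integer_cutoff(x)
    hi <- sum(x > cut)
    lo <- sum(x <= cut)
    ties <- sum(x == cut)
    expect_lte(abs(hi - lo), ties + 1)
  }
})

test_that("concordance_category is the three-way pooling, symmetric", {
  expect_equal(concordance_category("increase", "increase"), "mutual_increase")
  expect_equal(concordance_category("decrease", "decrease"), "mutual_decrease")
  expect_equal(concordance_category("increase", "decrease"), "discordant")
  dirs <- c("increase", "decrease")
  for (a in dirs) for (b in dirs) {
    expect_equal(concordance_category(a, b), concordance_category(b, a))
  }
  expect_true(is.na(concordance_category(NA, "increase")))
})

test_that("biomarker table aggregates a hand-computed cohort correctly", {
  fix <- tiny_cohort()
  tab <- suppressWarnings(build_biomarker_table(fix$lesions, fix$blood))
  expect_s3_class(tab, "biomarker_table")
  expect_equal(nrow(tab), 2L)
  a <- tab[tab$patient_id == "A", ]
  expect_equal(a$volume_baseline, 0.8)        # (600 + 200) / 1000
  expect_equal(a$volume_eval1, 1.1)
  expect_equal(a$n_lesions_baseline, 2)
  expect_equal(a$n_lesions_eval1, 1)
  expect_equal(a$n_organs_baseline, 1)
  expect_equal(a$nlr_baseline, 5)
  expect_equal(a$nlr_variation, 20)           # 5 -> 6
  expect_equal(a$volume_variation, 37.5)
  expect_equal(a$recist_sum_variation, 25)    # 40 -> 50
  expect_equal(a$volume_direction, "increase")
  expect_equal(a$concordance_vol_nlr, "mutual_increase")
  b <- tab[tab$patient_id == "B", ]
  expect_equal(b$n_organs_eval1, 2)
  expect_equal(b$nlr_variation, -100 / 3, tolerance = 1e-12)
  expect_equal(b$concordance_vol_nlr, "mutual_decrease")
  expect_equal(b$concordance_recist_nlr, "mutual_decrease")
  # baseline classes at the default cutoffs
  expect_equal(a$volume_baseline_class, "low")
  expect_equal(a$nlr_baseline_class, "low")   # exactly 5 is not > 5
  expect_equal(b$nlr_baseline_class, "low")
})

test_that("patients missing a timepoint are rejected, not analyzed", {
  fix <- tiny_cohort()
  blood <- rbind(fix$blood,
                 data.frame(patient_id = "C", timepoint = "baseline",
                            neutrophils = 4, lymphocytes = 2,
                            recist_sum_mm = 30))
  tab <- suppressWarnings(build_biomarker_table(fix$lesions, blood))
  expect_equal(nrow(tab), 2L)
  rej <- attr(tab, "rejects")
  expect_equal(rej$patient_id, "C")
  expect_match(rej$reason, "eval1")
})

test_that("zero baselines carry explicit missing markers through the table", {
  fix <- tiny_cohort()
  # patient C: blood at both timepoints but lesions only at eval1
  blood <- rbind(fix$blood, data.frame(
    patient_id = c("C", "C"), timepoint = c("baseline", "eval1"),
    neutrophils = c(4, 4), lymphocytes = c(2, 2),
    recist_sum_mm = c(0, 10)))
  lesions <- rbind(fix$lesions, data.frame(
    patient_id = "C", timepoint = "eval1", lesion_id = "L1", organ = "brain",
    surface = 40, major_axis = 8, minor_axis = 6, volume = 160))
  tab <- suppressWarnings(build_biomarker_table(lesions, blood))
  cc <- tab[tab$patient_id == "C", ]
  expect_equal(cc$volume_baseline, 0)
  expect_true(is.na(cc$volume_variation))
  expect_true(is.na(cc$volume_direction))
  expect_true(is.na(cc$concordance_vol_nlr))
  expect_false(is.na(cc$nlr_variation))
})

test_that("biomarker CSV writes missing values as empty fields", {
  fix <- tiny_cohort()
  tab <- suppressWarnings(build_biomarker_table(fix$lesions, fix$blood))
  path <- withr::local_tempfile(fileext = ".csv")
  write_biomarker_table(tab, path)
  back <- read.csv(path, stringsAsFactors = FALSE)
  expect_equal(nrow(back), 2L)
  expect_equal(back$volume_baseline, tab$volume_baseline)
  expect_equal(names(back), names(tab))
})
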