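test_that("product-limit estimate matches hand computations", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km$n_risk, c(3, 2, 1))

  # censoring at t=2 keeps that subject out of later risk sets
  km <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km$time, c(1, 3))
  expect_equal(km$survival, c(2 / 3, 0))

  # all censored: curve stays at 1
  km <- km_estimate(c(4, 5, 6), c(0, 0, 0))
  expect_equal(nrow(km), 0L)
  expect_equal(km_survival_at(km, c(1, 10)), c(1, 1))

  expect_error(km_estimate(numeric(0), numeric(0)), "no outcomes")
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "> 0")
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(5)
  t <- round(rexp(40, 0.2), 2)
  km <- km_estimate(t, rep(1, 40))
  for (q in quantile(t, c(0.1, 0.5, 0.9))) {
    expect_equal(km_survival_at(km, q), mean(t > q))
  }
})

test_that("curve is monotone with CI bracketing the estimate", {
  set.seed(6)
  t <- rexp(50, 0.1)
  e <- rbinom(50, 1, 0.7)
  km <- km_estimate(t, e)
  expect_true(all(diff(km$survival) <= 0))
  ok <- !is.na(km$lower)
  expect_true(all(km$lower[ok] <= km$survival[ok] + 1e-12))
  expect_true(all(km$upper[ok] >= km$survival[ok] - 1e-12))
  expect_true(all(km$upper[ok] <= 1))
})

test_that("KM curve and Greenwood log-scale CI match the survival package", {
  set.seed(8)
  t <- pmax(round(rexp(60, 0.08), 1), 0.1)  # rounding forces ties
  e <- rbinom(60, 1, 0.6)
  km <- km_estimate(t, e)
  sf <- summary(survival::survfit(survival::Surv(t, e) ~ 1, conf.type = "log"))
  expect_equal(km$time, sf$time)
  expect_equal(km$survival, sf$surv, tolerance = 1e-12)
  expect_equal(km$n_risk, as.numeric(sf$n.risk))
  ok <- !is.na(km$lower)
  expect_equal(km$lower[ok], sf$lower[ok], tolerance = 1e-12)
  expect_equal(km$upper[ok], sf$upper[ok], tolerance = 1e-12)
})

test_that("log-rank matches the direct Mantel-Cox hand computation", {
  # 6-subject fixture: group 1 fails early, group 0 late, one censoring
  time <- c(1, 2, 3, 8, 9, 10)
  event <- c(1, 1, 0, 1, 1, 1)
  g <- c(1, 1, 1, 0, 0, 0)
  res <- logrank_test(time, event, g)
  expect_equal(res$chi_square, hand_logrank_chisq(time, event, g),
               tolerance = 1e-12)
  expect_equal(res$dof, 1L)

  # identical groups: statistic 0, p 1
  t2 <- c(1, 2, 3, 1, 2, 3)
  res0 <- logrank_test(t2, rep(1, 6), rep(c("a", "b"), each = 3))
  expect_equal(res0$chi_square, 0, tolerance = 1e-12)
  expect_equal(res0$p_value, 1)

  # relabeling invariance
  res_ab <- logrank_test(time, event, ifelse(g == 1, "x", "y"))
  expect_equal(res_ab$chi_square, res$chi_square)

  expect_error(logrank_test(time, rep(0, 6), g), "no events")
  expect_error(logrank_test(1, 1, "a"), "2 groups")
})

test_that("log-rank agrees with survival::survdiff including ties", {
  set.seed(9)
  t <- round(rexp(80, 0.1), 1)
  e <- rbinom(80, 1, 0.7)
  g <- sample(c("a", "b", "c"), 80, replace = TRUE)
  res <- logrank_test(t, e, g)
  sd <- survival::survdiff(survival::Surv(t, e) ~ g)
  expect_equal(res$chi_square, sd$chisq, tolerance = 1e-10)
  expect_equal(res$dof, 2L)
})

test_that("log-rank p-values are approximately uniform under the null", {
  set.seed(12)
  t <- rexp(30, 0.1)
  e <- rbinom(30, 1, 0.8)
  if (sum(e) == 0) e[1] <- 1
  ps <- replicate(1000, {
    logrank_test(t, e, sample(rep(0:1, each = 15)))$p_value
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("pairwise log-rank is consistent and symmetric", {
  set.seed(13)
  t <- rexp(60, 0.1)
  e <- rbinom(60, 1, 0.7)
  g3 <- rep(c("a", "b", "c"), each = 20)
  pw <- pairwise_logrank(t, e, g3)
  expect_equal(pw$p_value, t(pw$p_value))
  expect_true(all(is.na(diag(pw$p_value))))

  # two categories: the single pair equals the plain test
  g2 <- rep(c("a", "b"), each = 30)
  pw2 <- pairwise_logrank(t, e, g2)
  expect_equal(pw2$p_value["a", "b"], logrank_test(t, e, g2)$p_value)

  # three copies of the same group: all p = 1
  t3 <- rep(rexp(10, 0.2), 3)
  pw3 <- pairwise_logrank(t3, rep(1, 30), rep(c("a", "b", "c"), each = 10))
  expect_true(all(pw3$p_value[upper.tri(pw3$p_value)] == 1))

  # bonferroni never decreases a p-value
  pwb <- pairwise_logrank(t, e, g3, adjust = "bonferroni")
  expect_true(all(pwb$p_value >= pw$p_value, na.rm = TRUE))
})

test_that("Cox fit matches survival::coxph with Efron ties", {
  set.seed(14)
  n <- 80
  x <- cbind(bin = rbinom(n, 1, 0.5), cont = rnorm(n))
  t <- round(rexp(n, 0.1 * exp(0.8 * x[, 1] - 0.3 * x[, 2])), 1)
  e <- rbinom(n, 1, 0.75)
  if (sum(e) < 2) e[1:2] <- 1
  fit <- cox_fit(x, t, e)
  ref <- survival::coxph(survival::Surv(t, e) ~ x, ties = "efron")
  expect_equal(fit$coefficients$coef, unname(coef(ref)), tolerance = 1e-7)
  expect_equal(fit$coefficients$se, unname(sqrt(diag(vcov(ref)))),
               tolerance = 1e-7)
  expect_equal(fit$loglik[["fitted"]], ref$loglik[2], tolerance = 1e-7)
  expect_true(fit$converged)
  expect_equal(fit$coefficients$hr, exp(fit$coefficients$coef))
  expect_true(all(fit$coefficients$lower <= fit$coefficients$hr &
                    fit$coefficients$hr <= fit$coefficients$upper))
})

test_that("degenerate Cox designs raise named errors", {
  t <- rexp(20, 0.1)
  e <- rep(1, 20)
  expect_error(cox_fit(cbind(flat = rep(1, 20)), t, e), "zero-variance")
  expect_error(cox_fit(cbind(a = rnorm(20), b = rnorm(20)),
                       rexp(20), c(1, rep(0, 19))), "fewer events")
  # perfect separation: the lone early failure defines the covariate
  ts <- c(1:10, 101:110)
  xs <- cbind(grp = rep(c(1, 0), each = 10))
  expect_error(cox_fit(xs, ts, rep(1, 20)), "separat")
})

test_that("score test at beta = 0 equals the log-rank chi-square (no ties)", {
  set.seed(15)
  t <- rexp(50, 0.1)  # continuous: no ties
  e <- rbinom(50, 1, 0.7)
  g <- rbinom(50, 1, 0.5)
  if (length(unique(g)) == 1) g[1] <- 1 - g[1]
  score <- tumorburden:::.cox_score_test(cbind(g), t, e)
  lr <- logrank_test(t, e, g)$chi_square
  expect_equal(score, lr, tolerance = 1e-6)
})

test_that("spearman screen flags monotone-dependent pairs only", {
  set.seed(16)
  x <- runif(1000)
  df <- data.frame(x = x, cube = x^3, neg = -x, indep = runif(1000))
  sc <- spearman_screen(df, threshold = 0.8)
  expect_equal(sc$rho["x", "cube"], 1)
  expect_equal(sc$rho["x", "neg"], -1)
  expect_lt(abs(sc$rho["x", "indep"]), 0.1)
  expect_equal(sc$rho, t(sc$rho))
  expect_equal(unname(diag(sc$rho)), rep(1, 4))
  flagged_pairs <- paste(sc$flagged$var_a, sc$flagged$var_b)
  expect_setequal(flagged_pairs, c("x cube", "x neg", "cube neg"))
  expect_error(spearman_screen(df[1:2, ]), "at least 3")
})
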