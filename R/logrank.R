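#' Mantel-Cox log-rank test
#'
#' Compares the survival distributions of two or more groups. At each
#' distinct event time the observed events per group are compared with the
#' expectation under the null hypergeometric allocation; the summed
#' observed-minus-expected vector and its covariance give a chi-square
#' statistic on (k - 1) degrees of freedom. The statistic is invariant to
#' relabeling of the groups.
#'
#' @param time Positive follow-up times (months).
#' @param event 1 = event observed, 0 = right-censored.
#' @param group Group labels (coerced to factor); each group non-empty.
#' @return Object of class `logrank_test` with `chi_square`, `dof`,
#'   `p_value`, per-group `observed` and `expected` event counts, and `n`.
#' @examples
#' logrank_test(c(1, 2, 3, 4, 5, 6), c(1, 1, 1, 1, 1, 1),
#'              rep(c("a", "b"), each = 3))
#' @export
logrank_test <- function(time, event, group) {
  .check_surv(time, event)
  group <- factor(group)
  if (length(group) != length(time)) stop("group length differs from time")
  if (any(tabulate(group, nbins = nlevels(group)) == 0L)) {
    stop("every group must be non-empty")
  }
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  if (sum(event) == 0) stop("log-rank statistic undefined: no events observed")

  k <- nlevels(group)
  event_times <- sort(unique(time[event == 1]))
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (t in event_times) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    d_t <- sum(time == t & event == 1)
    n_g <- tabulate(group[at_risk], nbins = k)
    d_g <- tabulate(group[time == t & event == 1], nbins = k)
    O <- O + d_g
    E <- E + d_t * n_g / n_t
    if (n_t > 1) {
      w <- d_t * (n_t - d_t) / (n_t - 1)
      p <- n_g / n_t
      V <- V + w * (diag(p, k) - tcrossprod(p, p))
    }
  }
  u <- (O - E)[-k]
  Vk <- V[-k, -k, drop = FALSE]
  chi <- tryCatch(drop(crossprod(u, solve(Vk, u))),
                  error = function(e) drop(crossprod(u, MASS::ginv(Vk) %*% u)))
  chi <- max(chi, 0)
  structure(list(chi_square = chi, dof = k - 1L,
                 p_value = stats::pchisq(chi, df = k - 1L, lower.tail = FALSE),
                 observed = stats::setNames(O, levels(group)),
                 expected = stats::setNames(E, levels(group)),
                 n = length(time)),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank (Mantel-Cox) test: chi-square = %.4g on %d df, p = %.4g\n",
              x$chi_square, x$dof, x$p_value))
  print(data.frame(group = names(x$observed), observed = x$observed,
                   expected = round(x$expected, 2)), row.names = FALSE)
  invisible(x)
}

#' Pairwise two-group log-rank tests
#'
#' One two-group Mantel-Cox test per unordered pair of categories. P-values
#' are reported unadjusted by default — each pairwise comparison stands on
#' its own — with an optional Bonferroni correction.
#'
#' @param time,event,group As in [logrank_test()]; at least two categories.
#' @param adjust `"none"` (default) or `"bonferroni"`.
#' @return Object of class `pairwise_logrank` with symmetric matrices
#'   `p_value` and `chi_square` (diagonal `NA`).
#' @export
pairwise_logrank <- function(time, event, group, adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  group <- factor(group)
  lev <- levels(group)
  if (length(lev) < 2L) stop("need at least 2 categories")
  k <- length(lev)
  p <- chi <- matrix(NA_real_, k, k, dimnames = list(lev, lev))
  n_pairs <- k * (k - 1) / 2
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      sel <- group %in% lev[c(i, j)]
      res <- logrank_test(time[sel], event[sel], droplevels(group[sel]))
      pv <- res$p_value
      if (adjust == "bonferroni") pv <- min(1, pv * n_pairs)
      p[i, j] <- p[j, i] <- pv
      chi[i, j] <- chi[j, i] <- res$chi_square
    }
  }
  structure(list(p_value = p, chi_square = chi, adjust = adjust),
            class = "pairwise_logrank")
}

#' @export
print.pairwise_logrank <- function(x, ...) {
  cat("Pairwise log-rank p-values (", x$adjust, " adjustment):\n", sep = "")
  print(round(x$p_value, 4))
  invisible(x)
}
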