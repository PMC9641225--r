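#' Kaplan-Meier product-limit estimate
#'
#' Estimates the survival function from right-censored times by the
#' product-limit method: at each distinct event time \eqn{t_j} with
#' \eqn{d_j} events among \eqn{n_j} at risk, the curve drops by the factor
#' \eqn{1 - d_j/n_j}. Subjects censored exactly at an event time are kept in
#' the risk set for that time (the standard convention). The 95% band uses
#' the Greenwood variance on the log-survival scale,
#' \eqn{\widehat{\mathrm{Var}}[\log \hat S(t)] = \sum_{t_j \le t}
#' d_j / (n_j (n_j - d_j))}, with the resulting interval clipped to [0, 1].
#'
#' @param time Positive follow-up times (months).
#' @param event 1 = event observed, 0 = right-censored.
#' @param conf_level Confidence level for the band (default 0.95).
#' @return Object of class `km_curve`: a data.frame with one row per distinct
#'   event time (`time`, `n_risk`, `n_event`, `survival`, `lower`, `upper`)
#'   plus attributes `n`, `n_events`, `median` (median survival, `NA` if the
#'   curve never falls below 0.5) and `conf_level`.
#' @examples
#' km_estimate(c(1, 2, 3), c(1, 1, 1))
#' @export
km_estimate <- function(time, event, conf_level = 0.95) {
  .check_surv(time, event)
  if (!length(time)) stop("no outcomes supplied")
  n <- length(time)
  event_times <- sort(unique(time[event == 1]))
  if (!length(event_times)) {
    curve <- data.frame(time = numeric(), n_risk = integer(),
                        n_event = integer(), survival = numeric(),
                        lower = numeric(), upper = numeric())
    return(.km_object(curve, n, 0L, conf_level))
  }
  n_risk <- vapply(event_times, function(t) sum(time >= t), 0)
  n_event <- vapply(event_times, function(t) sum(time == t & event == 1), 0)
  surv <- cumprod(1 - n_event / n_risk)
  # Greenwood variance of log S
  varlog <- cumsum(ifelse(n_risk > n_event,
                          n_event / (n_risk * (n_risk - n_event)), NA_real_))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(varlog)
  lower <- pmin(pmax(exp(log(surv) - z * se), 0), 1)
  upper <- pmin(pmax(exp(log(surv) + z * se), 0), 1)
  lower[surv == 0] <- NA_real_
  upper[surv == 0] <- NA_real_
  curve <- data.frame(time = event_times, n_risk = n_risk, n_event = n_event,
                      survival = surv, lower = lower, upper = upper)
  .km_object(curve, n, sum(event), conf_level)
}

.km_object <- function(curve, n, n_events, conf_level) {
  med <- if (any(curve$survival < 0.5)) {
    min(curve$time[curve$survival < 0.5])
  } else if (any(curve$survival == 0.5)) {
    # flat at exactly 0.5: midpoint convention is not used; first time at 0.5
    min(curve$time[curve$survival == 0.5])
  } else {
    NA_real_
  }
  structure(curve, n = n, n_events = n_events, median = med,
            conf_level = conf_level, class = c("km_curve", "data.frame"))
}

.check_surv <- function(time, event) {
  if (length(time) != length(event)) stop("time and event lengths differ")
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop("survival times must be finite and > 0")
  }
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  invisible(TRUE)
}

#' Survival probability at given times from a KM curve
#'
#' Step-function evaluation of the product-limit estimate (right-continuous).
#'
#' @param curve A `km_curve`.
#' @param times Times at which to evaluate.
#' @return Numeric vector of survival probabilities.
#' @export
km_survival_at <- function(curve, times) {
  vapply(times, function(t) {
    below <- curve$time <= t
    if (!any(below)) 1 else curve$survival[max(which(below))]
  }, 0)
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier estimate: n =", attr(x, "n"),
      ", events =", attr(x, "n_events"),
      ", median =", format(attr(x, "median"), digits = 4), "months\n")
  print(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Export KM step coordinates for plotting
#'
#' Returns the `(time, survival)` staircase including the `(0, 1)` origin so
#' external plotting tools can draw the curve with a simple step plot.
#'
#' @param curve A `km_curve`.
#' @return data.frame with columns `time`, `survival`, `lower`, `upper`.
#' @export
km_step_coordinates <- function(curve) {
  rbind(data.frame(time = 0, survival = 1, lower = 1, upper = 1),
        data.frame(time = curve$time, survival = curve$survival,
                   lower = curve$lower, upper = curve$upper))
}
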