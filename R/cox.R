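#' Cox proportional-hazards fit
#'
#' Maximises the Cox partial likelihood by Newton-Raphson with step halving,
#' handling tied event times with the Efron approximation. Covariates should
#' be binary indicators or standardized continuous values; a constant column
#' is rejected because its coefficient is not identifiable. Per-covariate
#' hazard ratios come with Wald confidence intervals and p-values.
#'
#' Convergence is declared when the relative change in partial log-likelihood
#' falls below `tol`; a fit that fails to converge within `max_iter`
#' iterations is returned with `converged = FALSE` and a warning rather than
#' an error. Monotone-likelihood (separation) fits, recognisable by a
#' coefficient diverging beyond `abs(beta) > 15`, raise an error naming the
#' covariate.
#'
#' @param x Covariate matrix (subjects x covariates); column names become
#'   term labels.
#' @param time Positive follow-up times (months).
#' @param event 1 = event observed, 0 = right-censored.
#' @param conf_level Confidence level for the Wald intervals.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum Newton iterations.
#' @return Object of class `cox_fit`: `coefficients` (data.frame with `term`,
#'   `coef`, `hr`, `se`, `z`, `p_value`, `lower`, `upper`), `loglik`
#'   (null and fitted), `n`, `n_events`, `iterations`, `converged`.
#' @examples
#' set.seed(1)
#' x <- cbind(arm = rep(0:1, each = 20))
#' tt <- rexp(40, 0.1 * exp(0.7 * x[, 1]))
#' cox_fit(x, tt, rep(1, 40))
#' @export
cox_fit <- function(x, time, event, conf_level = 0.95,
                    tol = 1e-9, max_iter = 25L) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  .check_surv(time, event)
  if (nrow(x) != length(time)) stop("covariate rows differ from time length")
  const <- apply(x, 2L, function(col) max(col) == min(col))
  if (any(const)) {
    stop("zero-variance covariate(s): ",
         paste(colnames(x)[const], collapse = ", "))
  }
  n_events <- sum(event)
  if (n_events < ncol(x)) {
    stop("fewer events (", n_events, ") than covariates (", ncol(x), ")")
  }

  beta <- numeric(ncol(x))
  ll <- .cox_partial(x, time, event, beta)
  loglik_null <- ll$loglik
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- solve(-ll$hessian, ll$gradient)
    new_beta <- beta + step
    new_ll <- .cox_partial(x, time, event, new_beta)
    halvings <- 0L
    while (!is.finite(new_ll$loglik) || new_ll$loglik < ll$loglik) {
      halvings <- halvings + 1L
      if (halvings > 30L) break
      step <- step / 2
      new_beta <- beta + step
      new_ll <- .cox_partial(x, time, event, new_beta)
    }
    if (any(abs(new_beta) > 15)) {
      worst <- which.max(abs(new_beta))
      stop("coefficient for '", colnames(x)[worst],
           "' diverges; data appear separated (monotone partial likelihood)")
    }
    done <- abs(new_ll$loglik - ll$loglik) <
      tol * (abs(ll$loglik) + tol)
    beta <- new_beta
    ll <- new_ll
    if (done) {
      converged <- TRUE
      break
    }
  }
  if (!converged) warning("Cox fit did not converge in ", max_iter, " iterations")

  info <- -ll$hessian
  vcov <- solve(info)
  se <- sqrt(diag(vcov))
  z <- beta / se
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  coefs <- data.frame(
    term = colnames(x),
    coef = beta,
    hr = exp(beta),
    se = se,
    z = z,
    p_value = 2 * stats::pnorm(-abs(z)),
    lower = exp(beta - zq * se),
    upper = exp(beta + zq * se),
    stringsAsFactors = FALSE
  )
  rownames(coefs) <- NULL
  structure(list(coefficients = coefs,
                 loglik = c(null = loglik_null, fitted = ll$loglik),
                 vcov = vcov,
                 n = length(time), n_events = n_events,
                 iterations = iter, converged = converged,
                 conf_level = conf_level),
            class = "cox_fit")
}

# Efron partial log-likelihood, gradient and hessian at beta.
.cox_partial <- function(x, time, event, beta) {
  eta <- drop(x %*% beta)
  w <- exp(eta)
  p <- ncol(x)
  loglik <- 0
  grad <- numeric(p)
  hess <- matrix(0, p, p)
  for (t in sort(unique(time[event == 1]))) {
    risk <- time >= t
    dead <- time == t & event == 1
    d <- sum(dead)
    s0 <- sum(w[risk])
    s1 <- drop(crossprod(x[risk, , drop = FALSE], w[risk]))
    xr <- x[risk, , drop = FALSE] * sqrt(w[risk])
    s2 <- crossprod(xr)
    s0d <- sum(w[dead])
    s1d <- drop(crossprod(x[dead, , drop = FALSE], w[dead]))
    xd <- x[dead, , drop = FALSE] * sqrt(w[dead])
    s2d <- crossprod(xd)
    loglik <- loglik + sum(eta[dead])
    for (l in seq_len(d) - 1L) {
      f <- l / d
      phi <- s0 - f * s0d
      z1 <- (s1 - f * s1d) / phi
      loglik <- loglik - log(phi)
      grad <- grad - z1
      hess <- hess - ((s2 - f * s2d) / phi - tcrossprod(z1, z1))
    }
    grad <- grad + colSums(x[dead, , drop = FALSE])
  }
  list(loglik = loglik, gradient = grad, hessian = hess)
}

# Score test of beta = 0 (U' I^-1 U). With no tied event times this equals
# the Mantel-Cox log-rank chi-square for a single binary covariate.
.cox_score_test <- function(x, time, event) {
  x <- as.matrix(x)
  ll <- .cox_partial(x, time, event, numeric(ncol(x)))
  u <- ll$gradient
  drop(crossprod(u, solve(-ll$hessian, u)))
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards fit: n = %d, events = %d, %s\n",
              x$n, x$n_events,
              if (x$converged) sprintf("converged in %d iterations", x$iterations)
              else "DID NOT CONVERGE"))
  tab <- x$coefficients
  tab[-1] <- lapply(tab[-1], function(col) signif(col, 4))
  print(tab, row.names = FALSE)
  invisible(x)
}
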