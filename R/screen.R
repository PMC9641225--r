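#' Spearman independence screen
#'
#' Rank-based (Spearman) correlation between every pair of candidate
#' biomarker variables, with average ranks for ties. Pairs whose absolute
#' coefficient reaches the threshold are flagged as non-independent; when a
#' combined score is built, only variables below the threshold should be
#' treated as carrying independent information.
#'
#' @param data data.frame or matrix of numeric variables (one column per
#'   biomarker parameter); rows with missing values are dropped pairwise.
#' @param threshold Absolute-coefficient threshold above which a pair is
#'   flagged (default 0.8).
#' @return Object of class `correlation_screen`: `rho` (symmetric matrix,
#'   unit diagonal), `threshold`, `flagged` (data.frame `var_a`, `var_b`,
#'   `rho` for flagged pairs), `n`.
#' @examples
#' spearman_screen(data.frame(a = 1:10, b = (1:10)^3, c = runif(10)))
#' @export
spearman_screen <- function(data, threshold = 0.8) {
  m <- as.matrix(as.data.frame(data))
  if (!is.numeric(m)) stop("all screened variables must be numeric")
  if (ncol(m) < 2L) stop("need at least 2 variables to screen")
  complete <- stats::complete.cases(m)
  if (sum(complete) < 3L) stop("need at least 3 patients with complete values")
  rho <- stats::cor(m, method = "spearman", use = "pairwise.complete.obs")
  flagged <- which(abs(rho) >= threshold & upper.tri(rho), arr.ind = TRUE)
  flagged_df <- data.frame(
    var_a = colnames(rho)[flagged[, 1L]],
    var_b = colnames(rho)[flagged[, 2L]],
    rho = rho[flagged],
    stringsAsFactors = FALSE
  )
  structure(list(rho = rho, threshold = threshold, flagged = flagged_df,
                 n = sum(complete)),
            class = "correlation_screen")
}

#' @export
print.correlation_screen <- function(x, ...) {
  cat("Spearman correlation screen (threshold ", x$threshold, "):\n", sep = "")
  print(round(x$rho, 3))
  if (nrow(x$flagged)) {
    cat("Non-independent pairs:\n")
    print(x$flagged, row.names = FALSE)
  } else {
    cat("All pairs below threshold: variables treated as independent.\n")
  }
  invisible(x)
}
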