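#' Cochran's Q heterogeneity test with I-squared
#'
#' Q is the weighted sum of squared deviations of the per-SNP Wald ratios
#' from the fixed-effect IVW estimate, `Q = sum(w_j (theta_j - theta_IVW)^2)`,
#' referred to a chi-square with J-1 degrees of freedom. The I-squared index
#' is `max(0, (Q - df)/Q) * 100`; its 95% CI uses the Higgins-Thompson
#' test-based method on the H scale (back-transform of a normal interval for
#' ln H, truncated to [0%, 100%]).
#'
#' @param set An [instrument_set()] with at least 2 instruments.
#' @return Object of class `heterogeneity_result`: `Q`, `df`, `pval`, `i2`,
#'   `i2_ci_low`, `i2_ci_high` (percent).
#' @export
cochran_q <- function(set) {
  J <- nrow(set)
  if (J < 2L) stop("Cochran's Q needs >= 2 instruments", call. = FALSE)
  r <- wald_ratios(set)
  theta <- sum(r$weight * r$theta) / sum(r$weight)
  Q <- sum(r$weight * (r$theta - theta)^2)
  df <- J - 1L
  pval <- stats::pchisq(Q, df, lower.tail = FALSE)
  i2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0

  # test-based CI for ln H, H = sqrt(Q/df)  (Higgins & Thompson 2002)
  ln_h <- 0.5 * log(max(Q, .Machine$double.eps) / df)
  se_ln_h <- if (J > 2L && Q > J) {
    0.5 * (log(Q) - log(df)) / (sqrt(2 * Q) - sqrt(2 * J - 3))
  } else if (J > 3L) {
    sqrt(1 / (2 * (J - 2)) * (1 - 1 / (3 * (J - 2)^2)))
  } else {
    NA_real_  # too few studies for the normal approximation
  }
  if (is.na(se_ln_h)) {
    ci <- c(0, 100)
  } else {
    z <- stats::qnorm(0.975)
    h_lim <- pmax(1, exp(ln_h + c(-1, 1) * z * se_ln_h))
    ci <- pmin(pmax(100 * (h_lim^2 - 1) / h_lim^2, 0), 100)
  }
  structure(list(Q = Q, df = df, pval = pval, i2 = i2,
                 i2_ci_low = ci[1L], i2_ci_high = ci[2L]),
            class = "heterogeneity_result")
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("<heterogeneity> Q = %.3f on %d df, p = %.4g; I2 = %.1f%% [%.1f%%, %.1f%%]\n",
              x$Q, x$df, x$pval, x$i2, x$i2_ci_low, x$i2_ci_high))
  invisible(x)
}
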