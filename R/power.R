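# Instrument strength (R2, F) and analytic power for a binary outcome,
# following the noncentrality-parameter approach of the mRnd calculator.

#' Variance in the exposure explained by the instruments
#'
#' `R2 = sum(beta_i^2 * 2 * MAF_i * (1 - MAF_i)) / var_x`, where MAF is the
#' folded effect-allele frequency `min(eaf, 1 - eaf)`. With a standardized
#' exposure (per-SD betas) `var_x = 1`.
#'
#' @param instruments An [instrument_set()] (uses `beta_exposure`, `eaf`) or
#'   a `summary_stats`-style table (uses `beta`, `eaf`).
#' @param var_x Exposure variance; default 1 (standardized exposure).
#' @return Proportion of variance explained, in `[0, 1)`.
#' @export
#' @examples
#' variance_explained(load_table1_fixture())  # ~0.017
variance_explained <- function(instruments, var_x = 1) {
  beta <- instruments$beta_exposure %||% instruments$beta
  eaf <- instruments$eaf
  if (is.null(beta) || is.null(eaf)) {
    stop("need `beta`/`beta_exposure` and `eaf` columns", call. = FALSE)
  }
  if (any(eaf <= 0 | eaf >= 1)) {
    stop("eaf must be strictly inside (0,1)", call. = FALSE)
  }
  if (var_x <= 0) stop("var_x must be > 0", call. = FALSE)
  maf <- pmin(eaf, 1 - eaf)
  sum(beta^2 * 2 * maf * (1 - maf)) / var_x
}

#' First-stage F statistic for instrument strength
#'
#' Two conventions are exposed. `joint` is the multi-instrument first-stage
#' F, `F = r2 (n - 1 - k) / ((1 - r2) k)`. `mrnd` (the default) is the
#' single-regressor form used by the mRnd power calculator,
#' `F = r2 (n - 2) / (1 - r2)`; the published 327.56 for the
#' education/stroke instrument matches this convention at the outcome
#' sample size. A common weak-instrument threshold is F > 10.
#'
#' @param r2 Variance explained, in (0,1).
#' @param n Sample size.
#' @param k Instrument count (required for `joint`).
#' @param convention `"mrnd"` or `"joint"`.
#' @return The F statistic, with the convention in `attr(, "convention")`.
#' @export
f_statistic <- function(r2, n, k = NULL, convention = c("mrnd", "joint")) {
  convention <- match.arg(convention)
  if (!is.numeric(r2) || r2 <= 0 || r2 >= 1) {
    stop("r2 must be strictly inside (0,1)", call. = FALSE)
  }
  f <- if (convention == "joint") {
    if (is.null(k) || k < 1) stop("`k` required for the joint convention",
                                  call. = FALSE)
    if (n <= k + 1) stop("need n > k + 1", call. = FALSE)
    r2 * (n - 1 - k) / ((1 - r2) * k)
  } else {
    if (n <= 2) stop("need n > 2", call. = FALSE)
    r2 * (n - 2) / (1 - r2)
  }
  structure(f, convention = convention)
}

#' Analytic power for a binary outcome
#'
#' The noncentrality parameter is
#' `NCP = n * r2 * K (1 - K) * log(OR)^2` with case fraction K; power is the
#' two-sided normal/chi-square form
#' `Phi(sqrt(NCP) - z) + Phi(-sqrt(NCP) - z)`, `z = qnorm(1 - alpha/2)`,
#' which makes `power(OR = 1) = alpha` hold exactly and gives
#' `power(OR) = power(1/OR)` by symmetry in `log(OR)`.
#'
#' @param n Outcome-GWAS sample size.
#' @param r2 Variance in the exposure explained by the instrument.
#' @param case_fraction Proportion of cases among the outcome sample, (0,1).
#' @param odds_ratio Odds ratio(s) under test (vectorized).
#' @param alpha Two-sided type-I error rate. Default 0.05.
#' @return Power in `[alpha, 1)`, same length as `odds_ratio`.
#' @export
#' @examples
#' power_binary(29633, 0.0109, 0.347822, 0.54)  # ~1
power_binary <- function(n, r2, case_fraction, odds_ratio, alpha = 0.05) {
  stopifnot(n > 0, r2 > 0, r2 < 1, all(odds_ratio > 0))
  assert_scalar_prob(case_fraction, "case_fraction", open_right = TRUE)
  assert_scalar_prob(alpha, "alpha", open_right = TRUE)
  ncp <- n * r2 * case_fraction * (1 - case_fraction) * log(odds_ratio)^2
  z <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(sqrt(ncp) - z) + stats::pnorm(-sqrt(ncp) - z)
}

#' Smallest detectable odds ratios at a target power
#'
#' Inverts [power_binary()] in `log(OR)` on each side of 1 by monotone
#' bisection until the achieved power is within 1e-8 of the target. The
#' two bounds are reciprocal (the NCP depends on `log(OR)^2` only).
#'
#' @inheritParams power_binary
#' @param target_power Desired power, in `(alpha, 1)`.
#' @return Named numeric `c(or_low, or_high)` with `or_low < 1 < or_high`.
#' @export
detectable_or <- function(n, r2, case_fraction, target_power = 0.8,
                          alpha = 0.05) {
  if (target_power <= alpha || target_power >= 1) {
    stop("target_power must be in (alpha, 1)", call. = FALSE)
  }
  f <- function(l) power_binary(n, r2, case_fraction, exp(l), alpha) -
    target_power
  hi <- 1
  while (f(hi) < 0 && hi < 50) hi <- hi * 2
  if (f(hi) < 0) {
    stop("detectable_or did not converge: power never reaches ",
         target_power, " (r2 or n too small)", call. = FALSE)
  }
  lo <- 0
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
    if (abs(f(mid)) < 1e-8) break
  }
  if (abs(f(mid)) >= 1e-8) {
    stop("detectable_or bisection failed: residual ", f(mid), call. = FALSE)
  }
  c(or_low = exp(-mid), or_high = exp(mid))
}
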