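# Causal estimators on a harmonized instrument set. Throughout, gamma-hat
# (beta_exposure) is the per-SD exposure effect, Gamma-hat (beta_outcome)
# the log-odds outcome effect, and weights are first-order: outcome
# uncertainty only, w_j = (gamma_j / sigma_Yj)^2 on the ratio scale.

#' Construct a causal-effect estimate record
#'
#' @param method One of `ivw_fixed`, `ivw_random`, `weighted_median`,
#'   `egger_slope`.
#' @param theta Log-OR per SD of exposure.
#' @param se Standard error of `theta`.
#' @param n_snps Instrument count used.
#' @param extra Optional named list merged into the record.
#' @return Object of class `mr_estimate` with 95% CI, two-sided normal
#'   p-value, and the odds-ratio scale (`exp(theta)` with exponentiated CI).
#' @export
mr_estimate <- function(method, theta, se, n_snps, extra = list()) {
  z <- stats::qnorm(0.975)
  ci_low <- theta - z * se
  ci_high <- theta + z * se
  out <- c(list(
    method = method, theta = theta, se = se,
    ci_low = ci_low, ci_high = ci_high,
    pval = 2 * stats::pnorm(-abs(theta) / se),
    odds_ratio = exp(theta),
    or_ci_low = exp(ci_low), or_ci_high = exp(ci_high),
    n_snps = n_snps,
    scale = "log-odds IS per SD (3.6 years) of schooling"
  ), extra)
  structure(out, class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate:%s>  theta = %.4f (SE %.4f)  OR = %.2f [%.2f, %.2f]  p = %.3g  (%d SNPs)\n",
              x$method, x$theta, x$se, x$odds_ratio, x$or_ci_low,
              x$or_ci_high, x$pval, x$n_snps))
  invisible(x)
}

#' Per-SNP Wald ratio estimates
#'
#' The ratio estimate for SNP j is `theta_j = beta_outcome / beta_exposure`
#' with first-order (delta-method) standard error
#' `se_j = se_outcome / |beta_exposure|` and inverse-variance weight
#' `w_j = se_j^-2`.
#'
#' @param set An [instrument_set()]; every exposure beta must be nonzero.
#' @return Data.frame with columns `snp_id`, `theta`, `se`, `weight`.
#' @export
wald_ratios <- function(set) {
  zero <- set$snp_id[set$beta_exposure == 0]
  if (length(zero)) {
    stop("zero exposure effect for SNP(s): ",
         paste(zero, collapse = ", "), call. = FALSE)
  }
  theta <- set$beta_outcome / set$beta_exposure
  se <- set$se_outcome / abs(set$beta_exposure)
  data.frame(snp_id = set$snp_id, theta = theta, se = se,
             weight = se^-2, stringsAsFactors = FALSE)
}

#' Inverse-variance-weighted estimate
#'
#' Precision-weighted mean of the Wald ratios,
#' `theta = sum(w_j theta_j) / sum(w_j)` with `w_j = (gamma_j/sigma_Yj)^2`;
#' algebraically identical to the weighted regression of Gamma-hat on
#' gamma-hat through the origin with weights `sigma_Yj^-2`. The fixed-effect
#' SE is `(sum w_j)^-1/2`; the multiplicative random-effects model (the
#' default) inflates it by `max(1, sqrt(Q/(J-1)))`. The point estimate is
#' the same under both models.
#'
#' @param set An [instrument_set()] with at least 2 instruments.
#' @param model `"random"` (default) or `"fixed"`.
#' @return An [mr_estimate()] with extra fields `Q` (Cochran statistic) and
#'   `model`.
#' @export
mr_ivw <- function(set, model = c("random", "fixed")) {
  model <- match.arg(model)
  if (nrow(set) < 2L) {
    stop("IVW needs >= 2 instruments; for a single SNP use wald_ratios()",
         call. = FALSE)
  }
  r <- wald_ratios(set)
  W <- sum(r$weight)
  theta <- sum(r$weight * r$theta) / W
  Q <- sum(r$weight * (r$theta - theta)^2)
  se <- sqrt(1 / W)
  if (model == "random") se <- se * max(1, sqrt(Q / (nrow(set) - 1L)))
  mr_estimate(paste0("ivw_", model), theta, se, nrow(set),
              extra = list(Q = Q, model = model))
}

# weighted median of theta at standardized cumulative weight 0.5;
# ties in theta broken by id for determinism
weighted_median_point <- function(theta, w, ids = NULL) {
  ord <- if (is.null(ids)) order(theta) else order(theta, ids)
  theta <- theta[ord]; w <- w[ord]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (s[1L] >= 0.5) return(theta[1L])
  n <- length(theta)
  if (s[n] <= 0.5) return(theta[n])
  stats::approx(s, theta, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median estimate
#'
#' The 50th weighted percentile of the ordered Wald ratios: with
#' standardized cumulative weights `s_j = (cumsum(w)_j - w_j/2) / sum(w)`,
#' the estimate interpolates theta against s at s = 0.5. It is consistent
#' when at least half the weight comes from valid instruments. The SE is
#' the standard deviation of the estimate over `n_boot` parametric
#' bootstrap replicates drawing `gamma* ~ N(gamma_j, se_exposure_j)` and
#' `Gamma* ~ N(Gamma_j, se_outcome_j)`.
#'
#' @param set An [instrument_set()] with at least 3 instruments.
#' @param n_boot Bootstrap replicates (default 2000); fewer than 100 draws a
#'   warning.
#' @param seed Seed for the bootstrap; recorded in the result. `NULL` uses
#'   the current RNG stream.
#' @return An [mr_estimate()] with extra fields `n_boot` and `seed`.
#' @export
mr_weighted_median <- function(set, n_boot = 2000L, seed = NULL) {
  J <- nrow(set)
  if (J < 3L) stop("weighted median needs >= 3 instruments", call. = FALSE)
  if (n_boot < 100L) {
    warning("n_boot < 100: bootstrap SE will be unreliable", call. = FALSE)
  }
  r <- wald_ratios(set)
  theta <- weighted_median_point(r$theta, r$weight, set$snp_id)
  boot <- with_seed(seed, {
    gx <- matrix(stats::rnorm(J * n_boot, set$beta_exposure,
                              set$se_exposure), nrow = J)
    gy <- matrix(stats::rnorm(J * n_boot, set$beta_outcome,
                              set$se_outcome), nrow = J)
    vapply(seq_len(n_boot), function(b) {
      th <- gy[, b] / gx[, b]
      w <- (gx[, b] / set$se_outcome)^2
      weighted_median_point(th, w, set$snp_id)
    }, numeric(1))
  })
  se <- stats::sd(boot)
  mr_estimate("weighted_median", theta, se, J,
              extra = list(n_boot = as.integer(n_boot), seed = seed))
}

#' MR-Egger regression
#'
#' Weighted linear regression of the outcome effects on the exposure
#' effects *with* an intercept, after orienting every instrument so its
#' exposure effect is positive (both betas negated where needed). Weights
#' are `se_outcome^-2`. The slope is the causal estimate under the InSIDE
#' assumption; the intercept estimates average directional pleiotropy.
#' Both standard errors are inflated by `max(1, sqrt(RSS_w / (J - 2)))`
#' (multiplicative random effects).
#'
#' @param set An [instrument_set()] with at least 3 instruments.
#' @return Object of class `mr_egger`: `$slope` (an [mr_estimate()]),
#'   `$intercept`, `$intercept_se`, `$intercept_pval`, `$n_snps`.
#' @export
mr_egger <- function(set) {
  J <- nrow(set)
  if (J < 3L) stop("MR-Egger needs >= 3 instruments", call. = FALSE)
  sgn <- ifelse(set$beta_exposure < 0, -1, 1)
  bx <- set$beta_exposure * sgn
  by <- set$beta_outcome * sgn
  w <- set$se_outcome^-2
  if (stats::var(bx) == 0) {
    stop("collinearity: all exposure effects identical after orientation",
         call. = FALSE)
  }
  X <- cbind(intercept = 1, slope = bx)
  XtW <- t(X * w)
  V <- solve(XtW %*% X)          # unit-variance covariance
  coefs <- drop(V %*% (XtW %*% by))
  resid <- by - drop(X %*% coefs)
  rss <- sum(w * resid^2)
  infl <- max(1, sqrt(rss / (J - 2L)))
  ses <- sqrt(diag(V)) * infl
  slope <- mr_estimate("egger_slope", coefs[["slope"]], ses[["slope"]], J,
                       extra = list(rss = rss))
  structure(list(
    slope = slope,
    intercept = coefs[["intercept"]],
    intercept_se = ses[["intercept"]],
    intercept_pval = 2 * stats::pnorm(-abs(coefs[["intercept"]]) /
                                        ses[["intercept"]]),
    n_snps = J
  ), class = "mr_egger")
}

#' @export
print.mr_egger <- function(x, ...) {
  print(x$slope)
  cat(sprintf("  intercept = %.4f (SE %.4f), p = %.3g\n",
              x$intercept, x$intercept_se, x$intercept_pval))
  invisible(x)
}

#' Report an estimate on the odds-ratio scale
#'
#' The odds ratio is `exp(theta)` with exponentiated CI endpoints,
#' interpreted per 1 SD (about 3.6 years) of schooling.
#'
#' @param estimate An [mr_estimate()] (log-odds scale).
#' @return Named list `odds_ratio`, `ci_low`, `ci_high`, `pval`, `per`.
#' @export
to_odds_ratio <- function(estimate) {
  stopifnot(inherits(estimate, "mr_estimate"))
  list(method = estimate$method,
       odds_ratio = exp(estimate$theta),
       ci_low = exp(estimate$ci_low),
       ci_high = exp(estimate$ci_high),
       pval = estimate$pval,
       per = "1 SD (3.6 years) increase in schooling")
}
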