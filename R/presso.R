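# MR-PRESSO: residual-sum-of-squares resampling test for horizontal
# pleiotropy. Residuals are taken against leave-one-out IVW slopes so an
# outlier cannot mask itself.

# leave-one-out IVW slopes, vectorized: theta_(-j) for each j
loo_ivw_slopes <- function(bx, by, sy) {
  w <- (bx / sy)^2
  th <- by / bx
  num <- sum(w * th) - w * th
  den <- sum(w) - w
  num / den
}

#' MR-PRESSO global, outlier and distortion tests
#'
#' The observed statistic is the weighted residual sum of squares
#' `RSS = sum(sy_j^-2 (Gamma_j - gamma_j * theta_(-j))^2)` where
#' `theta_(-j)` is the IVW slope with SNP j left out. The null distribution
#' is built by parametric simulation: `n_sim` times, draw
#' `gamma* ~ N(gamma_j, sx_j)` and `Gamma* ~ N(gamma_j * theta_(-j), sy_j)`
#' and recompute RSS (with the simulated data's own leave-one-out slopes).
#'
#' * global test: `p = (1 + #\{RSS* >= RSS_obs\}) / (n_sim + 1)`;
#' * outlier test: each SNP's observed weighted squared residual against its
#'   simulated residual distribution, Bonferroni-corrected by J; SNPs with
#'   corrected p < `outlier_alpha` are flagged;
#' * distortion test (only when outliers exist): the change in the IVW
#'   estimate after removing the flagged SNPs, referred to the simulated
#'   distribution of the change after removing equally many random SNPs.
#'
#' @param set An [instrument_set()] with at least 4 instruments.
#' @param n_sim Simulation count, at least 100 (default 1000).
#' @param seed Seed for the simulations (recorded in the result).
#' @param outlier_alpha Significance level for the Bonferroni-corrected
#'   per-SNP outlier test. Default 0.05.
#' @return Object of class `presso_result`: `global_rss`, `global_pval`,
#'   `per_snp_pvals` (named), `outliers`, `distortion_pval` (`NULL` when no
#'   outliers are flagged, flagged explicitly via `has_outliers`), `n_sim`,
#'   `seed`.
#' @export
mr_presso <- function(set, n_sim = 1000L, seed = NULL, outlier_alpha = 0.05) {
  J <- nrow(set)
  if (J < 4L) stop("MR-PRESSO needs >= 4 instruments", call. = FALSE)
  if (n_sim < 100L) stop("n_sim must be >= 100", call. = FALSE)
  bx <- set$beta_exposure; by <- set$beta_outcome
  sx <- set$se_exposure; sy <- set$se_outcome
  if (any(sx <= 0) || any(sy <= 0)) {
    stop("degenerate standard error (<= 0)", call. = FALSE)
  }
  theta_loo <- loo_ivw_slopes(bx, by, sy)
  resid_obs <- sy^-2 * (by - bx * theta_loo)^2
  rss_obs <- sum(resid_obs)

  res <- with_seed(seed, {
    bxs <- matrix(stats::rnorm(J * n_sim, bx, sx), nrow = J)
    bys <- matrix(stats::rnorm(J * n_sim, bx * theta_loo, sy), nrow = J)
    ws <- (bxs / sy)^2
    ths <- bys / bxs
    num <- sweep(-ws * ths, 2L, colSums(ws * ths), `+`)
    den <- sweep(-ws, 2L, colSums(ws), `+`)
    loo_s <- num / den
    resid_s <- sy^-2 * (bys - bxs * loo_s)^2   # J x n_sim
    rss_s <- colSums(resid_s)

    global_pval <- (1 + sum(rss_s >= rss_obs)) / (n_sim + 1)
    per_snp <- (1 + rowSums(resid_s >= resid_obs)) / (n_sim + 1)
    p_adj <- pmin(1, per_snp * J)
    outliers <- set$snp_id[p_adj < outlier_alpha]

    distortion_pval <- NULL
    if (length(outliers)) {
      out_idx <- match(outliers, set$snp_id)
      w_obs <- (bx / sy)^2; th_obs <- by / bx
      ivw_all <- sum(w_obs * th_obs) / sum(w_obs)
      if (length(out_idx) < J - 1L) {
        ivw_kept <- sum((w_obs * th_obs)[-out_idx]) / sum(w_obs[-out_idx])
        d_obs <- ivw_kept - ivw_all
        d_sim <- vapply(seq_len(n_sim), function(s) {
          drop_idx <- sample.int(J, length(out_idx))
          full <- sum(ws[, s] * ths[, s]) / sum(ws[, s])
          part <- sum((ws[, s] * ths[, s])[-drop_idx]) /
            sum(ws[, s][-drop_idx])
          part - full
        }, numeric(1))
        distortion_pval <- (1 + sum(abs(d_sim) >= abs(d_obs))) / (n_sim + 1)
      }
    }
    list(global_pval = global_pval,
         per_snp_pvals = stats::setNames(per_snp, set$snp_id),
         outliers = outliers, distortion_pval = distortion_pval)
  })

  structure(list(global_rss = rss_obs, global_pval = res$global_pval,
                 per_snp_pvals = res$per_snp_pvals,
                 outliers = res$outliers,
                 has_outliers = length(res$outliers) > 0L,
                 distortion_pval = res$distortion_pval,
                 n_sim = as.integer(n_sim), seed = seed,
                 outlier_alpha = outlier_alpha),
            class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("<mr_presso> global RSS = %.3f, p = %.4g (%d sims)\n",
              x$global_rss, x$global_pval, x$n_sim))
  if (x$has_outliers) {
    cat("  outliers:", paste(x$outliers, collapse = ", "), "\n")
    if (!is.null(x$distortion_pval)) {
      cat(sprintf("  distortion test p = %.4g\n", x$distortion_pval))
    }
  } else {
    cat("  no horizontal pleiotropic outliers identified\n")
  }
  invisible(x)
}
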