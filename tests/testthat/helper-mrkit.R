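# Shared fixtures and independent oracles for the test suite.

# Build an instrument set directly from harmonized effect vectors.
make_set <- function(bx, sx, by, sy, ids = NULL) {
  J <- length(bx)
  instrument_set(data.frame(
    snp_id = ids %||% sprintf("rs%04d", seq_len(J)),
    beta_exposure = bx, se_exposure = sx,
    beta_outcome = by, se_outcome = sy,
    eaf = rep(0.3, J), action = "kept_as_is",
    stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random harmonized set in a realistic summary-statistic regime.
random_set <- function(J, seed) {
  withr::local_seed(seed)
  bx <- rnorm(J, 0.02, 0.008)
  bx[abs(bx) < 1e-3] <- 1e-3   # keep ratios finite
  sx <- runif(J, 0.002, 0.004)
  sy <- runif(J, 0.01, 0.03)
  by <- rnorm(J, 0.3 * bx, sy)
  make_set(bx, sx, by, sy)
}

# Independent IVW oracle: weighted least squares of by on bx through the
# origin with weights 1/sy^2, coded as the closed-form normal equations --
# a different route than the precision-weighted mean of Wald ratios.
oracle_wls_origin <- function(bx, by, sy) {
  w <- sy^-2
  theta <- sum(w * bx * by) / sum(w * bx^2)
  se_fixed <- sqrt(1 / sum(w * bx^2))
  list(theta = theta, se_fixed = se_fixed)
}

# Write a summary-stats TSV from a data.frame of character columns.
write_raw_tsv <- function(df, path = withr::local_tempfile(fileext = ".tsv",
                                                           .local_envir = parent.frame())) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Minimal valid exposure-style table.
toy_table <- function(n = 3L) {
  data.frame(
    snp_id = sprintf("rs%d", seq_len(n)),
    effect_allele = rep(c("A", "T", "C"), length.out = n),
    other_allele = rep(c("G", "C", "A"), length.out = n),
    eaf = seq(0.2, 0.6, length.out = n),
    beta = seq(0.01, 0.03, length.out = n),
    se = rep(0.005, n),
    pval = rep(1e-10, n),
    stringsAsFactors = FALSE
  )
}
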