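# Orchestration: read -> genome-wide filter -> harmonize -> stage-1
# confounder screen -> stage-2 diagnostics (Q/I2, Egger intercept,
# MR-PRESSO) -> IVW + weighted median + MR-Egger -> OR conversion ->
# R2 / F / power. Emits one machine-readable report.

#' Run the full two-sample MR pipeline
#'
#' `config` is a plain list or the path to a JSON file with keys:
#' `exposure` / `outcome` (paths or data.frames), optional `confounders`
#' (named list of paths/data.frames), `gw_threshold` (default 5e-8),
#' `palindromic_eaf_window` (0.08), `alpha` (0.05), `screen_enabled`
#' (TRUE), `n_boot` (2000), `n_sim` (1000), `outlier_alpha` (0.05),
#' `seed` (required), and for the power block `n_outcome`,
#' `case_fraction`, `target_power` (0.8), `var_x` (1), `n_exposure`
#' (optional, for the joint-convention F).
#'
#' Any stage failure aborts with the stage name; a partial report is never
#' produced. Identical config and seeds give a byte-identical report via
#' [write_report()].
#'
#' @param config List or JSON path.
#' @return Object of class `mr_report`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  cfg <- config
  if (is.null(cfg$seed)) stop("config error: `seed` is required",
                              call. = FALSE)
  cfg$gw_threshold <- cfg$gw_threshold %||% 5e-8
  cfg$palindromic_eaf_window <- cfg$palindromic_eaf_window %||% 0.08
  cfg$alpha <- cfg$alpha %||% 0.05
  cfg$screen_enabled <- cfg$screen_enabled %||% TRUE
  cfg$n_boot <- cfg$n_boot %||% 2000L
  cfg$n_sim <- cfg$n_sim %||% 1000L
  cfg$outlier_alpha <- cfg$outlier_alpha %||% 0.05
  cfg$target_power <- cfg$target_power %||% 0.8
  cfg$var_x <- cfg$var_x %||% 1

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  load_tab <- function(x, what) {
    if (is.character(x)) read_summary_stats(x) else {
      stopifnot(is.data.frame(x))
      if (inherits(x, "summary_stats")) x else new_summary_stats(x)
    }
  }

  exposure <- stage("read_exposure", load_tab(cfg$exposure))
  outcome <- stage("read_outcome", load_tab(cfg$outcome))
  inputs <- list(
    exposure = list(path = if (is.character(cfg$exposure)) cfg$exposure
                    else "<in-memory>", n_rows = nrow(exposure)),
    outcome = list(path = if (is.character(cfg$outcome)) cfg$outcome
                   else "<in-memory>", n_rows = nrow(outcome)))

  exposure <- stage("genome_wide_filter",
                    genome_wide_filter(exposure, cfg$gw_threshold))
  set <- stage("harmonize",
               harmonize(exposure, outcome, cfg$palindromic_eaf_window))

  screen <- NULL
  if (isTRUE(cfg$screen_enabled) && length(cfg$confounders)) {
    conf <- stage("read_confounders",
                  lapply(cfg$confounders, load_tab))
    screen <- stage("confounder_screen",
                    confounder_screen(set, conf, alpha = cfg$alpha))
    set <- stage("apply_exclusions", apply_exclusions(set, screen))
  }
  if (nrow(set) < 4L) {
    stop("pipeline stage 'screen' failed: fewer than 4 instruments remain",
         call. = FALSE)
  }

  seeds <- sub_seeds(cfg$seed, 2L)
  het <- stage("heterogeneity", cochran_q(set))
  egger <- stage("mr_egger", mr_egger(set))
  presso <- stage("mr_presso",
                  mr_presso(set, n_sim = cfg$n_sim, seed = seeds[1L],
                            outlier_alpha = cfg$outlier_alpha))

  ivw_fixed <- stage("ivw", mr_ivw(set, "fixed"))
  ivw_random <- stage("ivw", mr_ivw(set, "random"))
  wm <- stage("weighted_median",
              mr_weighted_median(set, n_boot = cfg$n_boot,
                                 seed = seeds[2L]))
  estimates <- lapply(list(ivw_fixed = ivw_fixed, ivw_random = ivw_random,
                           weighted_median = wm, egger = egger$slope),
                      function(e) {
                        unclass(e)[c("method", "theta", "se", "ci_low",
                                     "ci_high", "pval", "odds_ratio",
                                     "or_ci_low", "or_ci_high", "n_snps")]
                      })

  power_block <- NULL
  if (!is.null(cfg$n_outcome) && !is.null(cfg$case_fraction)) {
    power_block <- stage("power", {
      r2 <- variance_explained(set, var_x = cfg$var_x)
      ors <- vapply(estimates, `[[`, numeric(1), "odds_ratio")
      det <- detectable_or(cfg$n_outcome, r2, cfg$case_fraction,
                           cfg$target_power, cfg$alpha)
      blk <- list(
        r2 = r2,
        f_mrnd = as.numeric(f_statistic(r2, cfg$n_outcome,
                                        convention = "mrnd")),
        ncp_per_log_or2 = cfg$n_outcome * r2 * cfg$case_fraction *
          (1 - cfg$case_fraction),
        power_at_estimates = as.list(power_binary(
          cfg$n_outcome, r2, cfg$case_fraction, ors, cfg$alpha)),
        detectable_or_low = unname(det["or_low"]),
        detectable_or_high = unname(det["or_high"]),
        target_power = cfg$target_power)
      if (!is.null(cfg$n_exposure)) {
        blk$f_joint <- as.numeric(
          f_statistic(r2, cfg$n_exposure, k = nrow(set),
                      convention = "joint"))
      }
      blk
    })
  }

  actions <- attr(set, "actions")
  report <- structure(list(
    tool = list(package = "mrkit",
                version = as.character(utils::packageVersion("mrkit"))),
    inputs = inputs,
    seeds = list(master = cfg$seed, presso = seeds[1L],
                 weighted_median_boot = seeds[2L]),
    thresholds = cfg[c("gw_threshold", "palindromic_eaf_window", "alpha",
                       "n_boot", "n_sim", "outlier_alpha")],
    filter_log = provenance(set),
    n_instruments = nrow(set),
    confounder_screen = if (is.null(screen)) NULL else list(
      threshold = screen$threshold, m = screen$m,
      excluded = screen$excluded,
      per_trait_counts = as.list(screen$per_trait_counts)),
    heterogeneity = unclass(het),
    egger_intercept = list(estimate = egger$intercept,
                           se = egger$intercept_se,
                           pval = egger$intercept_pval),
    presso = list(global_rss = presso$global_rss,
                  global_pval = presso$global_pval,
                  outliers = presso$outliers,
                  has_outliers = presso$has_outliers,
                  distortion_pval = presso$distortion_pval,
                  n_sim = presso$n_sim),
    estimates = estimates,
    power = power_block
  ), class = "mr_report")
  attr(report, "instruments") <- set
  report
}

#' Write an analysis report as canonical JSON
#'
#' Serialization is deterministic (fixed digit count, unboxed scalars), so
#' re-running the pipeline with identical inputs and seeds reproduces the
#' file byte for byte.
#'
#' @param report An `mr_report` from [run_pipeline()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "mr_report"))
  json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = I(15),
                           null = "null", dataframe = "rows", pretty = TRUE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' @export
print.mr_report <- function(x, ...) {
  cat("<mr_report>", x$n_instruments, "instruments\n")
  for (nm in names(x$estimates)) {
    e <- x$estimates[[nm]]
    cat(sprintf("  %-16s OR %.2f [%.2f, %.2f]  p = %.3g\n", nm,
                e$odds_ratio, e$or_ci_low, e$or_ci_high, e$pval))
  }
  cat(sprintf("  heterogeneity: I2 = %.1f%%, p = %.3g; Egger intercept p = %.3g; PRESSO global p = %.3g\n",
              x$heterogeneity$i2, x$heterogeneity$pval,
              x$egger_intercept$pval, x$presso$global_pval))
  if (!is.null(x$power)) {
    cat(sprintf("  R2 = %.3f%%, F(mRnd) = %.1f, detectable OR at %.0f%% power: [%.2f, %.2f]\n",
                100 * x$power$r2, x$power$f_mrnd, 100 * x$power$target_power,
                x$power$detectable_or_low, x$power$detectable_or_high))
  }
  invisible(x)
}

#' Scatter data backing the per-SNP causal-estimate plot
#'
#' One row per instrument: exposure effect (x), outcome effect (y) and both
#' standard errors, plus the fitted lines for each supplied estimate (IVW
#' and weighted-median lines pass through the origin; the MR-Egger line has
#' its pleiotropy intercept, on the gamma>0 oriented scale).
#'
#' @param set A non-empty [instrument_set()].
#' @param estimates List of [mr_estimate()] and/or `mr_egger` objects.
#' @return Data.frame with columns `snp_id`, `beta_exposure`,
#'   `beta_outcome`, `se_exposure`, `se_outcome`; fitted lines in
#'   `attr(, "lines")` (`method`, `intercept`, `slope`).
#' @export
scatter_data <- function(set, estimates = list()) {
  if (!nrow(set)) stop("empty instrument set", call. = FALSE)
  out <- data.frame(snp_id = set$snp_id,
                    beta_exposure = set$beta_exposure,
                    beta_outcome = set$beta_outcome,
                    se_exposure = set$se_exposure,
                    se_outcome = set$se_outcome,
                    stringsAsFactors = FALSE)
  lines <- do.call(rbind, lapply(estimates, function(e) {
    if (inherits(e, "mr_egger")) {
      data.frame(method = "egger", intercept = e$intercept,
                 slope = e$slope$theta, stringsAsFactors = FALSE)
    } else {
      data.frame(method = e$method, intercept = 0, slope = e$theta,
                 stringsAsFactors = FALSE)
    }
  }))
  attr(out, "lines") <- lines %||%
    data.frame(method = character(), intercept = numeric(),
               slope = numeric(), stringsAsFactors = FALSE)
  out
}
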