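# Synthetic paired exposure/outcome/confounder GWAS summary statistics with
# known causal effect and configurable horizontal pleiotropy. The defaults
# are the education -> ischemic-stroke regime: 111 instruments, exposure
# GWAS of 405,072, outcome GWAS of 29,633 with case fraction 0.347822,
# instrument R2 of 1.09%, standardized exposure (per-SD betas).

#' Simulation configuration
#'
#' @param J Instrument count. Default 111.
#' @param n_exposure,n_outcome GWAS sample sizes. Defaults 405072 / 29633.
#' @param case_fraction Outcome case fraction. Default 0.347822.
#' @param theta_true Causal log-OR per SD of exposure. Default `log(0.54)`.
#' @param target_r2 Exposure variance jointly explained by the true
#'   instrument effects. Default 0.0109.
#' @param var_x Exposure variance (1 = standardized, per-SD betas).
#' @param pleiotropy_mode One of `"none"`, `"balanced"`, `"directional"`,
#'   `"inside_violated"`. Direct (pleiotropic) effects `alpha_j` are drawn
#'   for a share `invalid_fraction` of SNPs: `balanced` is `N(0, tau_alpha)`;
#'   `directional` is `N(mu_alpha, tau_alpha)` applied in the gamma>0
#'   oriented frame (sign-aligned with the exposure effect, so the notion is
#'   invariant to effect-allele coding); `inside_violated` scales with
#'   instrument strength, violating InSIDE.
#' @param mu_alpha,tau_alpha Mean and SD of the direct effects (log-odds).
#' @param invalid_fraction Share of SNPs with nonzero `alpha_j`, in `[0,1]`.
#' @param eaf_range Range the effect-allele frequencies are drawn from.
#' @param confounder_traits Named numeric vector: per-trait fraction of SNPs
#'   truly associated with that confounder (e.g. `c(bmi = 0.25)`).
#'   `NULL` for none.
#' @param seed Master seed; one seed drives a per-purpose sub-seed sequence.
#' @return Validated list of class `simulation_config`.
#' @export
simulation_config <- function(J = 111L,
                              n_exposure = 405072L,
                              n_outcome = 29633L,
                              case_fraction = 0.347822,
                              theta_true = log(0.54),
                              target_r2 = 0.0109,
                              var_x = 1,
                              pleiotropy_mode = c("none", "balanced",
                                                  "directional",
                                                  "inside_violated"),
                              mu_alpha = 0,
                              tau_alpha = 0,
                              invalid_fraction = 0,
                              eaf_range = c(0.05, 0.95),
                              confounder_traits = NULL,
                              seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  stopifnot(J >= 1, n_exposure > 0, n_outcome > 0)
  assert_scalar_prob(case_fraction, "case_fraction", open_right = TRUE)
  if (invalid_fraction < 0 || invalid_fraction > 1) {
    stop("invalid_fraction must be in [0,1]", call. = FALSE)
  }
  if (length(eaf_range) != 2L || eaf_range[1] <= 0 || eaf_range[2] >= 1 ||
      eaf_range[1] > eaf_range[2]) {
    stop("eaf_range must be within (0,1)", call. = FALSE)
  }
  if (!is.null(confounder_traits) &&
      (is.null(names(confounder_traits)) ||
         any(confounder_traits < 0 | confounder_traits > 1))) {
    stop("confounder_traits must be a named vector of fractions in [0,1]",
         call. = FALSE)
  }
  structure(list(J = as.integer(J), n_exposure = n_exposure,
                 n_outcome = n_outcome, case_fraction = case_fraction,
                 theta_true = theta_true, target_r2 = target_r2,
                 var_x = var_x, pleiotropy_mode = pleiotropy_mode,
                 mu_alpha = mu_alpha, tau_alpha = tau_alpha,
                 invalid_fraction = invalid_fraction,
                 eaf_range = eaf_range,
                 confounder_traits = confounder_traits,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# non-palindromic allele pairs so synthetic data harmonizes without drops
draw_allele_pairs <- function(J) {
  pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                 c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
  pairs[sample.int(nrow(pairs), J, replace = TRUE), , drop = FALSE]
}

#' Simulate paired GWAS summary statistics with known truth
#'
#' Generates, under one master seed, an exposure table, an outcome table and
#' optional confounder tables in the standard `summary_stats` schema, plus
#' the simulation truth. Per SNP j: `eaf_j ~ U(eaf_range)`; true effects
#' `gamma_j` are standard-normal draws rescaled so the implied variance
#' explained equals `target_r2` exactly;
#' `se_X = 1/sqrt(2 n_exposure m(1-m))` (standardized exposure) and
#' `se_Y = 1/sqrt(2 n_outcome K(1-K) m(1-m))` (case-control approximation),
#' `m` the minor-allele frequency; observed effects are normal draws around
#' the truth; the outcome truth is `Gamma_j = theta_true gamma_j + alpha_j`.
#' Confounder p-values are Uniform(0,1) except for planted associations,
#' which get two-sided p-values of z-scores drawn from `N(6, 1)` (a clearly
#' detectable GWAS hit). Identical config implies identical output.
#'
#' @param config A [simulation_config()].
#' @return List with elements `exposure`, `outcome`, `confounders` (named
#'   list, possibly empty) and `truth` (per-SNP `gamma`, `alpha`,
#'   `theta_true`, invalid ids, per-trait confounder ids, seed).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  if (cfg$target_r2 <= 0 || cfg$target_r2 >= cfg$var_x) {
    stop("infeasible target_r2: must be in (0, var_x)", call. = FALSE)
  }
  seeds <- sub_seeds(cfg$seed, 3L)

  with_seed(seeds[1L], {
    J <- cfg$J
    eaf <- stats::runif(J, cfg$eaf_range[1], cfg$eaf_range[2])
    m <- pmin(eaf, 1 - eaf)
    g_raw <- stats::rnorm(J)
    denom <- sum(g_raw^2 * 2 * m * (1 - m))
    if (denom <= 0) stop("infeasible target_r2: degenerate draw",
                         call. = FALSE)
    gamma <- g_raw * sqrt(cfg$target_r2 * cfg$var_x / denom)
    se_x <- 1 / sqrt(2 * cfg$n_exposure * m * (1 - m))
    beta_x <- stats::rnorm(J, gamma, se_x)

    n_invalid <- round(cfg$invalid_fraction * J)
    invalid <- if (cfg$pleiotropy_mode == "none" || n_invalid == 0L) {
      integer()
    } else {
      sample.int(J, n_invalid)
    }
    alpha <- numeric(J)
    if (length(invalid)) {
      sgn <- sign(gamma[invalid])
      alpha[invalid] <- switch(
        cfg$pleiotropy_mode,
        balanced = stats::rnorm(n_invalid, 0, cfg$tau_alpha),
        directional = sgn * stats::rnorm(n_invalid, cfg$mu_alpha,
                                         cfg$tau_alpha),
        inside_violated = sgn * cfg$mu_alpha *
          (abs(gamma[invalid]) / mean(abs(gamma))) +
          stats::rnorm(n_invalid, 0, cfg$tau_alpha),
        numeric(n_invalid)
      )
    }
    al <- draw_allele_pairs(J)
    snp_id <- sprintf("rs%07d", sample.int(9999999L, J))
  })

  Gamma <- cfg$theta_true * gamma + alpha
  K <- cfg$case_fraction
  se_y <- 1 / sqrt(2 * cfg$n_outcome * K * (1 - K) * m * (1 - m))
  beta_y <- with_seed(seeds[2L], stats::rnorm(cfg$J, Gamma, se_y))

  mk_tab <- function(beta, se, n) {
    new_summary_stats(data.frame(
      snp_id = snp_id, effect_allele = al[, 1L], other_allele = al[, 2L],
      eaf = eaf, beta = beta, se = se,
      pval = pmax(2 * stats::pnorm(-abs(beta / se)), 1e-300),
      n = n, stringsAsFactors = FALSE))
  }
  exposure <- mk_tab(beta_x, se_x, cfg$n_exposure)
  outcome <- mk_tab(beta_y, se_y, cfg$n_outcome)

  confounders <- list()
  conf_ids <- list()
  if (!is.null(cfg$confounder_traits)) {
    confounders <- with_seed(seeds[3L], {
      lapply(stats::setNames(names(cfg$confounder_traits),
                             names(cfg$confounder_traits)), function(trait) {
        frac <- cfg$confounder_traits[[trait]]
        planted <- sample.int(cfg$J, round(frac * cfg$J))
        z <- stats::rnorm(cfg$J)
        z[planted] <- sample(c(-1, 1), length(planted), replace = TRUE) *
          stats::rnorm(length(planted), 6, 1)
        conf_ids[[trait]] <<- snp_id[planted]
        mk_tab(z * 0.01, rep(0.01, cfg$J), NA_real_)
      })
    })
  }

  list(exposure = exposure, outcome = outcome, confounders = confounders,
       truth = list(snp_id = snp_id, gamma = gamma, alpha = alpha,
                    se_x = se_x, se_y = se_y,
                    theta_true = cfg$theta_true,
                    invalid_ids = snp_id[invalid],
                    confounder_ids = conf_ids, seed = cfg$seed))
}

#' Operating characteristics of the estimators by simulation
#'
#' Repeatedly simulates datasets under `config` (deriving one sub-seed per
#' replicate from `config$seed`), runs IVW (multiplicative random effects),
#' weighted median and MR-Egger, and summarizes bias, empirical SE, 95% CI
#' coverage of the true effect, and the rejection rate of theta = 0 at
#' `alpha`.
#'
#' @param config A [simulation_config()].
#' @param n_reps Number of replicates, at least 100.
#' @param n_boot Bootstrap replicates for the weighted median per dataset
#'   (default 500 here, for simulation throughput).
#' @param alpha Test level for the rejection rate. Default 0.05.
#' @param methods Subset of `c("ivw", "weighted_median", "egger")`.
#' @return Data.frame with one row per estimator: `mean_bias`,
#'   `empirical_se`, `coverage`, `rejection_rate`; the config and seed are
#'   attached as attributes.
#' @export
operating_characteristics <- function(config, n_reps, n_boot = 500L,
                                      alpha = 0.05,
                                      methods = c("ivw", "weighted_median",
                                                  "egger")) {
  stopifnot(inherits(config, "simulation_config"))
  if (n_reps < 100L) stop("n_reps must be >= 100", call. = FALSE)
  methods <- match.arg(methods, several.ok = TRUE)
  rep_seeds <- sub_seeds(config$seed + 1L, 2L * n_reps)
  theta_true <- config$theta_true

  one_rep <- function(r) {
    cfg <- config
    cfg$seed <- rep_seeds[r]
    sim <- simulate_dataset(cfg)
    set <- harmonize(sim$exposure, sim$outcome)
    ests <- list()
    if ("ivw" %in% methods) ests$ivw <- mr_ivw(set, "random")
    if ("weighted_median" %in% methods) {
      ests$weighted_median <- mr_weighted_median(set, n_boot,
                                                 seed = rep_seeds[n_reps + r])
    }
    if ("egger" %in% methods) ests$egger <- mr_egger(set)$slope
    vapply(ests, function(e) {
      c(theta = e$theta,
        cover = as.numeric(e$ci_low <= theta_true & theta_true <= e$ci_high),
        reject = as.numeric(e$pval < alpha))
    }, c(theta = 0, cover = 0, reject = 0))
  }
  per_rep <- lapply(seq_len(n_reps), one_rep)   # list of 3 x M matrices
  arr <- simplify2array(per_rep)                # 3 x M x n_reps
  out <- data.frame(
    method = dimnames(arr)[[2L]] %||% methods,
    mean_bias = apply(arr["theta", , , drop = FALSE], 2, mean) - theta_true,
    empirical_se = apply(arr["theta", , , drop = FALSE], 2, stats::sd),
    coverage = apply(arr["cover", , , drop = FALSE], 2, mean),
    rejection_rate = apply(arr["reject", , , drop = FALSE], 2, mean),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "config") <- config
  attr(out, "n_reps") <- n_reps
  out
}
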