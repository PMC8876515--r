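#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise type-I error rate, in (0,1).
#' @param m Number of tests, a positive integer. With the 162 candidate
#'   instruments this gives 0.05/162 = 3.09e-4 (3 s.f.).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  assert_scalar_prob(alpha, "alpha", open_right = TRUE)
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 1 ||
      m != round(m)) {
    stop("`m` must be a positive integer", call. = FALSE)
  }
  alpha / m
}

#' Genome-wide significance filter on exposure associations
#'
#' Retains variants whose exposure p-value is below the threshold
#' (default 5e-8, the conventional genome-wide significance level) and logs
#' the removals in the table's provenance.
#'
#' @param table A `summary_stats` table with a `pval` column.
#' @param threshold Significance level; rows with `pval < threshold` are kept.
#' @return The filtered table, provenance updated.
#' @export
genome_wide_filter <- function(table, threshold = 5e-8) {
  stopifnot(is.data.frame(table), !is.null(table$pval))
  keep <- table$pval < threshold
  removed <- table$snp_id[!keep]
  out <- as.data.frame(table)[keep, , drop = FALSE]
  out <- new_summary_stats(out, provenance = provenance(table))
  add_provenance(out, "genome_wide_filter", removed, threshold)
}

#' Stage-1 confounder screen
#'
#' Flags instruments associated with any known confounder trait at the
#' Bonferroni-corrected threshold `alpha / m`. Following the source
#' analysis, `m` defaults to the number of instruments *before* screening
#' (162 in the education/stroke application), not the SNP-by-trait test
#' count. A SNP absent from a confounder table cannot be tested against
#' that trait: it is logged as untested, never excluded on missing evidence.
#'
#' @param instruments An [instrument_set()] or `summary_stats` table (only
#'   `snp_id` is used).
#' @param confounders Named list of `summary_stats` tables, one per
#'   confounder trait (`snp_id` and `pval` are used).
#' @param alpha Family-wise error rate before correction. Default 0.05.
#' @param m Number of tests for the Bonferroni correction; defaults to the
#'   instrument count.
#' @param allow_empty If `FALSE` (default) an empty confounder list is an
#'   error — the screen would be vacuous.
#' @return Object of class `confounder_screen`: the threshold, the excluded
#'   rsIDs, per-trait exclusion lists and counts, and per-trait untested ids.
#' @export
confounder_screen <- function(instruments, confounders, alpha = 0.05,
                              m = NULL, allow_empty = FALSE) {
  ids <- instruments$snp_id
  if (!length(confounders)) {
    if (allow_empty) {
      return(structure(list(traits = character(),
                            threshold = NA_real_, alpha = alpha,
                            m = m %||% length(ids),
                            excluded = character(),
                            per_trait = list(), per_trait_counts = integer(),
                            untested = list()),
                       class = "confounder_screen"))
    }
    stop("empty confounder map: the screen would be vacuous ",
         "(set allow_empty = TRUE to disable stage 1)", call. = FALSE)
  }
  if (is.null(names(confounders)) || any(!nzchar(names(confounders)))) {
    stop("`confounders` must be a named list (trait -> table)", call. = FALSE)
  }
  m <- m %||% length(ids)
  thr <- bonferroni_threshold(alpha, m)
  per_trait <- untested <- vector("list", length(confounders))
  names(per_trait) <- names(untested) <- names(confounders)
  for (trait in names(confounders)) {
    tab <- confounders[[trait]]
    j <- match(ids, tab$snp_id)
    p <- tab$pval[j]
    per_trait[[trait]] <- ids[!is.na(p) & p < thr]
    untested[[trait]] <- ids[is.na(j)]
  }
  excluded <- sort(unique(unlist(per_trait, use.names = FALSE)))
  structure(list(traits = names(confounders), threshold = thr,
                 alpha = alpha, m = m, excluded = excluded,
                 per_trait = per_trait,
                 per_trait_counts = vapply(per_trait, length, integer(1)),
                 untested = untested),
            class = "confounder_screen")
}

#' @export
print.confounder_screen <- function(x, ...) {
  cat(sprintf("<confounder_screen> %d SNP(s) excluded at p < %.3g (= %.3g/%d)\n",
              length(x$excluded), x$threshold, x$alpha, x$m))
  for (trait in x$traits) {
    cat(sprintf("  %-20s %3d excluded, %d untested\n", trait,
                x$per_trait_counts[[trait]], length(x$untested[[trait]])))
  }
  invisible(x)
}

#' Apply a confounder screen's exclusions to an instrument set
#'
#' @param instruments An [instrument_set()].
#' @param screen A `confounder_screen` built from the same instrument list.
#' @return The instrument set minus the excluded SNPs, provenance appended.
#' @export
apply_exclusions <- function(instruments, screen) {
  stopifnot(inherits(screen, "confounder_screen"))
  unknown <- setdiff(screen$excluded, instruments$snp_id)
  if (length(unknown)) {
    stop("screen references SNP(s) not in the instrument set: ",
         paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  }
  drop_instruments(instruments, screen$excluded, "confounder_screen",
                   screen$threshold)
}
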