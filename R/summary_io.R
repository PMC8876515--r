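#' Read a GWAS summary-statistic table
#'
#' Reads a tab- or comma-separated association table with a header row and
#' validates every row against the per-variant invariants: effect-allele
#' frequency strictly inside (0,1), standard error > 0, p-value in (0,1],
#' effect allele distinct from the other allele.
#'
#' The expected columns are `snp_id`, `effect_allele`, `other_allele`, `eaf`,
#' `beta`, `se`, `pval` and optionally `n`. Foreign headers are accepted
#' through `column_map`, a named character vector mapping the standard names
#' to the file's column names, e.g. `c(snp_id = "SNP", beta = "b")`.
#'
#' @param path Path to the file.
#' @param column_map Optional named character vector renaming foreign columns
#'   to the standard schema.
#' @param sep Field separator; `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#' @param on_invalid `"error"` (default) stops with a message listing each
#'   offending line number and field; `"drop"` removes invalid rows with a
#'   warning and records them in the `"invalid_rows"` attribute.
#' @return A `data.frame` of class `summary_stats` with validated columns.
#' @export
#' @examples
#' path <- system.file("extdata", "table1_education_instruments.tsv",
#'                     package = "mrkit")
#' head(read_summary_stats(path))
read_summary_stats <- function(path, column_map = NULL, sep = NULL,
                               on_invalid = c("error", "drop")) {
  on_invalid <- match.arg(on_invalid)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  if (is.null(sep)) sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", comment.char = "",
                           quote = "\"", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (std in names(column_map)) {
      j <- match(column_map[[std]], names(raw))
      if (!is.na(j)) names(raw)[j] <- std
    }
  }
  mandatory <- c("snp_id", "effect_allele", "other_allele",
                 "eaf", "beta", "se", "pval")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols)) {
    stop("configuration error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    snp_id        = raw$snp_id,
    effect_allele = toupper(raw$effect_allele),
    other_allele  = toupper(raw$other_allele),
    eaf  = suppressWarnings(as.numeric(raw$eaf)),
    beta = suppressWarnings(as.numeric(raw$beta)),
    se   = suppressWarnings(as.numeric(raw$se)),
    pval = suppressWarnings(as.numeric(raw$pval)),
    stringsAsFactors = FALSE
  )
  if ("n" %in% names(raw)) out$n <- suppressWarnings(as.numeric(raw$n))

  issues <- validate_summary_rows(out, raw)
  if (nrow(issues)) {
    msg <- paste(sprintf("line %d: field '%s' %s",
                         issues$line, issues$field, issues$problem),
                 collapse = "\n  ")
    if (on_invalid == "error") {
      stop("row-level validation error(s):\n  ", msg, call. = FALSE)
    }
    warning("dropping ", length(unique(issues$line)),
            " invalid row(s):\n  ", msg, call. = FALSE)
    out <- out[-(unique(issues$line) - 1L), , drop = FALSE]
    rownames(out) <- NULL
  }
  out <- new_summary_stats(out)
  attr(out, "invalid_rows") <- issues
  out
}

# Per-row invariant checks; `line` is the 1-based file line (header = line 1).
validate_summary_rows <- function(parsed, raw) {
  issue <- function(rows, field, problem) {
    if (!length(rows)) return(NULL)
    data.frame(line = rows + 1L, field = field, problem = problem,
               stringsAsFactors = FALSE)
  }
  n <- nrow(parsed)
  if (!n) {
    return(data.frame(line = integer(), field = character(),
                      problem = character(), stringsAsFactors = FALSE))
  }
  bad_num <- function(col) which(is.na(parsed[[col]]) & nzchar(raw[[col]]) &
                                   !is.na(raw[[col]]))
  missing_num <- function(col) which(is.na(parsed[[col]]) &
                                       (!nzchar(raw[[col]]) | is.na(raw[[col]])))
  out <- list()
  for (col in c("eaf", "beta", "se", "pval")) {
    out[[length(out) + 1L]] <- issue(bad_num(col), col, "is not numeric")
    out[[length(out) + 1L]] <- issue(missing_num(col), col, "is missing")
  }
  ok_num <- function(col) !is.na(parsed[[col]])
  out[[length(out) + 1L]] <-
    issue(which(ok_num("eaf") & (parsed$eaf <= 0 | parsed$eaf >= 1)),
          "eaf", "must be strictly inside (0,1)")
  out[[length(out) + 1L]] <-
    issue(which(ok_num("se") & parsed$se <= 0), "se", "must be > 0")
  out[[length(out) + 1L]] <-
    issue(which(ok_num("pval") & (parsed$pval <= 0 | parsed$pval > 1)),
          "pval", "must be in (0,1]")
  out[[length(out) + 1L]] <-
    issue(which(parsed$effect_allele == parsed$other_allele),
          "effect_allele", "must differ from other_allele")
  out[[length(out) + 1L]] <-
    issue(which(!grepl("^[ACGT]+$", parsed$effect_allele)),
          "effect_allele", "is not an ACGT allele")
  out[[length(out) + 1L]] <-
    issue(which(!grepl("^[ACGT]+$", parsed$other_allele)),
          "other_allele", "is not an ACGT allele")
  out <- do.call(rbind, Filter(Negate(is.null), out))
  if (is.null(out)) {
    out <- data.frame(line = integer(), field = character(),
                      problem = character(), stringsAsFactors = FALSE)
  }
  out[order(out$line), , drop = FALSE]
}

new_summary_stats <- function(df, provenance = NULL) {
  rownames(df) <- NULL
  class(df) <- c("summary_stats", "data.frame")
  attr(df, "provenance") <- provenance %||% new_provenance()
  df
}

#' Write a summary-statistic table to TSV
#'
#' Numeric fields are written with enough digits (17 significant) that a
#' read/write/read round trip reproduces every value exactly.
#'
#' @param x A `summary_stats` table (or plain data.frame with the schema).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(x, path) {
  fmt <- x
  for (col in intersect(c("eaf", "beta", "se", "pval", "n"), names(fmt))) {
    fmt[[col]] <- formatC(fmt[[col]], digits = 17, format = "g")
  }
  utils::write.table(fmt, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# ---- provenance -------------------------------------------------------------

new_provenance <- function() {
  data.frame(step = character(), n_removed = integer(),
             threshold = numeric(), snps = character(),
             stringsAsFactors = FALSE)
}

add_provenance <- function(x, step, removed, threshold = NA_real_) {
  prov <- attr(x, "provenance") %||% new_provenance()
  prov <- rbind(prov, data.frame(
    step = step, n_removed = length(removed), threshold = threshold,
    snps = paste(removed, collapse = ","), stringsAsFactors = FALSE))
  attr(x, "provenance") <- prov
  x
}

#' Provenance log of a table or instrument set
#'
#' Every filtering step appends one row: the step name, the number of
#' variants removed, the threshold applied, and the removed rsIDs.
#'
#' @param x A `summary_stats` table or `instrument_set`.
#' @return A data.frame with columns `step`, `n_removed`, `threshold`, `snps`.
#' @export
provenance <- function(x) attr(x, "provenance") %||% new_provenance()

# ---- instrument set ---------------------------------------------------------

#' Construct an instrument set
#'
#' An instrument set holds, per SNP, the exposure and outcome effects
#' expressed on the same effect allele (the harmonized gamma-hat and
#' Gamma-hat with their standard errors), plus a provenance log of every
#' removal. Usually produced by [harmonize()].
#'
#' @param df Data.frame with columns `snp_id`, `beta_exposure`,
#'   `se_exposure`, `beta_outcome`, `se_outcome`, `eaf` and `action`.
#' @param provenance Optional provenance data.frame to carry over.
#' @param n_initial Initial SNP count before any removals (defaults to
#'   `nrow(df)` plus provenance removals).
#' @return Object of class `instrument_set`.
#' @export
instrument_set <- function(df, provenance = NULL, n_initial = NULL) {
  needed <- c("snp_id", "beta_exposure", "se_exposure",
              "beta_outcome", "se_outcome", "eaf")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("instrument set lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$snp_id)) {
    stop("duplicate snp_id in instrument set", call. = FALSE)
  }
  if (nrow(df) && (any(df$se_exposure <= 0) || any(df$se_outcome <= 0))) {
    stop("retained instruments must have positive standard errors",
         call. = FALSE)
  }
  if (is.null(df$action)) df$action <- "kept_as_is"
  rownames(df) <- NULL
  class(df) <- c("instrument_set", "data.frame")
  attr(df, "provenance") <- provenance %||% new_provenance()
  attr(df, "n_initial") <-
    n_initial %||% (nrow(df) + sum(attr(df, "provenance")$n_removed))
  df
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("<instrument_set> %d instruments (from %d initial)\n",
              nrow(x), attr(x, "n_initial")))
  prov <- provenance(x)
  if (nrow(prov)) {
    cat("filter log:\n")
    for (i in seq_len(nrow(prov))) {
      cat(sprintf("  %-28s removed %3d%s\n", prov$step[i], prov$n_removed[i],
                  if (is.na(prov$threshold[i])) "" else
                    sprintf("  (threshold %.3g)", prov$threshold[i])))
    }
  }
  print(utils::head(as.data.frame(x), 5L))
  if (nrow(x) > 5L) cat("...", nrow(x) - 5L, "more rows\n")
  invisible(x)
}

# remove rows by id, appending provenance; internal
drop_instruments <- function(set, ids, step, threshold = NA_real_) {
  keep <- !(set$snp_id %in% ids)
  out <- as.data.frame(set)[keep, , drop = FALSE]
  out <- instrument_set(out, provenance = provenance(set),
                        n_initial = attr(set, "n_initial"))
  add_provenance(out, step, set$snp_id[!keep], threshold)
}

# ---- harmonization ----------------------------------------------------------

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome association of each exposure SNP onto the exposure's
#' effect allele. Matching is by rsID. For each exposure SNP found in the
#' outcome table:
#'
#' * identical allele pair: kept as is;
#' * swapped effect/other alleles: outcome beta negated and outcome EAF
#'   reflected (`action = "allele_flip"`);
#' * palindromic SNP (A/T or C/G) with exposure EAF within
#'   `palindromic_eaf_window` of 0.5: dropped as strand-ambiguous;
#' * alleles matching only after strand complement: aligned the same way
#'   (complement first, then the swap rule);
#' * no allele correspondence at all: dropped with reason
#'   `allele_mismatch`, never silently kept;
#' * absent from the outcome table: dropped as `missing`.
#'
#' The exposure EAF governs all downstream frequency-based computations;
#' a missing outcome EAF is tolerated.
#'
#' @param exposure,outcome `summary_stats` tables.
#' @param palindromic_eaf_window Half-width around EAF 0.5 inside which a
#'   palindromic SNP is considered strand-ambiguous and dropped. Default 0.08.
#' @return An [instrument_set()] of the retained SNPs; the full per-SNP
#'   action table is in `attr(, "actions")` and all drops are logged in
#'   [provenance()].
#' @export
harmonize <- function(exposure, outcome, palindromic_eaf_window = 0.08) {
  stopifnot(is.data.frame(exposure), is.data.frame(outcome))
  if (palindromic_eaf_window < 0 || palindromic_eaf_window > 0.5) {
    stop("`palindromic_eaf_window` must be in [0, 0.5]", call. = FALSE)
  }
  J <- nrow(exposure)
  idx <- match(exposure$snp_id, outcome$snp_id)
  action <- character(J)
  beta_out <- se_out <- eaf_out <- rep(NA_real_, J)
  pval_out <- rep(NA_real_, J)

  for (i in seq_len(J)) {
    ea <- exposure$effect_allele[i]; oa <- exposure$other_allele[i]
    j <- idx[i]
    if (is.na(j)) { action[i] <- "dropped_missing"; next }
    if (is_palindromic(ea, oa) &&
        abs(exposure$eaf[i] - 0.5) < palindromic_eaf_window) {
      action[i] <- "dropped_palindromic"; next
    }
    oe <- outcome$effect_allele[j]; oo <- outcome$other_allele[j]
    flip <- NA
    if (oe == ea && oo == oa) flip <- FALSE
    else if (oe == oa && oo == ea) flip <- TRUE
    else {
      ce <- allele_complement(oe); co <- allele_complement(oo)
      if (ce == ea && co == oa) flip <- FALSE
      else if (ce == oa && co == ea) flip <- TRUE
    }
    if (is.na(flip)) { action[i] <- "dropped_allele_mismatch"; next }
    action[i] <- if (flip) "allele_flip" else "kept_as_is"
    beta_out[i] <- if (flip) -outcome$beta[j] else outcome$beta[j]
    se_out[i] <- outcome$se[j]
    of <- if (is.null(outcome$eaf)) NA_real_ else outcome$eaf[j]
    eaf_out[i] <- if (flip) 1 - of else of
    pval_out[i] <- outcome$pval[j]
  }

  kept <- action %in% c("kept_as_is", "allele_flip")
  df <- data.frame(
    snp_id        = exposure$snp_id[kept],
    beta_exposure = exposure$beta[kept],
    se_exposure   = exposure$se[kept],
    beta_outcome  = beta_out[kept],
    se_outcome    = se_out[kept],
    eaf           = exposure$eaf[kept],
    eaf_outcome   = eaf_out[kept],
    pval_exposure = exposure$pval[kept],
    pval_outcome  = pval_out[kept],
    action        = action[kept],
    stringsAsFactors = FALSE
  )
  set <- instrument_set(df, provenance = provenance(exposure), n_initial = J)
  for (reason in c("dropped_missing", "dropped_palindromic",
                   "dropped_allele_mismatch")) {
    ids <- exposure$snp_id[action == reason]
    if (length(ids)) {
      set <- add_provenance(set, paste0("harmonize_", sub("dropped_", "", reason)),
                            ids,
                            if (reason == "dropped_palindromic")
                              palindromic_eaf_window else NA_real_)
    }
  }
  attr(set, "actions") <- data.frame(snp_id = exposure$snp_id,
                                     action = action,
                                     stringsAsFactors = FALSE)
  set
}

# ---- packaged fixture -------------------------------------------------------

TABLE1_MD5 <- "dce365bc3ae9225eae1029d4c479dc90"
TABLE1_N <- 162L

#' Load the packaged 162-variant education instrument table
#'
#' The 162 genome-wide-significant (p < 5e-8) educational attainment
#' variants used as candidate instruments, with effect allele, other allele,
#' effect-allele frequency, per-SD effect size, standard error and p-value.
#' The file checksum is verified so silent fixture corruption is a hard
#' packaging error.
#'
#' @return A `summary_stats` data.frame with 162 rows.
#' @export
#' @examples
#' tab1 <- load_table1_fixture()
#' nrow(tab1)  # 162
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_education_instruments.tsv",
                      package = "mrkit")
  if (!nzchar(path)) stop("packaging error: fixture not installed",
                          call. = FALSE)
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, TABLE1_MD5)) {
    stop("packaging error: fixture checksum mismatch (got ", md5, ")",
         call. = FALSE)
  }
  out <- read_summary_stats(path)
  if (nrow(out) != TABLE1_N) {
    stop("packaging error: fixture must have exactly 162 records",
         call. = FALSE)
  }
  out
}
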