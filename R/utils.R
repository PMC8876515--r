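# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
assert_scalar_prob <- function(x, name, open_right = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 ||
      (if (open_right) x >= 1 else x > 1)) {
    stop(sprintf("`%s` must be a single number in (0,1%s)", name,
                 if (open_right) "" else "]"), call. = FALSE)
  }
  invisible(x)
}

# Run `code` with a temporary RNG seed, restoring the caller's RNG state.
# `seed = NULL` leaves the RNG stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed sequence derived from one master seed, so draws,
# bootstrap and resampling stages can be re-run independently. Stays < 2^31.
sub_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# DNA complement for strand-flip matching.
allele_complement <- function(x) chartr("ACGT", "TGCA", toupper(x))

is_palindromic <- function(ea, oa) {
  toupper(ea) == allele_complement(oa)
}
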