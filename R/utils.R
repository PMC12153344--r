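# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Sets the global RNG to `seed`, evaluates `code`, and restores the previous
#' RNG state on exit.  All stochastic operations in the package route their
#' randomness through this helper so that no call leaves hidden global state
#' behind and identical seeds give byte-identical results.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing integer", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

DNA_BASES <- c("A", "C", "G", "T")
RNA_BASES <- c("A", "C", "G", "U")

#' Complement / reverse-complement of a DNA string (base alphabet only)
#' @keywords internal
complement_base <- function(x) {
  unname(c(A = "T", C = "G", G = "C", T = "A")[x])
}

#' @keywords internal
revcomp <- function(x) {
  stopifnot(is.character(x))
  vapply(x, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    paste(rev(complement_base(chars)), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' @keywords internal
assert_proportion <- function(x, name, allow_zero = TRUE, allow_one = TRUE) {
  ok <- is.numeric(x) && all(!is.na(x)) &&
    all(x > 0 | (allow_zero & x == 0)) &&
    all(x < 1 | (allow_one & x == 1))
  if (!ok) stop(sprintf("`%s` must lie in [0, 1]", name), call. = FALSE)
  invisible(x)
}

#' Type-7 (linear interpolation) quantile
#'
#' The single quantile convention used by every percentile rule in the filter
#' cascade; isolated here so tests can pin it down once.
#' @keywords internal
quantile7 <- function(x, p) {
  unname(stats::quantile(x, probs = p, type = 7, names = FALSE))
}

#' Strict-above filter with degenerate relaxation
#'
#' Keep values strictly above `threshold`; when every value in the reference
#' distribution is identical the strict rule would silently discard
#' everything, so the comparison relaxes to `>=`.
#' @keywords internal
keep_above <- function(values, threshold, reference = values) {
  if (length(reference) > 0L && length(unique(reference)) == 1L) {
    values >= threshold
  } else {
    values > threshold
  }
}

#' Split a genome character string into a per-position base vector
#' @keywords internal
seq_to_bases <- function(seq) {
  strsplit(seq, "", fixed = TRUE)[[1L]]
}

#' @keywords internal
is_single_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
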