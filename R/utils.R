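# small shared helpers (internal)

#' Evaluate code under a fixed RNG seed, restoring global RNG state after
#' @noRd
local_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Derive a reproducible child seed from a parent seed and an index
#'
#' Fixed splitting rule so that cohorts are reproducible leaf-by-leaf; results
#' always stay within the 32-bit integer range.
#' @noRd
derive_seed <- function(seed, index) {
  m <- 2147483647  # 2^31 - 1
  as.integer((as.numeric(seed) %% m * 1009 + 9973 * as.numeric(index)) %% m)
}

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed comparison tables in this
#' field round half away from zero (e.g. 0.4545 -> 0.45, 0.666 -> 0.67, and
#' 0.265 -> 0.27). Used wherever a table value is reported at fixed decimals.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @examples
#' round_half_away(0.665, 2)   # 0.67, not 0.66
#' round_half_away(-0.665, 2)  # -0.67
#' @export
round_half_away <- function(x, digits = 0) {
  stopifnot(is.numeric(x), is.numeric(digits), length(digits) == 1L)
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# scalar validators -----------------------------------------------------------

assert_scalar_finite <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  if (nonneg && x < 0) {
    stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  }
  invisible(x)
}

#' Deterministic string hash (djb2) used for run provenance
#' @noRd
djb2_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 5381
  for (b in utf8ToInt(x)) {
    h <- (h * 33 + b) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}
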