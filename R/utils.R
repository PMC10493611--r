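#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero, the
#' convention used for all reported percentages and fold ratios in this
#' package (base [round()] rounds half to even, which does not reproduce
#' values such as 12.45 -> 12.5).
#'
#' @param x numeric vector.
#' @param digits integer, decimal places (may be 0).
#' @return numeric vector of the same length as `x`.
#' @export
#' @examples
#' round_half_up(2.5)      # 3
#' round_half_up(-2.5)     # -3
#' round_half_up(12.445, 1)
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), length(digits) == 1L, digits >= 0)
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Internal: stop() with a consistent prefix-free message built by sprintf.
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Internal: check a data.frame has the required columns.
require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort("%s is missing required column(s): %s", what,
          paste(missing, collapse = ", "))
  }
  invisible(df)
}

# Internal: error on duplicated keys, listing the offenders.
require_unique <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    abort("duplicate %s: %s", what, paste(dup, collapse = ", "))
  }
  invisible(ids)
}
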