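#' Round half away from zero
#'
#' Decimal rounding with exact halves carried upward (`0.5 -> 1`,
#' `32.5 -> 33`), the convention used throughout the reported tables. Base
#' [round()] ties to even and would print 32 where the tables print 33.
#'
#' @param x Numeric vector (non-negative in all pipeline uses).
#' @param digits Number of decimal places to keep.
#' @return Numeric vector rounded to `digits` places.
#' @examples
#' round_half_up(32.5) # 33, where round(32.5) is 32
#' round_half_up(2.125, 1) # 2.1 (not a decimal tie)
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  # small guard so quotients like 0.325 * 100 that land a hair under the
  # true decimal value still round as their exact value would
  floor(x * m + 0.5 + 1e-9) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop unless every named condition holds; names become the message
check_that <- function(..., class = "ydegen_error") {
  conds <- list(...)
  bad <- names(conds)[!vapply(conds, isTRUE, logical(1))]
  if (length(bad) > 0) abort(bad[[1]], class = class)
  invisible(TRUE)
}

# levels shared by calls and combined categories
call_levels <- c("XY", "X_HEMI", "NOT_SEX_LINKED")
category_levels <- c("XY", "X_HEMI", "UNDETECTED", "NO_MATCH")
linkage_levels <- c("X", "Y", "unknown")
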