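#' Round half-up
#'
#' Rounds to `digits` decimal places with ties going away from zero, the
#' convention used for every percentage printed by this package. Base
#' [round()] rounds half-to-even, which does not reproduce values such as
#' 17.7 from 17/96.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(100 * 1858 / 2052, 1)  # 90.5
#' round_half_up(100 * 17 / 96, 1)      # 17.7
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' Percentage with half-up rounding to one decimal
#' @param num,den numerator and denominator.
#' @param digits decimal places (default 1).
#' @return numeric percentage.
#' @export
percent <- function(num, den, digits = 1) {
  round_half_up(100 * num / den, digits)
}

# internal: stop with a classed validation error
abort_validation <- function(msg) {
  stop(errorCondition(msg, class = c("barcodeval_validation_error", "error")))
}

abort_format <- function(msg) {
  stop(errorCondition(msg, class = c("barcodeval_format_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# internal: rbind a list of data.frames without mangled row names;
# returns NULL for an empty list
rbind_rows <- function(lst) {
  lst <- Filter(Negate(is.null), lst)
  if (length(lst) == 0) return(NULL)
  do.call(rbind, c(lst, list(make.row.names = FALSE)))
}

# internal: run expr with a temporary seed when one is supplied, leaving the
# caller's RNG stream untouched; with seed = NULL the current stream is used.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
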