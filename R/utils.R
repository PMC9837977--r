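# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round a ratio to an integer percentage
#'
#' Computes `100 * numerator / denominator` and rounds half away from zero,
#' the convention used when reporting overlap fractions (so 80.5 -> 81 and
#' -0.5 -> -1, unlike banker's rounding).
#'
#' @param numerator Count (non-negative number).
#' @param denominator Positive count.
#' @return Integer percentage.
#' @examples
#' percent(8779, 11549) # 76
#' percent(45, 56)      # 80
#' @export
percent <- function(numerator, denominator) {
  if (length(denominator) != 1L || !is.finite(denominator) || denominator <= 0)
    stop("denominator must be a single positive count")
  x <- 100 * numerator / denominator
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

# Deterministic per-permutation seed stream. Keeps every derived seed inside
# the 32-bit signed range expected by set.seed().
derive_seed <- function(master_seed, i) {
  as.integer((abs(as.numeric(master_seed)) * 69069 + as.numeric(i) * 104729) %% 2147483629)
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Locale-independent ordering used everywhere a deterministic interval order
# is promised.
radix_order <- function(...) order(..., method = "radix")

stop_line <- function(line_no, msg) {
  stop(sprintf("line %d: %s", line_no, msg), call. = FALSE)
}
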