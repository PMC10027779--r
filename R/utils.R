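#' Internal validation and numeric helpers
#'
#' @name pdxmm-utils
#' @keywords internal
NULL

abort <- function(..., class = "pdxmm_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

abort_validation <- function(...) {
  abort(..., class = "pdxmm_validation_error")
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x != floor(x) || x < min)
    abort_validation(sprintf("`%s` must be a single integer >= %d", name, min))
  as.integer(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lo || x > hi)
    abort_validation(sprintf("`%s` must be a number in [%g, %g]", name, lo, hi))
  as.numeric(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0)
    abort_validation(sprintf("`%s` must be a single positive number", name))
  as.numeric(x)
}

#' Round half away from zero
#'
#' Deterministic rounding used for micron-to-pixel conversion and tile
#' subsampling counts; unlike [base::round()] it never rounds to even.
#'
#' @param x numeric vector.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

# Evaluate `code` under a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a child seed from a base seed and a stream index, staying within
# the 32-bit integer range R requires.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(stream)) %% 2147483629) + 1L
}
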