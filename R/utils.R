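#' Round half away from zero
#'
#' Commercial ("half-up") rounding used when mirroring printed report tables;
#' `base::round()` rounds half to even, which disagrees with printed values
#' such as 0.545 -> 0.55.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  # nudge by an ulp-scale epsilon so values like 0.545 stored as 0.54499...
  # still round up the way the printed tables do
  sign(x) * floor(abs(x) * m + 0.5 + sqrt(.Machine$double.eps)) / m
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic 32-bit sub-seed for unit-level RNG substreams
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1009 + index * 7919) %% 2147483647L)
}

stop_named <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0)
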