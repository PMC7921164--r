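#' Derive a per-job random seed from a master seed
#'
#' Deterministic mixing of a master seed with a job index so that ensemble
#' jobs have independent, reproducible RNG streams whatever the execution
#' order or worker count. The result always fits a 32-bit signed integer.
#'
#' @param master single integer master seed.
#' @param index nonnegative integer job index.
#' @return an integer scalar in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(master, index) {
  stopifnot(length(master) == 1L, length(index) == 1L, index >= 0)
  # splitmix-style mixing in double precision, reduced mod 2^31 - 1
  m <- 2147483647
  z <- (as.numeric(master) %% m)
  for (k in seq_len(5L)) {
    z <- (z * 48271 + as.numeric(index) * 16807 + k * 12345) %% m
  }
  as.integer(z)
}

# numeric floor used wherever a divisor may be zero
.floor_eps <- function(x, scale = 1) {
  pmax(abs(x), 1e-6 * abs(scale) + 1e-12) * ifelse(x < 0, -1, 1)
}

.assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

.is_named_num <- function(x) is.numeric(x) && !is.null(names(x))
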