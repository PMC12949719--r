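#' Derive a reproducible sub-stream seed from a master seed
#'
#' Independent pipeline stages (phantom geometry, Rician noise, cohort draws,
#' bootstrap resampling) each get their own RNG stream so that regenerating one
#' stage does not disturb the others. The sub-seed is a deterministic hash of
#' the master seed and a stream label, kept below 2^31 - 1 so it is always a
#' valid `set.seed()` argument.
#'
#' @param master integer master seed.
#' @param stream character stream label, e.g. `"phantom"`, `"noise"`, `"cohort"`.
#' @return A single integer seed.
#' @export
substream_seed <- function(master, stream) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stream))
  codes <- utf8ToInt(stream)
  h <- sum(codes * seq_along(codes)) %% 2147483647
  as.integer((abs(as.numeric(master)) %% 65521) * 31627 + h * 7919) %% 2147483629L
}

# Internal: set the RNG only when a seed is supplied.
set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

# Internal: stop() with a consistent prefix, sprintf-style.
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Internal: check a numeric scalar.
chk_scalar <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort("'%s' must be a finite numeric scalar", name)
  if (strict && x <= lower) abort("'%s' must be > %g", name, lower)
  if (!strict && x < lower) abort("'%s' must be >= %g", name, lower)
  invisible(x)
}
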