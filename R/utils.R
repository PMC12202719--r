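# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Format doubles so that read-back is bit-exact (17 significant digits
# round-trips IEEE-754 binary64).
fmt_exact <- function(x) sprintf("%.17g", x)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Derive per-stage RNG seeds from one run seed using a fixed counter scheme,
# keeping results < 2^31.
derive_seed <- function(seed, stage) {
  offsets <- c(physio = 101L, coupling = 211L, noise = 307L, sweep = 401L,
               phantom = 503L, misc = 601L)
  off <- offsets[[stage]] %||% 701L
  (as.integer(seed) * 7919L + off) %% .Machine$integer.max
}

# Sample standard deviation with the n-1 denominator (documented convention
# for jitter); returns NA for fewer than two values.
sample_sd <- function(x) if (length(x) < 2L) NA_real_ else stats::sd(x)

# Pearson correlation that tolerates zero-variance input.
safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

rms <- function(x) sqrt(mean(abs(x)^2))
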