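#' @importFrom rlang .data %||%
#' @importFrom stats rnorm runif sd
NULL

# 32-bit FNV-1a hash of a string, returned as a non-negative double < 2^31.
# Used to derive independent, reproducible per-trial RNG substreams from the
# master seed and a human-readable key.
fnv32 <- function(x) {
  h <- 2166136261
  for (b in utf8ToInt(x)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    # 32-bit modular multiply by the FNV prime, done in doubles
    h <- (h * 16777619) %% 4294967296
  }
  h %% 2147483647
}

# Deterministic substream seed from a master seed and key parts.
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "|")
  as.integer(fnv32(key))
}

# Run `expr` under a local RNG seeded with `seed`, restoring the caller's
# RNG state afterwards.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Normal draw clamped to a range (keeps simulated scales physiologic without
# rejection loops; clamping mass is negligible at the ranges used).
rnorm_clamped <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  pmin(pmax(rnorm(n, mean, sd), lo), hi)
}

#' Coefficient of variation
#'
#' Sample standard deviation divided by the mean; a scale-free variability
#' measure used for the trial-level jitter/shimmer variability features.
#'
#' @param values Numeric vector.
#' @param na.rm Drop missing values first.
#' @return `sd(values) / mean(values)`; `NA` with fewer than two values;
#'   errors when the mean is zero (the ratio is undefined).
#' @examples
#' coefficient_of_variation(c(1, 3)) # 0.7071
#' @export
coefficient_of_variation <- function(values, na.rm = FALSE) {
  if (na.rm) values <- values[!is.na(values)]
  if (length(values) < 2L) return(NA_real_)
  m <- mean(values)
  if (m == 0) stop("coefficient of variation undefined for zero mean", call. = FALSE)
  stats::sd(values) / m
}
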