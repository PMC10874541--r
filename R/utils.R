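#' Derive a stage-specific child seed from a run seed
#'
#' A single top-level seed fans out to per-stage seeds by stable string
#' hashing, so adding a stage never reshuffles the random streams of earlier
#' stages. The result is always a valid 32-bit integer seed.
#'
#' @param seed Integer run seed.
#' @param tag Character stage tag (e.g. `"simulate"`, `"well:R1_C003"`).
#' @return An integer in `[0, 2^31 - 1]`.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- as.double(seed) %% 2147483647
  for (b in utf8ToInt(tag)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## run `expr` under a local RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

stop_if_not_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max)
    stop(sprintf("'%s' must be a single number in [%s, %s]", name,
                 format(min), format(max)), call. = FALSE)
  invisible(x)
}

## discrete 1-D Gaussian kernel, radius = ceil(truncate * sigma), sum 1
gaussian_kernel <- function(sigma, truncate = 4) {
  stopifnot(sigma > 0)
  r <- max(1L, as.integer(ceiling(truncate * sigma)))
  x <- -r:r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

## separable Gaussian smoothing of a matrix (reflect padding)
gaussian_smooth <- function(img, sigma, truncate = 4) {
  if (sigma <= 0) return(img)
  cpp_conv_sep(img, gaussian_kernel(sigma, truncate))
}
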