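#' @keywords internal
"_PACKAGE"

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards.  All stochastic entry points route
# through this so a seed argument never clobbers the session RNG.
with_local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

# 2-D FFT helpers; R's fft() on a matrix already computes the 2-D DFT.
fft2 <- function(x) stats::fft(x)
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)
ifft2_re <- function(x) Re(stats::fft(x, inverse = TRUE)) / length(x)

# Slice-wise 2-D FFT of an H x W x K array.
fft3 <- function(a, inverse = FALSE) {
  out <- array(complex(real = 0), dim = dim(a))
  n <- prod(dim(a)[1:2])
  for (k in seq_len(dim(a)[3])) {
    f <- stats::fft(a[, , k], inverse = inverse)
    out[, , k] <- if (inverse) f / n else f
  }
  out
}

ifft3_re <- function(a) {
  out <- array(0, dim = dim(a))
  n <- prod(dim(a)[1:2])
  for (k in seq_len(dim(a)[3])) {
    out[, , k] <- Re(stats::fft(a[, , k], inverse = TRUE)) / n
  }
  out
}

# Zero-pad a small s x s kernel into an H x W raster at the origin.
pad_kernel <- function(kern, h, w) {
  out <- matrix(0, h, w)
  out[seq_len(nrow(kern)), seq_len(ncol(kern))] <- kern
  out
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

`%||%` <- function(a, b) if (is.null(a)) b else a
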