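# Gradient filters for the TV term: first differences along columns (g0,
# horizontal gradient) and along rows (g1, vertical gradient), applied with
# circular boundary so they stay diagonal in the frequency domain.
tv_filters <- function() {
  list(g0 = matrix(c(-1, 1), nrow = 1L),
       g1 = matrix(c(-1, 1), ncol = 1L))
}

#' Anisotropic total variation of a 2-D array
#'
#' `TV(X) = ||g0 * X||_1 + ||g1 * X||_1` where g0 and g1 are the horizontal
#' and vertical first-difference filters and `*` is circular convolution.
#' Zero on constant arrays; positively homogeneous.
#'
#' @param x Numeric matrix.
#' @return Scalar TV value.
#' @export
tv_value <- function(x) {
  if (!all(is.finite(x))) stop("`x` contains non-finite values", call. = FALSE)
  h <- nrow(x); w <- ncol(x)
  dh <- x[, c(2:w, 1L), drop = FALSE] - x
  dv <- x[c(2:h, 1L), , drop = FALSE] - x
  sum(abs(dh)) + sum(abs(dv))
}

#' TV-regularized convolutional sparse coding
#'
#' Codes a sub-band image `s` against a convolutional dictionary by solving
#' `argmin_x 0.5 ||s - sum_k d_k * x_k||^2 + lambda sum_k ||x_k||_1
#'  + lambda1 TV(sum_k d_k * x_k)`
#' with ADMM: one split for the L1 term (soft threshold at `lambda/rho`)
#' and one split per gradient filter applied to the reconstruction (soft
#' threshold at `lambda1/rho`); the coupled primal solve is diagonal per
#' frequency up to a rank-1 term (Sherman-Morrison).  With `lambda1 = 0`
#' this reduces to plain convolutional sparse coding.
#'
#' @param s Numeric matrix, the image to code.
#' @param dict A `conv_dictionary`; filters must fit inside the image.
#' @param lambda Sparsity weight (default 0.01).
#' @param lambda1 TV weight (default 1e-3).
#' @param max_iters ADMM iteration budget (default 150).
#' @param tol Stop when the relative objective change falls below this
#'   (default 1e-4).
#' @return `h x w x K` array of coefficient maps with attributes
#'   `objective_trace` and `converged`; a warning is raised when the
#'   iteration budget is exhausted before `tol` is met.
#' @export
csc_encode <- function(s, dict, lambda = 0.01, lambda1 = 1e-3,
                       max_iters = 150L, tol = 1e-4) {
  validate_gray_image(s, "s", range = FALSE)
  stopifnot(inherits(dict, "conv_dictionary"))
  if (lambda < 0 || lambda1 < 0) stop("weights must be non-negative",
                                      call. = FALSE)
  h <- nrow(s); w <- ncol(s); K <- dict$K
  if (dict$s > min(h, w)) stop("dictionary filters larger than the image",
                               call. = FALSE)
  rho <- 10 * lambda + 0.1
  Df <- dict_freq(dict, h, w)
  DtD <- rowSums(abs(Df)^2, dims = 2L)
  Yf <- fft2(s)
  use_tv <- lambda1 > 0
  if (use_tv) {
    tf <- tv_filters()
    G0 <- fft2(pad_kernel(tf$g0, h, w))
    G1 <- fft2(pad_kernel(tf$g1, h, w))
    gamma <- abs(G0)^2 + abs(G1)^2
    alpha <- 1 + rho * gamma
  } else {
    alpha <- matrix(1, h, w)
  }
  x <- array(0, c(h, w, K)); z <- x; u <- x
  w0 <- matrix(0, h, w); u0 <- w0; w1 <- w0; u1 <- w0
  trace <- numeric(0)
  prev <- Inf
  converged <- FALSE
  for (it in seq_len(max_iters)) {
    B <- fft3(z - u)
    rhs_extra <- if (use_tv) {
      rho * (Conj(G0) * fft2(w0 - u0) + Conj(G1) * fft2(w1 - u1))
    } else 0
    for (k in seq_len(K)) {
      B[, , k] <- Conj(Df[, , k]) * (Yf + rhs_extra) + rho * B[, , k]
    }
    dtb <- reconstruct_freq(Df, B)
    corr <- alpha * dtb / (rho + alpha * DtD)
    Xf <- B
    for (k in seq_len(K)) {
      Xf[, , k] <- (B[, , k] - Conj(Df[, , k]) * corr) / rho
    }
    x <- ifft3_re(Xf)
    z <- soft_threshold(x + u, lambda / rho)
    u <- u + x - z
    recf <- reconstruct_freq(Df, Xf)
    rec <- ifft2_re(recf)
    if (use_tv) {
      r0 <- ifft2_re(G0 * recf)
      r1 <- ifft2_re(G1 * recf)
      w0 <- soft_threshold(r0 + u0, lambda1 / rho)
      w1 <- soft_threshold(r1 + u1, lambda1 / rho)
      u0 <- u0 + r0 - w0
      u1 <- u1 + r1 - w1
    }
    obj <- 0.5 * sum((s - rec)^2) + lambda * sum(abs(x)) +
      if (use_tv) lambda1 * tv_value(rec) else 0
    trace <- c(trace, obj)
    if (is.finite(prev) && abs(prev - obj) / max(prev, 1e-12) < tol) {
      converged <- TRUE
      break
    }
    prev <- obj
  }
  if (!converged) {
    warning(sprintf("csc_encode: not converged after %d iterations", max_iters))
  }
  # report the sparse iterate: feasible for the L1 term and what the
  # fusion rules consume
  out <- z
  attr(out, "objective_trace") <- trace
  attr(out, "converged") <- converged
  out
}

#' Reconstruct an image from convolutional coefficient maps
#'
#' `sum_k d_k * x_k` with circular 2-D convolution; the filter origin sits
#' at the map pixel, extending down-right (modulo the extent).
#'
#' @param maps `h x w x K` array (or list of K matrices).
#' @param dict A `conv_dictionary` with K filters.
#' @return Numeric matrix of the maps' extent.
#' @export
csc_reconstruct <- function(maps, dict) {
  stopifnot(inherits(dict, "conv_dictionary"))
  a <- as_coef_array(maps)
  if (dim(a)[3L] != dict$K) {
    stop("map count does not match dictionary filter count", call. = FALSE)
  }
  h <- dim(a)[1L]; w <- dim(a)[2L]
  Df <- dict_freq(dict, h, w)
  ifft2_re(reconstruct_freq(Df, fft3(a)))
}
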