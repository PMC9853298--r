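#' Initialize a convolutional dictionary
#'
#' Draws K filters of size s x s from a seeded standard normal, removes the
#' DC component of each (mean subtracted), and projects each to unit L2
#' norm.  Deterministic for a fixed seed; the session RNG is untouched.
#'
#' @param K Number of filters (>= 1).
#' @param s Filter side length in pixels (>= 2; default 8).
#' @param seed RNG seed.
#' @param scale_tag Optional label naming the sub-band family the
#'   dictionary serves.
#' @return An object of class `conv_dictionary`: list with `filters` (list
#'   of K `s x s` matrices, each unit norm), `K`, `s`, `scale_tag`, `seed`.
#' @export
init_dictionary <- function(K, s = 8L, seed = 1L, scale_tag = NULL) {
  if (!is.numeric(K) || K < 1L) stop("`K` must be >= 1", call. = FALSE)
  if (!is.numeric(s) || s < 2L) stop("`s` must be >= 2", call. = FALSE)
  K <- as.integer(K); s <- as.integer(s)
  filters <- with_local_seed(seed, {
    lapply(seq_len(K), function(k) {
      f <- matrix(stats::rnorm(s * s), s, s)
      f <- f - mean(f)
      f / sqrt(sum(f^2))
    })
  })
  structure(list(filters = filters, K = K, s = s,
                 scale_tag = scale_tag, seed = seed),
            class = "conv_dictionary")
}

#' @export
print.conv_dictionary <- function(x, ...) {
  cat(sprintf("<conv_dictionary> %d filters of %dx%d%s\n", x$K, x$s, x$s,
              if (!is.null(x$scale_tag)) paste0(" [", x$scale_tag, "]") else ""))
  invisible(x)
}

# Frequency-domain stack of zero-padded filters: h x w x K complex array.
dict_freq <- function(dict, h, w) {
  D <- array(0, c(h, w, dict$K))
  for (k in seq_len(dict$K)) D[, , k] <- pad_kernel(dict$filters[[k]], h, w)
  fft3(D)
}

# Circular 2-D convolution of each filter with its coefficient map, summed:
# the reconstruction sum_k d_k * x_k.
reconstruct_freq <- function(Df, Xf) {
  acc <- matrix(complex(real = 0), dim(Df)[1L], dim(Df)[2L])
  for (k in seq_len(dim(Df)[3L])) acc <- acc + Df[, , k] * Xf[, , k]
  acc
}

#' Convolutional sparse-coding objective
#'
#' Evaluates
#' `0.5 * sum_m || y_m - sum_k d_k * x_{m,k} ||_2^2
#'  + lambda * sum_m sum_k || x_{m,k} ||_1`
#' with `*` the 2-D circular convolution.  This is the quantity the
#' dictionary-learning alternation drives down.
#'
#' @param dict A `conv_dictionary`.
#' @param coeffs List (one per training image) of `h x w x K` coefficient
#'   arrays.
#' @param images List of training image matrices.
#' @param lambda Sparsity weight (>= 0).
#' @return Scalar objective value.
#' @export
cdl_objective <- function(dict, coeffs, images, lambda) {
  stopifnot(length(coeffs) == length(images))
  h <- nrow(images[[1L]]); w <- ncol(images[[1L]])
  Df <- dict_freq(dict, h, w)
  obj <- 0
  for (m in seq_along(images)) {
    a <- as_coef_array(coeffs[[m]])
    if (!identical(dim(a), c(h, w, dict$K))) {
      stop("coefficient array shape does not match image/dictionary",
           call. = FALSE)
    }
    rec <- ifft2_re(reconstruct_freq(Df, fft3(a)))
    obj <- obj + 0.5 * sum((images[[m]] - rec)^2) + lambda * sum(abs(a))
  }
  obj
}

# Solve, at every frequency, (rho I + sum_m a_m a_m^H) v = b for the
# K-vector v, by iterated Sherman-Morrison over the M rank-1 terms.
# A: h x w x K x M complex, B: h x w x K complex.
ism_solve <- function(A, B, rho) {
  M <- dim(A)[4L]
  dims <- dim(B)
  dot_k <- function(x, y) {
    acc <- matrix(complex(real = 0), dims[1L], dims[2L])
    for (k in seq_len(dims[3L])) acc <- acc + Conj(x[, , k]) * y[, , k]
    acc
  }
  slice4 <- function(m) array(A[, , , m], dims)
  cs <- vector("list", M)
  as_list <- vector("list", M)
  deltas <- vector("list", M)
  apply_R <- function(t, upto) {
    t <- t / rho
    for (j in seq_len(upto)) {
      t <- t - cs[[j]] * as.vector(dot_k(as_list[[j]], t) / deltas[[j]])
    }
    t
  }
  for (m in seq_len(M)) {
    as_list[[m]] <- slice4(m)
    cs[[m]] <- apply_R(as_list[[m]], m - 1L)
    deltas[[m]] <- 1 + dot_k(as_list[[m]], cs[[m]])
  }
  apply_R(B, M)
}

# Internal learning state for the interleaved ADMM alternation.
new_cdl_state <- function(images, dict, lambda, rho) {
  h <- nrow(images[[1L]]); w <- ncol(images[[1L]])
  zeros <- function() array(0, c(h, w, dict$K))
  structure(list(
    images = images, dict = dict,
    lambda = lambda, rho = rho,
    h = h, w = w,
    x = lapply(images, function(i) zeros()),
    z = lapply(images, function(i) zeros()),
    u = lapply(images, function(i) zeros()),
    d_pad = {
      dp <- zeros()
      for (k in seq_len(dict$K)) dp[, , k] <- pad_kernel(dict$filters[[k]], h, w)
      dp
    },
    h_dual = zeros(),
    iteration = 0L,
    objective_trace = numeric(0)
  ), class = "cdl_state")
}

# Circular shift: out[i, j] = m[i - dy, j - dx] (indices mod extent).
circ_shift <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  ri <- ((seq_len(h) - 1L - dy) %% h) + 1L
  ci <- ((seq_len(w) - 1L - dx) %% w) + 1L
  m[ri, ci, drop = FALSE]
}

# Top-left corner of the s x s circular window of maximal energy; used to
# re-center a filter iterate on its support before projection.  Circular
# shifts of the filter (with the opposite shift applied to its coefficient
# maps) leave the convolution unchanged, so re-centering only changes how
# much energy the support crop keeps.
best_support_window <- function(dp, s, gain = 1.05) {
  h <- nrow(dp); w <- ncol(dp)
  ones <- pad_kernel(matrix(1, s, s), h, w)
  E <- Re(stats::fft(fft2(dp^2) * Conj(fft2(ones)), inverse = TRUE)) / (h * w)
  idx <- arrayInd(which.max(E), dim(E))
  # hysteresis: keep the current corner window unless the best window
  # carries clearly more energy, so shifts do not oscillate
  if (E[idx[1L], idx[2L]] <= gain * E[1L, 1L]) return(c(1L, 1L))
  c(idx[1L], idx[2L])
}

# Project an image-sized filter iterate onto the constraint set: restrict
# support to the s x s corner window, then renormalize to unit L2 norm.
project_cpn <- function(dp, s) {
  kern <- dp[seq_len(s), seq_len(s)]
  nrm <- sqrt(sum(kern^2))
  if (nrm < 1e-12) {
    # degenerate: no signal reached this filter; keep a unit impulse
    kern <- matrix(0, s, s); kern[1L, 1L] <- 1
  } else {
    kern <- kern / nrm
  }
  kern
}

#' One coefficient-update sweep (sparse coding step of dictionary learning)
#'
#' Holds the filters fixed and advances the coefficient maps of every
#' training image by `n_iter` ADMM iterations: a frequency-domain linear
#' solve for the data-fit primal (rank-1 Sherman-Morrison per frequency),
#' soft-thresholding of the auxiliary at `lambda/rho`, and a dual update.
#'
#' @param state A `cdl_state` (see [learn_dictionary()]).
#' @param n_iter Number of ADMM iterations (default 1, the interleaved
#'   schedule).
#' @return The updated state.
#' @export
update_coeffs <- function(state, n_iter = 1L) {
  if (state$rho <= 0) stop("`rho` must be positive", call. = FALSE)
  Df <- fft3(state$d_pad)
  DtD <- rowSums(abs(Df)^2, dims = 2L)
  rho <- state$rho
  for (m in seq_along(state$images)) {
    Yf <- fft2(state$images[[m]])
    x <- state$x[[m]]; z <- state$z[[m]]; u <- state$u[[m]]
    for (it in seq_len(n_iter)) {
      B <- fft3(z - u)
      for (k in seq_len(state$dict$K)) {
        B[, , k] <- Conj(Df[, , k]) * Yf + rho * B[, , k]
      }
      # (d* d^T + rho I)^{-1} b via Sherman-Morrison at each frequency
      dtb <- reconstruct_freq(Df, B)
      corr <- dtb / (rho + DtD)
      Xf <- B
      for (k in seq_len(state$dict$K)) {
        Xf[, , k] <- (B[, , k] - Conj(Df[, , k]) * corr) / rho
      }
      x <- ifft3_re(Xf)
      z <- soft_threshold(x + u, state$lambda / rho)
      u <- u + x - z
    }
    state$x[[m]] <- x; state$z[[m]] <- z; state$u[[m]] <- u
  }
  state
}

#' One filter-update sweep of dictionary learning
#'
#' Holds the coefficient maps fixed and advances the filters by `n_iter`
#' ADMM iterations in the frequency domain: a linear solve over the M
#' training images (iterated Sherman-Morrison over their rank-1 normal
#' equations), then projection of the auxiliary onto the constraint set
#' (s x s support, unit L2 norm), then a dual update.  Every call leaves
#' the dictionary exactly unit-norm.
#'
#' @param state A `cdl_state`.
#' @param n_iter Number of ADMM iterations (default 1).
#' @param recenter Re-center each filter on its maximal-energy support
#'   window before projecting, shifting its coefficient maps oppositely so
#'   the reconstruction is unchanged (default `TRUE`); prevents atoms from
#'   settling half outside the support crop.
#' @return The updated state.
#' @export
update_filters <- function(state, n_iter = 1L, recenter = TRUE) {
  M <- length(state$images)
  h <- state$h; w <- state$w; K <- state$dict$K
  rho <- state$rho
  A <- array(complex(real = 0), c(h, w, K, M))
  B0 <- array(complex(real = 0), c(h, w, K))
  for (m in seq_len(M)) {
    Xf <- fft3(as_coef_array(state$z[[m]]))
    Yf <- fft2(state$images[[m]])
    for (k in seq_len(K)) {
      A[, , k, m] <- Conj(Xf[, , k])
      B0[, , k] <- B0[, , k] + Conj(Xf[, , k]) * Yf
    }
  }
  g <- state$d_pad
  hd <- state$h_dual
  for (it in seq_len(n_iter)) {
    B <- B0 + rho * fft3(g - hd)
    Df <- ism_solve(A, B, rho)
    d_new <- ifft3_re(Df)
    gh <- d_new + hd
    for (k in seq_len(K)) {
      ghk <- gh[, , k]
      if (recenter) {
        at <- best_support_window(ghk, state$dict$s)
        if (at[1L] != 1L || at[2L] != 1L) {
          dy <- 1L - at[1L]; dx <- 1L - at[2L]
          ghk <- circ_shift(ghk, dy, dx)
          d_new[, , k] <- circ_shift(d_new[, , k], dy, dx)
          hd[, , k] <- circ_shift(hd[, , k], dy, dx)
          for (m in seq_len(M)) {
            state$x[[m]][, , k] <- circ_shift(state$x[[m]][, , k], -dy, -dx)
            state$z[[m]][, , k] <- circ_shift(state$z[[m]][, , k], -dy, -dx)
            state$u[[m]][, , k] <- circ_shift(state$u[[m]][, , k], -dy, -dx)
          }
        }
      }
      kern <- project_cpn(ghk, state$dict$s)
      state$dict$filters[[k]] <- kern
      g[, , k] <- pad_kernel(kern, h, w)
    }
    hd <- hd + d_new - g
  }
  state$d_pad <- g
  state$h_dual <- hd
  state
}

#' Learn a convolutional sparse dictionary by ADMM alternation
#'
#' Alternates coefficient updates and filter updates (one interleaved ADMM
#' iteration each) on a set of training images, tracking the sparse-coding
#' objective, until the relative objective change drops below `tol` or
#' `max_iters` alternations have run.
#'
#' @param images List of training image matrices (same extent).
#' @param K Number of filters.
#' @param s Filter size (default 8).
#' @param lambda Sparsity weight (default 0.01).
#' @param max_iters Maximum alternations (default 30).
#' @param tol Relative objective-change stopping threshold (default 0.03).
#' @param seed Seed for the filter initialization.
#' @param scale_tag Optional label stored on the dictionary.
#' @return A `conv_dictionary` with attributes `objective_trace` (numeric
#'   vector) and `no_signal` (TRUE when the training set carried no
#'   energy, in which case the initialized dictionary is returned and a
#'   warning is raised).
#' @export
learn_dictionary <- function(images, K, s = 8L, lambda = 0.01,
                             max_iters = 30L, tol = 0.03, seed = 1L,
                             scale_tag = NULL) {
  if (length(images) < 1L) stop("need at least one training image",
                                call. = FALSE)
  d <- dim(images[[1L]])
  for (im in images) {
    validate_gray_image(im, "training image", range = FALSE)
    if (!identical(dim(im), d)) stop("training image extents differ",
                                     call. = FALSE)
  }
  dict <- init_dictionary(K, s, seed, scale_tag)
  energy <- sum(vapply(images, function(i) sum(i^2), 0))
  if (energy < 1e-12) {
    warning("training images carry no signal; returning initialized dictionary")
    attr(dict, "objective_trace") <- 0
    attr(dict, "no_signal") <- TRUE
    return(dict)
  }
  rho <- 10 * lambda + 0.1
  state <- new_cdl_state(images, dict, lambda, rho)
  prev <- Inf
  for (it in seq_len(max_iters)) {
    state <- update_coeffs(state)
    state <- update_filters(state)
    obj <- cdl_objective(state$dict, state$z, images, lambda)
    state$objective_trace <- c(state$objective_trace, obj)
    state$iteration <- it
    if (is.finite(prev) && abs(prev - obj) / max(prev, 1e-12) < tol) {
      prev <- obj
      break
    }
    prev <- obj
  }
  out <- state$dict
  attr(out, "objective_trace") <- state$objective_trace
  attr(out, "no_signal") <- FALSE
  out
}

#' Learn the multi-scale dictionary family from two source pyramids
#'
#' For each scale, the three orientation sub-images of both sources form
#' the training set of that scale's sub-dictionary; the two low sub-images
#' train the low-frequency dictionary.  The high-frequency dictionary is
#' the concatenation of the per-scale sub-dictionaries.
#'
#' @param pyr_a,pyr_b `subband_pyramid` objects from the same decomposition
#'   configuration.
#' @param K Filters per sub-dictionary.
#' @param s Filter size.
#' @param lambda Sparsity weight.
#' @param max_iters,tol Stopping rule, as in [learn_dictionary()].
#' @param seed Base seed (each sub-dictionary derives its own).
#' @return List: `d_low` (`conv_dictionary`), `d_scales` (list of per-scale
#'   dictionaries), `d_high` (their concatenation).
#' @export
learn_multiscale <- function(pyr_a, pyr_b, K = 32L, s = 8L, lambda = 0.01,
                             max_iters = 30L, tol = 0.03, seed = 1L) {
  stopifnot(inherits(pyr_a, "subband_pyramid"), inherits(pyr_b, "subband_pyramid"))
  if (!identical(dim(pyr_a$low), dim(pyr_b$low)) ||
      !identical(names(pyr_a$highs), names(pyr_b$highs))) {
    stop("pyramids come from different decompositions", call. = FALSE)
  }
  # canonical training order: the training sets are unordered unions of
  # sub-images from both sources, but the ADMM trajectory depends on the
  # list order, so sort by a content-derived key to make the learned
  # dictionaries invariant under swapping the two sources
  canon <- function(imgs) {
    key <- vapply(imgs, function(x) sum(x^2) + 1e-3 * mean(x) +
                    1e-6 * x[1L, 1L], 0)
    imgs[order(key, method = "radix")]
  }
  d_low <- canon(list(pyr_a$low, pyr_b$low))
  d_low <- learn_dictionary(d_low, K = K, s = s,
                            lambda = lambda, max_iters = max_iters, tol = tol,
                            seed = seed, scale_tag = "low")
  d_scales <- list()
  for (l in seq_len(pyr_a$levels)) {
    keys <- grep(sprintf("^s%d_", l), names(pyr_a$highs), value = TRUE)
    train <- canon(c(pyr_a$highs[keys], pyr_b$highs[keys]))
    d_scales[[l]] <- learn_dictionary(unname(train), K = K, s = s,
                                      lambda = lambda, max_iters = max_iters,
                                      tol = tol, seed = seed + l,
                                      scale_tag = sprintf("scale%d", l))
  }
  d_high <- structure(list(
    filters = do.call(c, lapply(d_scales, `[[`, "filters")),
    K = sum(vapply(d_scales, `[[`, 0L, "K")),
    s = s, scale_tag = "high", seed = seed
  ), class = "conv_dictionary")
  list(d_low = d_low, d_scales = d_scales, d_high = d_high)
}
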