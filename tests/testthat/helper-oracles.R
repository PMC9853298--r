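# Independent brute-force oracles used across the suite.  These are
# deliberately written as plain nested loops (or direct formula
# transcriptions), sharing no code with the package internals they check.

rand_img <- function(n, m = n, seed = 1) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); code
  }
  withr_seed(matrix(runif(n * m), n, m))
}

# replicate-padded pixel accessor
.px <- function(x, i, j) {
  i <- min(max(i, 1L), nrow(x)); j <- min(max(j, 1L), ncol(x))
  x[i, j]
}

oracle_region_std <- function(x, r) {
  d <- (2 * r + 1)^2
  out <- matrix(0, nrow(x), ncol(x))
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x))) {
    v <- numeric(0)
    for (m in (i - r):(i + r)) for (n in (j - r):(j + r)) {
      v <- c(v, .px(x, m, n))
    }
    out[i, j] <- sqrt(sum((v - mean(v))^2) / (d - 1))
  }
  out
}

oracle_region_energy <- function(x, r) {
  out <- matrix(0, nrow(x), ncol(x))
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x))) {
    s <- 0
    for (m in (i - r):(i + r)) for (n in (j - r):(j + r)) {
      s <- s + .px(x, m, n)^2
    }
    out[i, j] <- s
  }
  out
}

oracle_activity <- function(maps, r) {
  K <- dim(maps)[3]
  h <- dim(maps)[1]; w <- dim(maps)[2]
  l1 <- matrix(0, h, w)
  for (k in seq_len(K)) l1 <- l1 + abs(maps[, , k])
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    s <- 0; cnt <- 0
    for (m in (i - r):(i + r)) for (n in (j - r):(j + r)) {
      if (m >= 1 && m <= h && n >= 1 && n <= w) {
        s <- s + l1[m, n]; cnt <- cnt + 1
      }
    }
    out[i, j] <- s / cnt
  }
  out
}

oracle_nmsf <- function(x, r) {
  h <- nrow(x); w <- ncol(x)
  dh <- dv <- dd <- da <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    dh[i, j] <- (x[i, j] - .px(x, i, j - 1))^2
    dv[i, j] <- (x[i, j] - .px(x, i - 1, j))^2
    dd[i, j] <- (x[i, j] - .px(x, i - 1, j - 1))^2
    da[i, j] <- (x[i, j] - .px(x, i - 1, j + 1))^2
  }
  d <- (2 * r + 1)^2
  wmean <- function(m, i, j) {
    s <- 0
    for (a in (i - r):(i + r)) for (b in (j - r):(j + r)) s <- s + .px(m, a, b)
    s / d
  }
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    out[i, j] <- sqrt(wmean(dh, i, j) + wmean(dv, i, j) +
                        wmean(dd, i, j) / sqrt(2) + wmean(da, i, j) / sqrt(2))
  }
  out
}

oracle_sf <- function(x) {
  h <- nrow(x); w <- ncol(x)
  rf <- 0; cf <- 0
  for (i in seq_len(h)) for (j in 2:w) rf <- rf + (x[i, j] - x[i, j - 1])^2
  for (i in 2:h) for (j in seq_len(w)) cf <- cf + (x[i, j] - x[i - 1, j])^2
  sqrt(rf / (h * (w - 1)) + cf / ((h - 1) * w))
}

oracle_rmse <- function(f, a, b) {
  ra <- sqrt(mean((f - a)^2)); rb <- sqrt(mean((f - b)^2))
  (ra + rb) / 2
}

oracle_sobel <- function(x) {
  h <- nrow(x); w <- ncol(x)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    gx <- .px(x, i - 1, j + 1) + 2 * .px(x, i, j + 1) + .px(x, i + 1, j + 1) -
      .px(x, i - 1, j - 1) - 2 * .px(x, i, j - 1) - .px(x, i + 1, j - 1)
    gy <- .px(x, i + 1, j - 1) + 2 * .px(x, i + 1, j) + .px(x, i + 1, j + 1) -
      .px(x, i - 1, j - 1) - 2 * .px(x, i - 1, j) - .px(x, i - 1, j + 1)
    out[i, j] <- sqrt(gx^2 + gy^2)
  }
  out
}

oracle_gsm <- function(f, a, b) {
  cc <- 1e-4
  gf <- oracle_sobel(f)
  one <- function(s) {
    g <- oracle_sobel(s)
    mean((2 * gf * g + cc) / (gf^2 + g^2 + cc))
  }
  (one(a) + one(b)) / 2
}

oracle_ag <- function(x) {
  h <- nrow(x); w <- ncol(x)
  v <- c()
  for (i in 2:(h - 1)) for (j in 2:(w - 1)) {
    dx <- (x[i, j + 1] - x[i, j - 1]) / 2
    dy <- (x[i + 1, j] - x[i - 1, j]) / 2
    v <- c(v, sqrt((dx^2 + dy^2) / 2))
  }
  mean(v)
}

oracle_mi <- function(x, y, bins = 256) {
  bx <- pmin(floor(x * bins) + 1, bins)
  by <- pmin(floor(y * bins) + 1, bins)
  n <- length(x)
  joint <- matrix(0, bins, bins)
  for (i in seq_len(n)) joint[bx[i], by[i]] <- joint[bx[i], by[i]] + 1
  joint <- joint / n
  px <- rowSums(joint); py <- colSums(joint)
  s <- 0
  for (i in seq_len(bins)) for (j in seq_len(bins)) {
    if (joint[i, j] > 0) {
      s <- s + joint[i, j] * log2(joint[i, j] / (px[i] * py[j]))
    }
  }
  s
}

# direct circular 2-D convolution by nested loops (the transform oracle
# for everything that goes through the FFT path)
oracle_cconv <- function(kern, x) {
  h <- nrow(x); w <- ncol(x)
  kh <- nrow(kern); kw <- ncol(kern)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    s <- 0
    for (a in seq_len(kh)) for (b in seq_len(kw)) {
      ii <- ((i - a) %% h) + 1L
      jj <- ((j - b) %% w) + 1L
      s <- s + kern[a, b] * x[ii, jj]
    }
    out[i, j] <- s
  }
  out
}

oracle_cdl_objective <- function(filters, coeffs, images, lambda) {
  obj <- 0
  for (m in seq_along(images)) {
    rec <- matrix(0, nrow(images[[m]]), ncol(images[[m]]))
    for (k in seq_along(filters)) {
      rec <- rec + oracle_cconv(filters[[k]], coeffs[[m]][, , k])
    }
    obj <- obj + 0.5 * sum((images[[m]] - rec)^2) +
      lambda * sum(abs(coeffs[[m]]))
  }
  obj
}

# ISTA (proximal gradient) reference solver for plain convolutional
# sparse coding; an algorithmically independent route to the Eq-level
# optimum used to cross-check the ADMM coefficient solver.
ista_csc <- function(s, dict, lambda, iters = 200) {
  h <- nrow(s); w <- ncol(s); K <- dict$K
  Df <- array(complex(real = 0), c(h, w, K))
  for (k in seq_len(K)) {
    pad <- matrix(0, h, w)
    pad[seq_len(dict$s), seq_len(dict$s)] <- dict$filters[[k]]
    Df[, , k] <- fft(pad)
  }
  L <- max(Reduce(`+`, lapply(seq_len(K), function(k) abs(Df[, , k])^2)))
  eta <- 1 / L
  x <- array(0, c(h, w, K))
  Yf <- fft(s)
  soft <- function(v, t) sign(v) * pmax(abs(v) - t, 0)
  for (it in seq_len(iters)) {
    Xf <- array(complex(real = 0), c(h, w, K))
    for (k in seq_len(K)) Xf[, , k] <- fft(x[, , k])
    Rf <- Reduce(`+`, lapply(seq_len(K), function(k) Df[, , k] * Xf[, , k])) - Yf
    for (k in seq_len(K)) {
      grad <- Re(fft(Conj(Df[, , k]) * Rf, inverse = TRUE)) / (h * w)
      x[, , k] <- soft(x[, , k] - eta * grad, eta * lambda)
    }
  }
  x
}

csc_objective_of <- function(x, s, dict, lambda) {
  rec <- csc_reconstruct(x, dict)
  0.5 * sum((s - rec)^2) + lambda * sum(abs(x))
}

# best absolute correlation between two unit-norm filters over all
# circular shifts on a 16x16 torus, by direct search
best_shift_corr <- function(f, g) {
  n <- 16L
  fp <- matrix(0, n, n); fp[1:nrow(f), 1:ncol(f)] <- f
  gp <- matrix(0, n, n); gp[1:nrow(g), 1:ncol(g)] <- g
  best <- 0
  for (dy in 0:(n - 1)) for (dx in 0:(n - 1)) {
    gs <- gp[((seq_len(n) - 1 + dy) %% n) + 1, ((seq_len(n) - 1 + dx) %% n) + 1]
    best <- max(best, abs(sum(fp * gs)))
  }
  best
}

make_dict <- function(filters, s = nrow(filters[[1]])) {
  structure(list(filters = filters, K = length(filters), s = s,
                 scale_tag = NULL, seed = NA),
            class = "conv_dictionary")
}

# data synthesized from known filters with sparse coefficient maps
planted_images <- function(truth, n = 64, m = 4, density = 0.02,
                           noise = 0.01, seed = 99, amp_min = NULL) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  lapply(seq_len(m), function(i) {
    acc <- matrix(0, n, n)
    for (k in seq_len(truth$K)) {
      x <- matrix(0, n, n)
      idx <- sample(n * n, round(density * n * n))
      x[idx] <- rnorm(length(idx))
      acc <- acc + csc_reconstruct(array(x, c(n, n, 1)),
                                   make_dict(truth$filters[k]))
    }
    acc + matrix(rnorm(n * n, 0, noise), n, n)
  })
}
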