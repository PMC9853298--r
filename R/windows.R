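# Sliding-window primitives shared by the salience measures.  All windows
# are square, (2*radius+1) on a side, centered on each pixel.

pad_replicate <- function(x, r) {
  h <- nrow(x); w <- ncol(x)
  x[c(rep(1L, r), seq_len(h), rep(h, r)),
    c(rep(1L, r), seq_len(w), rep(w, r)), drop = FALSE]
}

# Running-sum along rows: column sums over each vertical window of height
# 2r+1, for a matrix already padded by r on top/bottom.
.strip_sum <- function(p, r, n_out) {
  cs <- rbind(0, apply(p, 2L, cumsum))
  cs[(2L * r + 2L):(n_out + 2L * r + 1L), , drop = FALSE] -
    cs[seq_len(n_out), , drop = FALSE]
}

# Windowed sum with edge replication.
win_sum <- function(x, radius) {
  r <- as.integer(radius)
  if (r < 1L) stop("`radius` must be >= 1", call. = FALSE)
  p <- pad_replicate(x, r)
  s1 <- .strip_sum(p, r, nrow(x))
  t(.strip_sum(t(s1), r, ncol(x)))
}

# Windowed mean over the pixels of the window that fall inside the image
# (no replication; the divisor is the actual pixel count, so a window that
# overhangs the border averages over fewer pixels).
win_mean_clipped <- function(x, radius) {
  r <- as.integer(radius)
  if (r < 1L) stop("`radius` must be >= 1", call. = FALSE)
  h <- nrow(x); w <- ncol(x)
  zp <- matrix(0, h + 2L * r, w + 2L * r)
  zp[r + seq_len(h), r + seq_len(w)] <- x
  cp <- matrix(0, h + 2L * r, w + 2L * r)
  cp[r + seq_len(h), r + seq_len(w)] <- 1
  s <- .strip_sum(zp, r, h); s <- t(.strip_sum(t(s), r, w))
  n <- .strip_sum(cp, r, h); n <- t(.strip_sum(t(n), r, w))
  s / n
}

.check_window <- function(x, radius, what = "map") {
  if (2L * radius + 1L > min(dim(x))) {
    stop(sprintf("window of radius %d is too large for a %dx%d %s",
                 radius, nrow(x), ncol(x), what), call. = FALSE)
  }
}
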