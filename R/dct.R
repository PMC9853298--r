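# Orthonormal DCT-II basis matrix of order n: C %*% x transforms a length-n
# signal; C is orthogonal, so Parseval holds exactly.
dct_matrix <- function(n = 8L) {
  k <- seq_len(n) - 1L
  C <- sqrt(2 / n) * outer(k, k, function(u, x) cos(pi * (2 * x + 1) * u / (2 * n)))
  C[1L, ] <- C[1L, ] / sqrt(2)
  C
}

#' Zig-zag scan order of an 8x8 coefficient block
#'
#' Returns the standard JPEG zig-zag index (0-based, 0 = DC) of every
#' coefficient position, as an 8x8 integer matrix indexed by
#' (vertical frequency u + 1, horizontal frequency v + 1).
#'
#' @param n Block size (default 8).
#' @return `n x n` integer matrix of zig-zag indices.
#' @export
zigzag_index <- function(n = 8L) {
  z <- matrix(0L, n, n)
  pos <- 0L
  for (s in 0:(2L * n - 2L)) {
    us <- max(0L, s - n + 1L):min(s, n - 1L)
    if (s %% 2L == 0L) us <- rev(us)  # even diagonals run bottom-left to top-right
    for (u in us) {
      z[u + 1L, s - u + 1L] <- pos
      pos <- pos + 1L
    }
  }
  z
}

#' Sub-band layout of the 8x8 block-DCT coefficients
#'
#' Orders the 64 coefficients of each block by zig-zag index z and assigns
#' them to one low band and `levels` scales of three orientations each:
#' the low band is z in 0..5; at three levels the scales are z in 6..20,
#' 21..42 and 43..63; within a scale, orientation is `vertical` where the
#' vertical frequency dominates (u > v), `horizontal` where u < v, and
#' `diagonal` where u = v.  The index sets are pairwise disjoint and cover
#' 0..63 exactly, which is what makes the decomposition an exact partition.
#'
#' @param levels Number of scales, 1 to 3.
#' @return Named list of 0-based zig-zag index vectors: `low` plus
#'   `s<l>_<orientation>` for each scale/orientation.
#' @export
band_spec <- function(levels = 3L) {
  if (!is.numeric(levels) || length(levels) != 1L || levels < 1L || levels > 3L) {
    stop("`levels` must be 1, 2 or 3", call. = FALSE)
  }
  levels <- as.integer(levels)
  cuts <- c(6L, 21L, 43L, 64L)
  lo <- cuts[seq_len(levels)]
  hi <- if (levels > 1L) c(cuts[2:levels], 64L) else 64L
  zz <- zigzag_index(8L)
  u <- row(zz) - 1L
  v <- col(zz) - 1L
  spec <- list(low = sort(zz[zz < 6L]))
  for (l in seq_len(levels)) {
    in_scale <- zz >= lo[l] & zz < hi[l]
    spec[[sprintf("s%d_vertical", l)]]   <- sort(zz[in_scale & u > v])
    spec[[sprintf("s%d_horizontal", l)]] <- sort(zz[in_scale & u < v])
    spec[[sprintf("s%d_diagonal", l)]]   <- sort(zz[in_scale & u == v])
  }
  all_z <- sort(unlist(spec, use.names = FALSE))
  stopifnot(identical(as.integer(all_z), 0:63))
  spec
}

# Apply an 8x8 matrix M to every vertical 8-strip of rows of X (block rows).
.block_rows <- function(X, M) {
  h <- nrow(X); w <- ncol(X)
  A <- matrix(array(X, c(8L, h / 8L * w)), nrow = 8L)
  Y <- M %*% A
  matrix(array(Y, c(8L, h / 8L, w)), nrow = h, ncol = w)
}

#' Blockwise 2-D DCT of a grayscale image
#'
#' Pads the image to multiples of 8 by edge replication, then applies the
#' orthonormal 2-D DCT-II to each 8x8 block.  Orthonormality means total
#' coefficient energy equals total (padded) pixel energy.
#'
#' @param img Numeric matrix of intensities.
#' @return An object of class `block_coeffs`: a list with `coeffs`
#'   (block-row x block-col x 8 x 8 array), the original extent and the
#'   padded extent.
#' @export
block_dct2 <- function(img) {
  validate_gray_image(img, "img", range = FALSE)
  p <- pad_to_block(img, 8L)
  C <- dct_matrix(8L)
  T1 <- .block_rows(p, C)
  T2 <- t(.block_rows(t(T1), C))
  br <- nrow(p) / 8L; bc <- ncol(p) / 8L
  A <- array(T2, c(8L, br, 8L, bc))
  structure(list(
    coeffs = aperm(A, c(2L, 4L, 1L, 3L)),
    orig_h = attr(p, "orig_h"), orig_w = attr(p, "orig_w"),
    pad_h = nrow(p), pad_w = ncol(p)
  ), class = "block_coeffs")
}

#' Inverse blockwise 2-D DCT
#'
#' Exact inverse of [block_dct2()]; the result is cropped to the original
#' (pre-padding) extent.
#'
#' @param bc A `block_coeffs` object.
#' @return Numeric matrix with the original image extent.
#' @export
block_idct2 <- function(bc) {
  if (!inherits(bc, "block_coeffs")) stop("`bc` must be a block_coeffs object",
                                          call. = FALSE)
  d <- dim(bc$coeffs)
  if (d[1] * 8L != bc$pad_h || d[2] * 8L != bc$pad_w) {
    stop("coefficient array inconsistent with recorded geometry", call. = FALSE)
  }
  A <- aperm(bc$coeffs, c(3L, 1L, 4L, 2L))
  X <- matrix(A, nrow = bc$pad_h, ncol = bc$pad_w)
  C <- dct_matrix(8L)
  T1 <- .block_rows(X, t(C))
  out <- t(.block_rows(t(T1), t(C)))
  out[seq_len(bc$orig_h), seq_len(bc$orig_w), drop = FALSE]
}

#' Multi-scale sub-band decomposition of an image
#'
#' Computes the 8x8 block DCT, masks the coefficients to each band of
#' [band_spec()], and inverse-transforms every band back to the spatial
#' domain.  Because the bands partition an orthonormal transform, the low
#' sub-image plus all high sub-images reproduce the source exactly.
#'
#' @param img Numeric matrix of intensities.
#' @param levels Number of scales (1..3, default 3).
#' @return An object of class `subband_pyramid`: list with `low` (matrix),
#'   `highs` (named list of matrices, names as in [band_spec()]), the
#'   `band_spec`, and the source extent.
#' @export
dct_decompose <- function(img, levels = 3L) {
  spec <- band_spec(levels)
  bc <- block_dct2(img)
  zz <- zigzag_index(8L)
  masks <- lapply(spec, function(zset) zz %in% zset)
  sub <- lapply(masks, function(m) {
    mb <- bc
    mask4 <- aperm(array(matrix(m, 8L, 8L),
                         c(8L, 8L, dim(bc$coeffs)[1], dim(bc$coeffs)[2])),
                   c(3L, 4L, 1L, 2L))
    mb$coeffs <- bc$coeffs * mask4
    block_idct2(mb)
  })
  structure(list(
    low = sub$low,
    highs = sub[setdiff(names(sub), "low")],
    band_spec = spec,
    levels = as.integer(levels),
    height = bc$orig_h, width = bc$orig_w
  ), class = "subband_pyramid")
}

#' Reconstruct an image from a sub-band pyramid
#' @param pyr A `subband_pyramid`.
#' @return Numeric matrix: `low` plus the sum of all high sub-images.
#' @export
pyramid_reconstruct <- function(pyr) {
  stopifnot(inherits(pyr, "subband_pyramid"))
  Reduce(`+`, pyr$highs, pyr$low)
}

#' Per-block focus-evaluation ratio
#'
#' For each 8x8 block the 64 DCT coefficients are normalized to unit L2
#' norm, and the ratio of high-order to low-order coefficient energy
#' (in zig-zag order) is returned.  Blocks with no energy get ratio 0; a
#' small guard (1e-12) in the denominator caps the ratio at 1e12 for blocks
#' with no low-order energy.  Exposed as a focus/detail diagnostic; the
#' default fusion pipeline does not consume it.
#'
#' @param bc A `block_coeffs` object.
#' @param low_order_count Number of leading zig-zag coefficients counted as
#'   "low order" (1..63; default 6, the size of the low band).
#' @return Matrix of per-block ratios (block-rows x block-cols).
#' @export
focus_ratio <- function(bc, low_order_count = 6L) {
  stopifnot(inherits(bc, "block_coeffs"))
  if (low_order_count < 1L || low_order_count > 63L) {
    stop("`low_order_count` must be in 1..63", call. = FALSE)
  }
  eps_guard <- 1e-12
  cap <- 1e12
  zz <- zigzag_index(8L)
  lo_mask <- zz < low_order_count
  d <- dim(bc$coeffs)
  out <- matrix(0, d[1], d[2])
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      blk <- bc$coeffs[i, j, , ]
      n2 <- sum(blk^2)
      if (n2 == 0) next
      blk2 <- blk^2 / n2
      lo <- sum(blk2[lo_mask])
      hi <- sum(blk2[!lo_mask])
      out[i, j] <- min(hi / (lo + eps_guard), cap)
    }
  }
  out
}
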