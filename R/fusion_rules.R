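#' Average low-frequency coefficients of aligned sources
#'
#' Fuses p aligned low-frequency coefficient maps (or sub-images) by
#' uniform weighted averaging: each source gets weight 1/p, so the weights
#' sum to one at every pixel.
#'
#' @param lows List of p >= 2 numeric matrices with identical extents.
#' @return Fused matrix; the per-source weights (all `1/p`) are attached as
#'   attribute `"weights"`.
#' @export
dct_fuse_low <- function(lows) {
  p <- length(lows)
  if (p < 2L) stop("need at least two sources", call. = FALSE)
  d <- dim(lows[[1L]])
  for (x in lows) {
    if (!identical(dim(x), d)) stop("source extents differ", call. = FALSE)
  }
  out <- Reduce(`+`, lows) / p
  attr(out, "weights") <- rep(1 / p, p)
  out
}

#' Regional standard deviation
#'
#' Unbiased standard deviation of the values in the (2*radius+1)-square
#' window centered on each pixel, with edge replication: the divisor is
#' d - 1 where d is the window pixel count.
#'
#' @param map Numeric matrix (typically high-frequency coefficients).
#' @param radius Window radius in pixels (window is `2*radius+1` square).
#' @return Matrix of per-pixel regional standard deviations (>= 0).
#' @export
region_std <- function(map, radius = 1L) {
  .check_window(map, radius)
  d <- (2 * radius + 1)^2
  # shift by the global mean: the windowed variance is shift-invariant and
  # this keeps constant maps at exactly zero
  map <- map - mean(map)
  m <- win_sum(map, radius) / d
  ss <- win_sum(map^2, radius)
  sqrt(pmax(ss - d * m^2, 0) / (d - 1))
}

#' Fuse high-frequency maps by maximum regional-deviation weight
#'
#' Each source's regional standard deviation is converted to a per-pixel
#' weight (deviations normalized to sum to one across sources; pixels where
#' every deviation is zero get uniform weights), and the fused value at a
#' pixel is taken from the source with the largest weight.  Ties go to the
#' earliest source in the list.
#'
#' @param highs List of p >= 2 aligned numeric matrices.
#' @param radius Window radius for [region_std()].
#' @return Fused matrix; attributes `"weights"` (list of per-source weight
#'   maps) and `"winner"` (matrix of winning source indices) are attached.
#' @export
dct_fuse_high <- function(highs, radius = 1L) {
  p <- length(highs)
  if (p < 2L) stop("need at least two sources", call. = FALSE)
  d <- dim(highs[[1L]])
  for (x in highs) {
    if (!identical(dim(x), d)) stop("source extents differ", call. = FALSE)
  }
  C <- lapply(highs, region_std, radius = radius)
  tot <- Reduce(`+`, C)
  W <- lapply(C, function(ck) {
    w <- ck / tot
    w[tot == 0] <- 1 / p
    w
  })
  wm <- vapply(W, as.vector, numeric(prod(d)))
  winner <- max.col(wm, ties.method = "first")
  hm <- vapply(highs, as.vector, numeric(prod(d)))
  fused <- matrix(hm[cbind(seq_len(prod(d)), winner)], d[1L], d[2L])
  attr(fused, "weights") <- W
  attr(fused, "winner") <- matrix(winner, d[1L], d[2L])
  fused
}

#' Regional energy of a low-frequency sub-image
#'
#' Sum of squared intensities over the (2*radius+1)-square window centered
#' on each pixel (edges replicated); a salience proxy for local brightness
#' and contour strength.
#'
#' @param low Numeric matrix.
#' @param radius Window radius.
#' @return Non-negative matrix of regional energies.
#' @export
region_energy <- function(low, radius = 1L) {
  if (radius < 1L) stop("`radius` must be >= 1", call. = FALSE)
  win_sum(low^2, radius)
}

#' Averaged-L1 activity map of convolutional coefficients
#'
#' At each pixel, the L1 norm of the coefficient vector across all filter
#' maps is averaged over the surrounding window (the window is clipped at
#' the image border and the divisor is the in-image pixel count).  Measures
#' how strongly the dictionary fires around a pixel.
#'
#' @param maps `h x w x K` array of coefficient maps (or a list of K
#'   matrices).
#' @param radius Window radius.
#' @return Non-negative matrix, same extent as the maps.
#' @export
activity_map <- function(maps, radius = 1L) {
  a <- as_coef_array(maps)
  l1 <- rowSums(abs(a), dims = 2L)
  win_mean_clipped(l1, radius)
}

as_coef_array <- function(maps) {
  if (is.list(maps)) {
    maps <- array(unlist(maps), c(dim(maps[[1L]]), length(maps)))
  }
  if (length(dim(maps)) == 2L) maps <- array(maps, c(dim(maps), 1L))
  stopifnot(length(dim(maps)) == 3L)
  maps
}

#' Sum-modified spatial frequency map
#'
#' A windowed spatial-frequency measure with diagonal terms: at each pixel,
#' the squared horizontal, vertical, main-diagonal and anti-diagonal first
#' differences are averaged over the window (edges replicated), the two
#' diagonal terms are down-weighted by 1/sqrt(2) for their longer step, and
#' the four terms combine as
#' `sqrt(RF^2 + CF^2 + MDF^2 + SDF^2)`.  Zero on constant images; a
#' salience proxy for local texture sharpness.
#'
#' @param x Numeric matrix.
#' @param radius Window radius.
#' @return Non-negative matrix of the same extent.
#' @export
nmsf <- function(x, radius = 1L) {
  if (radius < 1L) stop("`radius` must be >= 1", call. = FALSE)
  h <- nrow(x); w <- ncol(x)
  p <- pad_replicate(x, 1L)
  ic <- 1L + seq_len(h); jc <- 1L + seq_len(w)
  dh <- (p[ic, jc] - p[ic, jc - 1L])^2
  dv <- (p[ic, jc] - p[ic - 1L, jc])^2
  dd <- (p[ic, jc] - p[ic - 1L, jc - 1L])^2
  da <- (p[ic, jc] - p[ic - 1L, jc + 1L])^2
  d <- (2 * radius + 1)^2
  rf2 <- win_sum(dh, radius) / d
  cf2 <- win_sum(dv, radius) / d
  mdf2 <- win_sum(dd, radius) / d / sqrt(2)
  sdf2 <- win_sum(da, radius) / d / sqrt(2)
  sqrt(rf2 + cf2 + mdf2 + sdf2)
}

# Winner-take-all merge of two coefficient stacks by per-pixel salience.
# The whole K-vector at a pixel comes from the source with the larger
# salience; ties (within a tiny relative tolerance, so floating-point
# noise cannot break the A/B symmetry of the rule) average the two
# vectors.
select_coeffs <- function(maps_a, maps_b, sal_a, sal_b) {
  a <- as_coef_array(maps_a); b <- as_coef_array(maps_b)
  stopifnot(identical(dim(a), dim(b)))
  K <- dim(a)[3L]
  tie <- abs(sal_a - sal_b) <= 1e-9 * pmax(sal_a, sal_b)
  pick_a <- sal_a > sal_b & !tie
  fused <- b
  for (k in seq_len(K)) {
    fa <- a[, , k]; fk <- fused[, , k]
    fk[pick_a] <- fa[pick_a]
    fk[tie] <- (fa[tie] + b[, , k][tie]) / 2
    fused[, , k] <- fk
  }
  winner <- matrix(2L, nrow(sal_a), ncol(sal_a))
  winner[pick_a] <- 1L
  winner[tie] <- 0L
  attr(fused, "winner") <- winner
  fused
}

#' Fuse low-frequency sub-bands in the convolutional sparse domain
#'
#' Salience for each source is the product of the regional energy of its
#' low sub-image and the averaged-L1 activity of its coefficient maps.  The
#' fused coefficient stack takes, at every pixel, the entire coefficient
#' vector of the higher-salience source (ties averaged), and is then
#' reconstructed through the low-frequency dictionary.
#'
#' @param maps_a,maps_b Coefficient maps of the two sources (same
#'   dictionary).
#' @param low_a,low_b The low-frequency sub-images.
#' @param dict The low-frequency `conv_dictionary` used for coding.
#' @param radius Salience window radius (default 1, a 3x3 window).
#' @param offset Common DC offset removed from both sources before coding
#'   and added back to the fused reconstruction (default 0).  Using one
#'   shared offset keeps the two codes mutually consistent, so pixel-wise
#'   winner-take-all mixing cannot create brightness seams.
#' @return List: `image` (fused low sub-image), `maps` (fused stack),
#'   `salience_a`, `salience_b`, `winner` (1 = first source, 2 = second,
#'   0 = tie).
#' @export
fuse_low_csr <- function(maps_a, maps_b, low_a, low_b, dict, radius = 1L,
                         offset = 0) {
  a <- as_coef_array(maps_a)
  if (dim(a)[3L] != length(dict$filters)) {
    stop("coefficient map count does not match dictionary size", call. = FALSE)
  }
  sal_a <- region_energy(low_a, radius) * activity_map(maps_a, radius)
  sal_b <- region_energy(low_b, radius) * activity_map(maps_b, radius)
  fused <- select_coeffs(maps_a, maps_b, sal_a, sal_b)
  list(image = csc_reconstruct(fused, dict) + offset, maps = fused,
       salience_a = sal_a, salience_b = sal_b,
       winner = attr(fused, "winner"))
}

#' Fuse a high-frequency sub-band in the convolutional sparse domain
#'
#' Same winner-take-all scheme as [fuse_low_csr()], but salience is the
#' product of the sum-modified spatial frequency of the sub-band image and
#' the averaged-L1 activity of its coefficient maps: texture sharpness
#' rather than brightness drives the selection in the detail bands.
#'
#' @inheritParams fuse_low_csr
#' @param high_a,high_b The high-frequency sub-band images.
#' @param dict The `conv_dictionary` of the matching scale.
#' @return Same structure as [fuse_low_csr()].
#' @export
fuse_high_csr <- function(maps_a, maps_b, high_a, high_b, dict, radius = 1L) {
  a <- as_coef_array(maps_a)
  if (dim(a)[3L] != length(dict$filters)) {
    stop("coefficient map count does not match dictionary size", call. = FALSE)
  }
  sal_a <- nmsf(high_a, radius) * activity_map(maps_a, radius)
  sal_b <- nmsf(high_b, radius) * activity_map(maps_b, radius)
  fused <- select_coeffs(maps_a, maps_b, sal_a, sal_b)
  list(image = csc_reconstruct(fused, dict), maps = fused,
       salience_a = sal_a, salience_b = sal_b,
       winner = attr(fused, "winner"))
}
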