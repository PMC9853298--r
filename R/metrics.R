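.check_pair <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("image extents differ", call. = FALSE)
}

#' Root-mean-square error against the two sources
#'
#' Mean of RMSE(fused, A) and RMSE(fused, B); lower values mean the fused
#' image stays closer to its sources.
#'
#' @param fused,src_a,src_b Numeric matrices of equal extent.
#' @return Scalar (>= 0).
#' @export
metric_rmse <- function(fused, src_a, src_b) {
  .check_pair(fused, src_a); .check_pair(fused, src_b)
  r <- function(x, y) sqrt(mean((x - y)^2))
  (r(fused, src_a) + r(fused, src_b)) / 2
}

#' Spatial frequency of an image
#'
#' `SF = sqrt(RF^2 + CF^2)` where RF^2 is the mean squared horizontal first
#' difference over pixels that have a left neighbour, and CF^2 its vertical
#' counterpart.  Larger values mean richer, sharper detail.
#'
#' @param img Numeric matrix, at least 2x2.
#' @return Scalar (>= 0); 0 for constant images.
#' @export
metric_sf <- function(img) {
  h <- nrow(img); w <- ncol(img)
  if (h < 2L || w < 2L) stop("image must be at least 2x2", call. = FALSE)
  rf2 <- sum((img[, -1L, drop = FALSE] - img[, -w, drop = FALSE])^2) / (h * (w - 1L))
  cf2 <- sum((img[-1L, , drop = FALSE] - img[-h, , drop = FALSE])^2) / ((h - 1L) * w)
  sqrt(rf2 + cf2)
}

#' Standard deviation of image intensities
#'
#' Population standard deviation; a global contrast measure.
#'
#' @param img Numeric matrix.
#' @return Scalar (>= 0).
#' @export
metric_sd <- function(img) {
  sqrt(mean((img - mean(img))^2))
}

.hist_bin <- function(x, bins) {
  pmin(pmax(floor(x * bins) + 1L, 1L), bins)
}

# Mutual information between two equally-sized images, in bits, from a
# joint histogram with `bins` levels over [0, 1].
.mi2 <- function(x, y, bins) {
  ix <- .hist_bin(x, bins); iy <- .hist_bin(y, bins)
  joint <- tabulate((ix - 1L) * bins + iy, nbins = bins * bins) / length(x)
  px <- tabulate(ix, nbins = bins) / length(x)
  py <- tabulate(iy, nbins = bins) / length(y)
  jm <- matrix(joint, bins, bins)  # [iy, ix]
  prod_p <- outer(py, px)
  nz <- jm > 0
  sum(jm[nz] * log2(jm[nz] / prod_p[nz]))
}

#' Mutual information of a fused image with its sources
#'
#' `MI(F;A) + MI(F;B)`, each computed from a 256-bin joint intensity
#' histogram and reported in bits.  Higher values mean the fused image
#' carries more of the sources' information.
#'
#' @param fused,src_a,src_b Numeric matrices of equal extent, values in
#'   \[0, 1\].
#' @param bins Histogram resolution (default 256).
#' @return Scalar (>= 0).
#' @export
metric_mi <- function(fused, src_a, src_b, bins = 256L) {
  .check_pair(fused, src_a); .check_pair(fused, src_b)
  .mi2(fused, src_a, bins) + .mi2(fused, src_b, bins)
}

# Sobel gradient magnitude with replicated edges.
sobel_magnitude <- function(img) {
  p <- pad_replicate(img, 1L)
  h <- nrow(img); w <- ncol(img)
  ic <- 1L + seq_len(h); jc <- 1L + seq_len(w)
  gx <- (p[ic - 1L, jc + 1L] + 2 * p[ic, jc + 1L] + p[ic + 1L, jc + 1L]) -
        (p[ic - 1L, jc - 1L] + 2 * p[ic, jc - 1L] + p[ic + 1L, jc - 1L])
  gy <- (p[ic + 1L, jc - 1L] + 2 * p[ic + 1L, jc] + p[ic + 1L, jc + 1L]) -
        (p[ic - 1L, jc - 1L] + 2 * p[ic - 1L, jc] + p[ic - 1L, jc + 1L])
  sqrt(gx^2 + gy^2)
}

#' Gradient similarity of a fused image with its sources
#'
#' Pixel-wise gradient-magnitude similarity
#' `(2 g_F g_X + c) / (g_F^2 + g_X^2 + c)` (Sobel magnitudes, stabilizer
#' `c = 1e-4`), averaged over pixels and then over the two sources.
#' Values lie in (0, 1]; 1 means identical gradient structure.
#'
#' @inheritParams metric_rmse
#' @return Scalar in \[0, 1\].
#' @export
metric_gsm <- function(fused, src_a, src_b) {
  .check_pair(fused, src_a); .check_pair(fused, src_b)
  cc <- 1e-4
  gf <- sobel_magnitude(fused)
  one <- function(src) {
    gx <- sobel_magnitude(src)
    mean((2 * gf * gx + cc) / (gf^2 + gx^2 + cc))
  }
  (one(src_a) + one(src_b)) / 2
}

#' Average gradient of an image
#'
#' Mean of `sqrt((dx^2 + dy^2) / 2)` over interior pixels, with dx and dy
#' central differences; a contrast/texture sharpness measure.
#'
#' @param img Numeric matrix, at least 3x3.
#' @return Scalar (>= 0); 0 for constant images.
#' @export
metric_ag <- function(img) {
  h <- nrow(img); w <- ncol(img)
  if (h < 3L || w < 3L) stop("image must be at least 3x3", call. = FALSE)
  ii <- 2:(h - 1L); jj <- 2:(w - 1L)
  dx <- (img[ii, jj + 1L] - img[ii, jj - 1L]) / 2
  dy <- (img[ii + 1L, jj] - img[ii - 1L, jj]) / 2
  mean(sqrt((dx^2 + dy^2) / 2))
}

#' Edge intensity of an image
#'
#' Mean Sobel gradient magnitude over all pixels (replicated edges);
#' reflects the sharpness of edges.
#'
#' @param img Numeric matrix, at least 3x3.
#' @return Scalar (>= 0); 0 for constant images.
#' @export
metric_ei <- function(img) {
  if (nrow(img) < 3L || ncol(img) < 3L) stop("image must be at least 3x3",
                                             call. = FALSE)
  mean(sobel_magnitude(img))
}

#' Full objective quality report for a fusion triple
#'
#' Computes MI, SF, SD, RMSE, GSM, AG and EI for a fused image and its two
#' registered sources (SF/SD/AG/EI are evaluated on the fused image).
#'
#' @inheritParams metric_rmse
#' @return Object of class `metric_report`: named list of scalars.
#' @export
metric_report <- function(fused, src_a, src_b) {
  structure(list(
    mi = metric_mi(fused, src_a, src_b),
    sf = metric_sf(fused),
    sd = metric_sd(fused),
    rmse = metric_rmse(fused, src_a, src_b),
    gsm = metric_gsm(fused, src_a, src_b),
    ag = metric_ag(fused),
    ei = metric_ei(fused)
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Fusion quality metrics:\n")
  for (nm in names(x)) cat(sprintf("  %-5s %.6f\n", toupper(nm), x[[nm]]))
  invisible(x)
}
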