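#' Validate a grayscale image
#'
#' A grayscale image is an ordinary numeric matrix of intensities.  After
#' normalization all values lie in \[0, 1\]; every pipeline entry point calls
#' this validator so non-finite or out-of-range pixels are rejected early.
#'
#' @param img Numeric matrix.
#' @param arg Name used in error messages.
#' @param range Check that values lie in \[0, 1\] (default `TRUE`).  Sub-band
#'   images produced by the decomposition are signed, so internal callers
#'   disable the range check.
#' @return The validated matrix, invisibly unchanged.
#' @export
validate_gray_image <- function(img, arg = "image", range = TRUE) {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  }
  if (nrow(img) < 1L || ncol(img) < 1L) {
    stop(sprintf("`%s` must be non-empty", arg), call. = FALSE)
  }
  if (!all(is.finite(img))) {
    stop(sprintf("`%s` contains non-finite pixels", arg), call. = FALSE)
  }
  if (range && (min(img) < -1e-9 || max(img) > 1 + 1e-9)) {
    stop(sprintf("`%s` must be normalized to [0, 1]", arg), call. = FALSE)
  }
  invisible(img)
}

#' Pad an image to multiples of a block size by edge replication
#'
#' Replicating the last row/column (rather than zero-padding) avoids
#' injecting artificial high-frequency energy at block boundaries.
#'
#' @param img Numeric matrix.
#' @param block Block size (default 8).
#' @return Matrix whose dimensions are multiples of `block`, with attributes
#'   `orig_h`/`orig_w` recording the original extent.
#' @export
pad_to_block <- function(img, block = 8L) {
  h <- nrow(img); w <- ncol(img)
  ph <- ceiling(h / block) * block
  pw <- ceiling(w / block) * block
  out <- img[c(seq_len(h), rep(h, ph - h)), c(seq_len(w), rep(w, pw - w)),
             drop = FALSE]
  attr(out, "orig_h") <- h
  attr(out, "orig_w") <- w
  out
}

# Fixed BT.601 luminance weights used for every RGB -> gray conversion.
LUMA_WEIGHTS <- c(r = 0.299, g = 0.587, b = 0.114)

# Forward YCbCr-style transform (analog, full-range, chroma offset 0.5).
.ycbcr_mat <- rbind(
  y  = c(0.299, 0.587, 0.114),
  cb = 0.564 * (c(0, 0, 1) - c(0.299, 0.587, 0.114)),
  cr = 0.713 * (c(1, 0, 0) - c(0.299, 0.587, 0.114))
)
.ycbcr_inv <- solve(.ycbcr_mat)

#' Convert between RGB and a YCbCr-style luminance/chrominance space
#'
#' Full-range BT.601 analog transform; chroma channels are offset by 0.5 so
#' every channel of a valid RGB image stays in \[0, 1\] apart from rounding.
#' The two functions are exact inverses (to machine precision), which is what
#' lets color fusion pass chrominance through untouched.
#'
#' @param img `h x w x 3` numeric array.
#' @return `h x w x 3` array (Y/Cb/Cr, or R/G/B for the inverse).
#' @export
rgb_to_ycbcr <- function(img) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  d <- dim(img)
  m <- matrix(img, ncol = 3L) %*% t(.ycbcr_mat)
  m[, 2:3] <- m[, 2:3] + 0.5
  array(m, dim = d)
}

#' @rdname rgb_to_ycbcr
#' @export
ycbcr_to_rgb <- function(img) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  d <- dim(img)
  m <- matrix(img, ncol = 3L)
  m[, 2:3] <- m[, 2:3] - 0.5
  array(m %*% t(.ycbcr_inv), dim = d)
}

#' Luminance of an RGB array
#' @param img `h x w x 3` numeric array.
#' @return Numeric matrix of BT.601 luminance.
#' @export
luminance <- function(img) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  LUMA_WEIGHTS[1] * img[, , 1] + LUMA_WEIGHTS[2] * img[, , 2] +
    LUMA_WEIGHTS[3] * img[, , 3]
}
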