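#' Read an image file as a normalized intensity raster
#'
#' Supports PNG and TIFF (8/16-bit; values are normalized to \[0, 1\] by
#' the readers) and, when the RNifti package is installed, single-slice
#' NIfTI (normalized by the volume maximum).  RGB inputs are converted to
#' grayscale with the fixed BT.601 luminance weights unless
#' `policy = "rgb"` keeps the channels.
#'
#' @param path File path; format is taken from the extension.
#' @param policy `"gray"` (default) or `"rgb"`.
#' @return Numeric matrix in \[0, 1\], or an `h x w x 3` array under the
#'   rgb policy.
#' @export
read_image <- function(path, policy = c("gray", "rgb")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) {
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    nii = ,
    gz = {
      if (!requireNamespace("RNifti", quietly = TRUE)) {
        stop("reading NIfTI requires the RNifti package", call. = FALSE)
      }
      v <- RNifti::readNifti(path)
      a <- as.array(v)
      if (length(dim(a)) > 2L) a <- a[, , 1L]
      mx <- max(a)
      if (mx > 0) a / mx else a * 0
    },
    stop(sprintf("unsupported image format '.%s' (%s)", ext, path),
         call. = FALSE)
  )
  if (length(dim(img)) == 3L) {
    if (dim(img)[3L] == 4L) img <- img[, , 1:3]  # drop alpha
    if (dim(img)[3L] == 2L) img <- img[, , 1L]   # gray+alpha
  }
  if (policy == "rgb") {
    if (length(dim(img)) == 2L) {
      img <- array(rep(img, 3L), c(dim(img), 3L))
    }
    return(img)
  }
  if (length(dim(img)) == 3L) img <- luminance(img)
  as.matrix(img)
}

#' Write an intensity raster to an image file
#'
#' Quantizes values in \[0, 1\] at the requested bit depth (round half
#' up) and writes PNG (8-bit) or TIFF (8- or 16-bit); byte-identical
#' output for identical input.
#'
#' @param img Numeric matrix or `h x w x 3` array with values in \[0, 1\].
#' @param path Output path (`.png`, `.tif`/`.tiff`).
#' @param bit_depth 8 or 16 (PNG supports 8 only; default 16 for TIFF,
#'   8 for PNG).
#' @return The path, invisibly.
#' @export
write_image <- function(img, path, bit_depth = NULL) {
  if (min(img) < 0 || max(img) > 1) {
    stop("image values must lie in [0, 1]; clip before writing",
         call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  if (is.null(bit_depth)) bit_depth <- if (ext == "png") 8L else 16L
  levels <- 2^bit_depth - 1
  q <- floor(img * levels + 0.5) / levels
  switch(ext,
    png = {
      if (bit_depth != 8L) stop("PNG output is 8-bit", call. = FALSE)
      png::writePNG(q, target = path)
    },
    tif = ,
    tiff = tiff::writeTIFF(q, path, bits.per.sample = as.integer(bit_depth),
                           compression = "none"),
    stop(sprintf("unsupported output format '.%s'", ext), call. = FALSE)
  )
  invisible(path)
}

#' Save a convolutional dictionary to a JSON archive
#'
#' Plain-text, versioned layout holding the filter arrays and metadata
#' (K, s, scale tag, seed); [load_dictionary()] restores it to double
#' precision.
#'
#' @param dict A `conv_dictionary`.
#' @param path Output path (conventionally `.json`).
#' @return The path, invisibly.
#' @export
save_dictionary <- function(dict, path) {
  stopifnot(inherits(dict, "conv_dictionary"))
  payload <- list(
    format = "csrfuse-dictionary",
    version = 1L,
    K = dict$K, s = dict$s,
    scale_tag = dict$scale_tag, seed = dict$seed,
    filters = lapply(dict$filters, function(f) unname(as.vector(f)))
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_dictionary
#' @export
load_dictionary <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "csrfuse-dictionary")) {
    stop("not a csrfuse dictionary archive", call. = FALSE)
  }
  f <- p$filters
  filters <- if (is.matrix(f)) {
    lapply(seq_len(nrow(f)), function(k) matrix(f[k, ], p$s, p$s))
  } else {
    lapply(f, function(v) matrix(unlist(v), p$s, p$s))
  }
  structure(list(filters = filters, K = as.integer(p$K), s = as.integer(p$s),
                 scale_tag = p$scale_tag, seed = p$seed),
            class = "conv_dictionary")
}
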