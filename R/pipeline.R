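#' Fusion pipeline configuration
#'
#' Collects every tunable of the fusion pipeline.  `mode = "csr"` is the
#' full method (multi-scale dictionaries + sparse-domain fusion);
#' `mode = "dct"` is the fast transform-domain fallback (uniform low-band
#' averaging plus maximum regional-deviation selection in the high bands).
#'
#' @param mode `"csr"` or `"dct"`.
#' @param levels Decomposition scales (1..3, default 3).
#' @param window_radius Salience window radius in pixels (default 1, a
#'   3x3 window).
#' @param K Filters per sub-dictionary (default 32).
#' @param s Filter size (fixed at 8 to match the 8x8 block transform).
#' @param lambda Sparsity weight (default 0.01).
#' @param lambda1 TV weight for the coding stage (default 1e-3).
#' @param max_iters Dictionary-learning alternation budget (default 30).
#' @param csc_iters Sparse-coding ADMM budget per sub-band (default 100).
#' @param tol Relative objective-change stopping threshold for dictionary
#'   learning (default 0.03).
#' @param csc_tol Stopping threshold for the coding stage (default 1e-4).
#' @param seed Seed for dictionary initialization.
#' @return Object of class `fusion_config`.
#' @export
fusion_config <- function(mode = c("csr", "dct"), levels = 3L,
                          window_radius = 1L, K = 32L, s = 8L,
                          lambda = 0.01, lambda1 = 1e-3,
                          max_iters = 30L, csc_iters = 100L,
                          tol = 0.03, csc_tol = 1e-4, seed = 1L) {
  mode <- match.arg(mode)
  if (s != 8L) stop("filter size is fixed at 8 (the block size)", call. = FALSE)
  stopifnot(levels >= 1L, levels <= 3L, window_radius >= 1L, K >= 1L,
            lambda >= 0, lambda1 >= 0, max_iters >= 1L, csc_iters >= 1L,
            tol >= 0, csc_tol >= 0)
  structure(list(mode = mode, levels = as.integer(levels),
                 window_radius = as.integer(window_radius),
                 K = as.integer(K), s = 8L, lambda = lambda,
                 lambda1 = lambda1, max_iters = as.integer(max_iters),
                 csc_iters = as.integer(csc_iters), tol = tol,
                 csc_tol = csc_tol, seed = seed),
            class = "fusion_config")
}

#' Fuse a registered pair of grayscale images
#'
#' The full pipeline: both sources are decomposed into sub-bands; in
#' `"csr"` mode per-scale convolutional dictionaries are learned from the
#' sub-images of both sources, every sub-band is sparse-coded with TV
#' regularization, the low band is fused by region-energy x activity
#' salience and each high band by spatial-frequency x activity salience
#' (winner-take-all on whole coefficient vectors), and the fused sub-bands
#' are reconstructed and summed; in `"dct"` mode the low sub-images are
#' averaged and the high sub-images selected by maximum regional-deviation
#' weight.  The output is clipped to \[0, 1\].
#'
#' @param img_a,img_b Numeric matrices in \[0, 1\], equal extents,
#'   registered.
#' @param config A [fusion_config()].
#' @return Object of class `csr_fusion`: list with `fused` (matrix in
#'   \[0, 1\]), `mode`, `clip_fraction`, `config`, and (in csr mode)
#'   `dictionaries`, `low` and `highs` diagnostics (saliences and winner
#'   maps per band).
#' @export
fuse_pair <- function(img_a, img_b, config = fusion_config()) {
  validate_gray_image(img_a, "img_a")
  validate_gray_image(img_b, "img_b")
  if (!identical(dim(img_a), dim(img_b))) {
    stop("source extents differ; images must be registered", call. = FALSE)
  }
  stopifnot(inherits(config, "fusion_config"))
  pyr_a <- dct_decompose(img_a, config$levels)
  pyr_b <- dct_decompose(img_b, config$levels)
  if (config$mode == "dct") {
    fused_low <- dct_fuse_low(list(pyr_a$low, pyr_b$low))
    highs <- lapply(names(pyr_a$highs), function(nm) {
      dct_fuse_high(list(pyr_a$highs[[nm]], pyr_b$highs[[nm]]),
                    radius = config$window_radius)
    })
    raw <- Reduce(`+`, highs, fused_low)
    fused <- clip01(raw)
    return(structure(list(
      fused = fused, mode = "dct",
      clip_fraction = mean(raw < 0 | raw > 1),
      config = config
    ), class = "csr_fusion"))
  }
  dicts <- learn_multiscale(pyr_a, pyr_b, K = config$K, s = config$s,
                            lambda = config$lambda,
                            max_iters = config$max_iters, tol = config$tol,
                            seed = config$seed)
  # The sparsity weight is scaled per band pair by the bands' RMS relative
  # to the sources' RMS: sub-band amplitudes span orders of magnitude, and
  # a fixed lambda would crush the weak high bands (large relative
  # shrinkage) while under-regularizing the low band.  The scaling is
  # symmetric in the two sources so their activity maps stay comparable.
  rms <- function(x) sqrt(mean(x^2))
  ref <- max(rms(img_a), rms(img_b))
  encode <- function(img, dict, lam) {
    suppressWarnings(csc_encode(img, dict, lambda = lam,
                                lambda1 = config$lambda1,
                                max_iters = config$csc_iters,
                                tol = config$csc_tol))
  }
  band_lambda <- function(ba, bb) {
    config$lambda * min(1, max(rms(ba), rms(bb)) / max(ref, 1e-12))
  }
  # the low band is coded as-is: pixel-wise selection mixes the two codes,
  # which is only harmless where coefficients are near zero, so the codes
  # must keep the natural zero baseline of the intensity scale
  lam_low <- band_lambda(pyr_a$low, pyr_b$low)
  maps_low_a <- encode(pyr_a$low, dicts$d_low, lam_low)
  maps_low_b <- encode(pyr_b$low, dicts$d_low, lam_low)
  # scalar debias: L1 shrinkage pulls the reconstruction down by a small
  # DC, which would darken the background; add back the mean residual
  delta <- (mean(pyr_a$low - csc_reconstruct(maps_low_a, dicts$d_low)) +
            mean(pyr_b$low - csc_reconstruct(maps_low_b, dicts$d_low))) / 2
  low <- fuse_low_csr(maps_low_a, maps_low_b,
                      pyr_a$low, pyr_b$low, dicts$d_low,
                      radius = config$window_radius, offset = delta)
  highs <- list()
  for (l in seq_len(config$levels)) {
    dict_l <- dicts$d_scales[[l]]
    for (nm in grep(sprintf("^s%d_", l), names(pyr_a$highs), value = TRUE)) {
      lam_b <- band_lambda(pyr_a$highs[[nm]], pyr_b$highs[[nm]])
      highs[[nm]] <- fuse_high_csr(encode(pyr_a$highs[[nm]], dict_l, lam_b),
                                   encode(pyr_b$highs[[nm]], dict_l, lam_b),
                                   pyr_a$highs[[nm]], pyr_b$highs[[nm]],
                                   dict_l, radius = config$window_radius)
    }
  }
  raw <- Reduce(`+`, lapply(highs, `[[`, "image"), low$image)
  structure(list(
    fused = clip01(raw), mode = "csr",
    clip_fraction = mean(raw < 0 | raw > 1),
    config = config, dictionaries = dicts,
    low = low[c("salience_a", "salience_b", "winner")],
    highs = lapply(highs, `[`, c("salience_a", "salience_b", "winner"))
  ), class = "csr_fusion")
}

#' @export
print.csr_fusion <- function(x, ...) {
  cat(sprintf("<csr_fusion> %dx%d, mode=%s, clipped %.3f%% of pixels\n",
              nrow(x$fused), ncol(x$fused), x$mode, 100 * x$clip_fraction))
  invisible(x)
}

#' Fuse a structural grayscale image with a pseudo-colored functional image
#'
#' The functional RGB image is converted to a luminance/chrominance space;
#' its luminance is fused with the structural image by [fuse_pair()]; the
#' original chrominance is recombined and transformed back to RGB.  The
#' hue of the functional channel is preserved exactly (up to final
#' clipping).
#'
#' @param structural Numeric matrix in \[0, 1\].
#' @param functional_rgb `h x w x 3` numeric array in \[0, 1\].
#' @param config A [fusion_config()].
#' @return List of class `csr_fusion_color`: `fused_rgb` (clipped),
#'   `fusion` (the grayscale `csr_fusion` of the luminance).
#' @export
fuse_color <- function(structural, functional_rgb, config = fusion_config()) {
  if (length(dim(functional_rgb)) != 3L || dim(functional_rgb)[3L] != 3L) {
    stop("`functional_rgb` must be a 3-channel array", call. = FALSE)
  }
  if (!identical(dim(structural), dim(functional_rgb)[1:2])) {
    stop("extents differ; images must be registered", call. = FALSE)
  }
  ycc <- rgb_to_ycbcr(functional_rgb)
  fz <- fuse_pair(structural, clip01(ycc[, , 1L]), config)
  out <- ycc
  out[, , 1L] <- fz$fused
  rgb <- ycbcr_to_rgb(out)
  structure(list(fused_rgb = clip01(rgb), fusion = fz),
            class = "csr_fusion_color")
}

#' Audit salience selection against phantom truth masks
#'
#' For a csr-mode fusion of a [make_pair()] phantom, measures which source
#' won each pixel: over the structural-exclusive mask, the fraction of
#' pixels whose aggregate high-band salience favours the structural
#' source; over the functional-exclusive mask, the fraction whose low-band
#' salience favours the functional source.
#'
#' @param fusion A `csr_fusion` from [fuse_pair()] in csr mode, called as
#'   `fuse_pair(structural, functional, ...)`.
#' @param masks The `masks` element of a `phantom_pair`.
#' @return List: `structural_accuracy`, `functional_accuracy` (fractions
#'   in \[0, 1\]).
#' @export
audit_selection <- function(fusion, masks) {
  stopifnot(inherits(fusion, "csr_fusion"), fusion$mode == "csr")
  agg_a <- Reduce(`+`, lapply(fusion$highs, `[[`, "salience_a"))
  agg_b <- Reduce(`+`, lapply(fusion$highs, `[[`, "salience_b"))
  list(
    structural_accuracy = mean((agg_a >= agg_b)[masks$structural]),
    functional_accuracy = mean((fusion$low$salience_b >
                                  fusion$low$salience_a)[masks$functional])
  )
}
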