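#' Specification of a synthetic multimodal phantom pair
#'
#' Collects the parameters of the seeded phantom generator: a structural
#' channel with sharp contours and fine texture (CT/MRI-like) and a
#' functional channel with smooth high-intensity blobs (PET/SPECT-like),
#' registered and with complementary detail.
#'
#' @param size Image side length in pixels; must be a multiple of 8
#'   (default 256).
#' @param seed RNG seed; the whole pair is deterministic given the spec.
#' @param n_blobs Number of functional uptake blobs (default 4).
#' @param blob_sigma Gaussian blob width in pixels (default 10).
#' @param texture_freq Texture frequency in cycles per image (default 24).
#' @param edge_count Number of sharp polygonal edge structures (default 4).
#' @param noise_sigma Additive Gaussian noise level (default 0.01).
#' @param complementary_split Fraction of the structural detail suppressed
#'   in the functional channel, in \[0, 1\] (default 0.8).
#' @return Object of class `phantom_spec` (a validated list).
#' @export
phantom_spec <- function(size = 256L, seed = 1L, n_blobs = 4L,
                         blob_sigma = 10, texture_freq = 24,
                         edge_count = 4L, noise_sigma = 0.01,
                         complementary_split = 0.8) {
  if (size %% 8L != 0L || size < 32L) {
    stop("`size` must be a multiple of 8 (and >= 32)", call. = FALSE)
  }
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)
  if (complementary_split < 0 || complementary_split > 1) {
    stop("`complementary_split` must lie in [0, 1]", call. = FALSE)
  }
  structure(list(size = as.integer(size), seed = seed,
                 n_blobs = as.integer(n_blobs), blob_sigma = blob_sigma,
                 texture_freq = texture_freq, edge_count = as.integer(edge_count),
                 noise_sigma = noise_sigma,
                 complementary_split = complementary_split),
            class = "phantom_spec")
}

# Normalized coordinate grids in [-1, 1].
.grids <- function(n) {
  g <- seq(-1, 1, length.out = n)
  list(x = matrix(g, n, n, byrow = TRUE), y = matrix(g, n, n))
}

# Elliptical masks shared by both channels: an outer "skull" ring and the
# tissue region it encloses.
.contours <- function(n) {
  g <- .grids(n)
  r2_outer <- (g$x / 0.85)^2 + (g$y / 0.92)^2
  r2_inner <- (g$x / 0.76)^2 + (g$y / 0.83)^2
  list(skull = r2_outer <= 1 & r2_inner > 1,
       tissue = r2_inner <= 1,
       x = g$x, y = g$y)
}

# Deterministic noiseless structural content: tissue base, ventricles,
# oriented sinusoid texture (left hemisphere) and sharp random edges.
.structural_content <- function(spec) {
  n <- spec$size
  ct <- .contours(n)
  img <- matrix(0.02, n, n)
  img[ct$tissue] <- 0.45
  img[ct$skull] <- 0.9
  # dark ventricles
  v1 <- ((ct$x + 0.12) / 0.1)^2 + (ct$y / 0.3)^2 <= 1
  v2 <- ((ct$x - 0.12) / 0.1)^2 + (ct$y / 0.3)^2 <= 1
  img[(v1 | v2) & ct$tissue] <- 0.12
  texture_zone <- ct$tissue & ct$x < -0.02 & !(v1 | v2)
  tex <- with_local_seed(spec$seed, {
    thetas <- stats::runif(3, 0, pi)
    phases <- stats::runif(3, 0, 2 * pi)
    t <- matrix(0, n, n)
    for (i in 1:3) {
      t <- t + sin(pi * spec$texture_freq *
                     (ct$x * cos(thetas[i]) + ct$y * sin(thetas[i])) + phases[i])
    }
    t / 3
  })
  img[texture_zone] <- img[texture_zone] + 0.16 * tex[texture_zone]
  # sharp polygonal edges: random half-plane intensity steps inside the
  # right-hemisphere tissue (kept off the texture zone)
  edge_zone <- ct$tissue & ct$x >= -0.02
  steps <- with_local_seed(spec$seed + 1L, {
    out <- matrix(0, n, n)
    for (e in seq_len(spec$edge_count)) {
      th <- stats::runif(1, 0, 2 * pi)
      off <- stats::runif(1, -0.4, 0.4)
      side <- ct$x * cos(th) + ct$y * sin(th) > off
      amp <- stats::runif(1, 0.08, 0.18) * sign(stats::runif(1, -1, 1))
      out[side] <- out[side] + amp
    }
    out
  })
  img[edge_zone] <- img[edge_zone] + steps[edge_zone]
  list(img = img, contours = ct,
       texture_zone = texture_zone, edge_zone = edge_zone)
}

#' Synthesize the structural (CT/MRI-like) phantom channel
#'
#' Nested elliptical skull/tissue contours, dark ventricles, oriented
#' sinusoidal texture in the left hemisphere, sharp polygonal intensity
#' steps in the right hemisphere, plus Gaussian noise; clipped to \[0, 1\]
#' and deterministic per seed.
#'
#' @param spec A [phantom_spec()].
#' @return Numeric matrix in \[0, 1\].
#' @export
make_structural <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  sc <- .structural_content(spec)
  img <- sc$img
  if (spec$noise_sigma > 0) {
    img <- img + with_local_seed(spec$seed + 2L, {
      matrix(stats::rnorm(spec$size^2, 0, spec$noise_sigma),
             spec$size, spec$size)
    })
  }
  clip01(img)
}

# Blob centers are drawn inside the right-hemisphere tissue.
.blob_centers <- function(spec, ct) {
  if (spec$n_blobs == 0L) return(matrix(numeric(0), ncol = 2L))
  with_local_seed(spec$seed + 3L, {
    ok <- which(ct$tissue & ct$x > 0.08, arr.ind = TRUE)
    ok <- ok[order(ok[, 1L], ok[, 2L]), , drop = FALSE]
    ok[sample(nrow(ok), spec$n_blobs), , drop = FALSE]
  })
}

# Noiseless blob intensity field (max over blobs) and the centers/peaks
# that generate it.
.blob_field <- function(spec, ct) {
  n <- spec$size
  centers <- .blob_centers(spec, ct)
  blobs <- matrix(0, n, n)
  peaks <- numeric(0)
  if (nrow(centers) > 0L) {
    idx_r <- matrix(seq_len(n), n, n)
    idx_c <- matrix(seq_len(n), n, n, byrow = TRUE)
    peaks <- with_local_seed(spec$seed + 4L,
                             stats::runif(nrow(centers), 0.75, 0.95))
    for (b in seq_len(nrow(centers))) {
      d2 <- (idx_r - centers[b, 1L])^2 + (idx_c - centers[b, 2L])^2
      blobs <- pmax(blobs, peaks[b] * exp(-d2 / (2 * spec$blob_sigma^2)))
    }
  }
  list(blobs = blobs, centers = centers, peaks = peaks)
}

# Fixed warm pseudo-colormap with exact BT.601 luminance: chroma is a
# smooth function of intensity, scaled so no channel leaves [0, 1].
.pseudo_color <- function(gray) {
  q <- 0.35 * gray * (1 - gray)
  ycc <- array(0, c(nrow(gray), ncol(gray), 3L))
  ycc[, , 1L] <- gray
  ycc[, , 2L] <- 0.5 - q   # Cb below neutral -> warm
  ycc[, , 3L] <- 0.5 + q   # Cr above neutral -> red
  ycbcr_to_rgb(ycc)
}

#' Synthesize the functional (PET/SPECT-like) phantom channel
#'
#' A sum of `n_blobs` Gaussian uptake blobs masked to the tissue contour,
#' a faint smooth background, and the structural content attenuated by
#' `complementary_split`; no fine texture.  Also returns a pseudo-colored
#' variant whose BT.601 luminance equals the grayscale channel exactly.
#'
#' @param spec A [phantom_spec()].
#' @return List: `gray` (matrix in \[0, 1\]), `color` (`size x size x 3`
#'   array), `centers` (blob center pixel coordinates, rows = (row, col)).
#' @export
make_functional <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$size
  sc <- .structural_content(spec)
  ct <- sc$contours
  bf <- .blob_field(spec, ct)
  blobs <- bf$blobs
  centers <- bf$centers
  base <- matrix(0.02, n, n)
  base[ct$tissue] <- 0.1
  residual_structure <- (1 - spec$complementary_split) * (sc$img - base)
  gray <- base + residual_structure
  gray[ct$tissue] <- pmax(gray[ct$tissue], blobs[ct$tissue])
  if (spec$noise_sigma > 0) {
    gray <- gray + with_local_seed(spec$seed + 5L, {
      matrix(stats::rnorm(n^2, 0, spec$noise_sigma), n, n)
    })
  }
  gray <- clip01(gray)
  list(gray = gray, color = .pseudo_color(gray), centers = centers)
}

#' Generate a registered multimodal phantom pair with truth masks
#'
#' Builds the structural and functional channels from one spec, together
#' with masks naming which tissue pixels carry detail exclusive to each
#' source: the textured left hemisphere (suppressed in the functional
#' channel when `complementary_split > 0`) belongs to the structural
#' source; the functional mask holds the pixels where the noiseless blob
#' field exceeds the noiseless structural content, i.e. where the
#' functional source's exclusive signal dominates (blobs are absent from
#' the structural channel).  The masks are disjoint subsets of the tissue
#' region and serve as ground truth for selection-rule audits.
#'
#' @param spec A [phantom_spec()].
#' @return List of class `phantom_pair`: `structural`, `functional`
#'   (grayscale), `functional_color`, `masks` (list `structural`,
#'   `functional` of logical matrices), `spec`.
#' @export
make_pair <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  sc <- .structural_content(spec)
  func <- make_functional(spec)
  struct <- make_structural(spec)
  n <- spec$size
  bf <- .blob_field(spec, sc$contours)
  blob_dominant <- bf$blobs > sc$img
  if (spec$complementary_split > 0) {
    mask_struct <- sc$texture_zone & !blob_dominant
    mask_func <- blob_dominant & sc$contours$tissue & !sc$texture_zone
  } else {
    mask_struct <- matrix(FALSE, n, n)
    mask_func <- matrix(FALSE, n, n)
  }
  structure(list(structural = struct, functional = func$gray,
                 functional_color = func$color,
                 masks = list(structural = mask_struct,
                              functional = mask_func),
                 spec = spec),
            class = "phantom_pair")
}
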