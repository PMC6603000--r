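# Shared deterministic image-processing primitives. All convolution and
# morphology filters operate plane-by-plane (square 2D kernels); connected
# components and volume statistics are 3D unless stated otherwise.

#' Square truncated Gaussian kernel
#'
#' "Size and standard deviation s pixel and sigma pixel" means a square s x s
#' kernel sampled from a 2D Gaussian with that standard deviation, normalized
#' to unit sum. Even sizes are rounded up to the next odd integer so the
#' kernel has a well-defined center.
#'
#' @param size kernel side length in pixels (>= 1).
#' @param sd Gaussian standard deviation in pixels (> 0).
#' @return Unit-sum numeric matrix.
#' @export
gaussian_kernel <- function(size, sd) {
  if (sd <= 0) stop("Gaussian sd must be > 0")
  if (size < 1) stop("kernel size must be >= 1")
  size <- as.integer(size)
  if (size %% 2L == 0L) size <- size + 1L
  r <- (size - 1L) / 2L
  x <- -r:r
  g <- exp(-(outer(x^2, x^2, "+")) / (2 * sd^2))
  g / sum(g)
}

#' Laplacian-of-Gaussian kernel
#'
#' Sampled LoG adjusted to zero sum (the usual fspecial-style construction):
#' negative at the center, so bright blobs give strongly negative responses.
#'
#' @inheritParams gaussian_kernel
#' @return Zero-sum numeric matrix.
#' @export
log_kernel <- function(size, sd) {
  if (sd <= 0) stop("Gaussian sd must be > 0")
  if (size < 3) stop("LoG kernel size must be >= 3")
  size <- as.integer(size)
  if (size %% 2L == 0L) size <- size + 1L
  r <- (size - 1L) / 2L
  x <- -r:r
  r2 <- outer(x^2, x^2, "+")
  g <- exp(-r2 / (2 * sd^2))
  g <- g / sum(g)
  h <- g * (r2 - 2 * sd^2) / sd^4
  h - sum(h) / length(h)
}

# Reflective padding of a matrix by p pixels on every side (whole-sample
# symmetry, repeating periodically when the pad exceeds the image).
pad_reflect <- function(m, p) {
  ref <- function(n) {
    if (n == 1L) return(rep(1L, n + 2L * p))
    base <- c(seq_len(n), (n - 1L):2L)
    base[((seq_len(n + 2L * p) - 1L - p) %% length(base)) + 1L]
  }
  m[ref(nrow(m)), ref(ncol(m))]
}

# 2D correlation with a symmetric odd kernel under reflective borders.
conv_plane <- function(m, kernel) {
  p <- (max(dim(kernel)) - 1L) %/% 2L
  if (p == 0L) return(m * kernel[1, 1])
  mp <- pad_reflect(m, p)
  f <- EBImage::filter2(mp, kernel, boundary = "circular")
  f[(p + 1L):(p + nrow(m)), (p + 1L):(p + ncol(m))]
}

#' Plane-wise Gaussian convolution
#'
#' @param image matrix or 3D array (graytone volume).
#' @param size,sd kernel specification, see [gaussian_kernel()].
#' @return Filtered image of the same shape.
#' @export
gaussian_convolve <- function(image, size, sd) {
  k <- gaussian_kernel(size, sd)
  .apply_planes(image, function(p) conv_plane(p, k))
}

#' Difference of Gaussians (spatial band-pass)
#'
#' Foreground blur minus background blur; requires `fg_sd < bg_sd` so the
#' band is oriented to highlight structures near the foreground scale.
#'
#' @param image matrix or 3D array.
#' @param fg,bg numeric length-2 vectors `c(size, sd)`.
#' @return Signed filtered image of the same shape.
#' @export
difference_of_gaussians <- function(image, fg, bg) {
  if (fg[2] >= bg[2]) stop("foreground sd must be smaller than background sd")
  gaussian_convolve(image, fg[1], fg[2]) - gaussian_convolve(image, bg[1], bg[2])
}

#' Plane-wise Laplacian-of-Gaussian filter
#'
#' @inheritParams gaussian_convolve
#' @export
laplacian_of_gaussian <- function(image, size = 20, sd = 1) {
  k <- log_kernel(size, sd)
  .apply_planes(image, function(p) conv_plane(p, k))
}

#' Grayscale top-hat filter (plane-wise, disc structuring element)
#'
#' Image minus its grayscale opening; extracts bright objects smaller than
#' the structuring element. Output is non-negative.
#'
#' @param image matrix or 3D array.
#' @param radius disc radius in pixels (>= 1).
#' @export
tophat_gray <- function(image, radius) {
  if (radius < 1) stop("structuring element radius must be >= 1")
  out <- image - open_gray_disc(image, radius)
  out[out < 0] <- 0
  out
}

#' Butterworth high-pass filter of one plane (Fourier domain)
#'
#' Transfer function `H(D) = 1 / (1 + (D0/D)^(2n))` over the centered
#' frequency radius D (pixels of the centered FFT grid); the DC bin gets
#' H = 0 exactly, and the gain at `D = cutoff` is exactly 0.5.
#'
#' @param plane numeric matrix.
#' @param cutoff cutoff radius D0 (> 0).
#' @param order filter order n (integer >= 1).
#' @export
butterworth_highpass_plane <- function(plane, cutoff = 10, order = 5) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (order < 1) stop("order must be >= 1")
  stopifnot(is.matrix(plane), all(is.finite(plane)))
  n1 <- nrow(plane); n2 <- ncol(plane)
  u <- ((seq_len(n1) - 1 + floor(n1 / 2)) %% n1) - floor(n1 / 2)
  v <- ((seq_len(n2) - 1 + floor(n2 / 2)) %% n2) - floor(n2 / 2)
  D <- sqrt(outer(u^2, v^2, "+"))
  H <- 1 / (1 + (cutoff / D)^(2 * order))
  H[D == 0] <- 0
  Re(stats::fft(stats::fft(plane) * H, inverse = TRUE)) / (n1 * n2)
}

# Plane-wise application over a volume.
butterworth_highpass <- function(image, cutoff = 10, order = 5) {
  .apply_planes(image, function(p) butterworth_highpass_plane(p, cutoff, order))
}

#' Green:red ratio image
#'
#' Both raw channels are blurred with a Gaussian (size 5, sd 2); the ratio is
#' the blurred green divided by the blurred red, with the denominator clamped
#' at `eps` graytone units so empty background cannot blow up.
#'
#' @param green_raw,red_raw raw channel volumes of identical shape.
#' @param blur length-2 `c(size, sd)` for the pre-division blur.
#' @param eps denominator clamp in graytone units.
#' @return Ratio volume (dimensionless), finite everywhere.
#' @export
ratio_image <- function(green_raw, red_raw, blur = c(5, 2), eps = 1) {
  if (!identical(dim(as_volume(green_raw)), dim(as_volume(red_raw)))) {
    stop("green and red volumes must share a shape")
  }
  g <- gaussian_convolve(green_raw, blur[1], blur[2])
  r <- gaussian_convolve(red_raw, blur[1], blur[2])
  g / pmax(r, eps)
}

#' Image complement
#'
#' `max(image) - image` (reference maximum defaults to the per-field maximum
#' of the input, making the complement well defined for floating-point ratio
#' images). Voxel ordering is reversed: former maxima become zeros.
#'
#' @param image matrix or 3D array.
#' @param ref_max reference maximum; default `max(image)`.
#' @export
complement_image <- function(image, ref_max = max(image)) {
  ref_max - image
}

#' Threshold an image and size-filter the resulting components
#'
#' Uniform wrapper for the pipeline's "threshold (>v), then remove components
#' outside a size window" steps. Bounds are inclusive; components touching
#' the image border are retained at this stage.
#'
#' @param image matrix or 3D array.
#' @param comparator one of `">"`, `"<"`, `">="`, `"<="`.
#' @param value graytone threshold.
#' @param min_size,max_size inclusive component-size window in voxels.
#' @param connectivity passed to [label_components()].
#' @return Binary mask of the same shape.
#' @export
threshold_components <- function(image, comparator, value, min_size = 0,
                                 max_size = Inf,
                                 connectivity = if (is.matrix(image)) 8L else 26L) {
  cmp <- switch(comparator,
    ">"  = image > value,
    "<"  = image < value,
    ">=" = image >= value,
    "<=" = image <= value,
    stop("comparator must be one of >, <, >=, <=")
  )
  if (min_size <= 1 && is.infinite(max_size)) return(cmp)
  filter_components_by_size(cmp, min_size, max_size, connectivity)
}

#' Binary morphological reconstruction
#'
#' Returns the union of connected components of `limit` that intersect
#' `seed` (the seed is intersected with the limit first). Idempotent and
#' monotone in the seed.
#'
#' @param seed,limit binary masks of identical shape.
#' @param connectivity passed to [label_components()].
#' @export
morphological_reconstruct <- function(seed, limit,
                                      connectivity = if (is.matrix(limit)) 8L else 26L) {
  if (!identical(dim(as_volume(seed)), dim(as_volume(limit)))) {
    stop("seed and limit must share a shape")
  }
  seed <- (seed != 0) & (limit != 0)
  lab <- label_components(limit != 0, connectivity)
  keep <- labels_touching(lab, seed)
  array(lab %in% keep, dim = dim(lab))
}
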