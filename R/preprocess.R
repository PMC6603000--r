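# Flatfield correction, PSF modelling and iterative (Richardson-Lucy)
# deconvolution producing the deconvolved volumes all later stages consume.

#' Point-spread-function model parameters
#'
#' Scalar Gaussian-approximation PSF for a confocal spinning-disk system.
#' Lateral FWHM is `0.51 * lambda / NA`; axial FWHM is `1.77 * n * lambda /
#' NA^2` (standard scalar widefield approximations). The PSF is only the
#' initial estimate for deconvolution, and downstream masks are
#' threshold-based, so this parametric model replaces a full vectorial
#' diffraction computation.
#'
#' @param wavelength_em emission wavelength in nm.
#' @param numerical_aperture objective NA.
#' @param pixel_pitch,z_step sampling in micrometers.
#' @param refractive_index immersion refractive index (water: 1.33).
#' @param support optional `c(z, y, x)` voxel extent (odd numbers); derived
#'   from the Gaussian widths when `NULL`.
#' @return An object of class `psf_model`.
#' @export
psf_model <- function(wavelength_em = 520, numerical_aperture = 1.2,
                      pixel_pitch = PIXEL_PITCH_UM, z_step = Z_STEP_UM,
                      refractive_index = 1.33, support = NULL) {
  if (numerical_aperture <= 0 || wavelength_em <= 0 || pixel_pitch <= 0 || z_step <= 0) {
    stop("optical parameters must be positive")
  }
  if (numerical_aperture > refractive_index) {
    stop("numerical aperture cannot exceed the immersion refractive index")
  }
  structure(list(
    wavelength_em = wavelength_em, numerical_aperture = numerical_aperture,
    pixel_pitch = pixel_pitch, z_step = z_step,
    refractive_index = refractive_index, support = support
  ), class = "psf_model")
}

#' Generate a PSF volume from a model
#'
#' @param model a [psf_model()].
#' @return Non-negative, unit-sum 3D array (y, x, z), radially symmetric in
#'   plane and symmetric in z.
#' @export
generate_psf <- function(model) {
  stopifnot(inherits(model, "psf_model"))
  lambda_um <- model$wavelength_em / 1000
  fwhm_lat <- 0.51 * lambda_um / model$numerical_aperture
  fwhm_ax <- 1.77 * model$refractive_index * lambda_um / model$numerical_aperture^2
  sd_lat_px <- (fwhm_lat / 2.3548) / model$pixel_pitch
  sd_ax_px <- (fwhm_ax / 2.3548) / model$z_step
  sup <- model$support
  if (is.null(sup)) {
    rl <- max(2L, ceiling(3 * sd_lat_px))
    rz <- max(1L, ceiling(3 * sd_ax_px))
    sup <- c(2L * rz + 1L, 2L * rl + 1L, 2L * rl + 1L)
  }
  sup <- as.integer(sup)
  if (any(sup %% 2L == 0L)) stop("PSF support must be odd in every dimension")
  rz <- (sup[1] - 1L) / 2L; ry <- (sup[2] - 1L) / 2L; rx <- (sup[3] - 1L) / 2L
  gy <- exp(-(-ry:ry)^2 / (2 * sd_lat_px^2))
  gx <- exp(-(-rx:rx)^2 / (2 * sd_lat_px^2))
  gz <- exp(-(-rz:rz)^2 / (2 * sd_ax_px^2))
  psf <- outer(outer(gy, gx), gz)
  psf / sum(psf)
}

#' Flatfield correction
#'
#' Divides every plane by a smoothed reference illumination image and
#' restores the reference mean, removing vignetting while preserving the
#' field mean for a uniform reference. The reference is Gaussian-smoothed
#' (sd `smooth_sd` px) to suppress reference shot noise.
#'
#' @param raw raw volume (or matrix).
#' @param ref 2D reference plane from an adjustment plate.
#' @param smooth_sd smoothing sd in pixels; 0 disables smoothing.
#' @export
flatfield_correct <- function(raw, ref, smooth_sd = 20) {
  stopifnot(is.matrix(ref))
  v <- as_volume(raw)
  if (!identical(dim(v)[1:2], dim(ref))) stop("reference shape must match the field planes")
  if (smooth_sd > 0) {
    ref <- conv_plane(ref, gaussian_kernel(4 * ceiling(smooth_sd) + 1, smooth_sd))
  }
  if (any(ref <= 0)) stop("flatfield reference must be strictly positive after smoothing")
  gain <- mean(ref) / ref
  out <- v * as.vector(gain)  # gain recycles over planes (column-major y,x fastest)
  if (is.matrix(raw)) out[, , 1] else out
}

# Circular 3D convolution via FFT with a kernel given at volume size,
# centered at the origin.
.conv3_otf <- function(vol_f, otf, n) {
  Re(stats::fft(vol_f * otf, inverse = TRUE)) / n
}

# Embed a (y,x,z) PSF into a volume-sized array with its center at [1,1,1].
.psf_to_otf <- function(psf, d) {
  if (any(dim(psf) > d)) stop("PSF support exceeds the padded volume")
  k <- array(0, d)
  dp <- dim(psf)
  k[seq_len(dp[1]), seq_len(dp[2]), seq_len(dp[3])] <- psf
  ctr <- (dp - 1L) %/% 2L
  for (ax in 1:3) {
    idx <- c(seq_len(d[ax])[-seq_len(ctr[ax])], seq_len(ctr[ax]))
    k <- switch(ax, k[idx, , , drop = FALSE], k[, idx, , drop = FALSE], k[, , idx, drop = FALSE])
  }
  stats::fft(k)
}

# Per-axis padding: at least the PSF half-support, rounded up so the padded
# extent is a 5-smooth FFT length.
.fft_pad <- function(dv, dp) {
  pad <- pmin((dp - 1L) %/% 2L + 1L, dv - 1L)
  pad[dv == 1L] <- 0L
  for (ax in 1:3) {
    if (pad[ax] == 0L) next
    target <- .next_fast_len(dv[ax] + 2L * pad[ax])
    if ((target - dv[ax]) %% 2L == 1L) target <- .next_fast_len(target + 1L)
    pad[ax] <- (target - dv[ax]) %/% 2L
  }
  pad
}

# Smallest 5-smooth integer >= n (fast FFT length).
.next_fast_len <- function(n) {
  while (TRUE) {
    m <- n
    for (p in c(2, 3, 5)) while (m %% p == 0) m <- m / p
    if (m == 1) return(n)
    n <- n + 1
  }
}

# Reflective padding of a volume in all three axes; pads may exceed the
# minimum to reach FFT-friendly sizes (reflection repeats as needed).
.pad_reflect3 <- function(v, p) {
  d <- dim(v)
  ref_idx <- function(n, pad) {
    if (pad == 0) return(seq_len(n))
    base <- if (n > 1) c(seq_len(n), (n - 1):2) else 1L  # period 2(n-1) reflection
    idx <- ((seq_len(n + 2 * pad) - 1 - pad) %% length(base)) + 1
    base[idx]
  }
  v[ref_idx(d[1], p[1]), ref_idx(d[2], p[2]), ref_idx(d[3], p[3]), drop = FALSE]
}

#' Richardson-Lucy deconvolution
#'
#' Multiplicative Richardson-Lucy restoration with a fixed PSF by default;
#' `blind = TRUE` alternates one PSF update per iteration (kept off in the
#' tested default because blind updates are platform-sensitive). The volume
#' is reflectively padded by the PSF half-support, so interior flux is
#' approximately conserved.
#'
#' @param image observed volume (matrix or 3D array), non-negative.
#' @param psf_init unit-sum PSF volume from [generate_psf()].
#' @param iterations number of RL iterations (>= 1).
#' @param blind alternate PSF refinement updates.
#' @return Non-negative restored volume of the input shape.
#' @export
deconvolve <- function(image, psf_init, iterations = 10, blind = FALSE) {
  if (iterations < 1) stop("iterations must be >= 1")
  if (abs(sum(psf_init) - 1) > 1e-6) stop("initial PSF must be normalized to unit sum")
  v <- as_volume(image)
  if (any(v < 0)) stop("observed image must be non-negative")
  psf <- as_volume(psf_init)
  pad <- .fft_pad(dim(v), dim(psf))
  vp <- .pad_reflect3(v, pad)
  d <- dim(vp); n <- prod(d)
  otf <- .psf_to_otf(psf, d)
  otf_c <- Conj(otf)
  est <- vp
  est[est <= 0] <- mean(vp)
  eps <- 1e-12
  for (it in seq_len(iterations)) {
    blur <- .conv3_otf(stats::fft(est), otf, n)
    blur[blur < eps] <- eps
    ratio <- vp / blur
    corr <- .conv3_otf(stats::fft(ratio), otf_c, n)
    est <- est * corr
    est[est < 0] <- 0
    if (blind) {
      # one multiplicative PSF update against the current estimate
      fest <- stats::fft(est)
      blur2 <- .conv3_otf(fest, otf, n)
      blur2[blur2 < eps] <- eps
      r2 <- vp / blur2
      # correlation of the residual ratio with the estimate, at the origin
      k <- Re(stats::fft(stats::fft(r2) * Conj(fest), inverse = TRUE)) / n / sum(est)
      dp <- dim(psf); ctr <- (dp - 1L) %/% 2L
      idx1 <- c(d[1] - ctr[1] + seq_len(ctr[1]), seq_len(dp[1] - ctr[1]))
      idx2 <- c(d[2] - ctr[2] + seq_len(ctr[2]), seq_len(dp[2] - ctr[2]))
      idx3 <- c(d[3] - ctr[3] + seq_len(ctr[3]), seq_len(dp[3] - ctr[3]))
      kk <- k[idx1, idx2, idx3, drop = FALSE]
      kk[kk < 0] <- 0
      psf_new <- psf * kk
      if (sum(psf_new) > 0) {
        psf <- psf_new / sum(psf_new)
        otf <- .psf_to_otf(psf, d)
        otf_c <- Conj(otf)
      }
    }
  }
  out <- est[pad[1] + seq_len(dim(v)[1]), pad[2] + seq_len(dim(v)[2]),
             pad[3] + seq_len(dim(v)[3]), drop = FALSE]
  if (is.matrix(image)) out[, , 1] else out
}
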