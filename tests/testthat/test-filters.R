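# Core image-processing primitives against dense brute-force oracles and
# their stated invariants.

test_that("Gaussian convolution matches the dense oracle and preserves constants", {
  expect_error(gaussian_convolve(matrix(0, 4, 4), 5, 0), "sd must be")
  cst <- matrix(737.5, 24, 24)
  expect_equal(gaussian_convolve(cst, 20, 1), cst, tolerance = 1e-12)

  # impulse at the plane center reproduces the unit-sum truncated kernel
  im <- matrix(0, 41, 41); im[21, 21] <- 1
  k <- gaussian_kernel(20, 1)  # rounded up to 21 x 21
  out <- gaussian_convolve(im, 20, 1)
  expect_equal(out[11:31, 11:31], k, tolerance = 1e-12)
  expect_equal(sum(k), 1, tolerance = 1e-12)

  set.seed(41)
  for (spec in list(c(5, 2), c(11, 1), c(20, 7))) {
    a <- matrix(runif(32 * 32, 0, 4000), 32)
    mine <- gaussian_convolve(a, spec[1], spec[2])
    oracle <- oracle_conv2(a, gaussian_kernel(spec[1], spec[2]))
    expect_lt(max(abs(mine - oracle)) / max(abs(oracle)), 1e-6)
  }

  # linearity on random images
  set.seed(42)
  i1 <- matrix(runif(1024), 32); i2 <- matrix(runif(1024), 32)
  lhs <- gaussian_convolve(3 * i1 - 2 * i2, 9, 1.5)
  rhs <- 3 * gaussian_convolve(i1, 9, 1.5) - 2 * gaussian_convolve(i2, 9, 1.5)
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("difference of Gaussians is band-oriented and zero on constants", {
  expect_error(difference_of_gaussians(matrix(0, 4, 4), c(20, 7), c(20, 1)),
               "foreground sd")
  expect_error(difference_of_gaussians(matrix(0, 4, 4), c(20, 3), c(20, 3)),
               "foreground sd")
  cst <- matrix(1234, 24, 24)
  expect_equal(max(abs(difference_of_gaussians(cst, c(20, 1), c(20, 7)))), 0,
               tolerance = 1e-9)
  # impulse response center equals the kernel difference at the origin
  im <- matrix(0, 45, 45); im[23, 23] <- 1
  out <- difference_of_gaussians(im, c(20, 1), c(20, 7))
  expect_equal(out[23, 23],
               gaussian_kernel(20, 1)[11, 11] - gaussian_kernel(20, 7)[11, 11],
               tolerance = 1e-9)
})

test_that("Laplacian of Gaussian matches the oracle with the expected sign pattern", {
  cst <- matrix(900, 24, 24)
  expect_lt(max(abs(laplacian_of_gaussian(cst, 20, 1))), 1e-6)
  # impulse reproduces the kernel
  im <- matrix(0, 41, 41); im[21, 21] <- 1
  out <- laplacian_of_gaussian(im, 20, 1)
  expect_equal(out[11:31, 11:31], log_kernel(20, 1), tolerance = 1e-9)
  # bright disk: strongly negative interior, positive ring outside
  disk <- matrix(0, 48, 48)
  disk[as.matrix(which(outer((1:48 - 24)^2, (1:48 - 24)^2, "+") <= 64, arr.ind = TRUE))] <- 3000
  lg <- laplacian_of_gaussian(disk, 20, 1)
  expect_lt(lg[24, 24 + 7], -400)      # just inside the rim
  expect_gt(lg[24, 24 + 10], 50)       # just outside
  oracle <- oracle_conv2(disk, log_kernel(20, 1))
  expect_lt(max(abs(lg - oracle)) / max(abs(oracle)), 1e-6)
})

test_that("grayscale top-hat matches the erosion+dilation oracle and is non-negative", {
  set.seed(43)
  a <- matrix(runif(32 * 32, 0, 5000), 32)
  for (r in c(3, 5)) {
    mine <- tophat_gray(a, r)
    oracle <- oracle_tophat2(a, r)
    # interior comparison: border handling differs (clamp vs none)
    core <- (r + 1):(32 - r)
    expect_lt(max(abs(mine[core, core] - oracle[core, core])) / max(a), 1e-6)
    expect_gte(min(mine), 0)
  }
  expect_equal(max(abs(tophat_gray(matrix(640, 20, 20), 5))), 0)
  # bright disk of radius 10 under SE radius 25 is returned at ~full height
  disk <- matrix(0, 80, 80)
  disk[outer((1:80 - 40)^2, (1:80 - 40)^2, "+") <= 100] <- 2000
  th <- tophat_gray(disk, 25)
  expect_equal(th[40, 40], 2000, tolerance = 1e-6)
  # linear ramp suppressed, small peak retained
  ramp <- matrix(rep(seq(0, 3000, length.out = 64), each = 64), 64)
  withpeak <- ramp; withpeak[30:32, 30:32] <- withpeak[30:32, 30:32] + 1200
  th2 <- tophat_gray(withpeak, 10)
  expect_lt(max(th2[1:20, 1:20]), 50)
  expect_gt(th2[31, 31], 1000)
})

test_that("Butterworth high-pass has exact DC rejection and half-gain at cutoff", {
  expect_error(butterworth_highpass_plane(matrix(1, 8, 8), cutoff = 0), "cutoff")
  expect_error(butterworth_highpass_plane(matrix(1, 8, 8), order = 0), "order")
  expect_lt(max(abs(butterworth_highpass_plane(matrix(812, 64, 64)))), 1e-9)
  # pure sinusoid at radius D0: amplitude halved exactly
  n <- 64; d0 <- 10
  s <- matrix(cos(2 * pi * d0 * (0:(n - 1)) / n), n, n, byrow = TRUE)
  out <- butterworth_highpass_plane(s, cutoff = d0, order = 5)
  expect_equal(max(abs(out)) / max(abs(s)), 0.5, tolerance = 1e-6)
  # far above cutoff (3.2 * D0, the highest integer frequency on n = 64):
  # amplitude preserved within 1%
  shi <- matrix(cos(2 * pi * 32 * (0:(n - 1)) / n), n, n, byrow = TRUE)
  outhi <- butterworth_highpass_plane(shi, cutoff = d0, order = 5)
  expect_equal(max(abs(outhi)) / max(abs(shi)), 1, tolerance = 0.01)
})

test_that("ratio image follows the blur/clamp contract", {
  g <- array(500, c(16, 16, 2)); r <- array(1000, c(16, 16, 2))
  expect_equal(ratio_image(g, r), array(0.5, c(16, 16, 2)), tolerance = 1e-9)
  expect_equal(ratio_image(r, r), array(1, c(16, 16, 2)), tolerance = 1e-9)
  r0 <- array(0, c(16, 16, 2))
  out <- ratio_image(g, r0, eps = 1)
  expect_true(all(is.finite(out)))
  expect_equal(out, array(500, c(16, 16, 2)), tolerance = 1e-9)
  expect_error(ratio_image(g, array(1, c(8, 8, 2))), "shape")
})

test_that("image complement reverses ordering and is an involution", {
  set.seed(44)
  a <- array(runif(100, 0, 3), c(5, 5, 4))
  comp <- complement_image(a)
  expect_equal(min(comp[a == max(a)]), 0)
  expect_equal(complement_image(comp, ref_max = max(a)), a, tolerance = 1e-12)
  expect_true(all(order(as.vector(a)) == rev(order(as.vector(comp)))) ||
                all(rank(as.vector(a)) == rev(rank(as.vector(-comp)))))
})

test_that("threshold_components applies comparator plus inclusive size window", {
  z <- array(0, c(16, 16, 2))
  expect_false(any(threshold_components(z, ">", 400)))
  expect_error(threshold_components(z, "!=", 1), "comparator")
  expect_error(threshold_components(z, ">", 1, min_size = 10, max_size = 5), "min_size")

  # blobs of 150 and 2500 voxels, window [200, 2000]: both removed
  v <- array(0, c(40, 80, 3))
  v[1:10, 1:15, 1] <- 500                       # 150 voxels
  v[1:25, 31:64, 1:3] <- 500                    # 2550 voxels
  m <- threshold_components(v, ">", 400, min_size = 200, max_size = 2000)
  expect_false(any(m))
  # blob of exactly min_size is retained (inclusive bound)
  v2 <- array(0, c(20, 20, 1)); v2[1:10, 1:20, 1] <- 9
  expect_true(all(threshold_components(v2, ">", 5, min_size = 200, max_size = 300)[v2 > 5]))
  # monotone: raising a ">" threshold never adds voxels
  set.seed(45)
  a <- array(runif(16 * 16 * 3, 0, 100), c(16, 16, 3))
  m1 <- threshold_components(a, ">", 30)
  m2 <- threshold_components(a, ">", 60)
  expect_true(all(m1[m2]))
})

test_that("morphological reconstruction returns limit components touching the seed", {
  lim <- array(FALSE, c(12, 30, 2))
  lim[2:5, 2:5, 1] <- TRUE; lim[2:5, 10:13, ] <- TRUE; lim[8:11, 20:23, 2] <- TRUE
  seed <- array(FALSE, dim(lim))
  expect_false(any(morphological_reconstruct(seed, lim)))
  expect_equal(morphological_reconstruct(lim, lim), lim + 0 > 0)
  seed[3, 3, 1] <- TRUE; seed[9, 21, 2] <- TRUE
  out <- morphological_reconstruct(seed, lim)
  expect_true(all(out[2:5, 2:5, 1]) && all(out[8:11, 20:23, 2]))
  expect_false(any(out[2:5, 10:13, ]))
  # idempotent, monotone in the seed, bounded by the limit
  expect_equal(morphological_reconstruct(out, lim), out)
  out2 <- morphological_reconstruct(seed | lim, lim)
  expect_true(all(out2[out]))
  expect_true(all(lim[out]))
  expect_error(morphological_reconstruct(array(TRUE, c(2, 2, 1)), lim), "shape")
})
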