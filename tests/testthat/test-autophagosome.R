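# Hollow-vesicle detection: Euler topology, circle Hough, shape filter.

test_that("Euler selection keeps one-hole components only", {
  n <- 40
  ring <- fixture_annulus(n, 20, 20, 8, 4)
  disk <- fixture_annulus(n, 20, 20, 8, 0)
  two <- fixture_annulus(n, 14, 14, 6, 3) | fixture_annulus(n, 28, 28, 6, 3)
  es_ring <- euler_select(ring)
  expect_true(all(es_ring$selected[ring]))
  es_disk <- euler_select(disk)
  expect_false(any(es_disk$selected))
  es_two <- euler_select(two)
  expect_true(all(es_two$selected[two]))   # two separate rings, one hole each
  # a component with two holes is rejected
  blob <- matrix(FALSE, 30, 50)
  blob[5:25, 5:45] <- TRUE
  blob[10:14, 10:18] <- FALSE
  blob[10:14, 30:38] <- FALSE
  es_blob <- euler_select(blob)
  expect_false(any(es_blob$selected))
  expect_equal(es_blob$holes, 2L)
})

test_that("proportion filter enforces the hole-size rules in the Fourier-Euler route", {
  # field-sized planes: the Butterworth cutoff is an absolute frequency
  # radius, so the pass-band depends on the plane extent
  d <- c(256, 256, 3)
  mk_green_dog <- function(r_out, r_in, amp = 4000) {
    v <- array(0, d)
    for (z in 1:3) v[, , z][fixture_annulus(256, 128, 128, r_out, r_in)] <- amp
    v
  }
  # generous annulus: detected and filled
  out <- fourier_euler_detect(mk_green_dog(11, 6.5))
  ctr <- out[128, 128, 2]
  expect_true(any(out))
  expect_true(ctr)  # filled interior included
  # filled disk: rejected (no hole)
  expect_false(any(fourier_euler_detect(mk_green_dog(11, 0))))
  # thin ring whose hole is under 20 px: rejected
  expect_false(any(fourier_euler_detect(mk_green_dog(8, 2.2))))
})

test_that("Hough route accepts textured red-dark rings and rejects the rest", {
  d <- c(96, 96, 1)
  set.seed(31)
  mk <- function(interior_sd, red_level) {
    g <- array(100 + rnorm(prod(d), 0, 5), d)
    for (y in 1:96) for (x in 1:96) {
      dd <- sqrt((y - 40)^2 + (x - 60)^2)
      if (abs(dd - 9) < 2.5) g[y, x, 1] <- 4000 + rnorm(1, 0, 250)
      else if (dd < 6.5) g[y, x, 1] <- 150 + rnorm(1, 0, interior_sd)
    }
    list(g = g, r = array(red_level, d))
  }
  none <- array(FALSE, d)
  ok <- mk(60, 120)
  hm <- hough_detect(ok$g, none, ok$r)
  expect_gt(sum(hm), 0)
  w <- which(hm, arr.ind = TRUE)
  expect_lt(sqrt((mean(w[, 1]) - 40)^2 + (mean(w[, 2]) - 60)^2), 6)
  # flat interior: MAD below 20, no accepted circle covers the vesicle lumen
  flat <- mk(2, 120)
  hflat <- hough_detect(flat$g, none, flat$r)
  expect_false(any(hflat[37:43, 57:63, 1]))
  # red-bright: 0.9 quantile above 300, rejected
  redbright <- mk(60, 900)
  expect_false(any(hough_detect(redbright$g, none, redbright$r)))
})

test_that("shape filter keeps spheres and drops specks and filaments", {
  d <- c(48, 48, 5)
  green <- array(100, d)
  sphere <- fixture_sphere(d, 24, 24, 3, 5)
  green[sphere] <- 4000
  # 40-voxel speck: removed by the size range
  speck <- array(FALSE, d); speck[10:13, 10:14, 2:3] <- TRUE
  out_speck <- shape_filter_autophagosomes(speck, green)
  expect_false(any(out_speck))
  out_sphere <- shape_filter_autophagosomes(sphere, green)
  expect_true(all(out_sphere[sphere]))
  # filament of comparable volume: removed
  fil <- array(FALSE, d); fil[10:12, 4:44, 2:3] <- TRUE
  greenf <- array(100, d); greenf[fil] <- 4000
  expect_false(any(shape_filter_autophagosomes(fil, greenf)))
  si <- sphericity_indices(sphere, green)
  expect_gt(si["idx1"], 1); expect_gt(si["idx2"], 1.5)
  sif <- sphericity_indices(fil, greenf)
  expect_lt(sif["idx1"], 1)
})

test_that("Hough circles stay inside the image with radii in range", {
  set.seed(32)
  g <- array(100 + rnorm(96 * 96, 0, 40), c(96, 96, 1))
  hm <- hough_detect(g, array(FALSE, dim(g)), array(100, dim(g)))
  expect_true(is.array(hm))  # no out-of-bounds errors on pure noise
})
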