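# Channel-mask construction: red DoG/top-hat pool, green DoG/LoG mask,
# ratio-based autolysosome rescue.

test_that("red DoG mask is empty on flat fields and finds rendered vesicles", {
  expect_false(any(build_dsred_dog_mask(array(650, c(48, 48, 3)))))
  v <- array(200, c(64, 64, 3))
  v[fixture_sphere(dim(v), 32, 32, 2, 3)] <- 5200
  m <- build_dsred_dog_mask(v)
  expect_true(m[32, 32, 2])
})

test_that("top-hat split substitutes only large components with enough DoG overlap", {
  d <- c(40, 120, 1)
  base <- array(0, d)
  # big blob (~800 voxels) and small blob (< 500)
  big <- fixture_sphere(d, 20, 30, 1, 16); big_area <- sum(big)
  small <- fixture_sphere(d, 20, 90, 1, 8)
  v <- array(0, d); v[big] <- 3000; v[small] <- 3000
  dogA <- array(FALSE, d); dogA[14:26, 24:36, 1] <- TRUE   # ~30% of big blob
  outA <- build_dsred_tophat_split(v, dogA)
  expect_true(big_area > 500)
  expect_equal(outA & big, dogA & big)                     # substituted
  expect_equal(sum(outA & small), sum(small))              # small unchanged
  # overlap below 10%: unchanged
  dogB <- array(FALSE, d); dogB[18:22, 28:32, 1] <- TRUE   # ~3%
  expect_lt(sum(dogB & big) / big_area, 0.10)
  outB <- build_dsred_tophat_split(v, dogB)
  expect_equal(sum(outB & big), big_area)
})

test_that("final red mask pools seed and confirmed stencil voxels", {
  v <- array(150, c(96, 96, 3))
  v[fixture_sphere(dim(v), 30, 30, 2, 4)] <- 6200
  v[fixture_sphere(dim(v), 30, 39, 2, 4)] <- 6200   # touching pair
  masks <- build_dsred_mask(v)
  expect_identical(masks$dsred_mask, masks$dsred_mask1 | masks$dsred_stencil2)
  expect_true(all(masks$dsred_mask[masks$dsred_mask1]))   # pool never loses seeds
  expect_false(any(build_dsred_mask(array(150, c(48, 48, 3)))$dsred_mask))
})

test_that("green mask merges DoG and LoG branches and drops sub-10-voxel specks", {
  v <- array(120, c(96, 96, 3))
  v[fixture_sphere(dim(v), 48, 48, 2, 6)] <- 5200
  gm <- build_phluorin_mask(v)
  expect_true(any(gm$phluorin_mask[fixture_sphere(dim(v), 48, 48, 2, 6)]))
  lab <- label_components(gm$phluorin_mask, 26L)
  if (max(lab) > 0) expect_gte(min(tabulate(lab[lab > 0])), 10)
  # an 8-voxel speck alone cannot survive
  v2 <- array(120, c(64, 64, 3)); v2[30:31, 30:33, 2] <- 30000
  gm2 <- build_phluorin_mask(v2)
  lab2 <- label_components(gm2$phluorin_mask, 26L)
  if (max(lab2) > 0) expect_gte(min(tabulate(lab2[lab2 > 0])), 10)
  expect_false(any(build_phluorin_mask(array(120, c(48, 48, 3)))$phluorin_mask))
})

test_that("autolysosome rescue applies the neighbourhood and volume rules", {
  d <- c(64, 64, 5)
  make_case <- function(cyto_green, ves_green, r) {
    green <- array(cyto_green, d)
    red <- array(150, d)
    ves <- fixture_sphere(d, 32, 32, 3, r)
    green[ves] <- ves_green
    red[ves] <- 4000
    list(ratio = ratio_image(green, red), green = green, ves = ves)
  }
  # red-only vesicle in bright cytoplasm, > 100 voxels: retained
  cs <- make_case(1500, 150, 5.5)
  expect_gt(sum(cs$ves), 100)
  out <- build_autolyso_mask(cs$ratio, cs$green)
  expect_gt(sum(out$autolyso_mask & cs$ves) / sum(cs$ves), 0.3)
  # same vesicle but only ~80 voxels: rejected by the volume rule
  cs2 <- make_case(1500, 150, 3.3)
  expect_lt(sum(cs2$ves), 100)
  out2 <- build_autolyso_mask(cs2$ratio, cs2$green)
  expect_false(any(out2$autolyso_mask))
  # neighbourhood only ~1.2x brighter: rejected
  cs3 <- make_case(680, 560, 5.5)
  out3 <- build_autolyso_mask(cs3$ratio, cs3$green)
  expect_false(any(out3$autolyso_mask & cs3$ves))
})

test_that("red-vesicle recall and precision hold on a rendered field", {
  sc <- render_scene(scene_spec(seed = 301, n_phagophore = 6, n_autophagosome = 0,
                                n_early = 0, n_late = 12, n_cytoplasm = 6))
  psf <- generate_psf(psf_model(600, 1.2))
  r_dec <- deconvolve(sc$field$red, psf, 10)
  masks <- build_dsred_mask(r_dec)
  tr <- sc$truth$labels
  red_truth <- tr$phagophore > 0 | tr$late > 0
  ids <- c(unique(tr$phagophore[tr$phagophore > 0]), unique(tr$late[tr$late > 0]))
  hit <- vapply(ids, function(i) {
    sel <- tr$phagophore == i | tr$late == i
    any(masks$dsred_mask[sel])
  }, logical(1))
  expect_gte(mean(hit), 0.9)                               # object-level recall
  # voxel-level precision against the (slightly dilated) rendered truth
  tol <- red_truth | autostager:::dilate_ball1(red_truth)
  expect_gte(sum(masks$dsred_mask & tol) / sum(masks$dsred_mask), 0.7)
})
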