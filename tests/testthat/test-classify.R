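# Vesicle pooling, eccentricity, the staging decision tree, summaries and
# well normalization.

test_that("staging agrees with the straight-line predicate oracle", {
  f <- random_feature_tuples(2000, seed = 12)
  got <- as.character(classify_vesicles(f)$class)
  want <- vapply(seq_len(nrow(f)), function(i) oracle_classify_one(f[i, ]),
                 character(1))
  expect_identical(got, want)
})

test_that("spec'd staging examples land in the printed classes", {
  base <- data.frame(overlap_autophagosome = 0, overlap_noncircular = 0,
                     overlap_phluorin = 0, overlap_dsred = 0, overlap_autolyso = 0,
                     median_ratio = 1, q3_green = 0, q3_red = 0,
                     center_green = 100, surface_green = 100)
  cases <- list(
    list(mod = list(overlap_autophagosome = 0.8), want = "autophagosome"),
    list(mod = list(overlap_phluorin = 0.30, overlap_dsred = 0.40, median_ratio = 2.4),
         want = "phagophore"),
    list(mod = list(overlap_dsred = 0.30, overlap_phluorin = 0.05, median_ratio = 1.1),
         want = "late_autolysosome"),
    list(mod = list(overlap_dsred = 0.30, overlap_phluorin = 0.20, median_ratio = 2.2),
         want = "early_autolysosome"),
    list(mod = list(overlap_autophagosome = 0.5, overlap_noncircular = 0.4,
                    overlap_dsred = 0.3, overlap_phluorin = 0.05),
         want = "late_autolysosome")
  )
  for (cs in cases) {
    f <- base
    for (nm in names(cs$mod)) f[[nm]] <- cs$mod[[nm]]
    expect_equal(as.character(classify_vesicles(f)$class), cs$want)
  }
})

test_that("pooling enforces the red gate, border exclusion and perimeter splits", {
  d <- c(40, 40, 3)
  red <- array(100, d)
  m <- array(FALSE, d)
  m[10:15, 10:15, 2] <- TRUE; red[10:15, 10:15, ] <- 800     # kept
  m[25:30, 10:15, 2] <- TRUE; red[25:30, 10:15, ] <- 250     # mean red too low
  m[18:23, 1:6, 2] <- TRUE;   red[18:23, 1:6, ] <- 900       # touches x border
  lab <- pool_vesicles(m, array(FALSE, d), red, min_volume = 5)
  expect_equal(max(lab), 1L)
  expect_true(all(lab[10:15, 10:15, 2] == 1L))
  # two vesicles bridged only across an autophagosome: the perimeter band
  # separates them into two labels
  d2 <- c(40, 60, 3)
  red2 <- array(1000, d2)
  ap <- array(FALSE, d2); ap[14:26, 25:35, 2] <- TRUE
  m2 <- array(FALSE, d2)
  m2[18:22, 12:26, 2] <- TRUE     # vesicle A ending at the ap edge
  m2[18:22, 34:48, 2] <- TRUE     # vesicle B starting at the other edge
  m2 <- m2 | ap
  lab2 <- pool_vesicles(m2, ap, red2, min_volume = 5)
  expect_gte(max(lab2), 2L)
  expect_false(any(lab2[18:22, 12:20, 2] %in% lab2[18:22, 40:48, 2]))
})

test_that("eccentricity mask flags bars but not circles or mild ellipses", {
  d <- c(60, 60, 1)
  lab <- array(0L, d)
  lab[, , 1][fixture_annulus(60, 15, 15, 8, 0)] <- 1L           # circle
  lab[40:41, 10:29, 1] <- 2L                                    # 20 x 2 bar
  ell <- outer((seq_len(60) - 45)^2 / 81, (seq_len(60) - 45)^2 / 100, "+") <= 1
  lab[, , 1][ell & lab[, , 1] == 0] <- 3L                       # 10 x 9 ellipse
  nc <- compute_noncircular_mask(lab)
  expect_false(any(nc[lab == 1L]))
  expect_true(all(nc[lab == 2L]))
  expect_false(any(nc[lab == 3L]))
})

test_that("feature extraction reports volumes, quartiles and overlaps coherently", {
  d <- c(30, 30, 3)
  lab <- array(0L, d); lab[10:19, 10:19, 1:3] <- 1L
  green <- array(100, d); green[lab == 1L] <- 2000
  red <- array(50, d); red[lab == 1L] <- 4000
  masks <- list(phluorin_mask = lab == 1L, dsred_mask = array(FALSE, d),
                autolyso_mask = array(FALSE, d))
  ft <- vesicle_features(lab, masks, array(FALSE, d), array(FALSE, d),
                         ratio_image(green, red), green, red)
  expect_equal(nrow(ft), 1L)
  expect_equal(ft$volume_vox, 300)
  expect_equal(ft$volume_um3, 300 * 0.2152^2 * 0.4)
  expect_equal(ft$overlap_phluorin, 1)
  expect_equal(ft$overlap_dsred, 0)
  expect_equal(ft$q3_red, 4000)
  expect_false(ft$touches_border)
})

test_that("field summaries satisfy the vacuole and rate identities", {
  mk <- function(counts) {
    data.frame(class = factor(rep(names(counts), counts),
                              levels = c("phagophore", "autophagosome",
                                         "early_autolysosome", "late_autolysosome",
                                         "unclassified")))
  }
  s <- summarize_field(mk(c(phagophore = 41, autophagosome = 10,
                            early_autolysosome = 10, late_autolysosome = 80)))
  expect_equal(s$autophagic_vacuoles, 100)
  expect_equal(s$autophagy_rate, 0.41)
  s0 <- summarize_field(mk(c(phagophore = 0)))
  expect_equal(s0$autophagic_vacuoles, 0)
  expect_false(s0$autophagy_rate_defined)
  expect_equal(s0$autophagy_rate, 0)
  s2 <- summarize_field(mk(c(phagophore = 0, late_autolysosome = 50)))
  expect_equal(s2$autophagy_rate, 0)
  expect_true(s2$autophagy_rate_defined)
})

test_that("well normalization divides by category means and clips to [0, 2]", {
  m <- matrix(5, 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_true(all(normalize_wells(m) == 1))
  m2 <- matrix(c(1, 1, 1, 9), 4, 1, dimnames = list(NULL, "a"))
  out <- normalize_wells(m2)
  expect_equal(unname(out[4, 1]), 2)  # 9 / 3 = 3, clipped
  expect_equal(unname(out[1, 1]), 1 / 3)
  m3 <- cbind(a = c(1, 2), b = c(0, 0))
  expect_warning(out3 <- normalize_wells(m3), "zero mean")
  expect_equal(colnames(out3), "a")
})

test_that("adding one red-only vesicle adds exactly one late autolysosome", {
  base <- scene_spec(n_phagophore = 3, n_autophagosome = 0, n_early = 0,
                     n_late = 4, n_cytoplasm = 0, shape = c(128, 128, 5),
                     poisson_noise = FALSE, read_noise_sd = 0,
                     vignette_amplitude = 0, seed = 77)
  plus <- scene_spec(n_phagophore = 3, n_autophagosome = 0, n_early = 0,
                     n_late = 5, n_cytoplasm = 0, shape = c(128, 128, 5),
                     poisson_noise = FALSE, read_noise_sd = 0,
                     vignette_amplitude = 0, seed = 77)
  s1 <- summarize_field(process_autophagy_field(render_scene(base)$field)$vesicles)
  s2 <- summarize_field(process_autophagy_field(render_scene(plus)$field)$vesicles)
  expect_equal(s2$n_late_autolysosome - s1$n_late_autolysosome, 1)
  expect_equal(s2$n_phagophore, s1$n_phagophore)
  expect_equal(s2$n_autophagosome, s1$n_autophagosome)
  expect_equal(s2$n_early_autolysosome, s1$n_early_autolysosome)
})
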