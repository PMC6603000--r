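# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths of the package (no filter2/FFT, no bwlabel).

# Reflective index into 1..n (whole-sample symmetric border).
reflect_idx <- function(i, n) {
  if (n == 1) return(rep(1L, length(i)))
  p <- 2L * (n - 1L)
  j <- (i - 1L) %% p
  j <- ifelse(j < 0, j + p, j)
  ifelse(j >= n, p - j, j) + 1L
}

# Dense 2D correlation with reflective borders: explicit loop over kernel
# offsets (shift-and-add), no FFT.
oracle_conv2 <- function(m, k) {
  r <- (nrow(k) - 1L) / 2L
  n1 <- nrow(m); n2 <- ncol(m)
  out <- matrix(0, n1, n2)
  for (di in -r:r) for (dj in -r:r) {
    w <- k[di + r + 1L, dj + r + 1L]
    if (w == 0) next
    out <- out + w * m[reflect_idx(seq_len(n1) + di, n1),
                       reflect_idx(seq_len(n2) + dj, n2)]
  }
  out
}

# Brute-force grayscale erosion / dilation with a flat disc SE (plane-wise),
# border handled by clamping to +/-Inf outside.
oracle_morph2 <- function(m, radius, op = c("erode", "dilate")) {
  op <- match.arg(op)
  n1 <- nrow(m); n2 <- ncol(m)
  offs <- which(outer((-radius:radius)^2, (-radius:radius)^2, "+") <= radius^2,
                arr.ind = TRUE) - radius - 1L
  out <- matrix(if (op == "erode") Inf else -Inf, n1, n2)
  pick <- if (op == "erode") pmin else pmax
  for (k in seq_len(nrow(offs))) {
    di <- offs[k, 1]; dj <- offs[k, 2]
    sh <- matrix(if (op == "erode") Inf else -Inf, n1, n2)
    ys <- max(1, 1 - di):min(n1, n1 - di)
    xs <- max(1, 1 - dj):min(n2, n2 - dj)
    sh[ys, xs] <- m[ys + di, xs + dj]
    out <- pick(out, sh)
  }
  out
}

oracle_tophat2 <- function(m, radius) {
  opened <- oracle_morph2(oracle_morph2(m, radius, "erode"), radius, "dilate")
  out <- m - opened
  out[out < 0] <- 0
  out
}

# BFS connected-component labelling (queue-based flood fill).
oracle_label <- function(mask, connectivity) {
  is2d <- is.matrix(mask)
  d <- if (is2d) c(dim(mask), 1L) else dim(mask)
  m <- array(mask != 0, d)
  offs <- expand.grid(dy = -1:1, dx = -1:1, dz = -1:1)
  offs <- offs[!(offs$dy == 0 & offs$dx == 0 & offs$dz == 0), ]
  if (is2d) offs <- offs[offs$dz == 0, ]
  if (connectivity %in% c(4L, 6L)) {
    offs <- offs[abs(offs$dy) + abs(offs$dx) + abs(offs$dz) == 1, ]
  }
  lab <- array(0L, d); cur <- 0L
  for (s in which(m)) {
    if (lab[s] > 0L) next
    cur <- cur + 1L
    q <- s; lab[s] <- cur
    while (length(q)) {
      p <- q[[1]]; q <- q[-1]
      z <- (p - 1L) %/% (d[1] * d[2])
      rest <- (p - 1L) %% (d[1] * d[2])
      x <- rest %/% d[1]; y <- rest %% d[1]
      for (k in seq_len(nrow(offs))) {
        yy <- y + offs$dy[k]; xx <- x + offs$dx[k]; zz <- z + offs$dz[k]
        if (yy < 0 || yy >= d[1] || xx < 0 || xx >= d[2] || zz < 0 || zz >= d[3]) next
        pp <- yy + xx * d[1] + zz * d[1] * d[2] + 1L
        if (m[pp] && lab[pp] == 0L) { lab[pp] <- cur; q <- c(q, pp) }
      }
    }
  }
  if (is2d) lab[, , 1] else lab
}

# Flood-fill hole counting for a 2D binary pattern: background flooded from
# a padded border with 4-connectivity; remaining background pixels form the
# holes; each hole is attributed to the 8-connected foreground component
# whose pixels bound it. Returns the mask of foreground components with
# exactly one hole (the ring selection an Euler number of 0 encodes).
oracle_euler_keep <- function(mask2d) {
  p <- matrix(FALSE, nrow(mask2d) + 2L, ncol(mask2d) + 2L)
  p[2:(nrow(mask2d) + 1L), 2:(ncol(mask2d) + 1L)] <- mask2d != 0
  bg <- !p
  outside <- matrix(FALSE, nrow(p), ncol(p))
  q <- 1L; outside[1, 1] <- TRUE
  while (length(q)) {
    i <- q[[1]]; q <- q[-1]
    y <- (i - 1L) %% nrow(p) + 1L; x <- (i - 1L) %/% nrow(p) + 1L
    for (o in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      yy <- y + o[1]; xx <- x + o[2]
      if (yy < 1 || yy > nrow(p) || xx < 1 || xx > ncol(p)) next
      ii <- yy + (xx - 1L) * nrow(p)
      if (bg[ii] && !outside[ii]) { outside[ii] <- TRUE; q <- c(q, ii) }
    }
  }
  holes <- bg & !outside
  flab <- oracle_label(p, 8L)
  hlab <- oracle_label(holes, 4L)
  nh <- integer(max(flab))
  if (max(hlab) > 0) {
    for (h in seq_len(max(hlab))) {
      sel <- which(hlab == h)
      owners <- integer(0)
      for (i in sel) {
        y <- (i - 1L) %% nrow(p) + 1L; x <- (i - 1L) %/% nrow(p) + 1L
        for (dy in -1:1) for (dx in -1:1) {
          yy <- y + dy; xx <- x + dx
          if (yy < 1 || yy > nrow(p) || xx < 1 || xx > ncol(p)) next
          l <- flab[yy, xx]
          if (l > 0) owners <- c(owners, l)
        }
      }
      owners <- unique(owners)
      if (length(owners)) nh[owners[1]] <- nh[owners[1]] + 1L
    }
  }
  keep <- which(nh == 1L)
  out <- matrix(flab %in% keep, nrow(p), ncol(p)) & p
  out[2:(nrow(mask2d) + 1L), 2:(ncol(mask2d) + 1L)]
}

# Straight-line re-implementation of the printed staging predicates,
# evaluated one vesicle at a time (scalar logic, no vectorization).
oracle_classify_one <- function(f) {
  if (f$overlap_autophagosome > 0 && f$overlap_noncircular == 0) return("autophagosome")
  if (f$overlap_phluorin >= 0.25 && f$overlap_dsred >= 0.25 &&
      f$median_ratio > 2 && f$overlap_autolyso == 0) return("phagophore")
  if (f$q3_green > 7500 && f$q3_red > 4000) return("phagophore")
  if (f$center_green >= 1.25 * f$surface_green) return("phagophore")
  if (f$overlap_dsred >= 0.25 && (f$overlap_phluorin < 0.10 || f$median_ratio <= 2)) {
    return("late_autolysosome")
  }
  if (f$center_green < f$surface_green) return("late_autolysosome")
  if (f$overlap_dsred >= 0.25 && f$overlap_phluorin <= 0.25) return("early_autolysosome")
  if (f$overlap_autolyso > 0) return("early_autolysosome")
  "unclassified"
}

# Random feature tuples for the decision-tree comparison.
random_feature_tuples <- function(n, seed) {
  set.seed(seed)
  data.frame(
    overlap_autophagosome = sample(c(0, runif(3)), n, replace = TRUE),
    overlap_noncircular = sample(c(0, 0, runif(2)), n, replace = TRUE),
    overlap_phluorin = round(runif(n), 2),
    overlap_dsred = round(runif(n), 2),
    overlap_autolyso = sample(c(0, 0, runif(2)), n, replace = TRUE),
    median_ratio = round(runif(n, 0, 4), 2),
    q3_green = runif(n, 0, 12000),
    q3_red = runif(n, 0, 8000),
    center_green = runif(n, 0, 3000),
    surface_green = runif(n, 1, 3000)
  )
}

# Tiny rendered fixtures ------------------------------------------------------

# Filled sphere mask in a volume (lateral radius r px, z-anisotropy from the
# acquisition geometry).
fixture_sphere <- function(d, cy, cx, cz, r, z_aniso = 0.4 / 0.2152) {
  arr <- array(FALSE, d)
  for (z in seq_len(d[3])) {
    dz2 <- ((z - cz) * z_aniso)^2
    if (dz2 > r^2) next
    rl2 <- r^2 - dz2
    arr[, , z] <- outer((seq_len(d[1]) - cy)^2, (seq_len(d[2]) - cx)^2, "+") <= rl2
  }
  arr
}

# 2D annulus mask.
fixture_annulus <- function(n, cy, cx, r_out, r_in) {
  dd <- outer((seq_len(n) - cy)^2, (seq_len(n) - cx)^2, "+")
  dd <= r_out^2 & dd >= r_in^2
}
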