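# Hollow-vesicle (autophagosome) detection. Non-acidified autophagosomes
# appear as bright rings: a Fourier band-pass + Euler-number topology route
# finds closed rings, a circle Hough route recovers the remainder, and a
# size/shape/contrast filter removes false positives.

# Holes of each 8-connected 2D component: hole pixels are the filled mask
# minus the mask (4-connected hole components), attributed to the component
# that surrounds them. Returns labels, hole counts and hole areas per label.
.component_holes <- function(mask2d) {
  lab <- label_components(mask2d, 8L)
  filled <- EBImage::fillHull(mask2d * 1) > 0.5
  hole_mask <- filled & !mask2d
  n <- max(lab)
  holes <- integer(n)
  hole_area <- integer(n)
  if (any(hole_mask) && n > 0) {
    fl <- label_components(filled, 8L)
    hl <- label_components(hole_mask, 4L)
    for (h in seq_len(max(hl))) {
      sel <- hl == h
      parent_f <- fl[sel][1]
      owner <- unique(lab[fl == parent_f & mask2d])
      owner <- owner[owner > 0]
      if (length(owner) >= 1) {
        holes[owner[1]] <- holes[owner[1]] + 1L
        hole_area[owner[1]] <- hole_area[owner[1]] + sum(sel)
      }
    }
  }
  list(hole_mask = hole_mask, holes = holes, hole_area = hole_area,
       labels = lab, filled = filled)
}

#' Select one-hole (Euler number 0) components of a 2D mask
#'
#' For an 8-connected component with h holes the 2D Euler number is `1 - h`;
#' components with exactly one hole (Euler 0) are the ring candidates.
#'
#' @param mask2d logical matrix.
#' @return List with `selected` (mask of one-hole components), `holes`
#'   (hole-count per label), `labels`, `hole_mask` and `filled`.
#' @export
euler_select <- function(mask2d) {
  ch <- .component_holes(mask2d)
  keep <- which(ch$holes == 1L)
  ch$selected <- array(ch$labels %in% keep, dim = dim(ch$labels))
  ch
}

#' Hollow-vesicle detection by Fourier filtering and Euler topology
#'
#' The green DoG volume is Butterworth high-pass filtered per plane
#' (cutoff 10, order 5), thresholded > 150, maximum-projected along z,
#' cleaned (objects < 20 px removed, 3x3 median filter, opening radius 1),
#' and components with Euler number 0 (exactly one hole) are kept. A
#' proportion filter retains objects with filled-area/area > 1.01 and
#' filled-area - area > 20. Holes are segmented from the mask inverse
#' (components below 10000 px), vesicle bodies are recovered by
#' morphological reconstruction of the filled mask from the holes, opened
#' with a disc of radius 5, and restored to 3D by keeping each component's
#' filled footprint on the planes where the thresholded volume was positive.
#'
#' @param green_dog green DoG volume from [build_phluorin_mask()].
#' @param config optional overrides of the `autophagosome` defaults.
#' @return Binary 3D mask of hollow-vesicle bodies.
#' @export
fourier_euler_detect <- function(green_dog, config = NULL) {
  p <- modifyList(pipeline_config()$autophagosome, config %||% list())
  v <- as_volume(green_dog)
  ftb <- butterworth_highpass(v, p$butterworth_cutoff, p$butterworth_order)
  g150 <- ftb > p$threshold
  proj <- zmax_project(g150) > 0
  proj <- filter_components_by_size(proj, min_size = p$min_object, connectivity = 8L)
  proj <- EBImage::medianFilter(proj * 1, 1) > 0.5
  proj <- open_disc(proj, p$opening_radius)
  es <- euler_select(proj)
  # proportion filter between object and hole size: filled_area / area must
  # exceed 1.01 and the hole must be larger than 20 px
  lab <- es$labels
  sz <- component_sizes(lab)
  keep <- integer(0)
  for (l in which(es$holes == 1L)) {
    area <- sz[l]
    filled_area <- area + es$hole_area[l]
    if (filled_area / area > p$proportion_ratio && (filled_area - area) > p$proportion_diff) {
      keep <- c(keep, l)
    }
  }
  sel <- array(lab %in% keep, dim = dim(lab))
  filled_sel <- EBImage::fillHull(sel * 1) > 0.5
  # holes from the mask inverse, background removed by the size threshold
  inv <- !sel
  hole_mask <- filter_components_by_size(inv, max_size = p$hole_max - 1,
                                         connectivity = 4L) & filled_sel
  # reconstruct vesicle bodies containing a detected hole, then restore shape
  body <- morphological_reconstruct(hole_mask, filled_sel, 8L)
  body <- open_disc(body, p$restore_opening_radius)
  # 3D restoration: each 2D body keeps its footprint on planes where the
  # Butterworth-thresholded volume saw it
  out <- array(FALSE, dim(v))
  blab <- label_components(body, 8L)
  nb <- max(blab)
  if (nb > 0) {
    for (z in seq_len(dim(v)[3])) {
      present <- unique(blab[blab > 0 & g150[, , z]])
      if (length(present)) out[, , z] <- blab %in% present
    }
  }
  out
}

# -- circle Hough transform ---------------------------------------------------

# Gradient-direction circle Hough on one plane. Returns data.frame
# (y, x, r, score). Votes are cast along +/- gradient direction; the
# accumulator is normalized by circumference before peak picking.
.hough_circles_plane <- function(plane, radii, sensitivity, max_circles = 60) {
  d <- dim(plane)
  gy <- (rbind(plane[-1, ], plane[d[1], ]) - rbind(plane[1, ], plane[-d[1], ])) / 2
  gx <- (cbind(plane[, -1], plane[, d[2]]) - cbind(plane[, 1], plane[, -d[2]])) / 2
  mag <- sqrt(gy^2 + gx^2)
  thr <- max(stats::quantile(mag, 0.97), 1e-6)
  edges <- which(mag > thr)
  if (length(edges) == 0) return(NULL)
  ey <- ((edges - 1) %% d[1]) + 1
  ex <- ((edges - 1) %/% d[1]) + 1
  uy <- gy[edges] / mag[edges]
  ux <- gx[edges] / mag[edges]
  rs <- radii[1]:radii[2]
  score <- array(0, c(d[1], d[2], length(rs)))
  npl <- d[1] * d[2]
  for (i in seq_along(rs)) {
    r <- rs[i]
    votes <- numeric(npl)
    for (sgn in c(-1, 1)) {
      cy <- round(ey + sgn * r * uy)
      cx <- round(ex + sgn * r * ux)
      okc <- cy >= 1 & cy <= d[1] & cx >= 1 & cx <= d[2]
      if (!any(okc)) next
      votes <- votes + tabulate(cy[okc] + (cx[okc] - 1L) * d[1], nbins = npl)
    }
    # smooth laterally, then score by fraction of the circumference voting
    sm <- conv_plane(matrix(votes, d[1], d[2]), gaussian_kernel(7, 1.5))
    score[, , i] <- sm * (2 * pi * 1.5^2) / (2 * pi * r)
  }
  found <- NULL
  for (k in seq_len(max_circles)) {
    m <- which.max(score)
    smax <- score[m]
    if (smax < sensitivity) break
    my <- ((m - 1) %% d[1]) + 1
    mx <- (((m - 1) %/% d[1]) %% d[2]) + 1
    mr <- rs[((m - 1) %/% (d[1] * d[2])) + 1]
    found <- rbind(found, data.frame(y = my, x = mx, r = mr, score = smax))
    # suppress the neighbourhood of the accepted circle across all radii
    ys <- pmax(1, my - mr):pmin(d[1], my + mr)
    xs <- pmax(1, mx - mr):pmin(d[2], mx + mr)
    score[ys, xs, ] <- -Inf
  }
  found
}

#' Circle-Hough detection of remaining autophagosomes
#'
#' Works on the raw green channel: already-identified vesicle voxels are
#' substituted by low-pass (Gaussian 5, 2) filtered values, the plane is
#' grayscale-eroded with a disc of radius 2, and circles with radius 3-30 px
#' are detected by a gradient-voting circle Hough transform. A candidate
#' circle is accepted only when the raw green pixels inside it are textured
#' (median absolute deviation > 20) and the raw red pixels are dark (0.9
#' quantile < 300): a green ring without a red core. Accepted circles are
#' rasterized as filled discs on their plane of detection.
#'
#' @param phluorin_raw raw green volume.
#' @param known_vesicles binary volume of all vesicle detections so far.
#' @param dsred_raw raw red volume.
#' @param config optional overrides of the `autophagosome` defaults.
#' @return Binary 3D mask.
#' @export
hough_detect <- function(phluorin_raw, known_vesicles, dsred_raw, config = NULL) {
  p <- modifyList(pipeline_config()$autophagosome, config %||% list())
  hp <- p$hough
  v <- as_volume(phluorin_raw)
  red <- as_volume(dsred_raw)
  known <- as_volume(known_vesicles != 0)
  low <- gaussian_convolve(v, 5, 2)
  input <- v
  input[known] <- low[known]
  input <- erode_gray_disc(input, hp$erosion_radius)
  out <- array(FALSE, dim(v))
  d <- dim(v)
  for (z in seq_len(d[3])) {
    circ <- .hough_circles_plane(input[, , z], hp$radii, hp$sensitivity)
    if (is.null(circ)) next
    for (i in seq_len(nrow(circ))) {
      cy <- circ$y[i]; cx <- circ$x[i]; r <- circ$r[i]
      ys <- pmax(1, cy - r):pmin(d[1], cy + r)
      xs <- pmax(1, cx - r):pmin(d[2], cx + r)
      disc <- outer((ys - cy)^2, (xs - cx)^2, "+") <= r^2
      gv <- v[, , z][ys, xs][disc]
      rv <- red[, , z][ys, xs][disc]
      if (stats::mad(gv, constant = 1) > hp$mad_min &&
          stats::quantile(rv, 0.9) < hp$red_q90_max) {
        pl <- out[, , z]
        pl[ys, xs][disc] <- TRUE
        out[, , z] <- pl
      }
    }
  }
  out
}

# -- shape filter -------------------------------------------------------------

#' Sphericity indices of a labelled component
#'
#' `idx1` is a circularity measure of the z-maximum projection,
#' `1.2 * 4 * pi * area / perimeter^2`, scaled so an ideal rendered sphere
#' scores about 1.2; `idx2` is the mean deconvolved green intensity inside
#' the component divided by the mean in its 1-voxel outer shell (vesicle
#' border-to-surroundings contrast). Both are isolated here so the
#' definitions can be swapped wholesale.
#'
#' @param comp binary 3D mask of one component.
#' @param green_deconvolved deconvolved green volume.
#' @return Named numeric vector `c(idx1, idx2)`.
#' @export
sphericity_indices <- function(comp, green_deconvolved) {
  comp <- as_volume(comp != 0)
  proj <- zmax_project(comp) > 0
  cf <- EBImage::computeFeatures.shape(proj * 1)
  area <- cf[1, "s.area"]
  per_len <- cf[1, "s.perimeter"]
  idx1 <- if (per_len > 0) 1.2 * 4 * pi * area / per_len^2 else 0
  g <- as_volume(green_deconvolved)
  shell <- dilate_ball1(comp) & !comp
  inside <- mean(g[comp])
  outside <- if (any(shell)) mean(g[shell]) else inside
  idx2 <- if (outside > 0) inside / outside else Inf
  c(idx1 = idx1, idx2 = idx2)
}

#' Size, shape and contrast filtering of autophagosome candidates
#'
#' Keeps candidate components with volume in 50-10000 voxels,
#' `SphericityIdx1 > 1` and `SphericityIdx2 > 1.5`.
#'
#' @param candidates binary 3D mask (Fourier-Euler OR Hough detections).
#' @param green_deconvolved deconvolved green volume.
#' @param config optional overrides of the `autophagosome` defaults.
#' @return Binary 3D mask of accepted autophagosomes.
#' @export
shape_filter_autophagosomes <- function(candidates, green_deconvolved, config = NULL) {
  p <- modifyList(pipeline_config()$autophagosome, config %||% list())
  lab <- label_components(candidates != 0, 26L)
  n <- max(lab)
  out <- array(FALSE, dim(lab))
  if (n == 0) return(out)
  sz <- component_sizes(lab)
  for (l in seq_len(n)) {
    if (sz[l] < p$size_range[1] || sz[l] > p$size_range[2]) next
    comp <- lab == l
    si <- sphericity_indices(comp, green_deconvolved)
    if (si["idx1"] > p$sphericity1_min && si["idx2"] > p$sphericity2_min) {
      out <- out | comp
    }
  }
  out
}
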