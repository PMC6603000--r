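#' @import EBImage
#' @importFrom stats median quantile rnorm rpois runif setNames mad
#' @importFrom utils write.csv read.csv modifyList
NULL

# Acquisition geometry shared by all workflows: 60x water objective, camera
# binning 2 (0.2152 um/pixel), 400 nm z-steps.
PIXEL_PITCH_UM <- 0.2152
Z_STEP_UM <- 0.4

#' Voxel volume in cubic micrometers
#'
#' @param pixel_pitch lateral pixel size in micrometers.
#' @param z_step axial plane spacing in micrometers.
#' @return Volume of one voxel in um^3.
#' @export
voxel_volume_um3 <- function(pixel_pitch = PIXEL_PITCH_UM, z_step = Z_STEP_UM) {
  pixel_pitch^2 * z_step
}

# Coerce a matrix to a 1-plane volume; pass 3D arrays through.
as_volume <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  stopifnot(length(dim(x)) == 3L)
  x
}

# Shift a 3D array by (dy, dx, dz), zero-filling the exposed margin.
shift3d <- function(a, dy, dx, dz) {
  d <- dim(a)
  out <- array(vector(typeof(a), 1L), dim = d)
  ys <- max(1, 1 + dy):min(d[1], d[1] + dy)
  xs <- max(1, 1 + dx):min(d[2], d[2] + dx)
  zs <- max(1, 1 + dz):min(d[3], d[3] + dz)
  if (length(ys) < 1 || length(xs) < 1 || length(zs) < 1) return(out)
  out[ys, xs, zs] <- a[ys - dy, xs - dx, zs - dz]
  out
}

# Neighbour offsets (half-set) beyond the 4/6-connected base used by bwlabel.
.extra_offsets <- function(connectivity, nz) {
  if (nz == 1L) {
    if (connectivity == 4L) return(list())
    if (connectivity == 8L) return(list(c(1, 1, 0), c(1, -1, 0)))
    stop("2D connectivity must be 4 or 8")
  }
  ax <- list(c(0, 0, 1))                       # z-link absent from per-plane labels
  if (connectivity == 6L) return(ax)
  if (connectivity == 26L) {
    off <- list(c(1, 1, 0), c(1, -1, 0))       # in-plane diagonals
    for (dy in -1:1) for (dx in -1:1) off <- c(off, list(c(dy, dx, 1)))
    return(off)
  }
  stop("3D connectivity must be 6 or 26")
}

# Minimal union-find.
.uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

#' Label connected components of a binary mask
#'
#' Plane-wise 4-connected labelling (EBImage) extended by a union-find merge
#' to full 8-connectivity in 2D and 6- or 26-connectivity in 3D. The default
#' follows the pipeline convention: 8 in-plane, 26 across the stack.
#'
#' @param mask logical/0-1 matrix or 3D array.
#' @param connectivity 4 or 8 for matrices; 6 or 26 for 3D arrays.
#' @return Integer array of the same shape; 0 is background, components are
#'   numbered 1..n in no particular order but deterministically.
#' @export
label_components <- function(mask, connectivity = if (is.matrix(mask)) 8L else 26L) {
  is2d <- is.matrix(mask)
  vol <- as_volume(mask != 0)
  d <- dim(vol)
  connectivity <- as.integer(connectivity)
  if (d[3] == 1L) {                       # single plane: 3D and 2D coincide
    if (connectivity == 26L) connectivity <- 8L
    if (connectivity == 6L) connectivity <- 4L
  }
  lab <- array(0L, d)
  offset <- 0L
  for (z in seq_len(d[3])) {
    lz <- EBImage::bwlabel(vol[, , z] * 1)
    m <- max(lz)
    if (m > 0) lab[, , z] <- as.integer(lz + offset * (lz > 0))
    offset <- offset + as.integer(m)
  }
  n <- offset
  if (n > 0L) {
    offs <- .extra_offsets(as.integer(connectivity), d[3])
    pairs <- NULL
    for (o in offs) {
      sh <- shift3d(lab, o[1], o[2], o[3])
      sel <- lab > 0L & sh > 0L
      if (any(sel)) pairs <- rbind(pairs, unique(cbind(lab[sel], sh[sel])))
    }
    if (!is.null(pairs)) {
      pairs <- unique(pairs)
      parent <- seq_len(n)
      for (i in seq_len(nrow(pairs))) {
        ra <- .uf_find(parent, pairs[i, 1]); rb <- .uf_find(parent, pairs[i, 2])
        if (ra != rb) parent[rb] <- ra
      }
      root <- vapply(seq_len(n), function(i) .uf_find(parent, i), integer(1))
      dense <- match(root, sort(unique(root)))
      lab[lab > 0L] <- dense[lab[lab > 0L]]
    }
  }
  if (is2d) lab <- lab[, , 1]
  lab
}

# Component voxel counts, named by label.
component_sizes <- function(lab) {
  v <- lab[lab > 0L]
  if (length(v) == 0L) return(integer(0))
  tabulate(v)
}

#' Remove connected components outside a size window
#'
#' Inclusive bounds; components touching the border are retained (border
#' handling happens once, at classification).
#'
#' @param mask binary mask (matrix or 3D array).
#' @param min_size,max_size inclusive voxel-count bounds.
#' @param connectivity passed to [label_components()].
#' @return Binary mask of the same shape.
#' @export
filter_components_by_size <- function(mask, min_size = 0, max_size = Inf,
                                      connectivity = if (is.matrix(mask)) 8L else 26L) {
  if (min_size > max_size) stop("min_size must be <= max_size")
  lab <- label_components(mask, connectivity)
  sz <- component_sizes(lab)
  if (length(sz) == 0L) return(array(FALSE, dim(lab)))
  keep <- which(sz >= min_size & sz <= max_size)
  array(lab %in% keep, dim = dim(lab))
}

# Mean of `values` per label; returns vector indexed by label id.
label_means <- function(lab, values) {
  sel <- lab > 0L
  if (!any(sel)) return(numeric(0))
  s <- rowsum(as.numeric(values[sel]), group = lab[sel])
  n <- rowsum(rep(1, sum(sel)), group = lab[sel])
  out <- as.numeric(s / n)
  names(out) <- rownames(s)
  out
}

# Labels whose components contain at least one voxel of `mask`.
labels_touching <- function(lab, mask) {
  sel <- lab > 0L & mask
  if (!any(sel)) return(integer(0))
  sort(unique(lab[sel]))
}

# Erosion of a 3D binary mask by the radius-1 digital ball (6-neighbourhood).
erode_ball1 <- function(mask) {
  m <- as_volume(mask != 0)
  out <- m
  for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
    out <- out & shift3d(m, o[1], o[2], o[3])
  }
  out
}

# Dilation by the same ball.
dilate_ball1 <- function(mask) {
  m <- as_volume(mask != 0)
  out <- m
  for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
    out <- out | shift3d(m, o[1], o[2], o[3])
  }
  out
}

# Plane-wise binary morphology with a disc structuring element.
.apply_planes <- function(vol, fun) {
  v <- as_volume(vol)
  out <- v
  for (z in seq_len(dim(v)[3])) out[, , z] <- fun(v[, , z])
  if (is.matrix(vol)) out[, , 1] else out
}

# Flat disc structuring element: offsets with dy^2 + dx^2 <= r^2 (radius-1
# disc is the 5-pixel cross, matching the usual disk-strel convention).
disc_brush <- function(radius) {
  r <- as.integer(radius)
  x <- -r:r
  (outer(x^2, x^2, "+") <= radius^2) * 1
}

open_disc <- function(mask, radius) {
  k <- disc_brush(radius)
  .apply_planes(mask * 1, function(p) EBImage::opening(p, k)) > 0.5
}

dilate_disc <- function(mask, radius) {
  k <- disc_brush(radius)
  .apply_planes(mask * 1, function(p) EBImage::dilate(p, k)) > 0.5
}

erode_disc <- function(mask, radius) {
  k <- disc_brush(radius)
  .apply_planes(mask * 1, function(p) EBImage::erode(p, k)) > 0.5
}

# Grayscale morphology on arbitrary-range data: EBImage operates on [0, 1],
# and min/max morphology commutes with affine rescaling.
.morph_gray <- function(plane, fun) {
  rng <- range(plane)
  if (rng[2] == rng[1]) return(plane)
  out <- fun((plane - rng[1]) / (rng[2] - rng[1]))
  out * (rng[2] - rng[1]) + rng[1]
}

# Grayscale erosion, plane-wise, disc SE.
erode_gray_disc <- function(vol, radius) {
  k <- disc_brush(radius)
  .apply_planes(vol, function(p) .morph_gray(p, function(q) EBImage::erode(q, k)))
}

# Grayscale opening, plane-wise, disc SE.
open_gray_disc <- function(vol, radius) {
  k <- disc_brush(radius)
  .apply_planes(vol, function(p) .morph_gray(p, function(q) EBImage::opening(q, k)))
}

# Maximum projection along z.
zmax_project <- function(vol) {
  v <- as_volume(vol)
  apply(v, c(1, 2), max)
}

# TRUE for components having a voxel on the y/x image border (any plane).
labels_touching_border <- function(lab) {
  l <- as_volume(lab)
  d <- dim(l)
  edge <- unique(c(
    l[1, , ], l[d[1], , ], l[, 1, ], l[, d[2], ]
  ))
  sort(setdiff(edge, 0L))
}

# Per-plane perimeter (boundary pixels) of a binary mask.
perimeter_mask <- function(mask) {
  m <- as_volume(mask != 0)
  inner <- .apply_planes(m * 1, function(p) EBImage::erode(p, disc_brush(1))) > 0.5
  m & !as_volume(inner)
}

# Grow integer seed labels into unlabeled space, 26-connected, marking
# voxels reached simultaneously by two labels as ridge lines (0, frozen).
# `within` optionally restricts the growth domain (geodesic growth); the
# returned labels are then defined on seeds plus that domain only.
# Returns list(labels, ridge).
grow_labels <- function(seed_lab, within = NULL, max_iter = 1000L) {
  lab <- as_volume(seed_lab)
  ridge <- array(FALSE, dim(lab))
  domain <- if (is.null(within)) array(TRUE, dim(lab)) else as_volume(within != 0) | lab > 0L
  offs <- list()
  for (dy in -1:1) for (dx in -1:1) for (dz in -1:1) {
    if (dy || dx || dz) offs <- c(offs, list(c(dy, dx, dz)))
  }
  for (it in seq_len(max_iter)) {
    free <- lab == 0L & !ridge & domain
    if (!any(free)) break
    cand <- array(0L, dim(lab))
    clash <- array(FALSE, dim(lab))
    for (o in offs) {
      sh <- shift3d(lab, o[1], o[2], o[3])
      new <- free & sh > 0L
      clash <- clash | (new & cand > 0L & cand != sh)
      cand[new & cand == 0L] <- sh[new & cand == 0L]
    }
    grew <- cand > 0L & !clash
    if (!any(grew) && !any(clash)) break
    lab[grew] <- cand[grew]
    ridge <- ridge | clash
  }
  list(labels = lab, ridge = ridge)
}
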