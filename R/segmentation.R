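# Channel masks: the red-vesicle mask (DoG + top-hat + watershed-confirmed
# pool), the green-vesicle mask (large-vesicle DoG + LoG edges), and the
# ratio-based autolysosome rescue mask.

#' Small red-vesicle mask via difference of Gaussians
#'
#' DoG with foreground (20, 1) and background (20, 7), thresholded > 400.
#'
#' @param dsred_deconvolved deconvolved red volume.
#' @param fg,bg,threshold filter parameters (paper defaults).
#' @return Binary volume.
#' @export
build_dsred_dog_mask <- function(dsred_deconvolved, fg = c(20, 1), bg = c(20, 7),
                                 threshold = 400) {
  difference_of_gaussians(dsred_deconvolved, fg, bg) > threshold
}

#' Top-hat red-vesicle mask with DoG-based splitting
#'
#' Top-hat (disc radius 25) thresholded > 1200; every connected component
#' with more than `split_min_size` voxels overlapping the DoG mask with more
#' than `split_overlap` of its voxels is substituted by its intersection
#' pattern with the DoG mask (the DoG mask separates touching vesicles that
#' the top-hat merges).
#'
#' @param dsred_deconvolved deconvolved red volume.
#' @param dog_mask output of [build_dsred_dog_mask()].
#' @param radius,threshold top-hat parameters.
#' @param split_min_size,split_overlap substitution rule parameters.
#' @export
build_dsred_tophat_split <- function(dsred_deconvolved, dog_mask, radius = 25,
                                     threshold = 1200, split_min_size = 500,
                                     split_overlap = 0.10) {
  th_mask <- tophat_gray(dsred_deconvolved, radius) > threshold
  lab <- label_components(th_mask, 26L)
  n <- max(lab)
  if (n == 0L) return(th_mask)
  sz <- component_sizes(lab)
  ov <- label_means(lab, dog_mask)  # overlap fraction |comp & dog| / |comp|
  subst <- which(sz > split_min_size & ov > split_overlap)
  out <- th_mask
  for (l in subst) {
    sel <- lab == l
    out[sel] <- dog_mask[sel]
  }
  out
}

#' Full red-channel mask construction
#'
#' Builds dsRedDoGmask, the split top-hat mask, their union (dsRedMask1), a
#' confirmative second DoG mask (size-filtered 200-2000 voxels), the
#' seeded-watershed region stencils, and the final pooled red mask
#' `dsred_mask = dsred_mask1 | dsred_stencil2`.
#'
#' @param dsred_deconvolved deconvolved red volume.
#' @param config optional list overriding the red-channel defaults (see
#'   [pipeline_config()], entry `dsred`).
#' @return List of intermediate and final masks (fields `dsred_dog_mask`,
#'   `dsred_tophat_split`, `dsred_mask1`, `dsred_dog2_mask`, `dsred_stencil1`,
#'   `dsred_stencil2`, `dsred_mask`).
#' @export
build_dsred_mask <- function(dsred_deconvolved, config = NULL) {
  p <- modifyList(pipeline_config()$dsred, config %||% list())
  dog_mask <- build_dsred_dog_mask(dsred_deconvolved, p$dog_fg, p$dog_bg, p$dog_threshold)
  th_split <- build_dsred_tophat_split(dsred_deconvolved, dog_mask, p$tophat_radius,
                                       p$tophat_threshold, p$split_min_size, p$split_overlap)
  mask1 <- dog_mask | th_split
  dog2 <- difference_of_gaussians(dsred_deconvolved, p$dog2_fg, p$dog2_bg)
  dog2_mask <- threshold_components(dog2, ">", p$dog2_threshold,
                                    p$dog2_size[1], p$dog2_size[2], 26L)
  # watershed split: Euclidean-style growth of the mask1 component labels;
  # ridge voxels (reached by two labels simultaneously) are excluded so the
  # confirmative mask inherits the splits
  seeds <- label_components(mask1, 26L)
  gw <- grow_labels(seeds, within = dog2_mask)
  stencil1 <- gw$labels
  stencil2 <- (stencil1 > 0L) & !gw$ridge & dog2_mask
  list(
    dsred_dog_mask = dog_mask,
    dsred_tophat_split = th_split,
    dsred_mask1 = mask1,
    dsred_dog2_mask = dog2_mask,
    dsred_stencil1 = stencil1,
    dsred_stencil2 = stencil2,
    dsred_mask = mask1 | stencil2
  )
}

#' Green-channel (non-acidic vesicle) mask
#'
#' Large vesicles from a DoG (foreground (100, 1), background (100, 5),
#' threshold > 1000) OR'ed with LoG edge detections (size 20, sd 1, values
#' < -2000); connected components below 10 voxels are removed.
#'
#' @param phluorin_deconvolved deconvolved green volume.
#' @param config optional overrides of the `green` defaults.
#' @return List with `green_dog` (graytone DoG volume, reused by the
#'   hollow-vesicle detector), `green_dog_mask`, `green_log_mask`, and the
#'   final `phluorin_mask`.
#' @export
build_phluorin_mask <- function(phluorin_deconvolved, config = NULL) {
  p <- modifyList(pipeline_config()$green, config %||% list())
  green_dog <- difference_of_gaussians(phluorin_deconvolved, p$dog_fg, p$dog_bg)
  dog_mask <- green_dog > p$dog_threshold
  log_im <- laplacian_of_gaussian(phluorin_deconvolved, p$log_size, p$log_sd)
  log_mask <- log_im < p$log_threshold
  merged <- dog_mask | log_mask
  phluorin_mask <- filter_components_by_size(merged, min_size = p$min_component,
                                             connectivity = 26L)
  list(green_dog = green_dog, green_dog_mask = dog_mask,
       green_log_mask = log_mask, phluorin_mask = phluorin_mask)
}

#' Ratio-based autolysosome rescue mask
#'
#' Acidified vesicles that escaped the red segmentation appear as dark holes
#' in the green:red ratio image. Candidates are bright spots of the top-hat
#' (disc radius 15) of the complemented ratio image above 1.5 (ratio scale).
#' A candidate is kept iff its green neighbourhood (dilation by disc radius
#' 7 minus the candidate) is at least 50% brighter (mean raw green) than the
#' candidate itself AND the candidate exceeds 100 voxels.
#'
#' @param ratio ratio volume from [ratio_image()].
#' @param green_raw raw green volume.
#' @param config optional overrides of the `autolyso` defaults.
#' @return List with `autolyso_candidates` and `autolyso_mask`.
#' @export
build_autolyso_mask <- function(ratio, green_raw, config = NULL) {
  p <- modifyList(pipeline_config()$autolyso, config %||% list())
  comp <- complement_image(ratio)
  th <- tophat_gray(comp, p$tophat_radius)
  candidates <- th > p$threshold
  lab <- label_components(candidates, 26L)
  n <- max(lab)
  keep <- integer(0)
  if (n > 0L) {
    sz <- component_sizes(lab)
    inside <- label_means(lab, green_raw)
    for (l in seq_len(n)) {
      if (sz[l] <= p$min_volume) next
      sel <- lab == l
      ring <- dilate_disc(sel, p$neighborhood_radius) & !sel
      if (!any(ring)) next
      if (mean(green_raw[ring]) >= p$brighter_factor * inside[l]) keep <- c(keep, l)
    }
  }
  list(autolyso_candidates = candidates,
       autolyso_mask = array(lab %in% keep, dim = dim(lab)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
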