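# Mitochondrial network segmentation and mitophagy event detection for
# matrix-targeted (ATP5C1) tandem-reporter 11-plane stacks.

#' Segment the mitochondrial network
#'
#' DoG of the red channel with foreground (50, 1) and background (50, 2),
#' thresholded above 12 graytones. The narrow band keeps thin tubules; a
#' local reduction in tubule cross-section can split the network into
#' several components, which is expected behaviour.
#'
#' @param dsred_raw red channel volume (11 planes).
#' @param config optional overrides of the `mitophagy` defaults.
#' @return List with `mito_dog` (graytone volume) and `mito_mask`.
#' @export
segment_mitochondria <- function(dsred_raw, config = NULL) {
  p <- modifyList(pipeline_config()$mitophagy, config %||% list())
  mito_dog <- difference_of_gaussians(dsred_raw, p$dog_fg, p$dog_bg)
  list(mito_dog = mito_dog, mito_mask = mito_dog > p$threshold)
}

#' Detect mitophagy events
#'
#' 26-connected components of the mitochondrial mask whose mean green:red
#' ratio is below 0.6 seed the events (quenched green marks delivery to an
#' acidic compartment); the event shapes are refined by morphological
#' reconstruction within a limiting mask (red DoG, foreground (50, 1),
#' background (50, 5), values above 50).
#'
#' @param mito_mask binary volume from [segment_mitochondria()].
#' @param ratio ratio volume from [ratio_image()] on the raw channels.
#' @param dsred_raw raw red volume.
#' @param config optional overrides of the `mitophagy` defaults.
#' @return List with `mitophagy_seed`, `mitophagy_limit`, `mitophagy_mask`.
#' @export
detect_mitophagy <- function(mito_mask, ratio, dsred_raw, config = NULL) {
  p <- modifyList(pipeline_config()$mitophagy, config %||% list())
  lab <- label_components(mito_mask != 0, 26L)
  mr <- label_means(lab, as_volume(ratio))
  seed_labels <- which(mr < p$ratio_max)
  seed <- array(lab %in% seed_labels, dim = dim(lab))
  limit_dog <- difference_of_gaussians(dsred_raw, p$limit_fg, p$limit_bg)
  limit <- limit_dog > p$limit_threshold
  mask <- morphological_reconstruct(seed, limit, 26L)
  list(mitophagy_seed = seed, mitophagy_limit = limit, mitophagy_mask = mask)
}

#' Mitochondrial and mitophagy volumes and event count
#'
#' Volumes are voxel counts times the voxel volume
#' (`pixel_pitch^2 * z_step` um^3); events are 26-connected components of
#' the mitophagy mask.
#'
#' @param masks list with `mito_mask` and `mitophagy_mask`.
#' @param pixel_pitch,z_step geometry in micrometers.
#' @return data.frame with `mito_volume_um3`, `mitophagy_volume_um3`,
#'   `mitophagy_event_count`.
#' @export
mito_volumes <- function(masks, pixel_pitch = PIXEL_PITCH_UM, z_step = Z_STEP_UM) {
  vx <- voxel_volume_um3(pixel_pitch, z_step)
  ev <- label_components(masks$mitophagy_mask != 0, 26L)
  data.frame(
    mito_volume_um3 = sum(masks$mito_mask != 0) * vx,
    mitophagy_volume_um3 = sum(masks$mitophagy_mask != 0) * vx,
    mitophagy_event_count = max(ev)
  )
}

#' Autophagy resource split between mitophagy and bulk autophagy
#'
#' Subtracts the mitochondria-reporter mitophagy frequency from the
#' cytosolic-reporter autophagic-vacuole frequency to estimate
#' non-mitochondrial autophagy, and expresses both components as
#' percentages of their basal reference values.
#'
#' @param lc3_vacuoles treated-condition autophagic-vacuole frequency
#'   (per-field mean from the cytosolic reporter).
#' @param mitophagy_events treated-condition mitophagy frequency (per-field
#'   mean from the mitochondrial reporter).
#' @param basal_lc3_vacuoles,basal_mitophagy_events basal references.
#' @return data.frame with `mitophagy_pct` and `non_mito_autophagy_pct`
#'   (percent of basal).
#' @export
resource_split <- function(lc3_vacuoles, mitophagy_events,
                           basal_lc3_vacuoles, basal_mitophagy_events) {
  if (basal_mitophagy_events <= 0 || (basal_lc3_vacuoles - basal_mitophagy_events) <= 0) {
    stop("basal reference frequencies must be positive (non-mito basal > 0)")
  }
  non_mito <- lc3_vacuoles - mitophagy_events
  if (non_mito < 0) {
    warning("negative non-mitochondrial autophagy frequency; clamped to 0")
    non_mito <- 0
  }
  basal_non_mito <- basal_lc3_vacuoles - basal_mitophagy_events
  data.frame(
    mitophagy_pct = 100 * mitophagy_events / basal_mitophagy_events,
    non_mito_autophagy_pct = 100 * non_mito / basal_non_mito
  )
}
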