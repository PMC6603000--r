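# Lysotracker assay: segmentation of acidic vesicles from single-channel
# 11-plane stacks and major-axis sizing of each lysosome.

#' Segment lysotracker-stained vesicles
#'
#' DoG (foreground (100, 1), background (100, 5)) thresholded > 2000, OR'ed
#' with LoG (size 20, sd 1) values < -2000; components below 10 voxels are
#' removed.
#'
#' @param lysotracker_deconvolved deconvolved single-channel volume.
#' @param config optional overrides of the `lysotracker` defaults.
#' @return Binary volume.
#' @export
segment_lysosomes <- function(lysotracker_deconvolved, config = NULL) {
  p <- modifyList(pipeline_config()$lysotracker, config %||% list())
  dog <- difference_of_gaussians(lysotracker_deconvolved, p$dog_fg, p$dog_bg)
  log_im <- laplacian_of_gaussian(lysotracker_deconvolved, p$log_size, p$log_sd)
  merged <- (dog > p$dog_threshold) | (log_im < p$log_threshold)
  filter_components_by_size(merged, min_size = p$min_component, connectivity = 26L)
}

#' Lysosome sizes from the projected mask
#'
#' The mask is maximum-projected along z and the major-axis length of each
#' 8-connected projected component is computed from the
#' normalized-second-central-moments ellipse (regionprops convention),
#' reported in pixels and micrometers.
#'
#' @param mask binary volume from [segment_lysosomes()].
#' @param pixel_pitch lateral pixel size in micrometers.
#' @return data.frame with `label`, `volume_vox`, `major_axis_px`,
#'   `major_axis_um`; empty for an empty mask.
#' @export
lysosome_sizes <- function(mask, pixel_pitch = PIXEL_PITCH_UM) {
  m <- as_volume(mask != 0)
  proj <- zmax_project(m) > 0
  lab <- label_components(proj, 8L)
  n <- max(lab)
  if (n == 0) {
    return(data.frame(label = integer(0), volume_vox = integer(0),
                      major_axis_px = numeric(0), major_axis_um = numeric(0)))
  }
  idx <- which(lab > 0L)
  yy <- ((idx - 1) %% nrow(lab)) + 1
  xx <- ((idx - 1) %/% nrow(lab)) + 1
  ll <- lab[idx]
  # 3D volume attributed by the projected footprint
  rows <- lapply(seq_len(n), function(l) {
    sel <- ll == l
    em <- .moments_ellipse(yy[sel], xx[sel])
    foot <- lab == l
    vol <- sum(m & array(foot, dim(m)))
    data.frame(label = l, volume_vox = vol,
               major_axis_px = unname(em["major_axis"]),
               major_axis_um = unname(em["major_axis"]) * pixel_pitch)
  })
  do.call(rbind, rows)
}
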