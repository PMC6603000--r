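# Pipeline configuration, orchestration of the three workflows, TIFF I/O
# and condition-level reporting.

#' Default pipeline configuration
#'
#' Every numeric parameter of every stage, with the published defaults on
#' the 16-bit graytone scale. Override any subset via nested lists (the
#' workflow functions use [utils::modifyList()] semantics). The defaults are
#' frozen in `inst/extdata/paper_defaults.yaml` and round-trip losslessly
#' through YAML.
#'
#' @return Nested list of parameters.
#' @export
pipeline_config <- function() {
  list(
    geometry = list(pixel_pitch = PIXEL_PITCH_UM, z_step = Z_STEP_UM,
                    planes_autophagy = 5L, planes_mitophagy = 11L),
    preprocess = list(
      iterations = 10L, flatfield_smooth_sd = 20,
      psf = list(
        green = list(wavelength_em = 520, numerical_aperture = 1.2, refractive_index = 1.33),
        red = list(wavelength_em = 600, numerical_aperture = 1.2, refractive_index = 1.33),
        lysotracker = list(wavelength_em = 690, numerical_aperture = 1.2, refractive_index = 1.33)
      )
    ),
    dsred = list(dog_fg = c(20, 1), dog_bg = c(20, 7), dog_threshold = 400,
                 tophat_radius = 25, tophat_threshold = 1200,
                 split_min_size = 500, split_overlap = 0.10,
                 dog2_fg = c(11, 1), dog2_bg = c(25, 6), dog2_threshold = 1000,
                 dog2_size = c(200, 2000)),
    green = list(dog_fg = c(100, 1), dog_bg = c(100, 5), dog_threshold = 1000,
                 log_size = 20, log_sd = 1, log_threshold = -2000,
                 min_component = 10),
    ratio = list(blur = c(5, 2), eps = 1),
    autolyso = list(tophat_radius = 15, threshold = 1.5, neighborhood_radius = 7,
                    brighter_factor = 1.5, min_volume = 100),
    autophagosome = list(
      butterworth_cutoff = 10, butterworth_order = 5, threshold = 150,
      min_object = 20, opening_radius = 1, proportion_ratio = 1.01,
      proportion_diff = 20, hole_max = 10000, restore_opening_radius = 5,
      hough = list(radii = c(3, 30), erosion_radius = 2, mad_min = 20,
                   red_q90_max = 300, sensitivity = 0.25),
      size_range = c(50, 10000), sphericity1_min = 1, sphericity2_min = 1.5
    ),
    classification = list(mean_red_min = 300, eccentricity_max = 0.9),
    mitophagy = list(dog_fg = c(50, 1), dog_bg = c(50, 2), threshold = 12,
                     ratio_max = 0.6, limit_fg = c(50, 1), limit_bg = c(50, 5),
                     limit_threshold = 50),
    lysotracker = list(dog_fg = c(100, 1), dog_bg = c(100, 5), dog_threshold = 2000,
                       log_size = 20, log_sd = 1, log_threshold = -2000,
                       min_component = 10)
  )
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config nested parameter list.
#' @param path file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

#' Construct a field stack from channel volumes
#'
#' @param green,red graytone volumes (red may be `NULL` for single-channel
#'   assays, in which case `green` holds the only channel).
#' @param pixel_pitch,z_step geometry in micrometers.
#' @export
field_stack <- function(green, red = NULL, pixel_pitch = PIXEL_PITCH_UM,
                        z_step = Z_STEP_UM) {
  green <- as_volume(green)
  if (!is.null(red)) {
    red <- as_volume(red)
    if (!identical(dim(green), dim(red))) stop("channel shapes differ")
  }
  structure(list(green = green, red = red, pixel_pitch = pixel_pitch,
                 z_step = z_step), class = "field_stack")
}

#' Read / write 16-bit multi-plane TIFF stacks
#'
#' Planes are stored as TIFF directories; graytones are mapped to the 16-bit
#' range on disk.
#'
#' @param path TIFF file path.
#' @return `read_stack`: a 3D array of graytones.
#' @export
read_stack <- function(path) {
  pl <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pl)) pl <- list(pl)
  pl <- lapply(pl, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
  arr <- array(0, c(dim(pl[[1]]), length(pl)))
  for (z in seq_along(pl)) arr[, , z] <- pl[[z]]
  arr
}

#' @rdname read_stack
#' @param volume 3D array (graytones, 0-65535) or binary mask.
#' @export
write_stack <- function(volume, path) {
  v <- as_volume(volume) * 1
  v <- pmin(pmax(v, 0), 65535) / 65535
  pl <- lapply(seq_len(dim(v)[3]), function(z) v[, , z])
  tiff::writeTIFF(pl, path, bits.per.sample = 16L)
  invisible(path)
}

# Deconvolve one channel with its modelled PSF.
.deconvolve_channel <- function(vol, psf_pars, geometry, iterations) {
  model <- psf_model(wavelength_em = psf_pars$wavelength_em,
                     numerical_aperture = psf_pars$numerical_aperture,
                     pixel_pitch = geometry$pixel_pitch, z_step = geometry$z_step,
                     refractive_index = psf_pars$refractive_index)
  deconvolve(vol, generate_psf(model), iterations = iterations)
}

#' Run the autophagy staging workflow on one field
#'
#' Full Fig.-2-style chain: (optional) flatfield correction, channel
#' deconvolution, red and green channel masks, ratio image and autolysosome
#' rescue mask, hollow-vesicle detection (Fourier-Euler + Hough), shape
#' filtering, pooling, staging and the per-field summary.
#'
#' @param field a `field_stack` with both channels.
#' @param config optional nested overrides of [pipeline_config()].
#' @param flatfield optional list with 2D references `green`, `red`.
#' @param field_id,well_id,condition identifiers for the outputs.
#' @param keep_masks return the intermediate masks as well.
#' @return List with `vesicles` (per-vesicle table), `summary` (per-field
#'   row), and optionally `masks`.
#' @export
process_autophagy_field <- function(field, config = NULL, flatfield = NULL,
                                    field_id = "field_1", well_id = "well_1",
                                    condition = "basal", keep_masks = FALSE) {
  if (is.null(field$red)) stop("the autophagy workflow needs both channels")
  cfg <- modifyList(pipeline_config(), config %||% list())
  geom <- cfg$geometry
  nz <- dim(field$green)[3]
  if (nz != geom$planes_autophagy) {
    warning(sprintf("expected %d planes, got %d", geom$planes_autophagy, nz))
  }
  g_raw <- field$green; r_raw <- field$red
  if (!is.null(flatfield)) {
    g_raw <- flatfield_correct(g_raw, flatfield$green, cfg$preprocess$flatfield_smooth_sd)
    r_raw <- flatfield_correct(r_raw, flatfield$red, cfg$preprocess$flatfield_smooth_sd)
  }
  geom$pixel_pitch <- field$pixel_pitch %||% geom$pixel_pitch
  geom$z_step <- field$z_step %||% geom$z_step
  g_dec <- .deconvolve_channel(g_raw, cfg$preprocess$psf$green, geom, cfg$preprocess$iterations)
  r_dec <- .deconvolve_channel(r_raw, cfg$preprocess$psf$red, geom, cfg$preprocess$iterations)

  red_masks <- build_dsred_mask(r_dec, cfg$dsred)
  green_masks <- build_phluorin_mask(g_dec, cfg$green)
  ratio <- ratio_image(g_raw, r_raw, cfg$ratio$blur, cfg$ratio$eps)
  autolyso <- build_autolyso_mask(ratio, g_raw, cfg$autolyso)

  fe <- fourier_euler_detect(green_masks$green_dog, cfg$autophagosome)
  known <- red_masks$dsred_mask | green_masks$phluorin_mask | autolyso$autolyso_mask | fe
  hough <- hough_detect(g_raw, known, r_raw, cfg$autophagosome)
  ap_mask <- shape_filter_autophagosomes(fe | hough, g_dec, cfg$autophagosome)

  all_masks <- red_masks$dsred_mask | green_masks$phluorin_mask |
    autolyso$autolyso_mask | ap_mask
  labels <- pool_vesicles(all_masks, ap_mask, r_raw, cfg$classification$mean_red_min)
  noncirc <- compute_noncircular_mask(labels, cfg$classification$eccentricity_max)
  feats <- vesicle_features(labels,
                            list(phluorin_mask = green_masks$phluorin_mask,
                                 dsred_mask = red_masks$dsred_mask,
                                 autolyso_mask = autolyso$autolyso_mask),
                            ap_mask, noncirc, ratio, g_raw, r_raw,
                            geom$pixel_pitch, geom$z_step)
  vesicles <- classify_vesicles(feats)
  vesicles$field_id <- rep(field_id, nrow(vesicles))
  vesicles$well_id <- rep(well_id, nrow(vesicles))
  vesicles$condition <- rep(condition, nrow(vesicles))
  summ <- summarize_field(vesicles, field_id, well_id, condition)
  out <- list(vesicles = vesicles, summary = summ)
  if (keep_masks) {
    out$masks <- c(red_masks, green_masks,
                   autolyso, list(fourier_euler = fe, hough = hough,
                                  autophagosome_mask = ap_mask, labels = labels,
                                  noncircular_mask = noncirc, ratio = ratio,
                                  green_deconvolved = g_dec, red_deconvolved = r_dec))
  }
  out
}

#' Run the mitophagy workflow on one field
#'
#' @param field `field_stack` with both channels (11 planes expected).
#' @inheritParams process_autophagy_field
#' @return List with `summary` (volumes, event count) and optionally `masks`.
#' @export
process_mitophagy_field <- function(field, config = NULL,
                                    field_id = "field_1", well_id = "well_1",
                                    condition = "basal", keep_masks = FALSE) {
  if (is.null(field$red)) stop("the mitophagy workflow needs both channels")
  cfg <- modifyList(pipeline_config(), config %||% list())
  nz <- dim(field$green)[3]
  if (nz != cfg$geometry$planes_mitophagy) {
    warning(sprintf("expected %d planes, got %d", cfg$geometry$planes_mitophagy, nz))
  }
  mito <- segment_mitochondria(field$red, cfg$mitophagy)
  ratio <- ratio_image(field$green, field$red, cfg$ratio$blur, cfg$ratio$eps)
  events <- detect_mitophagy(mito$mito_mask, ratio, field$red, cfg$mitophagy)
  masks <- c(mito, events)
  summ <- cbind(data.frame(field_id = field_id, well_id = well_id,
                           condition = condition),
                mito_volumes(masks, field$pixel_pitch %||% cfg$geometry$pixel_pitch,
                             field$z_step %||% cfg$geometry$z_step))
  out <- list(summary = summ)
  if (keep_masks) out$masks <- masks
  out
}

#' Run the lysotracker workflow on one field
#'
#' @param field `field_stack`; the single lysotracker channel is `green`.
#' @inheritParams process_autophagy_field
#' @return List with `lysosomes` (per-vesicle sizes) and optionally `mask`.
#' @export
process_lysotracker_field <- function(field, config = NULL,
                                      field_id = "field_1", well_id = "well_1",
                                      condition = "basal", keep_masks = FALSE) {
  cfg <- modifyList(pipeline_config(), config %||% list())
  geom <- cfg$geometry
  dec <- .deconvolve_channel(field$green, cfg$preprocess$psf$lysotracker,
                             list(pixel_pitch = field$pixel_pitch %||% geom$pixel_pitch,
                                  z_step = field$z_step %||% geom$z_step),
                             cfg$preprocess$iterations)
  mask <- segment_lysosomes(dec, cfg$lysotracker)
  sizes <- lysosome_sizes(mask, field$pixel_pitch %||% geom$pixel_pitch)
  if (nrow(sizes)) {
    sizes$field_id <- field_id; sizes$well_id <- well_id; sizes$condition <- condition
  }
  out <- list(lysosomes = sizes)
  if (keep_masks) out$mask <- mask
  out
}

#' Batch-run a workflow and write tidy CSV outputs
#'
#' `fields` is a named list of `field_stack` objects (names become field
#' ids) or a data.frame manifest with columns `field_id`, `green`, `red`
#' (TIFF paths) and optional `well_id`, `condition`.
#'
#' @param fields input fields (list or manifest data.frame).
#' @param workflow one of `"autophagy"`, `"mitophagy"`, `"lysotracker"`.
#' @param out_dir output directory (created); per-vesicle and per-field CSVs
#'   plus a YAML config snapshot are written there.
#' @param config optional overrides of [pipeline_config()].
#' @param save_masks write intermediate masks as multi-page TIFFs.
#' @return Invisibly, the list of per-field results.
#' @export
run_workflow <- function(fields, workflow = c("autophagy", "mitophagy", "lysotracker"),
                         out_dir = ".", config = NULL, save_masks = FALSE) {
  workflow <- match.arg(workflow)
  if (is.data.frame(fields)) {
    manifest <- fields
    fields <- lapply(seq_len(nrow(manifest)), function(i) {
      field_stack(read_stack(manifest$green[i]),
                  if ("red" %in% names(manifest) && nzchar(manifest$red[i]))
                    read_stack(manifest$red[i]) else NULL)
    })
    names(fields) <- manifest$field_id
    wells <- manifest$well_id %||% rep("well_1", length(fields))
    conds <- manifest$condition %||% rep("unknown", length(fields))
  } else {
    if (is.null(names(fields))) names(fields) <- sprintf("field_%03d", seq_along(fields))
    wells <- rep("well_1", length(fields))
    conds <- rep("unknown", length(fields))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fun <- switch(workflow,
                autophagy = process_autophagy_field,
                mitophagy = process_mitophagy_field,
                lysotracker = process_lysotracker_field)
  res <- lapply(seq_along(fields), function(i) {
    fun(fields[[i]], config = config, field_id = names(fields)[i],
        well_id = wells[i], condition = conds[i], keep_masks = save_masks)
  })
  names(res) <- names(fields)
  if (workflow == "autophagy") {
    ves <- do.call(rbind, lapply(res, `[[`, "vesicles"))
    summ <- do.call(rbind, lapply(res, `[[`, "summary"))
    write.csv(ves, file.path(out_dir, "vesicles.csv"), row.names = FALSE)
    write.csv(summ, file.path(out_dir, "fields.csv"), row.names = FALSE)
  } else if (workflow == "mitophagy") {
    summ <- do.call(rbind, lapply(res, `[[`, "summary"))
    write.csv(summ, file.path(out_dir, "mitophagy_fields.csv"), row.names = FALSE)
  } else {
    lys <- do.call(rbind, lapply(res, `[[`, "lysosomes"))
    write.csv(lys, file.path(out_dir, "lysosomes.csv"), row.names = FALSE)
  }
  write_config(modifyList(pipeline_config(), config %||% list()),
               file.path(out_dir, "config_snapshot.yaml"))
  if (save_masks) {
    for (i in seq_along(res)) {
      mk <- res[[i]]$masks %||% list(mask = res[[i]]$mask)
      for (nm in names(mk)) {
        v <- mk[[nm]]
        if (is.array(v) && (is.logical(v) || is.integer(v))) {
          write_stack((v != 0) * 65535, file.path(out_dir, sprintf("%s_%s.tif", names(res)[i], nm)))
        }
      }
    }
  }
  invisible(res)
}

#' Condition-level report: per-well means and the scaled heatmap matrix
#'
#' @param field_summaries data.frame of per-field rows (from the autophagy
#'   workflow), with `well_id` and the per-class count columns.
#' @param rescale passed to [normalize_wells()].
#' @return List with `per_well` (mean counts per well) and `heatmap`
#'   (category-mean normalized, 0-2 scaled matrix).
#' @export
report_conditions <- function(field_summaries, rescale = FALSE) {
  if (nrow(field_summaries) == 0) stop("no fields to report")
  cats <- c("n_phagophore", "n_autophagosome", "n_early_autolysosome",
            "n_late_autolysosome", "autophagic_vacuoles", "autophagy_rate")
  wells <- split(field_summaries, field_summaries$well_id)
  per_well <- do.call(rbind, lapply(wells, function(w) {
    cbind(data.frame(well_id = w$well_id[1], condition = w$condition[1],
                     n_fields = nrow(w)),
          as.data.frame(as.list(colMeans(w[cats]))))
  }))
  rownames(per_well) <- NULL
  m <- as.matrix(per_well[cats])
  rownames(m) <- per_well$well_id
  list(per_well = per_well, heatmap = normalize_wells(m, rescale = rescale))
}
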