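# Synthetic dual-channel 3D fields with voxel-level ground truth. The
# generator emulates spinning-disk acquisitions of tandem pH-sensor reporter
# lines: 5-plane (cytosolic reporter) or 11-plane (mitochondria-targeted
# reporter) stacks, 0.2152 um/pixel, 400 nm z-steps, 16-bit graytones.

#' Declarative description of a synthetic field
#'
#' Class signatures follow the tandem-reporter logic: phagophores are small
#' solid bodies bright in both channels; autophagosomes are hollow shells
#' bright in both; early autolysosomes are acidifying vesicles with partial
#' residual green; late autolysosomes are red-only; mitochondria are
#' dual-positive tubules; mitophagy events are red-retaining, green-quenched
#' bodies. Intensities are on the 16-bit camera scale.
#'
#' @param shape `c(ny, nx, nz)` field extent in voxels.
#' @param pixel_pitch,z_step sampling geometry in micrometers.
#' @param n_phagophore,n_autophagosome,n_early,n_late per-class vesicle counts.
#' @param n_cytoplasm number of diffuse cytoplasm patches.
#' @param n_tubules,n_mitophagy mitochondrial tubule and mitophagy-event counts.
#' @param radius_phagophore,radius_autophagosome,radius_early,radius_late,radius_mitophagy
#'   lateral radius ranges in pixels, `c(min, max)`.
#' @param shell_thickness autophagosome rim thickness in pixels.
#' @param tubule_length steps of the tubule random walk (pixels).
#' @param tubule_radius tubule half-width in pixels.
#' @param tortuosity sd (radians) of the tubule direction increments.
#' @param intensities named list of `c(green, red)` levels per class; see
#'   defaults.
#' @param background `c(green, red)` background graytones.
#' @param psf_blur apply channel-specific PSF blur (optics simulation).
#' @param vignette_amplitude relative illumination falloff at the field
#'   corner (0 disables).
#' @param poisson_noise apply Poisson shot noise.
#' @param read_noise_sd Gaussian read noise sd (graytones).
#' @param seed integer RNG seed; identical spec + seed gives identical output.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(shape = c(256, 256, 5),
                       pixel_pitch = PIXEL_PITCH_UM, z_step = Z_STEP_UM,
                       n_phagophore = 20, n_autophagosome = 5, n_early = 5,
                       n_late = 39, n_cytoplasm = 12,
                       n_tubules = 0, n_mitophagy = 0,
                       radius_phagophore = c(2.5, 4),
                       radius_autophagosome = c(6.9, 8.5),
                       radius_early = c(4.5, 6),
                       radius_late = c(3.5, 6),
                       radius_mitophagy = c(2.5, 4),
                       shell_thickness = 1.6,
                       early_model = list(pocket_px = 4, core_frac = 0.55,
                                          pocket_green = 250, periphery_green = 280,
                                          red_sd_frac = 0.7),
                       tubule_length = 60, tubule_radius = 1.2,
                       tortuosity = 0.45,
                       intensities = list(
                         phagophore = c(green = 9000, red = 4000),
                         autophagosome = c(green = 9000, red = 4000),
                         early = c(green = 330, red = 650),
                         late = c(green = 0, red = 6000),
                         cytoplasm = c(green = 1200, red = 500),
                         mito = c(green = 1500, red = 1500),
                         mitophagy = c(green = 60, red = 2500)
                       ),
                       background = c(green = 100, red = 100),
                       psf_blur = TRUE, vignette_amplitude = 0.1,
                       poisson_noise = TRUE, read_noise_sd = 10,
                       seed = 1L) {
  counts <- c(n_phagophore, n_autophagosome, n_early, n_late, n_cytoplasm,
              n_tubules, n_mitophagy)
  if (any(counts < 0)) stop("object counts must be >= 0")
  lv <- unlist(intensities)
  if (any(lv < 0) || any(lv > 65535)) stop("intensity levels must be within the 16-bit range")
  rm(counts, lv)
  spec <- as.list(environment())
  structure(spec, class = "scene_spec")
}

#' @export
print.scene_spec <- function(x, ...) {
  cat("Synthetic field spec:", paste(x$shape, collapse = " x "),
      sprintf("(%.4f um/px, %.2f um z-step), seed %d\n", x$pixel_pitch, x$z_step, x$seed))
  cat(sprintf("  vesicles: %d phagophore, %d autophagosome, %d early, %d late\n",
              x$n_phagophore, x$n_autophagosome, x$n_early, x$n_late))
  if (x$n_tubules > 0 || x$n_mitophagy > 0) {
    cat(sprintf("  mitochondria: %d tubules, %d mitophagy events\n",
                x$n_tubules, x$n_mitophagy))
  }
  invisible(x)
}

# Voxel mask of an anisotropic (lateral radius r px) sphere at (cy,cx,cz);
# returns index vector into the volume.
.sphere_idx <- function(d, cy, cx, cz, r, z_aniso, inner = 0) {
  ry <- ceiling(r); rz <- ceiling(r / z_aniso)
  ys <- max(1, floor(cy - ry)):min(d[1], ceiling(cy + ry))
  xs <- max(1, floor(cx - ry)):min(d[2], ceiling(cx + ry))
  zs <- max(1, floor(cz - rz)):min(d[3], ceiling(cz + rz))
  gy <- (ys - cy); gx <- (xs - cx); gz <- (zs - cz) * z_aniso
  rr <- outer(outer(gy^2, gx^2, "+"), gz^2, "+")
  sel <- rr <= r^2 & rr >= inner^2
  if (!any(sel)) return(integer(0))
  coords <- which(sel, arr.ind = TRUE)
  (ys[coords[, 1]]) + (xs[coords[, 2]] - 1L) * d[1] + (zs[coords[, 3]] - 1L) * d[1] * d[2]
}

# Rejection-sampled object centers: min pairwise lateral distance, border
# margin. Returns matrix (cy, cx, cz, r). Overlaps are tolerated after
# `max_tries` failed draws (objects may then touch).
.place_objects <- function(n, d, rrange, margin, placed, z_aniso, max_tries = 60,
                           zfrac = c(0.25, 0.75)) {
  out <- NULL
  for (i in seq_len(n)) {
    r <- runif(1, rrange[1], rrange[2])
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      cy <- runif(1, margin + r, d[1] - margin - r)
      cx <- runif(1, margin + r, d[2] - margin - r)
      cz <- runif(1, 1 + zfrac[1] * (d[3] - 1), 1 + zfrac[2] * (d[3] - 1))
      if (is.null(placed) || nrow(placed) == 0 ||
          all(sqrt((placed[, 1] - cy)^2 + (placed[, 2] - cx)^2) > (placed[, 4] + r + 3))) {
        ok <- TRUE; break
      }
    }
    row <- c(cy, cx, cz, r)
    placed <- rbind(placed, row)
    out <- rbind(out, row)
  }
  list(new = out, placed = placed)
}

#' Render a synthetic field with ground truth
#'
#' Composes the scene (vesicles, cytoplasm patches, mitochondria, mitophagy
#' events) on the 16-bit graytone scale, then applies optics (channel PSF
#' blur), vignetting, Poisson shot noise and Gaussian read noise. Ground
#' truth references pre-optics geometry.
#'
#' @param spec a [scene_spec()].
#' @return List with `field` (class `field_stack`: `green`, `red` volumes plus
#'   geometry) and `truth` (per-class label volumes, a per-object record
#'   table, and the vignette plane used).
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  d <- as.integer(spec$shape)
  z_aniso <- spec$z_step / spec$pixel_pitch
  green <- array(spec$background[["green"]], d)
  red <- array(spec$background[["red"]], d)
  labels <- list(
    phagophore = array(0L, d), autophagosome = array(0L, d),
    early = array(0L, d), late = array(0L, d),
    mito = array(0L, d), mitophagy = array(0L, d)
  )
  records <- NULL
  placed <- NULL
  margin <- 14
  obj_id <- 0L

  # diffuse cytoplasm patches: broad soft green (and weak red) mounds that
  # give autolysosome candidates their bright-green neighbourhoods
  cyto_centers <- NULL
  if (spec$n_cytoplasm > 0) {
    cy <- runif(spec$n_cytoplasm, margin + 12, d[1] - margin - 12)
    cx <- runif(spec$n_cytoplasm, margin + 12, d[2] - margin - 12)
    rad <- runif(spec$n_cytoplasm, 18, 36)
    cyto_centers <- cbind(cy, cx, rad)
    yy <- matrix(seq_len(d[1]), d[1], d[2])
    xx <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
    cyto <- matrix(0, d[1], d[2])
    for (i in seq_len(spec$n_cytoplasm)) {
      cyto <- pmax(cyto, exp(-((yy - cy[i])^2 + (xx - cx[i])^2) / (2 * (rad[i] / 1.6)^2)))
    }
    zprof <- exp(-((seq_len(d[3]) - (d[3] + 1) / 2)^2) / (2 * (0.45 * d[3])^2))
    for (z in seq_len(d[3])) {
      green[, , z] <- green[, , z] + spec$intensities$cytoplasm[["green"]] * cyto * zprof[z]
      red[, , z] <- red[, , z] + spec$intensities$cytoplasm[["red"]] * cyto * zprof[z]
    }
  }

  record_obj <- function(class, p, n_vox) {
    records <<- rbind(records, data.frame(
      id = obj_id, class = class, z = p[3], y = p[1], x = p[2],
      radius_px = p[4], n_voxels = n_vox
    ))
  }

  # early autolysosomes first: they sit at cytoplasm patch centers inside a
  # locally quenched pocket (green suppressed beyond the vesicle), with mild
  # residual luminal green (partial quenching) and a soft diffuse red mound
  # that passes the red-intensity gate without forming a red vesicle mask
  if (spec$n_early > 0 && !is.null(cyto_centers)) {
    em <- spec$early_model
    lv <- spec$intensities$early
    patch_order <- sample(nrow(cyto_centers))
    placed_e <- 0L
    for (pi in rep(patch_order, length.out = 4 * spec$n_early)) {
      if (placed_e >= spec$n_early) break
      r <- runif(1, spec$radius_early[1], spec$radius_early[2])
      cyv <- cyto_centers[pi, 1] + runif(1, -2, 2)
      cxv <- cyto_centers[pi, 2] + runif(1, -2, 2)
      czv <- 1 + (d[3] - 1) * runif(1, 0.45, 0.55)
      rr <- r + em$pocket_px
      if (!is.null(placed) && nrow(placed) > 0 &&
          any(sqrt((placed[, 1] - cyv)^2 + (placed[, 2] - cxv)^2) < placed[, 4] + rr + 3)) next
      placed <- rbind(placed, c(cyv, cxv, czv, rr))
      placed_e <- placed_e + 1L
      obj_id <- obj_id + 1L
      pocket <- .sphere_idx(d, cyv, cxv, czv, rr, z_aniso)
      ves <- .sphere_idx(d, cyv, cxv, czv, r, z_aniso)
      core <- .sphere_idx(d, cyv, cxv, czv, em$core_frac * r, z_aniso)
      green[pocket] <- em$pocket_green
      green[ves] <- em$periphery_green
      green[core] <- lv[["green"]]
      # soft red mound (Gaussian profile) centred on the vesicle
      ys <- max(1, floor(cyv - rr)):min(d[1], ceiling(cyv + rr))
      xs <- max(1, floor(cxv - rr)):min(d[2], ceiling(cxv + rr))
      zs <- max(1, floor(czv - rr / z_aniso)):min(d[3], ceiling(czv + rr / z_aniso))
      dist2 <- outer(outer((ys - cyv)^2, (xs - cxv)^2, "+"), ((zs - czv) * z_aniso)^2, "+")
      mound <- lv[["red"]] * exp(-dist2 / (2 * (em$red_sd_frac * r)^2))
      red[ys, xs, zs] <- red[ys, xs, zs] + mound
      labels$early[ves] <- obj_id
      record_obj("early", c(cyv, cxv, czv, r), length(ves))
    }
  }

  add_class <- function(class, n, rrange, hollow = FALSE, zfrac = c(0.25, 0.75)) {
    if (n == 0) return(invisible(NULL))
    pl <- .place_objects(n, d, rrange, margin, placed, z_aniso, zfrac = zfrac)
    placed <<- pl$placed
    lv <- spec$intensities[[class]]
    for (i in seq_len(n)) {
      p <- pl$new[i, ]
      obj_id <<- obj_id + 1L
      inner <- if (hollow) max(p[4] - spec$shell_thickness, 0.5) else 0
      idx <- .sphere_idx(d, p[1], p[2], p[3], p[4], z_aniso, inner = inner)
      if (length(idx) == 0) next
      if (class == "late") {
        # fully quenched lumen: green suppressed to background
        green[idx] <<- spec$background[["green"]]
        red[idx] <<- red[idx] + lv[["red"]]
      } else {
        green[idx] <<- green[idx] + lv[["green"]]
        red[idx] <<- red[idx] + lv[["red"]]
      }
      # ground truth marks the full vesicle footprint (filled for shells)
      full <- .sphere_idx(d, p[1], p[2], p[3], p[4], z_aniso)
      labels[[class]][full] <<- obj_id
      record_obj(class, p, length(full))
    }
  }

  add_class("phagophore", spec$n_phagophore, spec$radius_phagophore)
  # hollow shells are imaged at their equator: the 2 um stack cuts the caps
  add_class("autophagosome", spec$n_autophagosome, spec$radius_autophagosome,
            hollow = TRUE, zfrac = c(0.48, 0.52))
  add_class("late", spec$n_late, spec$radius_late)

  # mitochondrial tubules: 2D random walks dilated to the tubule radius,
  # spanning a few central planes; healthy mitochondria carry both channels
  if (spec$n_tubules > 0) {
    lv <- spec$intensities$mito
    for (i in seq_len(spec$n_tubules)) {
      obj_id <- obj_id + 1L
      y <- runif(1, margin, d[1] - margin); x <- runif(1, margin, d[2] - margin)
      th <- runif(1, 0, 2 * pi)
      path <- matrix(0, spec$tubule_length, 2)
      for (s in seq_len(spec$tubule_length)) {
        th <- th + rnorm(1, 0, spec$tortuosity)
        y <- min(max(y + sin(th), 2), d[1] - 1)
        x <- min(max(x + cos(th), 2), d[2] - 1)
        path[s, ] <- c(y, x)
      }
      m <- matrix(0, d[1], d[2])
      m[cbind(round(path[, 1]), round(path[, 2]))] <- 1
      m <- EBImage::dilate(m, disc_brush(ceiling(spec$tubule_radius))) > 0.5
      z0 <- round(runif(1, 1 + d[3] * 0.3, d[3] - d[3] * 0.3))
      zs <- unique(pmin(pmax(z0 + (-1:1), 1), d[3]))
      for (z in zs) {
        idx <- which(m) + (z - 1L) * d[1] * d[2]
        green[idx] <- green[idx] + lv[["green"]]
        red[idx] <- red[idx] + lv[["red"]]
        labels$mito[idx] <- obj_id
      }
      records <- rbind(records, data.frame(
        id = obj_id, class = "mito", z = mean(zs), y = mean(path[, 1]),
        x = mean(path[, 2]), radius_px = spec$tubule_radius,
        n_voxels = sum(m) * length(zs)
      ))
    }
  }

  # mitophagy events: red-retaining, green-quenched bodies detached from the
  # network (mitochondrial cargo inside acidic autolysosomes)
  if (spec$n_mitophagy > 0) {
    lv <- spec$intensities$mitophagy
    for (i in seq_len(spec$n_mitophagy)) {
      # events are mitochondria-derived bodies that have left the network;
      # keep them clear of the rendered tubules so each forms its own body
      p <- NULL
      for (t in 1:200) {
        r <- runif(1, spec$radius_mitophagy[1], spec$radius_mitophagy[2])
        cand <- c(runif(1, margin + r, d[1] - margin - r),
                  runif(1, margin + r, d[2] - margin - r),
                  1 + (d[3] - 1) * runif(1, 0.3, 0.7), r)
        if (!is.null(placed) && nrow(placed) > 0 &&
            any(sqrt((placed[, 1] - cand[1])^2 + (placed[, 2] - cand[2])^2) <
                  placed[, 4] + r + 3)) next
        if (any(labels$mito[.sphere_idx(d, cand[1], cand[2], cand[3], r + 4, z_aniso)] > 0)) next
        p <- cand
        break
      }
      if (is.null(p)) p <- cand
      placed <- rbind(placed, p)
      obj_id <- obj_id + 1L
      idx <- .sphere_idx(d, p[1], p[2], p[3], p[4], z_aniso)
      green[idx] <- spec$background[["green"]] + lv[["green"]]
      red[idx] <- red[idx] + lv[["red"]]
      labels$mitophagy[idx] <- obj_id
      records <- rbind(records, data.frame(
        id = obj_id, class = "mitophagy", z = p[3], y = p[1], x = p[2],
        radius_px = p[4], n_voxels = length(idx)
      ))
    }
  }

  # ---- optics and noise ----
  if (spec$psf_blur) {
    psf_g <- generate_psf(psf_model(520, pixel_pitch = spec$pixel_pitch, z_step = spec$z_step))
    psf_r <- generate_psf(psf_model(600, pixel_pitch = spec$pixel_pitch, z_step = spec$z_step))
    green <- blur_with_psf(green, psf_g)
    red <- blur_with_psf(red, psf_r)
  }
  vign <- matrix(1, d[1], d[2])
  if (spec$vignette_amplitude > 0) {
    yy <- (seq_len(d[1]) - (d[1] + 1) / 2) / (d[1] / 2)
    xx <- (seq_len(d[2]) - (d[2] + 1) / 2) / (d[2] / 2)
    vign <- 1 - spec$vignette_amplitude * outer(yy^2, xx^2, "+") / 2
    green <- green * as.vector(vign)
    red <- red * as.vector(vign)
  }
  if (spec$poisson_noise) {
    green <- array(rpois(length(green), pmax(green, 0)), d)
    red <- array(rpois(length(red), pmax(red, 0)), d)
  }
  if (spec$read_noise_sd > 0) {
    green <- green + rnorm(length(green), 0, spec$read_noise_sd)
    red <- red + rnorm(length(red), 0, spec$read_noise_sd)
  }
  green <- round(pmin(pmax(green, 0), 65535))
  red <- round(pmin(pmax(red, 0), 65535))

  field <- structure(list(green = green, red = red,
                          pixel_pitch = spec$pixel_pitch, z_step = spec$z_step),
                     class = "field_stack")
  truth <- list(labels = labels,
                records = if (is.null(records)) {
                  data.frame(id = integer(0), class = character(0), z = numeric(0),
                             y = numeric(0), x = numeric(0), radius_px = numeric(0),
                             n_voxels = integer(0))
                } else records,
                vignette = vign, spec = spec)
  list(field = field, truth = truth)
}

# Convolve a volume with a PSF (circular FFT after reflective padding).
blur_with_psf <- function(vol, psf) {
  v <- as_volume(vol)
  psf <- as_volume(psf)
  pad <- .fft_pad(dim(v), dim(psf))
  vp <- .pad_reflect3(v, pad)
  d <- dim(vp)
  out <- .conv3_otf(stats::fft(vp), .psf_to_otf(psf, d), prod(d))
  out[pad[1] + seq_len(dim(v)[1]), pad[2] + seq_len(dim(v)[2]),
      pad[3] + seq_len(dim(v)[3]), drop = FALSE]
}

#' @export
print.field_stack <- function(x, ...) {
  d <- dim(x$green)
  cat(sprintf("field_stack: %d x %d x %d voxels, %.4f um/px, %.2f um z-step\n",
              d[1], d[2], d[3], x$pixel_pitch, x$z_step))
  invisible(x)
}

#' Deterministic batteries of reference fields
#'
#' Named conditions used by the validation suite: `"basal"` (mixture
#' dominated by phagophores and late autolysosomes, transient intermediates
#' at low frequency), `"chloroquine-like"` (lysosomal-inhibition pattern:
#' phagophore/autophagosome-enriched) and `"CCCP-like"` (mitochondrial
#' depolarisation: 11-plane fields, mitophagy-enriched).
#'
#' @param config condition name.
#' @param n_fields number of fields to render.
#' @param seed base seed; field i uses `seed * 1000 + i`.
#' @param shape optional field shape override.
#' @return List of `render_scene()` results.
#' @export
render_suite <- function(config = c("basal", "chloroquine-like", "CCCP-like"),
                         n_fields = 10, seed = 1L, shape = NULL) {
  config <- match.arg(config)
  base <- switch(config,
    "basal" = list(),
    "chloroquine-like" = list(n_phagophore = 40, n_autophagosome = 14,
                              n_early = 6, n_late = 12),
    "CCCP-like" = c(list(n_tubules = 22, n_mitophagy = 8), .mito_field_base())
  )
  if (config == "basal") base$shape <- c(256, 256, 5)
  if (!is.null(shape)) base$shape <- shape
  lapply(seq_len(n_fields), function(i) {
    base$seed <- as.integer(seed * 1000 + i)
    render_scene(do.call(scene_spec, base))
  })
}

#' Synthetic lysotracker field
#'
#' Single-channel 11-plane stack of solid acidic vesicles (the lysotracker
#' channel is returned as the `green` member of the field stack with `red`
#' empty). Ground truth as in [render_scene()].
#'
#' @param n_vesicles number of lysosomes.
#' @param radius lateral radius range in pixels.
#' @param seed RNG seed.
#' @param shape field shape.
#' @return As [render_scene()], with a single-channel field.
#' @export
render_lysotracker_field <- function(n_vesicles = 25, radius = c(2.5, 5),
                                     seed = 1L, shape = c(256, 256, 11)) {
  sc <- render_scene(scene_spec(
    shape = shape, n_phagophore = n_vesicles, n_autophagosome = 0, n_early = 0,
    n_late = 0, n_cytoplasm = 4, radius_phagophore = radius, seed = seed
  ))
  sc$field$red <- NULL
  names(sc$truth$labels)[names(sc$truth$labels) == "phagophore"] <- "lysosome"
  sc$truth$records$class[sc$truth$records$class == "phagophore"] <- "lysosome"
  sc
}

# Shared settings of the mitochondria-reporter acquisitions: 11 planes and
# a dim-intensity regime (the narrow-band mitochondrial DoG threshold of 12
# graytones presumes low signal levels, where shot noise stays well below
# the detection band).
.mito_field_base <- function() {
  list(shape = c(256, 256, 11), n_phagophore = 0, n_autophagosome = 0,
       n_early = 0, n_late = 0, n_cytoplasm = 6,
       background = c(green = 12, red = 12), read_noise_sd = 2,
       intensities = list(
         phagophore = c(green = 0, red = 0),
         autophagosome = c(green = 0, red = 0),
         early = c(green = 0, red = 0),
         late = c(green = 0, red = 0),
         cytoplasm = c(green = 80, red = 30),
         mito = c(green = 200, red = 200),
         mitophagy = c(green = 5, red = 300)
       ))
}

#' Basal-condition mitochondrial battery
#'
#' 11-plane fields with the basal mitophagy load (same tubule density as the
#' CCCP-like battery, fewer events).
#'
#' @inheritParams render_suite
#' @export
render_mito_basal <- function(n_fields = 10, seed = 1L, shape = c(256, 256, 11)) {
  base <- .mito_field_base()
  base$shape <- shape
  base$n_tubules <- 22
  base$n_mitophagy <- 3
  lapply(seq_len(n_fields), function(i) {
    base$seed <- as.integer(seed * 1000 + 500 + i)
    render_scene(do.call(scene_spec, base))
  })
}
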