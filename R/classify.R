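# Vesicle pooling, feature extraction, the progressive-exclusion decision
# tree into four autophagy stages, and per-field summary statistics.

#' Pool all vesicle detections into a labelled volume
#'
#' All detection masks are OR-combined; the per-plane perimeter of the
#' autophagosome mask is carved out first so watershed/ring splits survive
#' the union. Components are 26-connected; only components with mean raw red
#' intensity above `mean_red_min` and no voxel on the lateral image border
#' are kept.
#'
#' @param all_masks binary volume: union of every vesicle detection.
#' @param autophagosome_mask binary volume from
#'   [shape_filter_autophagosomes()].
#' @param dsred_raw raw red volume.
#' @param mean_red_min red-intensity gate (graytones).
#' @param min_volume smallest pooled component kept (voxels); matches the
#'   minimum-component rule of the channel masks.
#' @return Integer label volume (relabelled 1..n).
#' @export
pool_vesicles <- function(all_masks, autophagosome_mask, dsred_raw,
                          mean_red_min = 300, min_volume = 10) {
  pooled <- as_volume(all_masks != 0) | as_volume(autophagosome_mask != 0)
  # perimeter band (boundary plus a 1-px outer margin): a single-voxel cut
  # leaks under 26-connectivity through diagonal hops
  ap <- as_volume(autophagosome_mask != 0)
  band <- dilate_disc(ap, 1) & !erode_disc(ap, 1)
  pooled <- pooled & !band
  lab <- label_components(pooled, 26L)
  n <- max(lab)
  if (n == 0L) return(lab)
  sz <- component_sizes(lab)
  mred <- label_means(lab, as_volume(dsred_raw))
  border <- labels_touching_border(lab)
  keep <- setdiff(which(mred > mean_red_min & sz >= min_volume), border)
  lab[!(lab %in% keep)] <- 0L
  lab[lab > 0L] <- match(lab[lab > 0L], sort(unique(lab[lab > 0L])))
  lab
}

# Second-moment ellipse of a set of (y, x) points: eccentricity and
# major-axis length (regionprops conventions: axes from the ellipse with the
# same normalized second central moments).
.moments_ellipse <- function(y, x) {
  my <- mean(y); mx <- mean(x)
  m20 <- mean((y - my)^2) + 1 / 12
  m02 <- mean((x - mx)^2) + 1 / 12
  m11 <- mean((y - my) * (x - mx))
  tr <- m20 + m02
  dd <- sqrt((m20 - m02)^2 + 4 * m11^2)
  l1 <- (tr + dd) / 2
  l2 <- (tr - dd) / 2
  c(eccentricity = sqrt(max(0, 1 - l2 / l1)),
    major_axis = 4 * sqrt(l1), minor_axis = 4 * sqrt(max(0, l2)))
}

#' Mask of elongated (non-circular) vesicles
#'
#' Eccentricity of the second-moment ellipse of each component's z-maximum
#' projection; components with eccentricity above `threshold` form the mask.
#'
#' @param labels label volume from [pool_vesicles()].
#' @param threshold eccentricity cut (default 0.9).
#' @return Binary volume.
#' @export
compute_noncircular_mask <- function(labels, threshold = 0.9) {
  lab <- as_volume(labels)
  n <- max(lab)
  out <- array(FALSE, dim(lab))
  if (n == 0) return(out)
  idx <- which(lab > 0L)
  d <- dim(lab)
  yy <- ((idx - 1) %% d[1]) + 1
  xx <- (((idx - 1) %/% d[1]) %% d[2]) + 1
  ll <- lab[idx]
  for (l in seq_len(n)) {
    sel <- ll == l
    pts <- unique(cbind(yy[sel], xx[sel]))
    if (nrow(pts) < 2) next
    e <- .moments_ellipse(pts[, 1], pts[, 2])
    if (e["eccentricity"] > threshold) out[idx[sel]] <- TRUE
  }
  out
}

#' Per-vesicle feature table
#'
#' Extracts, for every pooled component, the geometric and intensity
#' features the decision tree consumes: volume (voxels and um^3), centroid,
#' mean/3rd-quartile raw intensities, median ratio, overlap fractions
#' (|component intersect mask| / |component|) against the channel masks, the
#' autolysosome rescue mask, the autophagosome mask and the non-circular
#' mask, center and surface green means (center: erosion by the radius-1
#' ball; surface: the eroded-away shell; both fall back to the whole
#' component when the erosion is empty), eccentricity and major axis of the
#' projection, and border contact.
#'
#' @param labels label volume from [pool_vesicles()].
#' @param masks list with `phluorin_mask`, `dsred_mask`, `autolyso_mask`.
#' @param autophagosome_mask,noncircular_mask binary volumes.
#' @param ratio ratio volume.
#' @param green_raw,red_raw raw channel volumes.
#' @param pixel_pitch,z_step geometry (micrometers).
#' @return data.frame, one row per vesicle.
#' @export
vesicle_features <- function(labels, masks, autophagosome_mask, noncircular_mask,
                             ratio, green_raw, red_raw,
                             pixel_pitch = PIXEL_PITCH_UM, z_step = Z_STEP_UM) {
  lab <- as_volume(labels)
  n <- max(lab)
  cols <- c("label", "volume_vox", "volume_um3", "z", "y", "x",
            "mean_red_raw", "mean_green_raw", "q3_green", "q3_red",
            "median_ratio", "overlap_phluorin", "overlap_dsred",
            "overlap_autolyso", "overlap_autophagosome", "overlap_noncircular",
            "center_green", "surface_green", "eccentricity", "major_axis_um",
            "touches_border")
  if (n == 0) {
    df <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
    df$touches_border <- logical(0)
    return(df)
  }
  d <- dim(lab)
  idx <- which(lab > 0L)
  ll <- lab[idx]
  yy <- ((idx - 1) %% d[1]) + 1
  xx <- (((idx - 1) %/% d[1]) %% d[2]) + 1
  zz <- ((idx - 1) %/% (d[1] * d[2])) + 1
  g <- as_volume(green_raw); r <- as_volume(red_raw); rat <- as_volume(ratio)
  phl <- as_volume(masks$phluorin_mask != 0)
  dsr <- as_volume(masks$dsred_mask != 0)
  aly <- as_volume(masks$autolyso_mask != 0)
  apm <- as_volume(autophagosome_mask != 0)
  ncm <- as_volume(noncircular_mask != 0)
  core <- erode_ball1(lab > 0L)
  border_labels <- labels_touching_border(lab)
  vox_um3 <- pixel_pitch^2 * z_step
  rows <- vector("list", n)
  for (l in seq_len(n)) {
    sel <- ll == l
    vi <- idx[sel]
    gv <- g[vi]; rv <- r[vi]
    ctr <- core[vi]
    center_green <- if (any(ctr)) mean(gv[ctr]) else mean(gv)
    surface_green <- if (any(ctr) && any(!ctr)) mean(gv[!ctr]) else mean(gv)
    em <- .moments_ellipse(yy[sel], xx[sel])
    rows[[l]] <- data.frame(
      label = l, volume_vox = length(vi), volume_um3 = length(vi) * vox_um3,
      z = mean(zz[sel]), y = mean(yy[sel]), x = mean(xx[sel]),
      mean_red_raw = mean(rv), mean_green_raw = mean(gv),
      q3_green = unname(stats::quantile(gv, 0.75)),
      q3_red = unname(stats::quantile(rv, 0.75)),
      median_ratio = stats::median(rat[vi]),
      overlap_phluorin = mean(phl[vi]), overlap_dsred = mean(dsr[vi]),
      overlap_autolyso = mean(aly[vi]), overlap_autophagosome = mean(apm[vi]),
      overlap_noncircular = mean(ncm[vi]),
      center_green = center_green, surface_green = surface_green,
      eccentricity = unname(em["eccentricity"]),
      major_axis_um = unname(em["major_axis"]) * pixel_pitch,
      touches_border = l %in% border_labels
    )
  }
  do.call(rbind, rows)
}

#' Stage vesicles by progressive exclusion
#'
#' Applies the four-way decision tree to a feature table (see
#' [vesicle_features()]). Order: autophagosome, phagophore, late
#' autolysosome, early autolysosome; vesicles failing every rule are kept as
#' `"unclassified"`.
#'
#' * autophagosome: overlaps the autophagosome mask, no overlap with the
#'   non-circular mask.
#' * phagophore: (>= 25% overlap with both channel masks, median ratio > 2,
#'   no autolysosome-mask overlap) OR (green Q3 > 7500 and red Q3 > 4000) OR
#'   (center green >= 1.25 x surface green).
#' * late autolysosome: (>= 25% red overlap AND (green overlap < 10% OR
#'   median ratio <= 2)) OR center green < surface green.
#' * early autolysosome: (>= 25% red overlap and <= 25% green overlap) OR
#'   any autolysosome-mask overlap.
#'
#' @param features data.frame with the columns produced by
#'   [vesicle_features()] (only the predicate columns are required).
#' @return The input with a `class` factor column appended.
#' @export
classify_vesicles <- function(features) {
  f <- features
  n <- nrow(f)
  cls <- rep("unclassified", n)
  is_ap <- f$overlap_autophagosome > 0 & f$overlap_noncircular == 0
  ph1 <- f$overlap_phluorin >= 0.25 & f$overlap_dsred >= 0.25 &
    f$median_ratio > 2 & f$overlap_autolyso == 0
  ph2 <- f$q3_green > 7500 & f$q3_red > 4000
  ph3 <- f$center_green >= 1.25 * f$surface_green
  is_ph <- !is_ap & (ph1 | ph2 | ph3)
  la1 <- f$overlap_dsred >= 0.25 & (f$overlap_phluorin < 0.10 | f$median_ratio <= 2)
  la2 <- f$center_green < f$surface_green
  is_la <- !is_ap & !is_ph & (la1 | la2)
  ea1 <- f$overlap_dsred >= 0.25 & f$overlap_phluorin <= 0.25
  ea2 <- f$overlap_autolyso > 0
  is_ea <- !is_ap & !is_ph & !is_la & (ea1 | ea2)
  cls[is_ea] <- "early_autolysosome"
  cls[is_la] <- "late_autolysosome"
  cls[is_ph] <- "phagophore"
  cls[is_ap] <- "autophagosome"
  f$class <- factor(cls, levels = c("phagophore", "autophagosome",
                                    "early_autolysosome", "late_autolysosome",
                                    "unclassified"))
  f
}

#' Per-field summary statistics
#'
#' Counts per class, the autophagic-vacuole count (autophagosomes + early
#' autolysosomes + late autolysosomes) and the autophagy rate-constant
#' (phagophores / autophagic vacuoles; 0 and flagged undefined when there
#' are no vacuoles).
#'
#' @param records classified feature table from [classify_vesicles()].
#' @param field_id,well_id,condition identifiers carried into the summary.
#' @return One-row data.frame of class `field_summary`.
#' @export
summarize_field <- function(records, field_id = NA_character_,
                            well_id = NA_character_, condition = NA_character_) {
  lev <- c("phagophore", "autophagosome", "early_autolysosome",
           "late_autolysosome", "unclassified")
  cls <- factor(as.character(records$class), levels = lev)
  cnt <- as.integer(table(cls))
  names(cnt) <- lev
  vac <- cnt[["autophagosome"]] + cnt[["early_autolysosome"]] + cnt[["late_autolysosome"]]
  rate_defined <- vac > 0
  rate <- if (rate_defined) cnt[["phagophore"]] / vac else 0
  out <- data.frame(
    field_id = field_id, well_id = well_id, condition = condition,
    n_phagophore = cnt[["phagophore"]], n_autophagosome = cnt[["autophagosome"]],
    n_early_autolysosome = cnt[["early_autolysosome"]],
    n_late_autolysosome = cnt[["late_autolysosome"]],
    n_unclassified = cnt[["unclassified"]],
    n_vesicles_total = nrow(records),
    autophagic_vacuoles = vac,
    autophagy_rate = rate, autophagy_rate_defined = rate_defined
  )
  class(out) <- c("field_summary", class(out))
  out
}

#' @export
print.field_summary <- function(x, ...) {
  for (i in seq_len(nrow(x))) {
    cat(sprintf(
      "field %s: %d vesicles | ph %d, ap %d, ea %d, la %d (uncl %d) | vacuoles %d, rate %s\n",
      x$field_id[i], x$n_vesicles_total[i], x$n_phagophore[i], x$n_autophagosome[i],
      x$n_early_autolysosome[i], x$n_late_autolysosome[i], x$n_unclassified[i],
      x$autophagic_vacuoles[i],
      if (x$autophagy_rate_defined[i]) sprintf("%.3f", x$autophagy_rate[i]) else "undefined"
    ))
  }
  invisible(x)
}

#' Category-mean normalization of per-well counts
#'
#' Each well's count is divided by the mean of its category (column) over
#' all wells, then clipped to the 0.0-2.0 display range (heatmap scaling).
#' Categories with zero mean are dropped with a warning. `rescale = TRUE`
#' min-max rescales each category to [0, 2] instead of clipping.
#'
#' @param per_well_counts numeric matrix, wells x categories.
#' @param rescale use min-max rescaling instead of clipping.
#' @return Scaled matrix in [0, 2].
#' @export
normalize_wells <- function(per_well_counts, rescale = FALSE) {
  m <- as.matrix(per_well_counts)
  mu <- colMeans(m)
  bad <- which(mu == 0)
  if (length(bad)) {
    warning("dropping categories with zero mean: ",
            paste(colnames(m)[bad] %||% bad, collapse = ", "))
    m <- m[, -bad, drop = FALSE]
    mu <- mu[-bad]
  }
  s <- sweep(m, 2, mu, "/")
  if (rescale) {
    rng <- apply(s, 2, function(v) diff(range(v)))
    s <- sweep(sweep(s, 2, apply(s, 2, min), "-"), 2, pmax(rng, .Machine$double.eps), "/") * 2
  } else {
    s[s > 2] <- 2
    s[s < 0] <- 0
  }
  s
}
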