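# Synthetic two-modality microscopy scenes with planted ground truth.
#
# Each scene emulates the acquisition protocol for jaw-transparency and
# iridophore measurements: a transmitted-light blank ("control") image of the
# dish, a transmitted-light image with the tissue in place, and a
# reflected-light image in which iridophores appear as bright blobs on a dark
# background. Illumination is a smooth field shared exactly by the control
# and sample exposures of one scene; optional per-image gain factors emulate
# the acquisition-to-acquisition brightness drift that peripheral calibration
# exists to cancel.

run_with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Parameters of one synthetic scene
#'
#' All intensity-like quantities (`illumination_base`, `iridophore_reflectance`,
#' `reflected_background`, `noise_sd`) are fractions of the dynamic range in
#' `[0, 1]`; `tissue_transmittance` is the fraction of transmitted light the
#' tissue passes. `illumination_gradient` is the dimensionless peak-to-centre
#' relative slope of the smooth illumination field (`shape` selects a linear
#' ramp or a radial falloff).
#'
#' @param image_height,image_width scene size in pixels.
#' @param bit_depth 8 or 16.
#' @param illumination_base mean illumination as a fraction of dynamic range.
#' @param illumination_gradient relative amplitude of the smooth field.
#' @param illumination_shape `"linear"` or `"radial"`.
#' @param tissue_transmittance fraction in `[0, 1]`; group-dependent.
#' @param iridophore_count number of planted disks (>= 0).
#' @param iridophore_radius_range length-2 numeric, disk radii in pixels.
#' @param iridophore_reflectance blob intensity fraction under reflected light.
#' @param reflected_background background intensity fraction, reflected light.
#' @param noise_sd additive Gaussian noise SD as a fraction of dynamic range.
#' @param seed integer RNG seed for this scene.
#' @return An object of class `scene_params`.
#' @export
scene_params <- function(image_height = 96L, image_width = 96L,
                         bit_depth = 16L,
                         illumination_base = 0.7,
                         illumination_gradient = 0.1,
                         illumination_shape = c("linear", "radial"),
                         tissue_transmittance = 0.9,
                         iridophore_count = 0L,
                         iridophore_radius_range = c(4, 5.5),
                         iridophore_reflectance = 0.9,
                         reflected_background = 0.1,
                         noise_sd = 0.01,
                         seed = 1L) {
  illumination_shape <- match.arg(illumination_shape)
  p <- list(image_height = as.integer(image_height),
            image_width = as.integer(image_width),
            bit_depth = as.integer(bit_depth),
            illumination_base = illumination_base,
            illumination_gradient = illumination_gradient,
            illumination_shape = illumination_shape,
            tissue_transmittance = tissue_transmittance,
            iridophore_count = as.integer(iridophore_count),
            iridophore_radius_range = as.numeric(iridophore_radius_range),
            iridophore_reflectance = iridophore_reflectance,
            reflected_background = reflected_background,
            noise_sd = noise_sd,
            seed = as.integer(seed))
  if (p$image_height < 32L || p$image_width < 32L)
    stop("scene must be at least 32 x 32 pixels", call. = FALSE)
  if (!p$bit_depth %in% c(8L, 16L))
    stop("bit_depth must be 8 or 16", call. = FALSE)
  fracs <- c(illumination_base = p$illumination_base,
             tissue_transmittance = p$tissue_transmittance,
             iridophore_reflectance = p$iridophore_reflectance,
             reflected_background = p$reflected_background,
             noise_sd = p$noise_sd)
  bad <- fracs < 0 | fracs > 1
  if (any(bad))
    stop("parameter(s) outside [0, 1]: ",
         paste(names(fracs)[bad], collapse = ", "), call. = FALSE)
  if (p$iridophore_count < 0L)
    stop("iridophore_count must be >= 0", call. = FALSE)
  if (length(p$iridophore_radius_range) != 2L ||
      any(p$iridophore_radius_range <= 0) ||
      diff(p$iridophore_radius_range) < 0)
    stop("iridophore_radius_range must be increasing positive radii",
         call. = FALSE)
  structure(p, class = "scene_params")
}

# Standard scene geometry: two peripheral calibration rectangles in the top
# corners (sample-free), one central measurement rectangle over the tissue.
scene_roi_polygons <- function(h, w) {
  pw <- max(8L, round(w / 8)); ph <- max(8L, round(h / 8))
  list(
    peripheral_1 = rect_polygon(2, 2, 2 + pw, 2 + ph),
    peripheral_2 = rect_polygon(w - 2 - pw, 2, w - 2, 2 + ph),
    measurement  = rect_polygon(round(w * 0.2), round(h * 0.3),
                                round(w * 0.8), round(h * 0.9))
  )
}

scene_rois <- function(h, w) {
  polys <- scene_roi_polygons(h, w)
  roi_set(lapply(polys, rasterize_polygon, width = w, height = h))
}

illumination_field <- function(p) {
  h <- p$image_height; w <- p$image_width
  xn <- matrix(rep((seq_len(w) - 0.5) / w - 0.5, each = h), nrow = h)
  yn <- matrix(rep((seq_len(h) - 0.5) / h - 0.5, times = w), nrow = h)
  f <- if (p$illumination_shape == "linear") {
    1 + p$illumination_gradient * (xn + yn)
  } else {
    1 - p$illumination_gradient * sqrt(xn^2 + yn^2) * 2
  }
  pmax(pmin(p$illumination_base * f, 1), 0)
}

# Place disk centres uniformly such that each disk (plus its 1-px
# anti-aliasing band) lies inside the measurement rectangle; the peripheral
# areas are outside that rectangle by construction, so blobs can never
# overlap them.
place_blobs <- function(p) {
  if (p$iridophore_count == 0L)
    return(matrix(numeric(0), ncol = 3,
                  dimnames = list(NULL, c("x", "y", "r"))))
  polys <- scene_roi_polygons(p$image_height, p$image_width)
  m <- polys$measurement
  x0 <- min(m[, "x"]); x1 <- max(m[, "x"])
  y0 <- min(m[, "y"]); y1 <- max(m[, "y"])
  r <- stats::runif(p$iridophore_count,
                    p$iridophore_radius_range[1], p$iridophore_radius_range[2])
  pad <- r + 1
  cx <- stats::runif(p$iridophore_count, x0 + pad, x1 - pad)
  cy <- stats::runif(p$iridophore_count, y0 + pad, y1 - pad)
  cbind(x = cx, y = cy, r = r)
}

# Signed-distance anti-aliasing: per-pixel blob coverage ramps linearly from
# 0 to 1 over a 1-pixel band centred on the disk edge, so coverage > 1/2
# exactly when the pixel centre is strictly inside the disk. The planted
# truth mask uses that same centre-in-disk rule, which keeps
# default-threshold segmentation and ground truth consistent by construction.
blob_coverage <- function(blobs, h, w) {
  cov <- matrix(0, h, w)
  mask <- matrix(FALSE, h, w)
  if (nrow(blobs) == 0L) return(list(coverage = cov, mask = mask))
  px <- matrix(rep(seq_len(w) - 0.5, each = h), nrow = h)
  py <- matrix(rep(seq_len(h) - 0.5, times = w), nrow = h)
  for (i in seq_len(nrow(blobs))) {
    d <- sqrt((px - blobs[i, "x"])^2 + (py - blobs[i, "y"])^2)
    cov <- pmax(cov, pmax(pmin(blobs[i, "r"] - d + 0.5, 1), 0))
    mask <- mask | (d < blobs[i, "r"])
  }
  list(coverage = cov, mask = mask)
}

#' Render one synthetic scene
#'
#' Forward model: `control = gain_control * L`, `sample = gain_sample * L * T`
#' where `L` is the shared illumination field and `T` the transmittance field
#' (equal to `tissue_transmittance` inside the measurement region, 1
#' elsewhere); the reflected image is a flat background with planted
#' anti-aliased iridophore disks. Additive Gaussian noise (SD `noise_sd` of
#' dynamic range) is applied independently per image and the result clipped
#' to the dynamic range. With `noise_sd = 0` intensities stay continuous, so
#' the transparency pipeline recovers the planted transmittance to floating
#' point accuracy. Identical parameters and seed give bit-identical scenes.
#'
#' @param params a [scene_params].
#' @param subject_id subject identifier attached to the scene.
#' @param group_label group label (e.g. `"female"`, `"male"`).
#' @param gain_control,gain_sample per-image global brightness multipliers
#'   (> 0) emulating acquisition drift; peripheral calibration must cancel
#'   them.
#' @return An object of class `scene`: images `control_transmitted`,
#'   `sample_transmitted`, `sample_reflected` ([gray_image]), the planted
#'   `truth_transparency_field` (fractions) and `truth_iridophore_mask`
#'   (logical), the `rois`, and identifiers.
#' @export
render_scene <- function(params, subject_id = "s1", group_label = "g1",
                         gain_control = 1, gain_sample = 1) {
  stopifnot(inherits(params, "scene_params"))
  if (gain_control <= 0 || gain_sample <= 0)
    stop("gain factors must be positive", call. = FALSE)
  h <- params$image_height; w <- params$image_width
  maxval <- 2^params$bit_depth - 1
  rois <- scene_rois(h, w)
  L <- illumination_field(params)
  tfield <- matrix(1, h, w)
  tfield[rois$masks$measurement] <- params$tissue_transmittance

  run_with_seed(params$seed, {
    blobs <- place_blobs(params)
    bc <- blob_coverage(blobs, h, w)
    refl <- params$reflected_background +
      bc$coverage * (params$iridophore_reflectance - params$reflected_background)
    noisy <- function(frac) {
      x <- frac * maxval
      if (params$noise_sd > 0)
        x <- x + stats::rnorm(length(x), 0, params$noise_sd * maxval)
      gray_image(matrix(pmin(pmax(x, 0), maxval), h, w), params$bit_depth)
    }
    structure(list(
      control_transmitted = noisy(pmin(L * gain_control, 1)),
      sample_transmitted = noisy(pmin(L * tfield * gain_sample, 1)),
      sample_reflected = noisy(refl),
      truth_transparency_field = tfield,
      truth_iridophore_mask = bc$mask,
      blobs = blobs,
      rois = rois,
      roi_polygons = scene_roi_polygons(h, w),
      subject_id = subject_id,
      group_label = group_label,
      params = params
    ), class = "scene")
  })
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf(
    "<scene %s (%s): %d x %d, transmittance %.2f, %d iridophore blob(s), truth fraction %.2f%%>\n",
    x$subject_id, x$group_label,
    nrow(x$truth_iridophore_mask), ncol(x$truth_iridophore_mask),
    x$params$tissue_transmittance, nrow(x$blobs),
    truth_fraction(x)))
  invisible(x)
}

#' Planted iridophore area fraction of a scene
#'
#' Percentage of measurement-region pixels whose centre lies inside a
#' planted disk — the exact ground truth the segmentation step is judged
#' against.
#'
#' @param scene a [render_scene] result.
#' @return percent in `[0, 100]`.
#' @export
truth_fraction <- function(scene) {
  m <- scene$rois$masks$measurement
  100 * sum(scene$truth_iridophore_mask & m) / sum(m)
}

#' Cohort design for synthetic experiments
#'
#' Describes per-group scene counts and parameter overrides, and (optionally)
#' per-group location/scale for direct numeric simulation of measurement
#' tables via [generate_measurement_table].
#'
#' @param groups list of lists with fields `label`, `n`, and optional
#'   `params` (named overrides applied to `base_params`).
#' @param base_params a [scene_params] providing shared defaults.
#' @param measurement_effects optional named list: measure name -> list of
#'   per-group `list(mean =, sd =)` entries named by group label.
#' @param seed master seed; per-subject seeds derive deterministically.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(groups, base_params = scene_params(),
                          measurement_effects = NULL, seed = 1L) {
  labels <- vapply(groups, `[[`, "", "label")
  if (anyDuplicated(labels))
    stop("group labels must be unique", call. = FALSE)
  ns <- vapply(groups, function(g) as.integer(g$n), 0L)
  if (any(ns < 1L))
    stop("each group needs n >= 1", call. = FALSE)
  structure(list(groups = groups, base_params = base_params,
                 measurement_effects = measurement_effects,
                 seed = as.integer(seed)),
            class = "cohort_design")
}

subject_seed <- function(master, index) {
  as.integer((as.double(master) + 104729 * index) %% 2147483647)
}

#' Generate a cohort of scenes
#'
#' One scene per subject; subject ids are `<label>_<i>` and per-subject seeds
#' are derived deterministically from the design seed, so the same design
#' reproduces bit-identical scene sets.
#'
#' @param design a [cohort_design].
#' @return list of [render_scene] scenes.
#' @export
generate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  scenes <- list()
  k <- 0L
  for (g in design$groups) {
    for (i in seq_len(g$n)) {
      k <- k + 1L
      p <- design$base_params
      for (nm in names(g$params)) p[[nm]] <- g$params[[nm]]
      p$seed <- subject_seed(design$seed, k)
      p <- do.call(scene_params, p[setdiff(names(p), character(0))])
      sid <- paste0(g$label, "_", i)
      scenes[[sid]] <- render_scene(p, subject_id = sid,
                                    group_label = g$label)
    }
  }
  if (anyDuplicated(names(scenes)))
    stop("duplicate subject ids in cohort", call. = FALSE)
  scenes
}

#' Simulate a long-format measurement table directly
#'
#' Draws per-subject values from the per-group Gaussian location/scale
#' specifications in `design$measurement_effects`, bypassing image rendering.
#' Used for calibrating and stress-testing the statistics layer at arbitrary
#' sample sizes.
#'
#' @param design a [cohort_design] with `measurement_effects` set.
#' @return a `data.frame` with columns `subject_id`, `group_label`,
#'   `region_label`, `measure_name`, `value`, `units`.
#' @export
generate_measurement_table <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  eff <- design$measurement_effects
  if (is.null(eff))
    stop("design has no measurement_effects", call. = FALSE)
  run_with_seed(design$seed, {
    rows <- list()
    for (measure in names(eff)) {
      spec <- eff[[measure]]
      for (g in design$groups) {
        e <- spec[[g$label]]
        if (is.null(e))
          stop("no effect specification for group '", g$label,
               "' in measure '", measure, "'", call. = FALSE)
        vals <- stats::rnorm(g$n, e$mean, e$sd)
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = paste0(g$label, "_", seq_len(g$n)),
          group_label = g$label,
          region_label = "simulated",
          measure_name = measure,
          value = vals,
          units = if (is.null(e$units)) "a.u." else e$units,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

#' Write a scene to disk
#'
#' Writes the three modality images as grayscale TIFF, the ROI polygons as
#' JSON, the planted iridophore mask as an 8-bit PNG and the remaining truth
#' (transmittance, area fraction, seed) as JSON metadata.
#'
#' @param scene a [render_scene] result.
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- file.path(dir, scene$subject_id)
  paths <- c(control = paste0(stem, "_control.tif"),
             sample = paste0(stem, "_sample.tif"),
             reflected = paste0(stem, "_reflected.tif"),
             rois = paste0(stem, "_rois.json"),
             truth_mask = paste0(stem, "_truth_mask.png"),
             truth = paste0(stem, "_truth.json"))
  write_image(scene$control_transmitted, paths[["control"]])
  write_image(scene$sample_transmitted, paths[["sample"]])
  write_image(scene$sample_reflected, paths[["reflected"]])
  write_rois(scene$roi_polygons, paths[["rois"]])
  write_image(gray_image(ifelse(scene$truth_iridophore_mask, 255, 0), 8L),
              paths[["truth_mask"]])
  jsonlite::write_json(list(subject_id = scene$subject_id,
                            group_label = scene$group_label,
                            tissue_transmittance = scene$params$tissue_transmittance,
                            truth_fraction = truth_fraction(scene),
                            seed = scene$params$seed),
                       paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
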