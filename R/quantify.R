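# Calibrated transparency, iridophore area fraction, GSI and the DEG filter.

#' Peripheral illumination calibration factor
#'
#' Transmitted-light acquisitions drift slightly in overall brightness from
#' exposure to exposure. Two sample-free peripheral areas shared by the
#' sample and control images estimate that drift: for each area the ratio
#' (mean control intensity) / (mean sample intensity) is computed, and the
#' calibration factor is the mean of the two area-level ratios. Multiplying
#' the raw sample/control intensity ratio by this factor cancels any global
#' brightness change in either image exactly.
#'
#' The alternative `"ratio_of_means"` reading — the ratio of the pooled
#' peripheral mean intensities — is selectable; the two differ when the two
#' areas have unequal brightness or size (see the methods vignette).
#'
#' @param sample,control [gray_image] pair (validated).
#' @param rois [roi_set] with non-empty `peripheral_1`/`peripheral_2`.
#' @param method `"area_ratios"` (default) or `"ratio_of_means"`.
#' @return An object of class `calibration_factor` with fields `value` and
#'   `per_area_ratios`.
#' @export
peripheral_calibration <- function(sample, control, rois,
                                   method = c("area_ratios",
                                              "ratio_of_means")) {
  method <- match.arg(method)
  validate_pair(sample, control)
  stopifnot(inherits(rois, "roi_set"))
  areas <- c("peripheral_1", "peripheral_2")
  sm <- cm <- numeric(2)
  for (i in 1:2) {
    mask <- rois$masks[[areas[i]]]
    if (!any(mask))
      stop("empty peripheral calibration area: ", areas[i], call. = FALSE)
    sm[i] <- mean(sample$pixels[mask])
    cm[i] <- mean(control$pixels[mask])
    if (sm[i] <= 0)
      stop("degenerate calibration: zero mean sample intensity in ",
           areas[i], call. = FALSE)
  }
  ratios <- cm / sm
  value <- if (method == "area_ratios") mean(ratios) else {
    n <- vapply(rois$masks[areas], sum, 0L)
    sum(cm * n) / sum(sm * n)
  }
  structure(list(value = value, per_area_ratios = ratios, method = method),
            class = "calibration_factor")
}

#' @export
print.calibration_factor <- function(x, ...) {
  cat(sprintf("<calibration_factor %.6f (%s; area ratios %.6f, %.6f)>\n",
              x$value, x$method, x$per_area_ratios[1], x$per_area_ratios[2]))
  invisible(x)
}

#' Per-pixel calibrated transparency map
#'
#' Transparency of each pixel, in percent:
#' `100 * (sample intensity / control intensity) * calibration factor`.
#' Pixels with zero control intensity are undefined (`NA`) and excluded from
#' all downstream aggregation — substituting 0 or 100 there would bias group
#' comparisons. Values above 100 (e.g. specular highlights) are retained by
#' default; `clip = TRUE` caps the map to `[0, 100]`.
#'
#' @param sample,control validated [gray_image] pair.
#' @param factor a [peripheral_calibration] result (or a positive scalar).
#' @param clip cap values to `[0, 100]`? Default `FALSE`.
#' @return An object of class `transparency_map`: matrix `values` (percent,
#'   `NA` where undefined) plus provenance.
#' @export
transparency_map <- function(sample, control, factor, clip = FALSE) {
  validate_pair(sample, control)
  f <- if (inherits(factor, "calibration_factor")) factor$value else factor
  if (!is.numeric(f) || length(f) != 1L || !is.finite(f) || f <= 0)
    stop("calibration factor must be a positive scalar", call. = FALSE)
  if (all(control$pixels == 0))
    stop("control image is entirely zero; transparency undefined",
         call. = FALSE)
  vals <- 100 * (sample$pixels / control$pixels) * f
  vals[control$pixels == 0] <- NA_real_
  if (clip) vals <- pmin(pmax(vals, 0), 100)
  structure(list(values = vals, factor = f, clipped = clip),
            class = "transparency_map")
}

#' @export
print.transparency_map <- function(x, ...) {
  ok <- x$values[is.finite(x$values)]
  cat(sprintf(
    "<transparency_map %d x %d, factor %.4f, median %.2f%%, %d undefined px>\n",
    nrow(x$values), ncol(x$values), x$factor, stats::median(ok),
    sum(is.na(x$values))))
  invisible(x)
}

#' Summarize a transparency map over regions of interest
#'
#' Aggregates the per-pixel map to one value per region using the configured
#' statistic (mean by default, median selectable); undefined pixels are
#' excluded.
#'
#' @param map a [transparency_map].
#' @param rois [roi_set].
#' @param statistic `"mean"` or `"median"`.
#' @param regions region names to summarize (default `"measurement"`).
#' @param subject_id,group_label identifiers copied into the output rows.
#' @return measurement-table rows: `data.frame(subject_id, group_label,
#'   region_label, measure_name, value, units)`.
#' @export
summarize_region <- function(map, rois, statistic = c("mean", "median"),
                             regions = "measurement",
                             subject_id = NA_character_,
                             group_label = NA_character_) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(map, "transparency_map"), inherits(rois, "roi_set"))
  fun <- switch(statistic, mean = mean, median = stats::median)
  rows <- lapply(regions, function(rg) {
    mask <- rois$masks[[rg]]
    if (is.null(mask)) stop("unknown region: ", rg, call. = FALSE)
    vals <- map$values[mask]
    vals <- vals[!is.na(vals)]
    if (!length(vals))
      stop("no usable pixels in region '", rg, "'", call. = FALSE)
    data.frame(subject_id = subject_id, group_label = group_label,
               region_label = rg, measure_name = "transparency",
               value = fun(vals), units = "percent",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Segment iridophores by reflectance thresholding
#'
#' Iridophores reflect light strongly, so within the measurement region the
#' pixels with intensity strictly greater than the threshold are taken as
#' iridophore area. The iridophore percentage is the thresholded area divided
#' by the total measurement area, times 100.
#'
#' @param reflected reflected-light [gray_image].
#' @param rois [roi_set] with a non-empty `measurement` region.
#' @param threshold fraction of the dynamic range in `(0, 1)`; converted to
#'   counts internally.
#' @return An object of class `area_fraction_result`: `iridophore_pixels`,
#'   `roi_pixels`, `fraction` (percent) and `threshold_used` (counts).
#' @export
segment_iridophores <- function(reflected, rois, threshold = 0.5) {
  stopifnot(inherits(reflected, "gray_image"), inherits(rois, "roi_set"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stop("threshold must be a fraction of dynamic range in (0, 1)",
         call. = FALSE)
  mask <- rois$masks$measurement
  if (!any(mask)) stop("empty measurement region", call. = FALSE)
  thr <- threshold * dynamic_range(reflected)
  hit <- reflected$pixels > thr & mask
  structure(list(iridophore_pixels = sum(hit), roi_pixels = sum(mask),
                 fraction = 100 * sum(hit) / sum(mask),
                 threshold_used = thr, mask = hit),
            class = "area_fraction_result")
}

#' @export
print.area_fraction_result <- function(x, ...) {
  cat(sprintf(
    "<area_fraction_result %.2f%% (%d / %d px above %.1f counts)>\n",
    x$fraction, x$iridophore_pixels, x$roi_pixels, x$threshold_used))
  invisible(x)
}

#' Gonad-somatic index
#'
#' GSI, the ratio of gonad weight to whole body weight, reported here as a
#' percentage.
#'
#' @param gonad_weight,body_weight weights in grams.
#' @return `100 * gonad_weight / body_weight`.
#' @export
gsi <- function(gonad_weight, body_weight) {
  if (any(body_weight <= 0))
    stop("body weight must be positive", call. = FALSE)
  if (any(gonad_weight < 0) || any(gonad_weight > body_weight))
    stop("gonad weight must lie in [0, body weight]", call. = FALSE)
  100 * gonad_weight / body_weight
}

#' Filter a differential-expression table to DEGs
#'
#' Keeps genes with FDR strictly below `fdr` and |log2 fold change| strictly
#' above `lfc` (defaults 0.05 and 1), annotating each survivor as
#' up- or down-regulated by the sign of its log2FC.
#'
#' @param degs `data.frame` with columns `gene_id`, `log2FC`, `FDR`.
#' @param fdr FDR cutoff (exclusive).
#' @param lfc |log2FC| cutoff (exclusive).
#' @return the surviving rows with an added `direction` column
#'   (`"up"`/`"down"`).
#' @export
filter_degs <- function(degs, fdr = 0.05, lfc = 1) {
  need <- c("gene_id", "log2FC", "FDR")
  if (!all(need %in% names(degs)))
    stop("DEG table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(degs$FDR)) || any(degs$FDR < 0) || any(degs$FDR > 1))
    stop("FDR values must lie in [0, 1]", call. = FALSE)
  if (any(!is.finite(degs$log2FC)))
    stop("log2FC values must be finite", call. = FALSE)
  keep <- degs$FDR < fdr & (degs$log2FC > lfc | degs$log2FC < -lfc)
  out <- degs[keep, , drop = FALSE]
  out$direction <- ifelse(out$log2FC > 0, "up", "down")
  rownames(out) <- NULL
  out
}

#' Export a transparency map as a pseudo-color PNG
#'
#' Presentational export: values are mapped through a fixed viridis colormap
#' over `range` (default 0–100 percent, values outside clamped); undefined
#' pixels are rendered in a reserved sentinel color (magenta). The numeric
#' map round-trips through a side-car CSV written next to the PNG, not
#' through the PNG itself.
#'
#' @param map a [transparency_map].
#' @param path output PNG path; the side-car CSV gets the same stem.
#' @param range length-2 numeric display range in percent.
#' @return named paths (`png`, `csv`), invisibly.
#' @export
pseudocolor_export <- function(map, path, range = c(0, 100)) {
  stopifnot(inherits(map, "transparency_map"))
  pal <- grDevices::hcl.colors(256, "Viridis")
  rgbpal <- t(grDevices::col2rgb(pal)) / 255
  v <- map$values
  idx <- pmin(pmax(round(1 + 255 * (v - range[1]) / (range[2] - range[1])),
                   1), 256)
  h <- nrow(v); w <- ncol(v)
  arr <- array(0, c(h, w, 3))
  ok <- !is.na(idx)
  for (ch in 1:3) {
    plane <- matrix(0, h, w)
    plane[ok] <- rgbpal[idx[ok], ch]
    plane[!ok] <- c(1, 0, 1)[ch]  # sentinel magenta for undefined pixels
    arr[, , ch] <- plane
  }
  png::writePNG(arr, path)
  csv <- paste0(tools::file_path_sans_ext(path), ".csv")
  utils::write.table(v, csv, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(c(png = path, csv = csv))
}

#' Quantify one scene into measurement-table rows
#'
#' Runs the full per-subject quantification: peripheral calibration,
#' transparency map, region summary, and iridophore segmentation; returns
#' the long-format rows for this subject.
#'
#' @param scene a [render_scene] scene (or an equivalent list with the same
#'   fields read back from disk).
#' @param threshold segmentation threshold (fraction of dynamic range).
#' @param statistic aggregation statistic for transparency.
#' @param calibration calibration averaging method.
#' @return measurement-table rows (transparency + iridophore fraction).
#' @export
quantify_scene <- function(scene, threshold = 0.5,
                           statistic = c("mean", "median"),
                           calibration = c("area_ratios", "ratio_of_means")) {
  statistic <- match.arg(statistic)
  calibration <- match.arg(calibration)
  cf <- peripheral_calibration(scene$sample_transmitted,
                               scene$control_transmitted,
                               scene$rois, method = calibration)
  tmap <- transparency_map(scene$sample_transmitted,
                           scene$control_transmitted, cf)
  trow <- summarize_region(tmap, scene$rois, statistic = statistic,
                           subject_id = scene$subject_id,
                           group_label = scene$group_label)
  seg <- segment_iridophores(scene$sample_reflected, scene$rois,
                             threshold = threshold)
  frow <- data.frame(subject_id = scene$subject_id,
                     group_label = scene$group_label,
                     region_label = "measurement",
                     measure_name = "iridophore_fraction",
                     value = seg$fraction, units = "percent",
                     stringsAsFactors = FALSE)
  rbind(trow, frow)
}
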