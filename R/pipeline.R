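# Pipeline orchestration: generate -> quantify -> stats, with a YAML config,
# a run manifest, and file-based handoff between stages. The CLI script in
# inst/cli/ is a thin wrapper over these functions.

#' Default pipeline configuration
#'
#' Returns the default configuration as a nested list (serializable to
#' YAML). The default cohort mirrors the sexual-dimorphism study design:
#' five "female" subjects with highly transmissive jaw tissue
#' (transmittance 0.9) and no iridophores, five "male" subjects with opaque
#' tissue (transmittance 0.3) and iridophore coverage around 25% of the
#' measurement area; acquisition noise SD is 1% of the dynamic range.
#'
#' @param seed master seed.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    scene = list(image_height = 96L, image_width = 96L, bit_depth = 16L,
                 illumination_base = 0.7, illumination_gradient = 0.1,
                 illumination_shape = "linear",
                 iridophore_reflectance = 0.9, reflected_background = 0.1,
                 noise_sd = 0.01),
    cohort = list(groups = list(
      list(label = "female", n = 5L,
           params = list(tissue_transmittance = 0.9, iridophore_count = 0L)),
      list(label = "male", n = 5L,
           params = list(tissue_transmittance = 0.3, iridophore_count = 14L))
    )),
    analysis = list(threshold = 0.5, aggregate = "mean",
                    calibration = "area_ratios", alpha = 0.05,
                    clip = FALSE),
    comparisons = list(
      list(measure = "transparency", groups = c("female", "male"),
           test = "rank_sum"),
      list(measure = "iridophore_fraction", groups = c("female", "male"),
           test = "rank_sum")
    )
  )
}

#' Read and validate a pipeline configuration
#'
#' @param path YAML file path; `NULL` gives [default_config()].
#' @param seed optional seed override.
#' @return validated configuration list.
#' @export
read_config <- function(path = NULL, seed = NULL) {
  config <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    user <- yaml::read_yaml(path)
    for (nm in names(user)) {
      # scene/analysis merge field-wise; cohort and comparisons hold
      # unnamed lists and are replaced wholesale
      if (nm %in% c("scene", "analysis") && is.list(user[[nm]]))
        config[[nm]] <- utils::modifyList(config[[nm]], user[[nm]])
      else config[[nm]] <- user[[nm]]
    }
  }
  if (!is.null(seed)) config$seed <- as.integer(seed)
  a <- config$analysis
  if (a$alpha <= 0 || a$alpha >= 1)
    stop("config: alpha must lie in (0, 1)", call. = FALSE)
  if (a$threshold <= 0 || a$threshold >= 1)
    stop("config: threshold must lie in (0, 1)", call. = FALSE)
  for (g in config$cohort$groups)
    if (is.null(g$label) || is.null(g$n) || g$n < 1)
      stop("config: every cohort group needs a label and n >= 1",
           call. = FALSE)
  config
}

config_design <- function(config) {
  base <- do.call(scene_params, config$scene)
  cohort_design(config$cohort$groups, base_params = base,
                seed = config$seed)
}

write_manifest <- function(manifest, out_dir) {
  path <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Generate stage: render the cohort and write scenes to disk
#'
#' Renders one scene per subject (deterministic per seed), writes the three
#' modality TIFFs, ROI JSON and planted-truth files per subject, a cohort
#' manifest CSV, and a run manifest JSON listing every output.
#'
#' @param config configuration list (see [read_config]).
#' @param out_dir output directory.
#' @return invisible list with the scenes, cohort table and manifest path.
#' @export
run_generate <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scenes <- generate_cohort(config_design(config))
  rows <- list(); files <- character(0)
  for (sc in scenes) {
    paths <- write_scene(sc, file.path(out_dir, "scenes"))
    files <- c(files, unname(paths))
    rows[[sc$subject_id]] <- data.frame(
      subject_id = sc$subject_id, group_label = sc$group_label,
      control = paths[["control"]], sample = paths[["sample"]],
      reflected = paths[["reflected"]], rois = paths[["rois"]],
      stringsAsFactors = FALSE)
  }
  cohort <- do.call(rbind, rows)
  cohort_csv <- file.path(out_dir, "cohort.csv")
  utils::write.csv(cohort, cohort_csv, row.names = FALSE)
  manifest <- list(stage = "generate", seed = config$seed, config = config,
                   version = as.character(utils::packageVersion("iridoquant")),
                   timestamp = format(Sys.time(), tz = "UTC"),
                   outputs = c(files, cohort_csv))
  mpath <- write_manifest(manifest, out_dir)
  invisible(list(scenes = scenes, cohort = cohort, manifest = mpath))
}

read_scene_files <- function(row) {
  control <- read_image(row$control)
  sample <- read_image(row$sample)
  reflected <- read_image(row$reflected)
  rois <- load_rois(row$rois, control)
  list(control_transmitted = control, sample_transmitted = sample,
       sample_reflected = reflected, rois = rois,
       subject_id = row$subject_id, group_label = row$group_label)
}

#' Quantify stage: measure transparency and iridophore coverage per subject
#'
#' Reads the cohort manifest (or operates on in-memory scenes), runs
#' peripheral calibration, transparency mapping, region aggregation and
#' reflectance-threshold segmentation, and writes the long-format
#' measurement table as CSV. A subject whose images fail to read is flagged
#' and skipped; the run continues and flagged subjects are reported.
#'
#' @param config configuration list.
#' @param out_dir directory holding `cohort.csv` (from [run_generate]);
#'   outputs go there too.
#' @param scenes optional list of in-memory scenes to quantify instead of
#'   reading files.
#' @return invisible list with the measurement `table` (data.frame), the
#'   CSV path, and `flagged` subject ids.
#' @export
run_quantify <- function(config, out_dir, scenes = NULL) {
  a <- config$analysis
  flagged <- character(0)
  if (is.null(scenes)) {
    cohort_csv <- file.path(out_dir, "cohort.csv")
    if (!file.exists(cohort_csv))
      stop("no cohort manifest at ", cohort_csv,
           "; run the generate stage first", call. = FALSE)
    cohort <- utils::read.csv(cohort_csv, stringsAsFactors = FALSE)
    scenes <- list()
    for (i in seq_len(nrow(cohort))) {
      sc <- tryCatch(read_scene_files(cohort[i, ]), error = function(e) {
        warning("subject ", cohort$subject_id[i], " skipped: ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
      if (is.null(sc)) flagged <- c(flagged, cohort$subject_id[i])
      else scenes[[sc$subject_id]] <- sc
    }
  }
  tabs <- lapply(scenes, quantify_scene, threshold = a$threshold,
                 statistic = a$aggregate, calibration = a$calibration)
  table <- do.call(rbind, c(tabs, list(make.row.names = FALSE)))
  csv <- file.path(out_dir, "measurements.csv")
  utils::write.csv(table, csv, row.names = FALSE)
  invisible(list(table = table, csv = csv, flagged = flagged))
}

#' Stats stage: run the configured comparisons on a measurement table
#'
#' Each comparison spec names a measure and the groups to compare. Two
#' groups are compared with the Wilcoxon rank-sum test (or the signed-rank
#' test when `test: signed_rank`, pairing subjects by their order within
#' group); three or more groups are compared with the Steel-Dwass all-pairs
#' test plus a compact letter display. Results are written as JSON and as a
#' human-readable TSV.
#'
#' @param config configuration list.
#' @param table measurement data.frame (or path to the CSV).
#' @param out_dir output directory for `stats.json` / `stats.tsv`.
#' @return invisible list of per-comparison results.
#' @export
run_stats <- function(config, table, out_dir = NULL) {
  if (is.character(table)) table <- utils::read.csv(table,
                                                    stringsAsFactors = FALSE)
  alpha <- config$analysis$alpha
  results <- list(); tsv_rows <- list()
  for (cmp in config$comparisons) {
    sub <- table[table$measure_name == cmp$measure &
                   table$group_label %in% cmp$groups, , drop = FALSE]
    groups <- split(sub$value, factor(sub$group_label, levels = cmp$groups))
    if (length(groups) < 2L || any(lengths(groups) == 0L))
      stop("comparison '", cmp$measure, "': need data for groups ",
           paste(cmp$groups, collapse = ", "), call. = FALSE)
    key <- paste0(cmp$measure, ":", paste(cmp$groups, collapse = "_vs_"))
    if (length(groups) == 2L) {
      test <- if (!is.null(cmp$test) && cmp$test == "signed_rank")
        signed_rank_test(groups[[1]], groups[[2]])
      else if (is.null(cmp$test) || cmp$test == "rank_sum")
        rank_sum_test(groups[[1]], groups[[2]])
      else stop("unknown test '", cmp$test, "' in comparison spec",
                call. = FALSE)
      results[[key]] <- test
      tsv_rows[[key]] <- data.frame(
        comparison = key, method = test$method,
        statistic = unname(test$statistic), p_value = test$p_value,
        marker = test$marker, letters = NA_character_,
        stringsAsFactors = FALSE)
    } else {
      pw <- steel_dwass(groups, alpha = alpha)
      cl <- compact_letters(pw)
      results[[key]] <- list(pairwise = pw, letters = cl)
      tsv_rows[[key]] <- data.frame(
        comparison = paste0(key, ":", pw$group_i, "-", pw$group_j),
        method = "Steel-Dwass test", statistic = pw$q,
        p_value = pw$p_value, marker = pw$marker,
        letters = paste(names(cl$letters), unname(cl$letters),
                        sep = "=", collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    ser <- lapply(results, function(r) {
      if (inherits(r, "np_test_result"))
        list(method = r$method, statistic = unname(r$statistic),
             p_value = r$p_value, exact = r$exact, n = r$n,
             marker = r$marker)
      else
        list(method = "Steel-Dwass test",
             pairwise = as.data.frame(r$pairwise),
             letters = as.list(r$letters$letters))
    })
    jsonlite::write_json(ser, file.path(out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.table(do.call(rbind, c(tsv_rows,
                                        list(make.row.names = FALSE))),
                       file.path(out_dir, "stats.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(results)
}

#' Run the full pipeline: generate, quantify, stats
#'
#' @param config configuration list (see [read_config]).
#' @param out_dir output directory.
#' @param skip_generate reuse an existing cohort in `out_dir` (user-supplied
#'   images) instead of rendering scenes.
#' @return invisible list with `table`, `stats` and `flagged`.
#' @export
run_all <- function(config, out_dir, skip_generate = FALSE) {
  gen <- if (skip_generate) NULL else run_generate(config, out_dir)
  q <- run_quantify(config, out_dir)
  stats <- run_stats(config, q$table, out_dir)
  manifest <- list(stage = "run_all", seed = config$seed, config = config,
                   version = as.character(utils::packageVersion("iridoquant")),
                   timestamp = format(Sys.time(), tz = "UTC"),
                   flagged = q$flagged,
                   outputs = c(if (!is.null(gen)) gen$manifest, q$csv,
                               file.path(out_dir, c("stats.json",
                                                    "stats.tsv"))))
  write_manifest(manifest, out_dir)
  invisible(list(table = q$table, stats = stats, flagged = q$flagged))
}
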