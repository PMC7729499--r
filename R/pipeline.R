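# Orchestration: config-driven end-to-end runs
# (generate -> preprocess -> segment -> morphometry -> CTCF -> statistics),
# deterministic seed fan-out, manifests with checksums.

#' Derive a per-stage child seed from a global seed
#'
#' A single global seed fans out to per-stage seeds by hashing the stage name
#' into the linear-congruential step `seed * 1000003 + hash (mod 2^31 - 1)`,
#' so stages are individually reproducible and never share a stream.
#'
#' @param seed integer global seed.
#' @param stage stage name (string).
#' @return Integer seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * (seq_along(utf8ToInt(stage)) %% 31 + 1))
  as.integer((as.numeric(seed) %% 65536 * 1000003 + h * 2971) %% 2147483646 + 1)
}

#' Build and validate a pipeline run configuration
#'
#' @param n_fields number of fields of view to generate and analyze.
#' @param scene named list of overrides for [scene_config()] (everything but
#'   the seed, which is derived from the global seed per field).
#' @param scale_um_per_px pixel calibration; must be present and positive.
#' @param min_area_px minimum segmented-region area.
#' @param flatfield apply flat-field correction before segmentation and CTCF.
#' @param smoothing_scale_px flat-field smoothing scale.
#' @param disk_diameter_px opening structuring-element diameter for the CTCF
#'   background (default 20).
#' @param ctcf_mode `"standard"` or `"literal"`, see [ctcf()].
#' @param ar_min,protrusion_min_um phenotype-classification thresholds,
#'   see [classify_phenotype()].
#' @param seed global seed.
#' @return Object of class `run_config`.
#' @export
run_config <- function(n_fields = 2, scene = list(),
                       scale_um_per_px = 0.32,
                       min_area_px = 200, flatfield = TRUE,
                       smoothing_scale_px = 100, disk_diameter_px = 20,
                       ctcf_mode = "standard",
                       ar_min = 2.2, protrusion_min_um = NULL,
                       seed = 1L) {
  if (is.null(scale_um_per_px) || !is.numeric(scale_um_per_px) ||
      scale_um_per_px <= 0)
    stop("run_config: missing or invalid calibration (scale_um_per_px)",
         call. = FALSE)
  stopifnot(n_fields >= 1, min_area_px >= 0)
  scene$scale_um_per_px <- scale_um_per_px
  structure(list(n_fields = as.integer(n_fields), scene = scene,
                 scale_um_per_px = scale_um_per_px,
                 min_area_px = min_area_px, flatfield = flatfield,
                 smoothing_scale_px = smoothing_scale_px,
                 disk_diameter_px = disk_diameter_px,
                 ctcf_mode = ctcf_mode, ar_min = ar_min,
                 protrusion_min_um = protrusion_min_um,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline run configuration from YAML
#'
#' @param path YAML file whose keys are the arguments of [run_config()].
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  do.call(run_config, raw[intersect(names(raw), known)])
}

#' Segment a rendered scene into matched cell and nucleus labels
#'
#' Optional flat-field correction, Otsu thresholding and 8-connected labeling
#' on the cell-body channel; nuclei are segmented from the nuclear channel
#' and relabelled with the id of the cell containing their centroid.
#'
#' @param scene a `scene` from [render_scene()].
#' @param cell_channel,nucleus_channel channel names.
#' @param flatfield,smoothing_scale_px,min_area_px preprocessing options.
#' @return List with `cell_labels` and `nucleus_labels` (ids matched to the
#'   containing cell, 0 where a nucleus falls outside every cell).
#' @export
segment_scene <- function(scene, cell_channel = "marker",
                          nucleus_channel = "dapi",
                          flatfield = TRUE, smoothing_scale_px = 100,
                          min_area_px = 200) {
  stopifnot(inherits(scene, "scene"))
  img <- scene$channels[[cell_channel]]
  if (is.null(img)) stop("segment_scene: channel not found: ", cell_channel)
  if (flatfield) img <- flatfield_correct(img, smoothing_scale_px)
  cell_labels <- label_regions(threshold_mask(img), min_area_px)
  nucleus_labels <- matrix(0L, nrow(img), ncol(img))
  nimg <- scene$channels[[nucleus_channel]]
  if (!is.null(nimg)) {
    if (flatfield) nimg <- flatfield_correct(nimg, smoothing_scale_px)
    nl <- label_regions(threshold_mask(nimg), max(9, min_area_px %/% 8))
    if (max(nl) > 0) {
      props <- region_properties(nl)
      for (i in seq_len(nrow(props))) {
        r <- round(props$centroid_y[i]); c <- round(props$centroid_x[i])
        owner <- cell_labels[r, c]
        if (owner > 0) nucleus_labels[nl == props$label[i]] <- owner
      }
    }
  }
  list(cell_labels = cell_labels, nucleus_labels = nucleus_labels)
}

.write_csv_stable <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full pipeline on synthetic scenes
#'
#' Generates `n_fields` scenes (seeded per field from the global seed),
#' segments them, measures the morphometric descriptors and per-cell CTCF,
#' summarizes the descriptors, and writes `morphometry.csv`, `ctcf.csv`,
#' `stats.json` and a checksummed `manifest.json` under `outdir`. Identical
#' config and seed give byte-identical CSV outputs.
#'
#' @param config a [run_config()].
#' @param outdir output directory (created).
#' @return The run manifest (invisibly a list; also written as JSON).
#' @export
run_pipeline <- function(config, outdir) {
  if (!inherits(config, "run_config")) stop("run_pipeline: invalid config")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    config = unclass(config),
    package_version = as.character(utils::packageVersion("cytomorph")),
    seed = config$seed, stage_counts = list(), warnings = character())
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  cal <- calibration(config$scale_um_per_px)
  morpho <- list(); ctcf_rows <- list()
  for (f in seq_len(config$n_fields)) {
    sc_args <- config$scene
    sc_args$seed <- child_seed(config$seed, paste0("scene", f))
    scene <- render_scene(do.call(scene_config, sc_args))
    seg <- tryCatch(
      segment_scene(scene, flatfield = config$flatfield,
                    smoothing_scale_px = config$smoothing_scale_px,
                    min_area_px = config$min_area_px),
      error = function(e) stop("run_pipeline: stage segment, field ", f, ": ",
                               conditionMessage(e), call. = FALSE))
    if (max(seg$cell_labels) == 0) next
    sid <- sprintf("field%02d", f)
    morpho[[f]] <- tryCatch(
      measure_cells(seg$cell_labels, seg$nucleus_labels, cal, scene_id = sid,
                    ar_min = config$ar_min,
                    protrusion_min_um = config$protrusion_min_um),
      error = function(e) stop("run_pipeline: stage morphometry, field ", f,
                               ": ", conditionMessage(e), call. = FALSE))
    marker_channels <- names(scene$config$channels)[
      !vapply(scene$config$channels, function(ch) isTRUE(ch$nuclear), TRUE)]
    for (ch in marker_channels) {
      ctcf_rows[[paste(f, ch)]] <- tryCatch(
        quantify_marker(scene$channels[[ch]], seg$cell_labels,
                        flatfield = config$flatfield,
                        smoothing_scale_px = config$smoothing_scale_px,
                        disk_diameter_px = config$disk_diameter_px,
                        seed = child_seed(config$seed, paste0("rois", f, ch)),
                        mode = config$ctcf_mode, scene_id = sid, channel = ch),
        error = function(e) stop("run_pipeline: stage ctcf, field ", f, ": ",
                                 conditionMessage(e), call. = FALSE))
    }
  }
  morpho <- do.call(rbind, morpho)
  ctcf_tab <- do.call(rbind, ctcf_rows)
  files <- c(.write_csv_stable(morpho, file.path(outdir, "morphometry.csv")),
             .write_csv_stable(ctcf_tab, file.path(outdir, "ctcf.csv")))
  stats_out <- list(
    n_cells = nrow(morpho),
    descriptor_summaries = lapply(
      stats::setNames(nm = c("CSI", "NSI", "AR", "CL_um", "NP", "protrusion_um")),
      function(d) boxplot_summary(morpho[[d]][is.finite(morpho[[d]])])),
    elongated_fraction = mean(morpho$phenotype == "elongated_polarized"))
  stats_path <- file.path(outdir, "stats.json")
  jsonlite::write_json(stats_out, stats_path, auto_unbox = TRUE, digits = NA)
  files <- c(files, stats_path)
  manifest$stage_counts <- list(fields = config$n_fields,
                                cells = nrow(morpho),
                                ctcf_records = nrow(ctcf_tab))
  manifest$outputs <- lapply(files, function(f)
    list(file = basename(f), md5 = unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}

#' Simulate a multi-condition imaging experiment
#'
#' Emulates the study design this pipeline mirrors (conditions =
#' substrate x timepoint x serum, several fields per condition, on the order
#' of 100 cells per condition): each condition gets its own generator
#' parameters, scenes are rendered and analyzed end-to-end (segmentation,
#' morphometry, classification), and a long-format per-cell descriptor table
#' is returned for the statistics layer, together with the per-condition
#' ground truth.
#'
#' @param design list of conditions; each condition is a list with
#'   `substrate`, optional `timepoint` (default `"D2"`), optional `serum`
#'   (default `"+FBS"`), `n_fields`, and `scene` (overrides for
#'   [scene_config()], e.g. `polarized_fraction` or protrusion ranges).
#' @param seed global seed; each condition and field derives a child seed.
#' @param use_truth_masks measure on ground-truth masks instead of segmenting
#'   (faster; default `FALSE`).
#' @param ... classification thresholds passed to [measure_cells()].
#' @return List with `cells` (wide per-cell data frame including condition
#'   keys), `long` (long-format descriptor records: substrate, timepoint,
#'   serum, descriptor, value), and `truth` (per-condition generator
#'   parameters).
#' @export
simulate_experiment <- function(design, seed = 1L, use_truth_masks = FALSE,
                                ...) {
  if (!length(design)) stop("simulate_experiment: empty design")
  out <- list(); truth <- list()
  for (ci in seq_along(design)) {
    cond <- design[[ci]]
    if (is.null(cond$substrate)) stop("simulate_experiment: condition without substrate")
    tp <- cond$timepoint %||% "D2"
    serum <- cond$serum %||% "+FBS"
    n_fields <- cond$n_fields %||% 8L
    key <- paste(cond$substrate, tp, serum, sep = "|")
    truth[[key]] <- cond$scene
    for (f in seq_len(n_fields)) {
      sc_args <- cond$scene %||% list()
      sc_args$seed <- child_seed(seed, paste0(key, ":field", f))
      scene <- render_scene(do.call(scene_config, sc_args))
      cal <- calibration(scene$config$scale_um_per_px)
      if (use_truth_masks) {
        labs <- list(cell_labels = scene$truth$cell_labels,
                     nucleus_labels = scene$truth$nucleus_labels)
      } else {
        labs <- segment_scene(scene)
      }
      if (max(labs$cell_labels) == 0) next
      m <- measure_cells(labs$cell_labels, labs$nucleus_labels, cal,
                         scene_id = sprintf("%s|f%02d", key, f), ...)
      m$substrate <- cond$substrate; m$timepoint <- tp; m$serum <- serum
      out[[paste(key, f)]] <- m
    }
  }
  cells <- do.call(rbind, out)
  rownames(cells) <- NULL
  num_desc <- c("CSI", "NSI", "AR", "CL_um", "feret_angle_deg", "NP",
                "protrusion_um")
  long <- do.call(rbind, lapply(num_desc, function(d)
    data.frame(substrate = cells$substrate, timepoint = cells$timepoint,
               serum = cells$serum, scene_id = cells$scene_id,
               cell_id = cells$cell_id, descriptor = d,
               value = cells[[d]])))
  long <- long[is.finite(long$value), ]
  rownames(long) <- NULL
  list(cells = cells, long = long, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
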