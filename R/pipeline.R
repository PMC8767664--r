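#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run with its default. All
#' defaults can be overridden here or per call from the command line.
#'
#' @param input_dir directory of input images (TIFF/PNG/JPEG)
#' @param output_dir directory for all outputs (created if needed)
#' @param nuclear_channel 1-based index of the nuclear stain channel
#' @param tile_size,overlap tiling geometry (see [tile_image])
#' @param min_area artifact filter threshold in pixels (default 40)
#' @param grow_pixels mask expansion radius (default 1)
#' @param grow_method `"nearest_center"` or `"iterative"`
#' @param compensate run lateral bleed compensation (default `TRUE`)
#' @param flank off-diagonal attenuation for [compensate]
#' @param backend `"baseline"` or a custom segmentation function
#' @param smooth_sigma,min_seed_distance baseline backend parameters
#' @param brightness_reference `"first"` (the first input image) or a
#'   path to a reference image
#' @param brightness_quantile,brightness_target brightness rule parameters
#'   (see [compute_brightness_factor])
#' @param channel_names_file optional text file, one channel name per line
#' @param save_overlay,save_rois write overlay PNGs / ROI TIFF stacks
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(input_dir, output_dir,
                            nuclear_channel = 1L,
                            tile_size = 512L, overlap = 64L,
                            min_area = 40L,
                            grow_pixels = 1L,
                            grow_method = c("nearest_center", "iterative"),
                            compensate = TRUE, flank = 1.0,
                            backend = "baseline",
                            smooth_sigma = 2, min_seed_distance = 7L,
                            brightness_reference = "first",
                            brightness_quantile = 0.99,
                            brightness_target = 0.875,
                            channel_names_file = NULL,
                            save_overlay = FALSE, save_rois = FALSE) {
  grow_method <- match.arg(grow_method)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full segmentation and quantification pipeline
#'
#' For each image in the input directory: extract the nuclear channel,
#' scale brightness by the shared reference-derived factor, tile, segment
#' each tile with the configured backend, stitch, remove small artifacts,
#' expand masks, compute contact ratios and compensate lateral bleed
#' (when enabled), quantify, and write the outputs (`<name>_cells.csv`,
#' `<name>_cells.fcs`, `<name>_labels.tif`, optionally
#' `<name>_overlay.png` and `<name>_rois.tif`). A failure in one image is
#' logged and the remaining images are still processed.
#'
#' @param config a [pipeline_config]
#' @return invisibly, the run manifest (also written as `manifest.json`):
#'   parameters, backend name, brightness factor, per-image cell counts
#'   and failures. The manifest element `n_failed` is non-zero when any
#'   image failed.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  files <- sort(list.files(cfg$input_dir,
                           pattern = "\\.(tiff?|png|jpe?g)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0L)
    stop("no readable images found in ", cfg$input_dir)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)

  channel_names <- NULL
  if (!is.null(cfg$channel_names_file))
    channel_names <- readLines(cfg$channel_names_file)

  backend <- if (inherits(cfg$backend, "segmenter_backend")) cfg$backend
             else segmenter_backend(cfg$backend,
                                    smooth_sigma = cfg$smooth_sigma,
                                    min_seed_distance = cfg$min_seed_distance)

  ref_path <- if (identical(cfg$brightness_reference, "first")) files[1]
              else cfg$brightness_reference
  ref_img <- read_image(ref_path, channel_names = channel_names)
  factor <- compute_brightness_factor(
    get_channel(ref_img, cfg$nuclear_channel),
    target_fraction = cfg$brightness_target,
    quantile = cfg$brightness_quantile,
    dtype_max = ref_img$dtype_max)
  message(sprintf("[nucseg] brightness factor %.4f from %s",
                  factor, basename(ref_path)))

  images <- list(); failures <- character(0)
  for (path in files) {
    name <- tools::file_path_sans_ext(basename(path))
    res <- tryCatch(
      process_one_image(path, name, cfg, backend, factor, channel_names),
      error = function(e) e)
    if (inherits(res, "error")) {
      message(sprintf("[nucseg] FAILED %s: %s", name, conditionMessage(res)))
      failures <- c(failures, name)
    } else {
      message(sprintf("[nucseg] %s: %d cells", name, res$n_cells))
      images[[name]] <- res
    }
  }
  manifest <- list(
    parameters = cfg[setdiff(names(cfg), c("backend"))],
    backend = backend$name,
    brightness_factor = factor,
    images = images,
    failed = failures,
    n_failed = length(failures))
  jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       force = TRUE)
  invisible(manifest)
}

process_one_image <- function(path, name, cfg, backend, factor,
                              channel_names) {
  img <- read_image(path, channel_names = channel_names)
  nuc <- get_channel(img, cfg$nuclear_channel)
  nuc <- apply_brightness(nuc, factor, dtype_max = img$dtype_max)
  if (backend$name == "baseline") {
    # one threshold for the whole image so tiling cannot alter the result
    th <- global_threshold(nuc, smooth_sigma = cfg$smooth_sigma,
                           dtype_max = img$dtype_max)
    backend <- segmenter_backend("baseline",
                                 smooth_sigma = cfg$smooth_sigma,
                                 min_seed_distance = cfg$min_seed_distance,
                                 dtype_max = img$dtype_max,
                                 threshold = th)
  }
  tiles <- tile_image(nuc, tile_size = cfg$tile_size, overlap = cfg$overlap)
  tl <- lapply(tiles, function(tile)
    list(tile = tile, labels = backend$segment(tile$pixels)))
  labels <- stitch_tiles(tl, parent_dim = dim(nuc))
  labels <- filter_small_objects(labels, cfg$min_area)
  expanded <- switch(cfg$grow_method,
    nearest_center = expand_masks_nearest_center(labels, cfg$grow_pixels),
    iterative = expand_masks_iterative(labels, cfg$grow_pixels))
  table <- quantify_cells(labels, expanded, img)
  if (cfg$compensate && nrow(table) > 0L) {
    contacts <- contact_ratios(expanded)
    table <- apply_compensation(table, contacts, flank = cfg$flank)
  }
  out <- function(suffix) file.path(cfg$output_dir, paste0(name, suffix))
  write_cell_table(table, out("_cells.csv"), "csv")
  write_cell_table(table, out("_cells.fcs"), "fcs")
  write_label_tiff(labels, out("_labels.tif"))
  if (isTRUE(cfg$save_overlay))
    write_overlay_png(render_overlay(img, expanded, cfg$nuclear_channel),
                      out("_overlay.png"))
  if (isTRUE(cfg$save_rois) && nrow(table) > 0L)
    export_roi_stack(labels, out("_rois.tif"))
  list(n_cells = nrow(table))
}
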