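#' Pipeline parameters
#'
#' Builds the full parameter set controlling ROI segmentation, puncta
#' detection/segmentation and analysis, with the recommended initial values.
#' Parameter names and semantics follow the standard puncta-analysis
#' parameter files, so a JSON file written by [save_params()] is a drop-in
#' configuration. Channel indices are zero-based.
#'
#' ROI segmentation parameters: `channel` (index, or `[nuclei, cyto]` pair
#' for whole-cell segmentation with an auxiliary nuclear stain), `diameter`
#' (target ROI diameter in pixels, `NULL` to auto-estimate), `model_type`,
#' `gpu`, `do_3D` (if `FALSE`, per-layer 2D segmentation merged in 3D by
#' [merge_layers_3d()]), `flow_threshold`, `cellprob_threshold`,
#' `remove_small_mode` ("2D"/"3D") and `remove_small_diam_fraction`.
#'
#' Puncta parameters: `puncta_channels`, `minsize_um`/`maxsize_um` (blob
#' size range, mapped to LoG sigmas), `num_sigma`, `threshold_detection`,
#' `overlap`, `threshold_background`, `background_percentile`,
#' `global_background`, `global_background_percentile`,
#' `segmentation_mode` (0 = absolute threshold in LoG space; 1 = threshold
#' relative to ROI background in LoG space; 2 = relative threshold in raw
#' intensity space), `threshold_segmentation`, `remove_out_of_roi`,
#' `maxrad_um`.
#'
#' @param ... parameter overrides by name.
#' @return A named list of class `pipeline_params`.
#' @export
#' @examples
#' p <- pipeline_params(threshold_detection = 0.002, puncta_channels = 1)
#' p$minsize_um
pipeline_params <- function(...) {
  p <- utils::modifyList(default_pipeline_params(), list(...),
                         keep.null = TRUE)
  validate_params(p)
}

default_pipeline_params <- function() {
  list(
    # staging / I/O
    input_dir = NULL,
    output_dir = NULL,
    channel_names = NULL,
    # ROI segmentation
    roi_segmentation = TRUE,
    channel = 0L,
    diameter = NULL,
    model_type = "cyto",
    gpu = FALSE,
    do_3D = FALSE,
    flow_threshold = 0.4,
    cellprob_threshold = 0,
    remove_small_mode = "3D",
    remove_small_diam_fraction = 0.5,
    # puncta detection and segmentation
    puncta_channels = 1L,
    minsize_um = 0.2,
    maxsize_um = 2,
    num_sigma = 5L,
    threshold_detection = 0.001,
    overlap = 1,
    threshold_background = 3,
    background_percentile = 50,
    global_background = FALSE,
    global_background_percentile = 95,
    segmentation_mode = 0L,
    threshold_segmentation = 0.001,
    blob_boundary_fraction = 0.25,
    remove_out_of_roi = FALSE,
    maxrad_um = NULL
  )
}

#' Validate pipeline parameters
#'
#' Checks the invariants every downstream stage relies on and fails with the
#' name of the offending parameter.
#'
#' @param params a named list as returned by [pipeline_params()].
#' @return The validated `pipeline_params` object (invisibly classed).
#' @export
validate_params <- function(params) {
  fail <- function(name, why) {
    stop(sprintf("invalid parameter '%s': %s", name, why), call. = FALSE)
  }
  if (params$minsize_um <= 0) fail("minsize_um", "must be > 0")
  if (params$maxsize_um < params$minsize_um) {
    fail("maxsize_um", "must be >= minsize_um")
  }
  if (params$num_sigma < 1) fail("num_sigma", "must be >= 1")
  if (params$overlap < 0 || params$overlap > 1) fail("overlap", "must be in [0, 1]")
  bbf <- params$blob_boundary_fraction %||% 0.25
  if (bbf < 0 || bbf > 1) fail("blob_boundary_fraction", "must be in [0, 1]")
  if (params$threshold_background < 0) fail("threshold_background", "must be >= 0")
  for (nm in c("background_percentile", "global_background_percentile")) {
    if (params[[nm]] < 0 || params[[nm]] > 100) fail(nm, "must be in [0, 100]")
  }
  if (!params$segmentation_mode %in% c(0L, 1L, 2L)) {
    fail("segmentation_mode", "must be 0, 1 or 2")
  }
  if (!params$remove_small_mode %in% c("2D", "3D")) {
    fail("remove_small_mode", "must be \"2D\" or \"3D\"")
  }
  if (params$remove_small_diam_fraction < 0) {
    fail("remove_small_diam_fraction", "must be >= 0")
  }
  if (!is.null(params$diameter) && params$diameter <= 0) {
    fail("diameter", "must be > 0 (or NULL for auto)")
  }
  if (!is.null(params$maxrad_um) && params$maxrad_um <= 0) {
    fail("maxrad_um", "must be > 0 (or NULL to keep all puncta)")
  }
  structure(params, class = "pipeline_params")
}

#' Read pipeline parameters from a JSON file
#'
#' Absent keys take the recommended defaults; unknown keys are preserved so
#' files produced by other tools round-trip losslessly.
#'
#' @param path JSON file path.
#' @return A validated `pipeline_params` list.
#' @export
load_params <- function(path) {
  parsed <- tryCatch(
    suppressWarnings(jsonlite::read_json(path, simplifyVector = TRUE)),
    error = function(e) {
      stop(sprintf("malformed parameter JSON in '%s': %s", path,
                   conditionMessage(e)), call. = FALSE)
    }
  )
  p <- utils::modifyList(default_pipeline_params(), as.list(parsed),
                         keep.null = TRUE)
  # restore NULLs that JSON null parsing may have dropped
  for (nm in c("diameter", "maxrad_um", "input_dir", "output_dir", "channel_names")) {
    if (!nm %in% names(parsed) || is.null(parsed[[nm]])) {
      if (!nm %in% names(p) || length(p[[nm]]) == 0) p[nm] <- list(NULL)
    }
  }
  validate_params(p)
}

#' Write pipeline parameters to a JSON file
#'
#' @param params a `pipeline_params` list (validated before writing).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_params <- function(params, path) {
  params <- validate_params(params)
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE,
                       null = "null", pretty = TRUE, digits = NA)
  invisible(path)
}
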