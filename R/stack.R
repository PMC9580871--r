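#' Multi-channel image stack
#'
#' The core image container: a 4-d intensity array indexed `(z, y, x,
#' channel)` with physical voxel spacing. 2D images are represented with a
#' z-extent of 1 so that every downstream operation has a single code path;
#' area is then reported where volume would be for 3D data.
#'
#' @param voxels numeric array, either `(z, y, x, channel)`, a single-channel
#'   `(z, y, x)` array, or a 2D matrix `(y, x)`. Intensities must be finite
#'   and non-negative.
#' @param pixel_size_um xy pixel edge length in micrometres (> 0).
#' @param z_spacing_um distance between z-planes in micrometres (> 0).
#'   Ignored (and defaulted to 1) when the z-extent is 1.
#' @param channel_names optional character vector of channel labels; defaults
#'   to `"ch0"`, `"ch1"`, ... (zero-based, matching parameter-file channel
#'   indices).
#' @param source_name acquisition identifier, including any condition
#'   subdirectory (e.g. `"condition1/sample_07"`).
#'
#' @return An object of class `multichannel_stack`: a list with elements
#'   `voxels`, `pixel_size_um`, `z_spacing_um`, `channel_names`,
#'   `source_name`.
#' @export
#' @examples
#' st <- multichannel_stack(array(1, c(4, 8, 8, 2)), pixel_size_um = 0.11,
#'                          z_spacing_um = 0.2)
#' stack_spacing(st)
multichannel_stack <- function(voxels, pixel_size_um, z_spacing_um = NULL,
                               channel_names = NULL, source_name = "") {
  if (is.matrix(voxels)) voxels <- array(voxels, dim = c(1L, dim(voxels)))
  if (length(dim(voxels)) == 3L) voxels <- array(voxels, dim = c(dim(voxels), 1L))
  if (length(dim(voxels)) != 4L) {
    stop("voxels must be a (z, y, x, channel) array", call. = FALSE)
  }
  if (!all(is.finite(voxels)) || any(voxels < 0)) {
    stop("intensities must be finite and >= 0", call. = FALSE)
  }
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0) {
    stop("pixel_size_um must be > 0", call. = FALSE)
  }
  nz <- dim(voxels)[1]
  if (is.null(z_spacing_um)) {
    if (nz > 1L) stop("z_spacing_um is required for stacks with more than one z-plane",
                      call. = FALSE)
    z_spacing_um <- 1
  }
  if (z_spacing_um <= 0) stop("z_spacing_um must be > 0", call. = FALSE)
  n_ch <- dim(voxels)[4]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(n_ch) - 1L)
  if (length(channel_names) != n_ch) {
    stop("channel_names must have one entry per channel", call. = FALSE)
  }
  structure(
    list(voxels = voxels, pixel_size_um = pixel_size_um,
         z_spacing_um = z_spacing_um,
         channel_names = as.character(channel_names),
         source_name = source_name),
    class = "multichannel_stack"
  )
}

#' @export
print.multichannel_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<multichannel_stack> %s\n", if (nzchar(x$source_name)) x$source_name else "(unnamed)"))
  cat(sprintf("  %d channel(s) [%s], %d z-plane(s), %d x %d pixels\n",
              d[4], paste(x$channel_names, collapse = ", "), d[1], d[2], d[3]))
  cat(sprintf("  pixel size %.4g um, z spacing %.4g um\n",
              x$pixel_size_um, x$z_spacing_um))
  invisible(x)
}

#' Physical voxel spacing of a stack
#'
#' @param stack a [multichannel_stack()].
#' @return numeric vector `(z_spacing_um, pixel_size_um, pixel_size_um)`.
#' @export
stack_spacing <- function(stack) {
  c(stack$z_spacing_um, stack$pixel_size_um, stack$pixel_size_um)
}

#' Number of channels in a stack
#' @param stack a [multichannel_stack()].
#' @return integer.
#' @export
n_channels <- function(stack) dim(stack$voxels)[4]

#' Extract one channel as a 3-d volume
#'
#' @param stack a [multichannel_stack()].
#' @param channel zero-based channel index (matching parameter files) or a
#'   channel name.
#' @return `(z, y, x)` numeric array.
#' @export
channel_volume <- function(stack, channel) {
  if (is.character(channel)) {
    idx <- match(channel, stack$channel_names)
    if (is.na(idx)) stop("unknown channel name: ", channel, call. = FALSE)
  } else {
    idx <- as.integer(channel) + 1L
    if (idx < 1L || idx > n_channels(stack)) {
      stop("channel index out of range: ", channel, call. = FALSE)
    }
  }
  v <- stack$voxels[, , , idx]
  array(v, dim = dim(stack$voxels)[1:3])
}

#' Labeled segmentation volume
#'
#' An integer-labeled mask aligned to a stack: 0 is background, positive
#' integers identify ROIs (cells/nuclei) or puncta.
#'
#' @param labels integer array `(z, y, x)` (a matrix is promoted to z-extent
#'   1) of non-negative labels.
#' @param spacing `(z_spacing_um, pixel_size_um, pixel_size_um)`; see
#'   [stack_spacing()].
#' @param kind `"roi"` or `"puncta"`.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, spacing, kind = c("roi", "puncta")) {
  kind <- match.arg(kind)
  labels <- as_volume(labels)
  storage.mode(labels) <- "integer"
  if (any(labels < 0L)) stop("labels must be non-negative", call. = FALSE)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("spacing must be three positive values (z, y, x)", call. = FALSE)
  }
  structure(list(labels = labels, spacing = as.numeric(spacing), kind = kind),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  n <- length(unique(x$labels[x$labels > 0L]))
  cat(sprintf("<label_volume kind=%s> %d object(s), dims %s\n",
              x$kind, n, paste(dim(x$labels), collapse = " x ")))
  invisible(x)
}

#' Number of labeled objects in a label volume
#' @param lv a [label_volume()].
#' @return integer count of distinct positive labels.
#' @export
n_objects <- function(lv) length(unique(lv$labels[lv$labels > 0L]))
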