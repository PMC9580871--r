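#' Parse a per-slice filename into sample, z and channel indices
#'
#' Per-slice/per-channel datasets encode the acquisition in the filename: a
#' sample name plus tokens (e.g. `"_Z"`, `"_C"`) immediately followed by the
#' z-plane and channel numbers, as in `"my_sample_position_3_Z00_C01.tif"`.
#' The last occurrence of each code is used, so codes may also appear inside
#' the sample name itself.
#'
#' @param filename file name or path of one slice.
#' @param z_code,c_code tokens immediately preceding the z and channel
#'   numbers.
#' @return One-row tibble with `sample_name`, `z_index`, `c_index`, `path`.
#' @export
#' @examples
#' parse_slice_filename("my_sample_position_3_Z00_C01.tif")
parse_slice_filename <- function(filename, z_code = "_Z", c_code = "_C") {
  base <- basename(filename)
  noext <- tools::file_path_sans_ext(base)
  find_last <- function(code) {
    esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", code)
    m <- gregexpr(paste0(esc, "[0-9]+"), noext)[[1]]
    if (m[1] == -1L) return(NULL)
    i <- length(m)
    start <- m[i]
    len <- attr(m, "match.length")[i]
    list(start = start, end = start + len - 1L,
         value = as.integer(substr(noext, start + nchar(code), start + len - 1L)))
  }
  zm <- find_last(z_code)
  cm <- find_last(c_code)
  if (is.null(zm) || is.null(cm)) {
    missing <- c(if (is.null(zm)) z_code, if (is.null(cm)) c_code)
    stop(sprintf("staging error: file '%s' has no '%s' token followed by digits",
                 base, paste(missing, collapse = "' / '")), call. = FALSE)
  }
  # strip both tokens (later first so earlier offsets stay valid)
  sample <- noext
  for (tok in list(zm, cm)[order(c(zm$start, cm$start), decreasing = TRUE)]) {
    sample <- paste0(substr(sample, 1L, tok$start - 1L),
                     substr(sample, tok$end + 1L, nchar(sample)))
  }
  sample <- sub("[_ .-]+$", "", sample)
  tibble::tibble(sample_name = sample, z_index = zm$value, c_index = cm$value,
                 path = filename)
}

#' Parse a set of slice filenames
#'
#' @param files character vector of slice file paths.
#' @inheritParams parse_slice_filename
#' @return Tibble of slice keys, one row per file.
#' @export
parse_slice_filenames <- function(files, z_code = "_Z", c_code = "_C") {
  dplyr::bind_rows(lapply(files, parse_slice_filename,
                          z_code = z_code, c_code = c_code))
}

#' Assemble per-slice files into multi-channel stacks
#'
#' Groups slice keys by sample, checks that each sample forms a complete
#' z-by-channel grid, and reads the slices into one
#' [multichannel_stack()] per sample. z and channel numbering may start at
#' any value; indices are normalized by rank. Staging is order-independent.
#'
#' @param slice_keys tibble from [parse_slice_filenames()].
#' @param pixel_size_um,z_spacing_um physical voxel spacing; required here
#'   because per-slice TIFFs carry no usable calibration. Providing correct
#'   values is critical for accurate puncta volumes.
#' @param channel_names optional channel labels.
#' @return Named list of `multichannel_stack` objects, one per sample.
#' @export
assemble_stacks <- function(slice_keys, pixel_size_um, z_spacing_um = NULL,
                            channel_names = NULL) {
  stopifnot(all(c("sample_name", "z_index", "c_index", "path") %in%
                  names(slice_keys)))
  samples <- split(slice_keys, slice_keys$sample_name)
  out <- lapply(samples, function(keys) {
    # numbering may start anywhere, but must be consecutive and complete
    zs <- seq(min(keys$z_index), max(keys$z_index))
    cs <- seq(min(keys$c_index), max(keys$c_index))
    grid <- table(factor(keys$z_index, levels = zs),
                  factor(keys$c_index, levels = cs))
    if (any(grid != 1L) || nrow(keys) != length(zs) * length(cs)) {
      bad <- which(grid == 0L, arr.ind = TRUE)
      detail <- if (nrow(bad) > 0) {
        paste("missing", paste(sprintf("(z=%s, c=%s)", zs[bad[, 1]],
                                       cs[bad[, 2]]), collapse = ", "))
      } else "duplicated slices"
      stop(sprintf("staging error: sample '%s' has an incomplete z x channel grid: %s",
                   keys$sample_name[1], detail), call. = FALSE)
    }
    first <- read_slice(keys$path[1])
    vox <- array(0, dim = c(length(zs), nrow(first), ncol(first), length(cs)))
    for (i in seq_len(nrow(keys))) {
      m <- read_slice(keys$path[i])
      if (!identical(dim(m), dim(first))) {
        stop(sprintf("staging error: slice '%s' has dimensions %s, expected %s",
                     basename(keys$path[i]), paste(dim(m), collapse = "x"),
                     paste(dim(first), collapse = "x")), call. = FALSE)
      }
      vox[match(keys$z_index[i], zs), , , match(keys$c_index[i], cs)] <- m
    }
    multichannel_stack(vox, pixel_size_um = pixel_size_um,
                       z_spacing_um = z_spacing_um,
                       channel_names = channel_names,
                       source_name = keys$sample_name[1])
  })
  out
}

read_slice <- function(path) {
  m <- tryCatch(tiff::readTIFF(path, as.is = TRUE),
                error = function(e) stop(sprintf(
                  "staging error: cannot read '%s': %s", path,
                  conditionMessage(e)), call. = FALSE))
  if (length(dim(m)) == 3L) {
    if (dim(m)[3] > 1L) {
      stop(sprintf("staging error: '%s' has multiple samples per pixel; per-slice files must be single-channel grayscale",
                   path), call. = FALSE)
    }
    m <- m[, , 1]
  }
  m
}

#' Stage a directory of per-slice TIFFs into compiled stacks
#'
#' Walks `input_dir` (recursively; immediate subdirectories are treated as
#' condition names and recorded in each stack's `source_name`), parses
#' filenames, assembles stacks, and optionally writes them with
#' [write_stack()] under `output_dir` mirroring the condition layout.
#'
#' @param input_dir directory of slice TIFFs.
#' @param output_dir optional output directory for compiled stacks.
#' @inheritParams parse_slice_filename
#' @inheritParams assemble_stacks
#' @return Named list of `multichannel_stack` objects (invisibly when
#'   `output_dir` is given).
#' @export
stage_directory <- function(input_dir, pixel_size_um, z_spacing_um = NULL,
                            z_code = "_Z", c_code = "_C",
                            channel_names = NULL, output_dir = NULL) {
  files <- list.files(input_dir, pattern = "\\.tiff?$", recursive = TRUE,
                      full.names = TRUE, ignore.case = TRUE)
  if (length(files) == 0L) {
    stop("staging error: no TIFF files found in ", input_dir, call. = FALSE)
  }
  keys <- parse_slice_filenames(files, z_code = z_code, c_code = c_code)
  rel <- dirname(substring(files, nchar(input_dir) + 2L))
  keys$sample_name <- ifelse(rel == ".", keys$sample_name,
                             file.path(rel, keys$sample_name))
  stacks <- assemble_stacks(keys, pixel_size_um = pixel_size_um,
                            z_spacing_um = z_spacing_um,
                            channel_names = channel_names)
  if (!is.null(output_dir)) {
    for (st in stacks) {
      out <- file.path(output_dir, paste0(st$source_name, ".tif"))
      dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
      write_stack(st, out)
    }
    return(invisible(stacks))
  }
  stacks
}

stack_sidecar_path <- function(path) paste0(path, ".json")

#' Write a stack (plus optional label masks) to a multipage TIFF
#'
#' Pages are ordered channel-first (all z-planes of channel 1, then channel
#' 2, ...). Label volumes are appended as extra channels whose pixel values
#' equal the label IDs, so masks can be cross-referenced with the `ROI
#' label` / `Puncta label` columns of the measurement tables and inspected
#' in FIJI. Non-negative integer data up to 65535 are stored as 16-bit
#' (bit-exact round-trip); other data fall back to 32-bit float.
#'
#' Baseline TIFF has no tags for z spacing or channel names, and the R TIFF
#' bindings expose no free-text description tag, so physical metadata is
#' written to a JSON sidecar (`<path>.json`) that [read_stack()] consumes.
#'
#' @param stack a [multichannel_stack()].
#' @param path output TIFF path.
#' @param extra_label_channels named list of [label_volume()] objects to
#'   append as mask channels.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, extra_label_channels = list()) {
  d <- dim(stack$voxels)
  vols <- lapply(seq_len(d[4]), function(ci) channel_volume(stack, ci - 1L))
  ch_names <- stack$channel_names
  mask_names <- character(0)
  if (length(extra_label_channels) > 0) {
    nms <- names(extra_label_channels) %||% rep("", length(extra_label_channels))
    for (i in seq_along(extra_label_channels)) {
      lv <- extra_label_channels[[i]]
      stopifnot(inherits(lv, "label_volume"))
      if (!identical(dim(lv$labels), d[1:3])) {
        stop("label volume does not match the stack's spatial extents",
             call. = FALSE)
      }
      nm <- if (nzchar(nms[i])) nms[i] else paste0(lv$kind, "_labels")
      vols <- c(vols, list(lv$labels * 1.0))
      ch_names <- c(ch_names, nm)
      mask_names <- c(mask_names, nm)
    }
  }
  all_vals <- unlist(lapply(vols, range))
  integerish <- all(all_vals >= 0) && max(all_vals) <= 65535 &&
    all(vapply(vols, function(v) all(abs(v - round(v)) < 1e-9), logical(1)))
  pages <- list()
  for (v in vols) {
    for (z in seq_len(d[1])) pages <- c(pages, list(matrix(v[z, , ], d[2], d[3])))
  }
  if (integerish) {
    storage <- "uint16"
    value_scale <- 1
    tiff::writeTIFF(lapply(pages, function(m) round(m) / 65535),
                    path, bits.per.sample = 16L)
  } else {
    storage <- "float32"
    value_scale <- max(1, max(all_vals))
    tiff::writeTIFF(lapply(pages, function(m) m / value_scale),
                    path, bits.per.sample = 32L)
  }
  meta <- list(pixel_size_um = stack$pixel_size_um,
               z_spacing_um = stack$z_spacing_um,
               n_channels = length(vols), n_z = d[1],
               channel_names = as.list(ch_names),
               mask_channels = as.list(mask_names),
               source_name = stack$source_name,
               storage = storage, value_scale = value_scale,
               page_order = "channel_first")
  jsonlite::write_json(meta, stack_sidecar_path(path), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read a multipage TIFF stack
#'
#' Reads a stack written by [write_stack()] (using its JSON sidecar for
#' physical metadata) or any plain multipage TIFF. Explicit arguments
#' override file metadata. For plain TIFFs without a sidecar, supply
#' `n_channels` (pages are assumed channel-first) and the voxel spacing.
#'
#' @param path TIFF file path.
#' @param pixel_size_um,z_spacing_um physical spacing overrides.
#' @param n_channels number of channels when no sidecar is present
#'   (default 1).
#' @param channel_names optional channel name override.
#' @param source_name optional acquisition name; defaults to the sidecar
#'   value or the file name.
#' @return A [multichannel_stack()].
#' @export
read_stack <- function(path, pixel_size_um = NULL, z_spacing_um = NULL,
                       n_channels = NULL, channel_names = NULL,
                       source_name = NULL) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) stop(sprintf(
                      "cannot read TIFF '%s': %s", path,
                      conditionMessage(e)), call. = FALSE))
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(m) {
    if (length(dim(m)) == 3L) m[, , 1] else m
  })
  meta <- list()
  sidecar <- stack_sidecar_path(path)
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  pixel_size_um <- pixel_size_um %||% meta$pixel_size_um
  if (is.null(pixel_size_um)) {
    stop(sprintf(paste("no physical metadata found for '%s':",
                       "provide pixel_size_um (and z_spacing_um for z-stacks)",
                       "when reading plain TIFFs"), path), call. = FALSE)
  }
  n_pages <- length(pages)
  nc <- n_channels %||% meta$n_channels %||% 1L
  if (n_pages %% nc != 0L) {
    stop(sprintf("page count %d is not divisible by %d channels", n_pages, nc),
         call. = FALSE)
  }
  nz <- n_pages / nc
  z_spacing_um <- z_spacing_um %||% meta$z_spacing_um
  if (nz > 1L && is.null(z_spacing_um)) {
    stop(sprintf(paste("no z spacing found for multi-plane stack '%s':",
                       "provide z_spacing_um"), path), call. = FALSE)
  }
  scale <- if (identical(meta$storage, "float32")) meta$value_scale else 1
  vox <- array(0, dim = c(nz, nrow(pages[[1]]), ncol(pages[[1]]), nc))
  for (ci in seq_len(nc)) {
    for (z in seq_len(nz)) {
      vox[z, , , ci] <- pages[[(ci - 1L) * nz + z]] * scale
    }
  }
  multichannel_stack(
    vox, pixel_size_um = pixel_size_um, z_spacing_um = z_spacing_um,
    channel_names = channel_names %||% unlist(meta$channel_names) %||% NULL,
    source_name = source_name %||% meta$source_name %||%
      tools::file_path_sans_ext(basename(path))
  )
}
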