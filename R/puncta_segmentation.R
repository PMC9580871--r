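#' Scale-normalized Laplacian-of-Gaussian transform
#'
#' Smooths the volume with an anisotropic Gaussian (per-axis sigmas in voxel
#' units, so physical anisotropy is handled by dividing a physical sigma by
#' each axis' spacing) and returns the negated, scale-normalized Laplacian:
#' `-(sum_axis sigma_axis^2 d2/dx_axis^2)` of the smoothed volume. Bright
#' blobs become positive peaks whose response is maximal at the matching
#' scale; a constant image maps to zero everywhere.
#'
#' @param channel_volume `(z, y, x)` numeric array (or matrix for 2D).
#' @param sigma_vector per-axis Gaussian s.d. in voxels, `(z, y, x)`;
#'   entries of 0 skip that axis (used for 2D data).
#' @return numeric array of LoG responses, same dimensions.
#' @export
log_transform <- function(channel_volume, sigma_vector) {
  v <- as_volume(channel_volume)
  stopifnot(length(sigma_vector) == 3L, all(sigma_vector >= 0))
  sm <- cpp_gaussian_smooth(v, as.numeric(sigma_vector))
  d <- dim(v)
  resp <- array(0, dim = d)
  for (axis in 1:3) {
    if (sigma_vector[axis] <= 0 || d[axis] == 1L) next
    n <- d[axis]
    up <- c(2:n, n)
    dn <- c(1L, 1:(n - 1L))
    d2 <- switch(axis,
                 sm[up, , , drop = FALSE] + sm[dn, , , drop = FALSE] - 2 * sm,
                 sm[, up, , drop = FALSE] + sm[, dn, , drop = FALSE] - 2 * sm,
                 sm[, , up, drop = FALSE] + sm[, , dn, drop = FALSE] - 2 * sm)
    resp <- resp - sigma_vector[axis]^2 * d2
  }
  resp
}

# detection scales: blob "size" s (um) maps to per-axis sigma
# (s / spacing_axis) / (2 sqrt(D)) voxels, so the LoG maximum of a ball of
# diameter s falls at that scale
detection_scales <- function(spacing, minsize_um, maxsize_um, num_sigma, two_d) {
  sizes <- if (num_sigma == 1L) minsize_um else
    seq(minsize_um, maxsize_um, length.out = num_sigma)
  D <- if (two_d) 2 else 3
  lapply(sizes, function(s) {
    sigma_um <- s / (2 * sqrt(D))
    sig_vox <- sigma_um / spacing
    if (two_d) sig_vox[1] <- 0
    list(size_um = s, sigma_um = sigma_um, sigma_vox = sig_vox)
  })
}

# multiscale LoG detection. Centers are maxima of the full
# (scale x space) scale-space: spatial 26-neighborhood maxima at their own
# scale that also dominate the dilated responses of the adjacent scales.
# Returns the candidate centers, the per-scale responses, and their
# max-over-scales projection (used for LoG-space background statistics).
log_detect <- function(channel_volume, spacing, minsize_um = 0.2,
                       maxsize_um = 2, num_sigma = 5L,
                       threshold_detection = 0.001, overlap = 1) {
  v <- as_volume(channel_volume)
  mx <- max(v)
  if (mx > 0) v <- v / mx   # unit-maximum scale so thresholds are dimensionless
  two_d <- dim(v)[1] == 1L
  scales <- detection_scales(spacing, minsize_um, maxsize_um, num_sigma, two_d)
  responses <- lapply(scales, function(sc) log_transform(v, sc$sigma_vox))
  dilated <- lapply(responses, cpp_max_filter)
  rows <- list()
  for (s in seq_along(scales)) {
    resp <- responses[[s]]
    cand <- cpp_local_maxima(resp) & (resp > threshold_detection)
    if (s > 1L) cand <- cand & (resp >= dilated[[s - 1L]])
    if (s < length(scales)) cand <- cand & (resp >= dilated[[s + 1L]])
    idx <- which(cand)
    if (length(idx) == 0L) next
    co <- arrayInd(idx, dim(v))
    rows[[s]] <- tibble::tibble(
      z = co[, 1] - 1L, y = co[, 2] - 1L, x = co[, 3] - 1L,
      scale_um = scales[[s]]$size_um, sigma_um = scales[[s]]$sigma_um,
      response = resp[idx], roi_label = NA_integer_)
  }
  centers <- dplyr::bind_rows(rows)
  resp_max <- responses[[1]]
  for (s in seq_along(responses)[-1]) resp_max <- pmax(resp_max, responses[[s]])
  dim(resp_max) <- dim(v)
  if (nrow(centers) > 0L) {
    centers <- prune_overlapping_blobs(centers, spacing, overlap,
                                       D = if (two_d) 2 else 3)
  }
  list(centers = centers, response = resp_max, responses = responses,
       scales = scales)
}

# sphere-overlap pruning: blobs are spheres of radius sigma*sqrt(D) (um);
# of two blobs whose overlap fraction (lens volume over the smaller sphere)
# reaches `overlap`, the smaller is removed
prune_overlapping_blobs <- function(centers, spacing, overlap, D) {
  n <- nrow(centers)
  if (n <= 1L || overlap > 1) return(centers)
  pos <- cbind(centers$z * spacing[1], centers$y * spacing[2],
               centers$x * spacing[3])
  r <- centers$sigma_um * sqrt(D)
  keep <- cpp_prune_blobs(pos, r, centers$response, overlap)
  centers[keep, , drop = FALSE]
}

sphere_overlap_fraction <- function(r1, r2, d) {
  rmin <- min(r1, r2)
  if (rmin <= 0) return(1)
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(1)
  lens <- pi * (r1 + r2 - d)^2 *
    (d^2 + 2 * d * (r1 + r2) - 3 * (r1 - r2)^2) / (12 * d)
  lens / ((4 / 3) * pi * rmin^3)
}

#' Detect puncta centers with a multiscale LoG detector
#'
#' Applies [log_transform()] at `num_sigma` linearly spaced scales between
#' `minsize_um` and `maxsize_um` (sizes are converted to per-axis voxel
#' sigmas using the physical spacing), finds local maxima over space and
#' scale above `threshold_detection`, and removes the smaller of any two
#' blobs whose sphere-overlap fraction reaches `overlap`. Intensities are
#' rescaled to unit maximum before the transform, so thresholds are
#' dimensionless and independent of camera bit depth. Decreasing
#' `threshold_detection` yields a superset of centers.
#'
#' @param channel_volume `(z, y, x)` intensity array.
#' @param spacing voxel spacing `(z, y, x)` in micrometres.
#' @param minsize_um,maxsize_um,num_sigma,threshold_detection,overlap see
#'   [pipeline_params()].
#' @return Tibble of puncta centers: voxel coordinates `z`, `y`, `x`
#'   (0-based), detected blob size `scale_um`, `sigma_um`, LoG `response`,
#'   and `roi_label` (`NA` until assigned by [assign_roi_labels()]).
#' @export
detect_centers <- function(channel_volume, spacing, minsize_um = 0.2,
                           maxsize_um = 2, num_sigma = 5L,
                           threshold_detection = 0.001, overlap = 1) {
  log_detect(channel_volume, spacing, minsize_um, maxsize_um, num_sigma,
             threshold_detection, overlap)$centers
}

#' Assign puncta centers to enclosing ROIs
#'
#' @param centers tibble from [detect_centers()].
#' @param roi a [label_volume()] of ROIs (or a plain label array).
#' @return `centers` with `roi_label` filled in (0 = outside any ROI).
#' @export
assign_roi_labels <- function(centers, roi) {
  labels <- if (inherits(roi, "label_volume")) roi$labels else as_volume(roi)
  if (nrow(centers) == 0L) {
    centers$roi_label <- integer(0)
    return(centers)
  }
  centers$roi_label <- labels[cbind(centers$z + 1L, centers$y + 1L,
                                    centers$x + 1L)]
  centers
}

#' Compute ROI background intensities
#'
#' The background of each ROI is the `background_percentile` of its voxel
#' intensities (50 = median). With `global_background = TRUE` a single
#' value — the `global_background_percentile` of the per-ROI values — is
#' used for every ROI; otherwise each ROI keeps its own, which increases
#' sensitivity in dim cells and suppresses spurious detections in bright
#' ones. When a LoG response volume is supplied, the same statistics are
#' additionally computed on its absolute values (used by segmentation
#' mode 1).
#'
#' @param channel_volume raw intensity volume.
#' @param roi a [label_volume()] of ROIs (or plain label array).
#' @param background_percentile percentile in `[0, 100]` within each ROI.
#' @param global_background use one pooled value for all ROIs.
#' @param global_background_percentile percentile in `[0, 100]` across the
#'   per-ROI values.
#' @param log_volume optional LoG response volume aligned with
#'   `channel_volume`.
#' @return An object of class `background_model`.
#' @export
compute_background <- function(channel_volume, roi,
                               background_percentile = 50,
                               global_background = FALSE,
                               global_background_percentile = 95,
                               log_volume = NULL) {
  stopifnot(background_percentile >= 0, background_percentile <= 100,
            global_background_percentile >= 0,
            global_background_percentile <= 100)
  labels <- if (inherits(roi, "label_volume")) roi$labels else as_volume(roi)
  v <- as_volume(channel_volume)
  stopifnot(identical(dim(labels), dim(v)))
  pos <- labels > 0L
  per_roi <- vapply(split(v[pos], labels[pos]), quantile,
                    numeric(1), probs = background_percentile / 100,
                    names = FALSE)
  global_value <- if (length(per_roi) > 0) {
    unname(quantile(per_roi, global_background_percentile / 100))
  } else NA_real_
  log_vals <- NULL
  log_global <- NULL
  if (!is.null(log_volume)) {
    lv <- abs(as_volume(log_volume))
    log_vals <- vapply(split(lv[pos], labels[pos]), quantile,
                       numeric(1), probs = background_percentile / 100,
                       names = FALSE)
    log_global <- if (length(log_vals) > 0) {
      unname(quantile(log_vals, global_background_percentile / 100))
    } else NA_real_
  }
  structure(
    list(mode = if (global_background) "global" else "per_roi",
         per_roi_value = per_roi, global_value = global_value,
         percentile = background_percentile,
         global_percentile = global_background_percentile,
         log_space_values = log_vals, log_global_value = log_global),
    class = "background_model")
}

# background applicable to a vector of roi labels. Centers outside every
# ROI (label 0) are compared against the global value, which is always
# available once ROIs exist; NA means "no applicable background, keep".
applicable_background <- function(bg, roi_labels, space = c("raw", "log")) {
  space <- match.arg(space)
  vals <- if (space == "raw") bg$per_roi_value else bg$log_space_values
  gl <- if (space == "raw") bg$global_value else bg$log_global_value
  if (is.null(gl)) gl <- NA_real_
  if (bg$mode == "global") {
    rep(gl, length(roi_labels))
  } else {
    out <- unname(vals[as.character(roi_labels)])
    out[roi_labels == 0L] <- gl
    out
  }
}

#' Filter puncta centers by contrast to ROI background
#'
#' Keeps a center only when the raw intensity at its position is at least
#' `threshold_background` times the applicable background value (per-ROI or
#' global, see [compute_background()]). `threshold_background = 0` keeps
#' all centers. Centers outside every ROI are kept under per-ROI
#' backgrounds (no background applies) and tested against the global value
#' under a global background.
#'
#' @param centers tibble with `roi_label` filled (see
#'   [assign_roi_labels()]).
#' @param channel_volume raw intensity volume.
#' @param bg a `background_model` from [compute_background()].
#' @param threshold_background multiple of the background below which
#'   centers are removed.
#' @return Filtered centers tibble.
#' @export
filter_centers <- function(centers, channel_volume, bg,
                           threshold_background = 3) {
  if (threshold_background == 0 || nrow(centers) == 0L) return(centers)
  v <- as_volume(channel_volume)
  intensity <- v[cbind(centers$z + 1L, centers$y + 1L, centers$x + 1L)]
  ref <- applicable_background(bg, centers$roi_label, space = "raw")
  keep <- is.na(ref) | intensity >= threshold_background * ref
  centers[keep, , drop = FALSE]
}

#' Segment puncta voxels by thresholding and seeded watershed
#'
#' Foreground voxels are selected by the segmentation mode — mode 0: LoG
#' response above the absolute `threshold_segmentation`; mode 1: LoG
#' response above `threshold_segmentation` times the ROI's background in
#' LoG space; mode 2: raw intensity above `threshold_segmentation` times
#' the ROI's raw background — then partitioned among the surviving centers
#' by a 3D seeded watershed. In the LoG modes each punctum is thresholded
#' and flooded on the response at its own detected scale (smaller scales
#' claim voxels first), which keeps segmented volumes faithful to blob
#' size; mode 2 floods the negated raw intensity. Foreground components
#' containing no seed are discarded, which may remove some additional
#' puncta beyond the center filters. Modes 1–2 require ROI masks; under a
#' per-ROI background, voxels outside every ROI take the global background
#' value.
#'
#' @param channel_volume raw intensity volume.
#' @param centers surviving centers tibble (seeds), including their
#'   detected `scale_um`.
#' @param spacing voxel spacing `(z, y, x)` in micrometres.
#' @param roi a [label_volume()] of ROIs; required for modes 1–2.
#' @param bg a `background_model`; computed with defaults when omitted and
#'   needed.
#' @param segmentation_mode 0, 1 or 2.
#' @param threshold_segmentation threshold value, interpreted per mode.
#' @param log_detection optional detection object (responses per scale)
#'   from the internal detector, as reused by [run_puncta_segmentation()];
#'   recomputed from the volume when omitted.
#' @param minsize_um,maxsize_um,num_sigma detector settings used only if
#'   `log_detection` must be recomputed.
#' @param blob_boundary_fraction in the LoG modes, each blob's flood stops
#'   at the isoline `blob_boundary_fraction` times its own peak response.
#'   For a solid sphere probed at the matching scale the boundary lies at
#'   about a quarter of the central response, so the default keeps
#'   segmented volumes close to true blob volumes; set to 0 to flood the
#'   entire thresholded foreground.
#' @return A [label_volume()] of kind `"puncta"`, one label per punctum,
#'   labels ordered like `centers` rows.
#' @export
segment_puncta <- function(channel_volume, centers, spacing, roi = NULL,
                           bg = NULL, segmentation_mode = 0L,
                           threshold_segmentation = 0.001,
                           log_detection = NULL, minsize_um = 0.2,
                           maxsize_um = 2, num_sigma = 5L,
                           blob_boundary_fraction = 0.25) {
  v <- as_volume(channel_volume)
  if (segmentation_mode %in% c(1L, 2L) && is.null(roi)) {
    stop("segmentation modes 1 and 2 require ROI masks; use mode 0 when no ROIs were segmented",
         call. = FALSE)
  }
  roi_labels <- if (!is.null(roi)) {
    if (inherits(roi, "label_volume")) roi$labels else as_volume(roi)
  } else NULL
  labels <- array(0L, dim = dim(v))
  if (segmentation_mode == 2L) {
    if (is.null(bg)) bg <- compute_background(v, roi_labels)
    fg <- v > threshold_volume(bg, roi_labels, threshold_segmentation, "raw")
    dim(fg) <- dim(v)
    seeds <- array(0L, dim = dim(v))
    if (nrow(centers) > 0L) {
      seeds[cbind(centers$z + 1L, centers$y + 1L, centers$x + 1L)] <-
        seq_len(nrow(centers))
    }
    labels <- cpp_watershed_seeded(-v, seeds, fg,
                                   rep(Inf, max(1L, nrow(centers))))
    return(label_volume(relabel_consecutive(labels), spacing, kind = "puncta"))
  }
  det <- log_detection %||% log_detect(v, spacing, minsize_um, maxsize_um,
                                       num_sigma, threshold_detection = Inf)
  if (segmentation_mode == 1L) {
    if (is.null(bg) || is.null(bg$log_space_values)) {
      bg <- compute_background(v, roi_labels, log_volume = det$response)
    }
  } else if (!segmentation_mode %in% c(0L, 1L)) {
    stop("segmentation_mode must be 0, 1 or 2", call. = FALSE)
  }
  claimed <- array(FALSE, dim = dim(v))
  if (nrow(centers) == 0L) {
    return(label_volume(labels, spacing, kind = "puncta"))
  }
  for (s in seq_along(det$scales)) {
    size_s <- det$scales[[s]]$size_um
    rows <- which(abs(centers$scale_um - size_s) < 1e-9)
    if (length(rows) == 0L) next
    resp <- det$responses[[s]]
    fg <- if (segmentation_mode == 0L) {
      resp > threshold_segmentation
    } else {
      resp > threshold_volume(bg, roi_labels, threshold_segmentation, "log")
    }
    dim(fg) <- dim(v)
    fg <- fg & !claimed
    seeds <- array(0L, dim = dim(v))
    seeds[cbind(centers$z[rows] + 1L, centers$y[rows] + 1L,
                centers$x[rows] + 1L)] <- rows
    ceiling_h <- rep(Inf, nrow(centers))
    if (blob_boundary_fraction > 0) {
      peak <- resp[cbind(centers$z[rows] + 1L, centers$y[rows] + 1L,
                         centers$x[rows] + 1L)]
      ceiling_h[rows] <- -blob_boundary_fraction * pmax(peak, 0)
    }
    ws <- cpp_watershed_seeded(-resp, seeds, fg, ceiling_h)
    hit <- ws > 0L
    labels[hit] <- ws[hit]
    claimed <- claimed | hit
  }
  label_volume(relabel_consecutive(labels), spacing, kind = "puncta")
}

# per-voxel threshold: threshold * background of the enclosing ROI;
# +Inf where no background applies (outside ROIs under per-ROI mode)
threshold_volume <- function(bg, roi_labels, threshold, space) {
  vals <- if (space == "raw") bg$per_roi_value else bg$log_space_values
  gl <- if (space == "raw") bg$global_value else bg$log_global_value
  thr <- array(Inf, dim = dim(roi_labels))
  if (bg$mode == "global") {
    thr[] <- threshold * gl
  } else {
    pos <- roi_labels > 0L
    thr[pos] <- threshold * unname(vals[as.character(roi_labels[pos])])
  }
  thr
}

#' Filter segmented puncta by size and ROI membership
#'
#' @param puncta a [label_volume()] of kind `"puncta"`.
#' @param maxrad_um drop puncta whose equivalent-sphere radius (from voxel
#'   volume and physical voxel size) exceeds this; `NULL` keeps all puncta.
#' @param remove_out_of_roi delete punctum voxels lying outside every ROI.
#' @param roi a [label_volume()] of ROIs (required when
#'   `remove_out_of_roi = TRUE`).
#' @return A [label_volume()] relabeled consecutively.
#' @export
filter_puncta <- function(puncta, maxrad_um = NULL,
                          remove_out_of_roi = FALSE, roi = NULL) {
  labels <- puncta$labels
  spacing <- puncta$spacing
  if (remove_out_of_roi) {
    if (is.null(roi)) stop("remove_out_of_roi requires ROI masks", call. = FALSE)
    roi_labels <- if (inherits(roi, "label_volume")) roi$labels else as_volume(roi)
    labels[roi_labels == 0L] <- 0L
  }
  if (!is.null(maxrad_um) && max(labels) > 0L) {
    two_d <- dim(labels)[1] == 1L
    vox_vol <- voxel_volume_um(spacing, two_d)
    counts <- tabulate(labels[labels > 0L], nbins = max(labels))
    rad <- if (two_d) sqrt(counts * vox_vol / pi) else
      (3 * counts * vox_vol / (4 * pi))^(1 / 3)
    drop <- which(counts > 0L & rad > maxrad_um)
    if (length(drop) > 0L) labels[labels %in% drop] <- 0L
  }
  label_volume(relabel_consecutive(labels), spacing, kind = "puncta")
}

#' Run the full puncta segmentation for every puncta channel of a stack
#'
#' Convenience wrapper chaining [detect_centers()], [assign_roi_labels()],
#' [compute_background()], [filter_centers()], [segment_puncta()] and
#' [filter_puncta()] with the settings in a [pipeline_params()] object.
#'
#' @param stack a [multichannel_stack()].
#' @param roi optional [label_volume()] of ROIs from [segment_rois()].
#' @param params a [pipeline_params()] list.
#' @return A list with `labels_by_channel` (named list of puncta
#'   [label_volume()]s, keyed by channel name) and `centers_by_channel`
#'   (surviving centers per channel).
#' @export
run_puncta_segmentation <- function(stack, roi = NULL,
                                    params = pipeline_params()) {
  params <- validate_params(params)
  spacing <- stack_spacing(stack)
  labels_by_channel <- list()
  centers_by_channel <- list()
  for (ch in params$puncta_channels) {
    ch_name <- stack$channel_names[ch + 1L]
    vol <- channel_volume(stack, ch)
    det <- log_detect(vol, spacing, params$minsize_um, params$maxsize_um,
                      params$num_sigma, params$threshold_detection,
                      params$overlap)
    centers <- det$centers
    bg <- NULL
    if (!is.null(roi)) {
      centers <- assign_roi_labels(centers, roi)
      bg <- compute_background(vol, roi, params$background_percentile,
                               params$global_background,
                               params$global_background_percentile,
                               log_volume = det$response)
      centers <- filter_centers(centers, vol, bg, params$threshold_background)
    }
    pl <- segment_puncta(vol, centers, spacing, roi = roi, bg = bg,
                         segmentation_mode = params$segmentation_mode,
                         threshold_segmentation = params$threshold_segmentation,
                         log_detection = det,
                         blob_boundary_fraction = params$blob_boundary_fraction %||% 0.25)
    pl <- filter_puncta(pl, maxrad_um = params$maxrad_um,
                        remove_out_of_roi = params$remove_out_of_roi,
                        roi = roi)
    labels_by_channel[[ch_name]] <- pl
    centers_by_channel[[ch_name]] <- centers
  }
  list(labels_by_channel = labels_by_channel,
       centers_by_channel = centers_by_channel)
}
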