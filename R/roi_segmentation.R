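#' Classical ROI segmentation backend
#'
#' A threshold-based segmentation backend for cells/nuclei: Gaussian
#' smoothing followed by Otsu thresholding and connected-component labeling,
#' per z-layer (merged in 3D afterwards by [merge_layers_3d()]) or directly
#' in 3D. Deep-learning segmenters can be plugged in through the same
#' interface (see [segment_rois()]); this backend requires no model weights
#' and is what the test-suite exercises.
#'
#' @param smooth_sigma_um Gaussian smoothing s.d. in micrometres applied
#'   before thresholding.
#' @return A backend function
#'   `function(volume, spacing, params)` returning a list of per-layer 2D
#'   label matrices when `params$do_3D` is `FALSE`, or a 3D label array when
#'   `TRUE`.
#' @export
roi_backend_classical <- function(smooth_sigma_um = 0.25) {
  function(volume, spacing, params) {
    volume <- as_volume(volume)
    d <- dim(volume)
    empty_layers <- function() {
      lapply(seq_len(d[1]), function(z) matrix(0L, d[2], d[3]))
    }
    if (max(volume) <= 0) {
      return(if (isTRUE(params$do_3D)) array(0L, dim = d) else empty_layers())
    }
    sig <- smooth_sigma_um / spacing
    if (!isTRUE(params$do_3D) || d[1] == 1L) sig[1] <- 0
    sm <- cpp_gaussian_smooth(volume, sig)
    # one global Otsu threshold for the whole volume: layers without
    # objects stay empty instead of thresholding their own noise
    thr <- otsu_threshold(as.numeric(sm))
    mask <- array(as.integer(sm > thr), dim = d)
    if (isTRUE(params$do_3D)) {
      relabel_consecutive(cpp_label_components(mask, 26L))
    } else {
      lapply(seq_len(d[1]), function(z) {
        layer <- array(mask[z, , ], dim = c(1L, d[2], d[3]))
        lab <- relabel_consecutive(cpp_label_components(layer, 26L))
        matrix(lab[1, , ], d[2], d[3])
      })
    }
  }
}

#' Segment ROIs (cells or nuclei) in a stack
#'
#' Runs a segmentation backend on the designated channel and applies the
#' post-processing that turns raw backend output into analysis-ready 3D
#' ROI masks: per-layer 2D labels are merged across z by
#' [merge_layers_3d()], small ROIs are removed by [remove_small_rois()],
#' and (optionally) ROIs touching the xy image border are dropped.
#'
#' @param stack a [multichannel_stack()].
#' @param params a [pipeline_params()] list; uses `channel`, `do_3D`,
#'   `diameter`, `remove_small_mode`, `remove_small_diam_fraction`.
#' @param channel_spec overrides `params$channel`: one zero-based channel
#'   index, or `c(nuclei, cyto)` for whole-cell segmentation with an
#'   auxiliary nuclear stain (the backend receives the last index as the
#'   target channel).
#' @param backend a backend function as produced by
#'   [roi_backend_classical()] (the default).
#' @param min_overlap_fraction layer-linking threshold passed to
#'   [merge_layers_3d()].
#' @param exclude_edge_rois drop ROIs touching the xy image border
#'   (off by default; partial ROIs are otherwise handled by the volume-based
#'   small-ROI filter).
#' @return A [label_volume()] of kind `"roi"`.
#' @export
segment_rois <- function(stack, params = pipeline_params(),
                         channel_spec = NULL,
                         backend = roi_backend_classical(),
                         min_overlap_fraction = 0.5,
                         exclude_edge_rois = FALSE) {
  spec <- channel_spec %||% params$channel
  target <- as.integer(spec[length(spec)])
  if (target < 0L || target >= n_channels(stack)) {
    stop("ROI channel index out of range: ", target, call. = FALSE)
  }
  spacing <- stack_spacing(stack)
  vol <- channel_volume(stack, target)
  raw <- tryCatch(backend(vol, spacing, params), error = function(e) {
    stop(sprintf(paste("ROI segmentation backend failed: %s.",
                       "Consider do_3D = FALSE or gpu = FALSE for",
                       "resource-limited backends."),
                 conditionMessage(e)), call. = FALSE)
  })
  lv <- if (is.list(raw)) {
    merge_layers_3d(raw, min_overlap_fraction = min_overlap_fraction,
                    spacing = spacing)
  } else {
    label_volume(relabel_consecutive(raw), spacing, kind = "roi")
  }
  diameter <- params$diameter %||% estimate_diameter_px(lv)
  if (!is.null(diameter) && params$remove_small_diam_fraction > 0) {
    lv <- remove_small_rois(lv, diameter_px = diameter,
                            remove_small_diam_fraction =
                              params$remove_small_diam_fraction,
                            remove_small_mode = params$remove_small_mode)
  }
  if (exclude_edge_rois) lv <- drop_edge_rois(lv)
  lv
}

# median equivalent-sphere diameter (pixels) over current ROIs; NULL if none
estimate_diameter_px <- function(lv) {
  counts <- tabulate(lv$labels[lv$labels > 0L])
  counts <- counts[counts > 0L]
  if (length(counts) == 0L) return(NULL)
  stats::median(2 * (3 * counts / (4 * pi))^(1 / 3))
}

#' Merge per-layer 2D labels into 3D ROIs
#'
#' 2D segmentation backends label each z-layer independently; objects in
#' adjacent layers are linked into one 3D ROI when their xy overlap
#' fraction (intersection over the smaller object's area) reaches
#' `min_overlap_fraction`. Linking is transitive along chains of adjacent
#' layers but never bridges a z gap. Output labels are consecutive from 1.
#'
#' @param layer_labels list of integer 2D label matrices, one per z-layer
#'   (a single 3D array of per-layer labels is also accepted).
#' @param min_overlap_fraction minimum intersection-over-smaller-area to
#'   link objects in adjacent layers.
#' @param spacing voxel spacing `(z, y, x)` in micrometres recorded on the
#'   output.
#' @return A [label_volume()] of kind `"roi"`.
#' @export
merge_layers_3d <- function(layer_labels, min_overlap_fraction = 0.5,
                            spacing = c(1, 1, 1)) {
  if (!is.list(layer_labels)) {
    layer_labels <- lapply(seq_len(dim(layer_labels)[1]), function(z) {
      matrix(layer_labels[z, , ], dim(layer_labels)[2], dim(layer_labels)[3])
    })
  }
  nz <- length(layer_labels)
  stopifnot(nz >= 1L)
  dims2 <- dim(layer_labels[[1]])
  # global node id per (layer, label)
  offsets <- integer(nz)
  n_nodes <- 0L
  for (z in seq_len(nz)) {
    offsets[z] <- n_nodes
    n_nodes <- n_nodes + max(0L, max(layer_labels[[z]]))
  }
  parent <- seq_len(max(1L, n_nodes))
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  unite <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  for (z in seq_len(nz - 1L)) {
    a <- layer_labels[[z]]
    b <- layer_labels[[z + 1L]]
    if (max(a) == 0L || max(b) == 0L) next
    area_a <- tabulate(a[a > 0L], nbins = max(a))
    area_b <- tabulate(b[b > 0L], nbins = max(b))
    both <- a > 0L & b > 0L
    if (!any(both)) next
    pair_counts <- table(a[both], b[both])
    la <- as.integer(rownames(pair_counts))
    lb <- as.integer(colnames(pair_counts))
    for (i in seq_along(la)) {
      for (j in seq_along(lb)) {
        inter <- pair_counts[i, j]
        if (inter == 0) next
        frac <- inter / min(area_a[la[i]], area_b[lb[j]])
        if (frac >= min_overlap_fraction) {
          unite(offsets[z] + la[i], offsets[z + 1L] + lb[j])
        }
      }
    }
  }
  labels <- array(0L, dim = c(nz, dims2))
  if (n_nodes > 0L) {
    roots <- vapply(seq_len(n_nodes), find, integer(1))
    for (z in seq_len(nz)) {
      lay <- layer_labels[[z]]
      pos <- lay > 0L
      if (any(pos)) {
        out_lay <- matrix(labels[z, , ], dims2[1], dims2[2])
        out_lay[pos] <- roots[offsets[z] + lay[pos]]
        labels[z, , ] <- out_lay
      }
    }
    labels <- relabel_consecutive(labels)
  }
  label_volume(labels, spacing, kind = "roi")
}

#' Remove small ROIs
#'
#' Drops ROIs below a size threshold expressed as a fraction of the target
#' ROI diameter. In `"3D"` mode an ROI is removed when its voxel count is
#' below the volume of a sphere of diameter
#' `remove_small_diam_fraction * diameter_px`; this also excludes ROIs only
#' a small part of which is inside the field of view. In `"2D"` mode the
#' criterion is the maximal single-layer area against the corresponding
#' disk area. Survivors are relabeled consecutively, preserving order.
#'
#' @param lv a [label_volume()] of ROIs.
#' @param diameter_px target ROI diameter in pixels (> 0).
#' @param remove_small_diam_fraction size threshold as a fraction of
#'   `diameter_px`; 0 removes nothing.
#' @param remove_small_mode `"3D"` (volume) or `"2D"` (max layer area).
#' @return A [label_volume()] with small ROIs removed.
#' @export
remove_small_rois <- function(lv, diameter_px,
                              remove_small_diam_fraction = 0.5,
                              remove_small_mode = c("3D", "2D")) {
  remove_small_mode <- match.arg(remove_small_mode)
  stopifnot(diameter_px > 0)
  labels <- lv$labels
  n <- max(labels)
  if (n == 0L || remove_small_diam_fraction <= 0) return(lv)
  d <- remove_small_diam_fraction * diameter_px
  keep <- if (remove_small_mode == "3D") {
    vol <- tabulate(labels[labels > 0L], nbins = n)
    vol >= (pi / 6) * d^3
  } else {
    max_area <- numeric(n)
    for (z in seq_len(dim(labels)[1])) {
      lay <- labels[z, , ]
      if (max(lay) == 0L) next
      a <- tabulate(lay[lay > 0L], nbins = n)
      max_area <- pmax(max_area, a)
    }
    max_area >= (pi / 4) * d^2
  }
  drop <- which(!keep)
  if (length(drop) > 0L) labels[labels %in% drop] <- 0L
  label_volume(relabel_consecutive(labels), lv$spacing, kind = lv$kind)
}

#' Drop ROIs touching the xy image border
#'
#' @param lv a [label_volume()].
#' @return A [label_volume()] without edge-touching ROIs, relabeled
#'   consecutively.
#' @export
drop_edge_rois <- function(lv) {
  labels <- lv$labels
  d <- dim(labels)
  edge <- unique(c(labels[, c(1, d[2]), ], labels[, , c(1, d[3])]))
  edge <- edge[edge > 0L]
  if (length(edge) > 0L) labels[labels %in% edge] <- 0L
  label_volume(relabel_consecutive(labels), lv$spacing, kind = lv$kind)
}
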