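#' Pearson correlation with p-value
#'
#' Sample Pearson correlation between paired voxel intensities, with a
#' two-sided p-value from the t statistic
#' \eqn{r \sqrt{(n - 2) / (1 - r^2)}} on `n - 2` degrees of freedom.
#'
#' @param x,y paired numeric vectors (at least 3 values).
#' @return List with elements `r` and `p` (both `NA` when either input has
#'   zero variance or fewer than 3 pairs).
#' @export
#' @examples
#' pearson_with_p(1:10, 2 * (1:10) + 1)
pearson_with_p <- function(x, y) {
  n <- length(x)
  stopifnot(n == length(y))
  if (n < 3L || sd(x) == 0 || sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_))
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1) return(list(r = r, p = 0))
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t_stat), df = n - 2))
}

bin_indices <- function(x, bins) {
  r <- range(x)
  if (diff(r) == 0) return(rep(1L, length(x)))
  i <- as.integer(floor((x - r[1]) / diff(r) * bins)) + 1L
  pmin(i, bins)
}

#' Shannon entropy of an intensity distribution
#'
#' Entropy in bits, `-sum(p * log2(p))`, of the normalized histogram of
#' `x` over `bins` equal-width bins spanning the observed range.
#'
#' @param x numeric vector of intensities.
#' @param bins number of histogram bins (>= 2).
#' @return Entropy in bits (0 for a constant region).
#' @export
intensity_entropy <- function(x, bins = 256L) {
  stopifnot(length(x) >= 1L, bins >= 2L)
  p <- tabulate(bin_indices(x, bins), nbins = bins) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Mutual information between two intensity vectors
#'
#' MI in bits of the joint histogram,
#' `sum p(a,b) log2(p(a,b) / (p(a) p(b)))`, with `bins` equal-width bins
#' spanning each variable's observed range.
#'
#' @param x,y paired numeric vectors.
#' @param bins number of bins per variable (>= 2).
#' @return Mutual information in bits.
#' @export
mutual_information <- function(x, y, bins = 256L) {
  n <- length(x)
  stopifnot(n == length(y), n >= 1L, bins >= 2L)
  ix <- bin_indices(x, bins)
  iy <- bin_indices(y, bins)
  joint <- tabulate(ix + bins * (iy - 1L), nbins = bins * bins) / n
  px <- tabulate(ix, nbins = bins) / n
  py <- tabulate(iy, nbins = bins) / n
  jm <- matrix(joint, bins, bins)
  mi <- 0
  nz <- which(jm > 0, arr.ind = TRUE)
  for (k in seq_len(nrow(nz))) {
    pab <- jm[nz[k, 1], nz[k, 2]]
    mi <- mi + pab * log2(pab / (px[nz[k, 1]] * py[nz[k, 2]]))
  }
  mi
}

#' Overlap coefficient (intersection over union) of two puncta masks
#'
#' @param mask_a,mask_b logical arrays (or label arrays; positive = in a
#'   punctum).
#' @param roi_mask optional logical array restricting the comparison to one
#'   ROI.
#' @return `|A ∩ B| / |A ∪ B|`; `NA` when the union is empty.
#' @export
overlap_coefficient <- function(mask_a, mask_b, roi_mask = NULL) {
  a <- mask_a > 0
  b <- mask_b > 0
  if (!is.null(roi_mask)) {
    a <- a & roi_mask
    b <- b & roi_mask
  }
  uni <- sum(a | b)
  if (uni == 0) return(NA_real_)
  sum(a & b) / uni
}

#' Distance from a point to the ROI border
#'
#' Anisotropy-aware Euclidean distance (in micrometres) from a center of
#' mass to the nearest boundary voxel of its ROI. Returns 0 when the center
#' lies outside the mask (puncta located in the background).
#'
#' @param center `(z, y, x)` voxel coordinates, 0-based (fractional values
#'   from a center of mass are fine).
#' @param roi_mask logical `(z, y, x)` array of the single ROI.
#' @param spacing voxel spacing `(z, y, x)` in micrometres.
#' @return Distance in micrometres.
#' @export
distance_to_border_um <- function(center, roi_mask, spacing) {
  roi_mask <- as_volume(roi_mask)
  vox <- pmin(pmax(round(center) + 1L, 1L), dim(roi_mask))
  if (!roi_mask[vox[1], vox[2], vox[3]]) return(0)
  boundary <- cpp_label_boundary(array(as.integer(roi_mask), dim(roi_mask)))
  bidx <- which(boundary)
  if (length(bidx) == 0L) return(0)
  co <- arrayInd(bidx, dim(roi_mask)) - 1L
  d2 <- (co[, 1] - center[1])^2 * spacing[1]^2 +
    (co[, 2] - center[2])^2 * spacing[2]^2 +
    (co[, 3] - center[3])^2 * spacing[3]^2
  sqrt(min(d2))
}

# boundary voxel coordinates (0-based) per ROI label
roi_boundary_coords <- function(roi_labels) {
  boundary <- cpp_label_boundary(roi_labels)
  bidx <- which(boundary)
  if (length(bidx) == 0L) return(list())
  co <- arrayInd(bidx, dim(roi_labels)) - 1L
  split.data.frame(co, roi_labels[bidx])
}

pair_names <- function(channels) {
  if (length(channels) < 2L) return(NULL)
  utils::combn(channels, 2L, simplify = FALSE)
}

#' Measure individual puncta
#'
#' One row per punctum per segmentation channel: intensity-weighted center
#' of mass (0-based voxel coordinates, `x` = fastest image axis), volume in
#' pixels and um^3 (um^2 for 2D data), enclosing ROI (by center of mass; 0
#' = background, in which case the distance to the ROI border is reported
#' as 0), per-channel mean and integrated intensities, and pairwise Pearson
#' (with p-value) and mutual information between all fluorescent channels
#' inside the punctum. Column names follow the standard per-punctum
#' measurement schema, expanded per channel.
#'
#' @param stack a [multichannel_stack()].
#' @param puncta_labels_by_channel named list of puncta [label_volume()]s,
#'   keyed by the segmentation channel's name (as from
#'   [run_puncta_segmentation()]).
#' @param roi optional ROI [label_volume()].
#' @param bins histogram bins for mutual information.
#' @return Tibble of per-punctum measurements.
#' @export
measure_puncta <- function(stack, puncta_labels_by_channel, roi = NULL,
                           bins = 256L) {
  d <- dim(stack$voxels)[1:3]
  spacing <- stack_spacing(stack)
  two_d <- d[1] == 1L
  vox_um <- voxel_volume_um(spacing, two_d)
  ch_names <- stack$channel_names
  ch_vols <- lapply(seq_along(ch_names),
                    function(i) channel_volume(stack, i - 1L))
  names(ch_vols) <- ch_names
  roi_labels <- if (!is.null(roi)) {
    if (inherits(roi, "label_volume")) roi$labels else as_volume(roi)
  } else NULL
  boundary_by_roi <- if (!is.null(roi_labels)) roi_boundary_coords(roi_labels)
  pairs <- pair_names(ch_names)

  rows <- list()
  for (p_name in names(puncta_labels_by_channel)) {
    pl <- puncta_labels_by_channel[[p_name]]
    if (!identical(dim(pl$labels), d)) {
      stop("puncta labels for channel '", p_name,
           "' do not match the stack dimensions", call. = FALSE)
    }
    idx <- which(pl$labels > 0L)
    if (length(idx) == 0L) next
    labs <- pl$labels[idx]
    co <- arrayInd(idx, d) - 1L
    idx_by_lab <- split(idx, labs)
    lab_ids <- as.integer(names(idx_by_lab))
    n_p <- length(lab_ids)
    w <- ch_vols[[p_name]][idx]
    wsum <- unname(rowsum(w, labs)[, 1])
    counts <- unname(rowsum(rep(1, length(idx)), labs)[, 1])
    com <- sapply(1:3, function(ax) {
      ws <- unname(rowsum(w * co[, ax], labs)[, 1])
      ifelse(wsum > 0, ws / wsum,
             unname(rowsum(co[, ax], labs)[, 1]) / counts)
    })
    com <- matrix(com, ncol = 3)

    roi_of <- rep(0L, n_p)
    dist_border <- rep(0, n_p)
    if (!is.null(roi_labels)) {
      vox <- pmin(pmax(round(com) + 1L, 1L),
                  matrix(d, n_p, 3, byrow = TRUE))
      roi_of <- roi_labels[vox]
      for (i in seq_len(n_p)) {
        r <- roi_of[i]
        if (r > 0L && !is.null(boundary_by_roi[[as.character(r)]])) {
          bc <- boundary_by_roi[[as.character(r)]]
          d2 <- (bc[, 1] - com[i, 1])^2 * spacing[1]^2 +
            (bc[, 2] - com[i, 2])^2 * spacing[2]^2 +
            (bc[, 3] - com[i, 3])^2 * spacing[3]^2
          dist_border[i] <- sqrt(min(d2))
        }
      }
    }

    tb <- tibble::tibble(
      `Image name` = stack$source_name,
      `Puncta label` = lab_ids,
      `ROI label` = as.integer(roi_of),
      Channel = p_name,
      x = com[, 3], y = com[, 2], z = com[, 1],
      `Puncta volume pix` = as.numeric(counts),
      `Puncta volume um` = counts * vox_um,
      `Distance to ROI border um` = dist_border)
    for (f in ch_names) {
      iv <- ch_vols[[f]][idx]
      tb[[sprintf("%s mean intensity per puncta", f)]] <-
        unname(rowsum(iv, labs)[, 1]) / counts
      tb[[sprintf("%s integrated intensity per puncta", f)]] <-
        unname(rowsum(iv, labs)[, 1])
    }
    for (pr in pairs %||% list()) {
      r_col <- sprintf("Pearson correlation coefficient %s vs. %s", pr[1], pr[2])
      p_col <- sprintf("Pearson correlation p value %s vs. %s", pr[1], pr[2])
      mi_col <- sprintf("Mutual information %s vs. %s", pr[1], pr[2])
      stats_pp <- lapply(idx_by_lab, function(ii) {
        a <- ch_vols[[pr[1]]][ii]
        b <- ch_vols[[pr[2]]][ii]
        pp <- pearson_with_p(a, b)
        c(pp$r, pp$p, mutual_information(a, b, bins))
      })
      m <- unname(do.call(rbind, stats_pp))
      tb[[r_col]] <- m[, 1]
      tb[[p_col]] <- m[, 2]
      tb[[mi_col]] <- m[, 3]
    }
    rows[[p_name]] <- tb
  }
  dplyr::bind_rows(rows)
}

#' Measure individual ROIs
#'
#' One row per ROI (cell or nucleus): centroid, volume, per-channel mean
#' and integrated intensities inside the ROI and in the image background
#' (outside all ROIs; identical across the ROIs of an image), per-channel
#' entropy, pairwise Pearson and mutual information within the ROI; and per
#' puncta channel, the puncta count and volume aggregates, the mean and
#' integrated intensity of every fluorescent channel inside and outside the
#' channel's puncta (the dense and light phases when the fluorophore equals
#' the puncta channel), and pairwise overlap coefficients between puncta
#' masks. ROI voxels fully covered by puncta yield missing outside-puncta
#' statistics (not zeros); ROIs without puncta yield missing inside-puncta
#' statistics.
#'
#' @inheritParams measure_puncta
#' @param roi ROI [label_volume()] (required).
#' @param puncta_records optional precomputed [measure_puncta()] table;
#'   computed internally when omitted.
#' @return Tibble of per-ROI measurements.
#' @export
measure_rois <- function(stack, roi, puncta_labels_by_channel = list(),
                         puncta_records = NULL, bins = 256L) {
  stopifnot(!is.null(roi))
  d <- dim(stack$voxels)[1:3]
  spacing <- stack_spacing(stack)
  two_d <- d[1] == 1L
  vox_um <- voxel_volume_um(spacing, two_d)
  ch_names <- stack$channel_names
  ch_vols <- lapply(seq_along(ch_names),
                    function(i) channel_volume(stack, i - 1L))
  names(ch_vols) <- ch_names
  roi_labels <- if (inherits(roi, "label_volume")) roi$labels else as_volume(roi)
  if (!identical(dim(roi_labels), d)) {
    stop("ROI labels do not match the stack dimensions", call. = FALSE)
  }
  if (is.null(puncta_records) && length(puncta_labels_by_channel) > 0) {
    puncta_records <- measure_puncta(stack, puncta_labels_by_channel, roi,
                                     bins = bins)
  }
  idx_all <- which(roi_labels > 0L)
  labs <- roi_labels[idx_all]
  idx_by_roi <- split(idx_all, labs)
  roi_ids <- as.integer(names(idx_by_roi))
  if (length(roi_ids) == 0L) return(tibble::tibble())
  bg_idx <- which(roi_labels == 0L)
  pairs <- pair_names(ch_names)
  p_channels <- names(puncta_labels_by_channel)
  p_pairs <- pair_names(p_channels)

  rows <- lapply(roi_ids, function(r) {
    ii <- idx_by_roi[[as.character(r)]]
    co <- arrayInd(ii, d) - 1L
    row <- tibble::tibble(
      `Image name` = stack$source_name,
      `ROI label` = r,
      x = mean(co[, 3]), y = mean(co[, 2]), z = mean(co[, 1]),
      `ROI volume pix` = length(ii),
      `ROI volume um` = length(ii) * vox_um)
    for (f in ch_names) {
      iv <- ch_vols[[f]][ii]
      row[[sprintf("%s mean intensity per ROI", f)]] <- mean(iv)
      row[[sprintf("%s integrated intensity per ROI", f)]] <- sum(iv)
      bgv <- ch_vols[[f]][bg_idx]
      row[[sprintf("%s mean background intensity", f)]] <-
        if (length(bgv) > 0) mean(bgv) else NA_real_
      row[[sprintf("%s integrated background intensity", f)]] <-
        if (length(bgv) > 0) sum(bgv) else NA_real_
      row[[sprintf("%s entropy", f)]] <- intensity_entropy(iv, bins)
    }
    for (pr in pairs %||% list()) {
      a <- ch_vols[[pr[1]]][ii]
      b <- ch_vols[[pr[2]]][ii]
      pp <- pearson_with_p(a, b)
      row[[sprintf("Pearson correlation coefficient %s vs. %s", pr[1], pr[2])]] <- pp$r
      row[[sprintf("Pearson correlation p value %s vs. %s", pr[1], pr[2])]] <- pp$p
      row[[sprintf("Mutual information %s vs. %s", pr[1], pr[2])]] <-
        mutual_information(a, b, bins)
    }
    for (p in p_channels) {
      pmask_ii <- puncta_labels_by_channel[[p]]$labels[ii] > 0L
      rec <- if (!is.null(puncta_records) && nrow(puncta_records) > 0) {
        puncta_records[puncta_records$`ROI label` == r &
                         puncta_records$Channel == p, ]
      } else NULL
      n_puncta <- if (is.null(rec)) 0L else nrow(rec)
      row[[sprintf("number of %s puncta", p)]] <- n_puncta
      row[[sprintf("average %s puncta volume pix per ROI", p)]] <-
        if (n_puncta > 0) mean(rec$`Puncta volume pix`) else NA_real_
      row[[sprintf("average %s puncta volume um per ROI", p)]] <-
        if (n_puncta > 0) mean(rec$`Puncta volume um`) else NA_real_
      row[[sprintf("total %s puncta volume pix per ROI", p)]] <-
        if (n_puncta > 0) sum(rec$`Puncta volume pix`) else 0
      row[[sprintf("total %s puncta volume um per ROI", p)]] <-
        if (n_puncta > 0) sum(rec$`Puncta volume um`) else 0
      row[[sprintf("average %s puncta distance to ROI border um per nucleus", p)]] <-
        if (n_puncta > 0) mean(rec$`Distance to ROI border um`) else NA_real_
      for (f in ch_names) {
        iv <- ch_vols[[f]][ii]
        inside <- iv[pmask_ii]
        outside <- iv[!pmask_ii]
        row[[sprintf("%s mean intensity inside %s puncta", f, p)]] <-
          if (length(inside) > 0) mean(inside) else NA_real_
        row[[sprintf("%s mean intensity outside %s puncta", f, p)]] <-
          if (length(outside) > 0) mean(outside) else NA_real_
        row[[sprintf("%s integrated intensity inside %s puncta", f, p)]] <-
          if (length(inside) > 0) sum(inside) else NA_real_
        row[[sprintf("%s integrated intensity outside %s puncta", f, p)]] <-
          if (length(outside) > 0) sum(outside) else NA_real_
      }
    }
    for (pp in p_pairs %||% list()) {
      roi_mask_ii <- puncta_labels_by_channel[[pp[1]]]$labels[ii] > 0L
      other_ii <- puncta_labels_by_channel[[pp[2]]]$labels[ii] > 0L
      uni <- sum(roi_mask_ii | other_ii)
      row[[sprintf("Overlap coefficient %s_%s_coloc", pp[1], pp[2])]] <-
        if (uni > 0) sum(roi_mask_ii & other_ii) / uni else NA_real_
    }
    row
  })
  dplyr::bind_rows(rows)
}

#' Write measurement tables to CSV
#'
#' Missing values are serialized as empty cells.
#'
#' @param records a tibble from [measure_puncta()] or [measure_rois()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}
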