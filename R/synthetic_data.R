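#' Parameters for the synthetic-stack simulator
#'
#' Defines a simulated acquisition: ellipsoidal nuclei with per-nucleus
#' expression levels, spherical puncta with a prescribed dense/light
#' intensity ratio (the planted partition ratio), Gaussian approximation of
#' the microscope point-spread function, and Poisson-Gaussian camera noise.
#' Defaults emulate a high-resolution confocal acquisition (0.11 um xy
#' pixels, 0.2 um z spacing) at a peak-signal SNR of roughly 10.
#'
#' @param image_shape `(z, y, x)` voxel extents.
#' @param pixel_size_um,z_spacing_um physical voxel spacing in micrometres.
#' @param n_nuclei number of puncta-bearing nuclei to place.
#' @param nucleus_radius_um mean nucleus radius; per-axis semi-radii are
#'   jittered by `nucleus_radius_jitter` (fractional) within an axis ratio
#'   of at most ~1.5, giving irregular ellipsoids rather than spheres.
#' @param nucleus_radius_jitter fractional radius jitter per axis.
#' @param expression_range per-nucleus light-phase intensity drawn
#'   uniformly from this range (camera counts).
#' @param n_puncta puncta per nucleus.
#' @param puncta_radius_um range of punctum radii in micrometres.
#' @param partition_ratio dense/light intensity ratio rho (>= 1): puncta
#'   voxels carry `rho * LP`, other nuclear voxels `LP`.
#' @param psf_sigma_um s.d. of the Gaussian blur approximating the PSF.
#' @param poisson_gain camera gain g for scaled-Poisson photon noise:
#'   `observed = g * Poisson(signal / g)`; larger g means noisier.
#' @param read_noise_sd additive Gaussian read noise s.d. (counts).
#' @param nucleus_marker_intensity intensity of the nucleus-marker channel
#'   inside nuclei.
#' @param include_negative_control_nuclei number of additional nuclei with
#'   diffuse signal only (no puncta).
#' @param seed master seed; fully determines the output.
#' @return A list of class `simulation_params`.
#' @export
simulation_params <- function(image_shape = c(32L, 192L, 192L),
                              pixel_size_um = 0.11, z_spacing_um = 0.2,
                              n_nuclei = 3L, nucleus_radius_um = 2.5,
                              nucleus_radius_jitter = 0.12,
                              expression_range = c(80, 150),
                              n_puncta = 10L,
                              puncta_radius_um = c(0.4, 0.6),
                              partition_ratio = 5,
                              psf_sigma_um = 0.08,
                              poisson_gain = 5, read_noise_sd = 2,
                              nucleus_marker_intensity = 300,
                              include_negative_control_nuclei = 0L,
                              seed = 1L) {
  stopifnot(length(image_shape) == 3L, all(image_shape >= 1L),
            pixel_size_um > 0, z_spacing_um > 0, n_nuclei >= 0,
            nucleus_radius_um > 0, partition_ratio >= 1,
            length(puncta_radius_um) == 2L,
            puncta_radius_um[1] <= puncta_radius_um[2],
            poisson_gain >= 0, read_noise_sd >= 0)
  structure(as.list(environment()), class = "simulation_params")
}

# non-overlapping ellipsoid placement by rejection sampling
place_nuclei <- function(p, spacing) {
  n_total <- p$n_nuclei + p$include_negative_control_nuclei
  ext_um <- dim_um <- p$image_shape * spacing
  nuclei <- list()
  tries <- 0L
  margin <- 0.3
  while (length(nuclei) < n_total) {
    tries <- tries + 1L
    if (tries > 2000L) {
      stop("infeasible packing: could not place ", n_total,
           " nuclei of radius ", p$nucleus_radius_um,
           " um in a ", paste(round(dim_um, 1), collapse = " x "),
           " um volume", call. = FALSE)
    }
    radii <- p$nucleus_radius_um *
      (1 + runif(3, -p$nucleus_radius_jitter, p$nucleus_radius_jitter))
    if (any(2 * (radii + margin) >= ext_um)) {
      stop("infeasible packing: nuclei do not fit inside the image",
           call. = FALSE)
    }
    center <- vapply(1:3, function(a) {
      runif(1, radii[a] + margin, ext_um[a] - radii[a] - margin)
    }, numeric(1))
    clash <- any(vapply(nuclei, function(nu) {
      sqrt(sum((nu$center - center)^2)) <
        max(nu$radii) + max(radii) + margin
    }, logical(1)))
    if (!clash) {
      nuclei[[length(nuclei) + 1L]] <- list(
        center = center, radii = radii,
        negative = length(nuclei) >= p$n_nuclei)
    }
  }
  nuclei
}

place_puncta <- function(nucleus, p) {
  if (nucleus$negative || p$n_puncta == 0L) return(list())
  puncta <- list()
  tries <- 0L
  while (length(puncta) < p$n_puncta) {
    tries <- tries + 1L
    if (tries > 5000L) {
      stop("infeasible packing: could not place ", p$n_puncta,
           " puncta inside a nucleus of radius ",
           round(min(nucleus$radii), 2), " um", call. = FALSE)
    }
    r <- runif(1, p$puncta_radius_um[1], p$puncta_radius_um[2])
    # uniform within the nucleus shrunk by the punctum radius plus a PSF
    # margin, so every planted sphere (and its blurred support) lies fully
    # inside the nucleus and the sphere-volume ground truth is exact
    margin <- r + max(3 * p$psf_sigma_um, 0.25)
    u <- rnorm(3)
    u <- u / sqrt(sum(u^2))
    frac <- runif(1)^(1 / 3)
    center <- nucleus$center + u * frac * pmax(nucleus$radii - margin, 0)
    clash <- any(vapply(puncta, function(pt) {
      sqrt(sum((pt$center - center)^2)) < pt$r + r + 0.1
    }, logical(1)))
    if (!clash) puncta[[length(puncta) + 1L]] <- list(center = center, r = r)
  }
  puncta
}

# voxel-center coordinate grids in physical units
coord_grids_um <- function(shape, spacing) {
  list(z = (seq_len(shape[1]) - 0.5) * spacing[1],
       y = (seq_len(shape[2]) - 0.5) * spacing[2],
       x = (seq_len(shape[3]) - 0.5) * spacing[3])
}

ellipsoid_mask <- function(grids, center, radii, shape) {
  dz <- (grids$z - center[1]) / radii[1]
  dy <- (grids$y - center[2]) / radii[2]
  dx <- (grids$x - center[3]) / radii[3]
  q <- outer(outer(dz^2, dy^2, `+`), dx^2, `+`)
  array(q <= 1, dim = shape)
}

#' Simulate a multi-channel stack with known ground truth
#'
#' Builds a noiseless intensity model — channel 0 a uniform nucleus marker,
#' channel 1 a puncta channel where nuclear voxels carry each nucleus'
#' light-phase intensity and puncta voxels carry `partition_ratio` times it
#' — then blurs with a Gaussian PSF approximation, applies scaled-Poisson
#' photon noise plus Gaussian read noise, and rounds to integer camera
#' counts. All derived truth quantities are computed from the noiseless
#' model, never re-measured from the noisy image. Identical parameters and
#' seed give bit-identical output.
#'
#' @param params a [simulation_params()] list.
#' @return A list with `stack` (a [multichannel_stack()]; channels
#'   `"nuclei"` and `"puncta"`) and `truth`, containing `nucleus_labels`
#'   and `puncta_labels` ([label_volume()]s of the noiseless supports),
#'   `puncta_table` (planted center, radius, nucleus id per punctum) and
#'   `nucleus_table` (per-nucleus planted `lp`, `dp`, `kp`, `f_vol`,
#'   `f_mol`).
#' @export
simulate_stack <- function(params = simulation_params()) {
  p <- params
  spacing <- c(p$z_spacing_um, p$pixel_size_um, p$pixel_size_um)
  shape <- as.integer(p$image_shape)
  with_local_seed(p$seed, {
    nuclei <- place_nuclei(p, spacing)
    grids <- coord_grids_um(shape, spacing)
    nucleus_labels <- array(0L, dim = shape)
    puncta_labels <- array(0L, dim = shape)
    nuc_chan <- array(0, dim = shape)
    pun_chan <- array(0, dim = shape)
    puncta_rows <- list()
    nucleus_rows <- list()
    p_label <- 0L
    for (i in seq_along(nuclei)) {
      nu <- nuclei[[i]]
      lp <- runif(1, p$expression_range[1], p$expression_range[2])
      dp <- p$partition_ratio * lp
      nmask <- ellipsoid_mask(grids, nu$center, nu$radii, shape)
      nucleus_labels[nmask] <- i
      nuc_chan[nmask] <- p$nucleus_marker_intensity
      pun_chan[nmask] <- lp
      puncta <- place_puncta(nu, p)
      n_vox_puncta <- 0L
      for (pt in puncta) {
        p_label <- p_label + 1L
        pmask <- ellipsoid_mask(grids, pt$center, rep(pt$r, 3), shape)
        pmask <- pmask & nmask
        puncta_labels[pmask] <- p_label
        pun_chan[pmask] <- dp
        n_vox_puncta <- n_vox_puncta + sum(pmask)
        puncta_rows[[p_label]] <- tibble::tibble(
          puncta_label = p_label, nucleus = i,
          z_um = pt$center[1], y_um = pt$center[2], x_um = pt$center[3],
          z = pt$center[1] / spacing[1] - 0.5,
          y = pt$center[2] / spacing[2] - 0.5,
          x = pt$center[3] / spacing[3] - 0.5,
          radius_um = pt$r)
      }
      n_vox_nuc <- sum(nmask)
      f_vol <- n_vox_puncta / n_vox_nuc
      f_mol <- (dp * n_vox_puncta) /
        (dp * n_vox_puncta + lp * (n_vox_nuc - n_vox_puncta))
      nucleus_rows[[i]] <- tibble::tibble(
        nucleus = i, negative_control = nu$negative,
        lp = lp, dp = if (n_vox_puncta > 0) dp else NA_real_,
        kp = if (n_vox_puncta > 0) p$partition_ratio else NA_real_,
        n_puncta = length(puncta), f_vol = f_vol,
        f_mol = if (n_vox_puncta > 0) f_mol else 0)
    }
    corrupt <- function(v) {
      sig <- p$psf_sigma_um / spacing
      if (shape[1] == 1L) sig[1] <- 0
      if (p$psf_sigma_um > 0) v <- cpp_gaussian_smooth(v, sig)
      if (p$poisson_gain > 0) {
        v <- p$poisson_gain * array(rpois(length(v), v / p$poisson_gain),
                                    dim = dim(v))
      }
      if (p$read_noise_sd > 0) {
        v <- v + array(rnorm(length(v), 0, p$read_noise_sd), dim = dim(v))
      }
      array(pmax(round(v), 0), dim = dim(v))
    }
    vox <- array(0, dim = c(shape, 2L))
    vox[, , , 1] <- corrupt(nuc_chan)
    vox[, , , 2] <- corrupt(pun_chan)
    stack <- multichannel_stack(vox, pixel_size_um = p$pixel_size_um,
                                z_spacing_um = p$z_spacing_um,
                                channel_names = c("nuclei", "puncta"),
                                source_name = sprintf("synthetic_seed%d", p$seed))
    truth <- list(
      nucleus_labels = label_volume(nucleus_labels, spacing, "roi"),
      puncta_labels = label_volume(puncta_labels, spacing, "puncta"),
      puncta_table = dplyr::bind_rows(puncta_rows),
      nucleus_table = dplyr::bind_rows(nucleus_rows),
      params = p)
    list(stack = stack, truth = truth)
  })
}

#' Simulate a negative-control stack (diffuse signal, no puncta)
#'
#' The negative control every acquisition should include: nuclei expressing
#' diffuse fluorescence with no planted puncta. A correctly tuned pipeline
#' must detect zero puncta here.
#'
#' @param params a [simulation_params()] list; `n_puncta` is forced to 0.
#' @return As [simulate_stack()], with an empty truth puncta mask.
#' @export
make_negative_control <- function(params = simulation_params()) {
  params$n_puncta <- 0L
  simulate_stack(params)
}

#' Write a simulation to disk (stack as TIFF, truth as CSV + label TIFFs)
#'
#' @param sim result of [simulate_stack()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base <- sim$stack$source_name
  write_stack(sim$stack, file.path(dir, paste0(base, ".tif")),
              extra_label_channels = list(
                roi_labels = sim$truth$nucleus_labels,
                puncta_labels = sim$truth$puncta_labels))
  utils::write.csv(sim$truth$puncta_table,
                   file.path(dir, paste0(base, "_puncta_truth.csv")),
                   row.names = FALSE)
  utils::write.csv(sim$truth$nucleus_table,
                   file.path(dir, paste0(base, "_nucleus_truth.csv")),
                   row.names = FALSE)
  invisible(dir)
}
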