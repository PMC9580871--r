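# programmatic fixtures shared across test files

# a digital ball/ellipsoid mask in voxel units, dims (z, y, x)
ball_mask <- function(shape, center, radii) {
  if (length(radii) == 1L) radii <- rep(radii, 3L)
  g <- lapply(1:3, function(a) (seq_len(shape[a]) - center[a]) / radii[a])
  q <- outer(outer(g[[1]]^2, g[[2]]^2, `+`), g[[3]]^2, `+`)
  array(q <= 1, dim = shape)
}

# a soft 3D Gaussian spot, dims (z, y, x), sd in voxels
gaussian_spot <- function(shape, center, sd_vox, amplitude = 1) {
  if (length(sd_vox) == 1L) sd_vox <- rep(sd_vox, 3L)
  g <- lapply(1:3, function(a) {
    ((seq_len(shape[a]) - center[a]) / sd_vox[a])^2
  })
  q <- outer(outer(g[[1]], g[[2]], `+`), g[[3]], `+`)
  amplitude * exp(-q / 2)
}

# small, fast simulation settings used by most pipeline tests
tiny_sim_params <- function(...) {
  args <- utils::modifyList(
    list(image_shape = c(24L, 96L, 96L), n_nuclei = 2L,
         nucleus_radius_um = 1.6, n_puncta = 3L,
         puncta_radius_um = c(0.3, 0.42)),
    list(...))
  do.call(simulation_params, args)
}

# analysis parameters tuned for the simulated acquisitions (see the methods
# vignette): target size range matching the planted radii, detection and
# mode-0 segmentation thresholds above the simulated LoG noise floor
tuned_params <- function(...) {
  pipeline_params(
    channel = 0, puncta_channels = 1,
    minsize_um = 0.5, maxsize_um = 1.5,
    threshold_detection = 0.1, threshold_segmentation = 0.12,
    threshold_background = 1.5, ...
  )
}

# independent brute-force oracles for colocalization statistics
oracle_pearson <- function(x, y) {
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

oracle_entropy <- function(x, bins) {
  r <- range(x)
  if (diff(r) == 0) return(0)
  i <- pmin(as.integer(floor((x - r[1]) / diff(r) * bins)) + 1L, bins)
  p <- as.vector(table(factor(i, levels = 1:bins))) / length(x)
  -sum(ifelse(p > 0, p * log2(p), 0))
}

oracle_mi <- function(x, y, bins) {
  bi <- function(v) {
    r <- range(v)
    if (diff(r) == 0) rep(1L, length(v)) else
      pmin(as.integer(floor((v - r[1]) / diff(r) * bins)) + 1L, bins)
  }
  ix <- bi(x); iy <- bi(y)
  n <- length(x)
  mi <- 0
  for (a in unique(ix)) for (b in unique(iy)) {
    pab <- sum(ix == a & iy == b) / n
    if (pab > 0) mi <- mi + pab * log2(pab / ((sum(ix == a) / n) * (sum(iy == b) / n)))
  }
  mi
}

# Hungarian-free greedy matching of detected centers to planted puncta
# (one-to-one, nearest first); adequate because planted puncta are well
# separated relative to the matching radius
match_centers <- function(centers, truth, spacing, max_dist_um) {
  if (nrow(centers) == 0L || nrow(truth) == 0L) {
    return(list(matches = 0L, dists = numeric(0)))
  }
  d <- outer(seq_len(nrow(centers)), seq_len(nrow(truth)),
             Vectorize(function(i, j) {
               sqrt(((centers$z[i] - truth$z[j]) * spacing[1])^2 +
                      ((centers$y[i] - truth$y[j]) * spacing[2])^2 +
                      ((centers$x[i] - truth$x[j]) * spacing[3])^2)
             }))
  matches <- 0L
  dists <- numeric(0)
  while (TRUE) {
    m <- which(d == min(d), arr.ind = TRUE)[1, , drop = FALSE]
    if (d[m] > max_dist_um) break
    matches <- matches + 1L
    dists <- c(dists, d[m])
    d[m[1], ] <- Inf
    d[, m[2]] <- Inf
    if (all(is.infinite(d))) break
  }
  list(matches = matches, dists = dists)
}
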