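sp_iso <- c(0.2, 0.11, 0.11)

test_that("the LoG transform is zero on constants and peaks at spot centers", {
  const <- array(3.7, dim = c(8, 16, 16))
  resp <- log_transform(const, c(1, 2, 2))
  expect_equal(max(abs(resp)), 0)

  # single Gaussian spot probed at its own scale: unique maximum at center
  shape <- c(21L, 41L, 41L)
  spot <- gaussian_spot(shape, c(11, 21, 21), c(2, 4, 4))
  resp <- log_transform(spot, c(2, 4, 4))
  expect_equal(as.integer(arrayInd(which.max(resp), shape)), c(11L, 21L, 21L))

  # two spots of different sizes peak at their own scales
  big_small <- gaussian_spot(shape, c(11, 12, 12), c(1.2, 2, 2)) +
    gaussian_spot(shape, c(11, 30, 30), c(2.4, 5, 5))
  r_small <- log_transform(big_small, c(1.2, 2, 2))
  r_big <- log_transform(big_small, c(2.4, 5, 5))
  at <- function(r, co) r[co[1], co[2], co[3]]
  expect_gt(at(r_small, c(11, 12, 12)), at(r_big, c(11, 12, 12)))
  expect_gt(at(r_big, c(11, 30, 30)), at(r_small, c(11, 30, 30)))
})

test_that("detect_centers finds planted noise-free spheres within one voxel", {
  sim <- simulate_stack(tiny_sim_params(seed = 51, poisson_gain = 0,
                                        read_noise_sd = 0))
  vol <- channel_volume(sim$stack, 1)
  cent <- detect_centers(vol, sp_iso, minsize_um = 0.5, maxsize_um = 1.2,
                         threshold_detection = 0.1)
  truth <- sim$truth$puncta_table
  expect_equal(nrow(cent), nrow(truth))
  m <- match_centers(cent, truth, sp_iso, max_dist_um = 0.25)
  expect_equal(m$matches, nrow(truth))
  expect_true(all(m$dists <= max(sp_iso)))  # within one voxel pitch
})

test_that("an all-zero volume yields no centers", {
  expect_equal(nrow(detect_centers(array(0, c(4, 16, 16)), sp_iso)), 0L)
})

test_that("lowering threshold_detection yields a superset of centers", {
  sim <- simulate_stack(tiny_sim_params(seed = 61))
  vol <- channel_volume(sim$stack, 1)
  lo <- detect_centers(vol, sp_iso, threshold_detection = 0.001)
  hi <- detect_centers(vol, sp_iso, threshold_detection = 0.003)
  key <- function(d) paste(d$z, d$y, d$x, d$scale_um)
  expect_true(all(key(hi) %in% key(lo)))
  expect_lte(nrow(hi), nrow(lo))
})

test_that("ROI backgrounds follow the requested percentiles", {
  shape <- c(2L, 10L, 10L)
  labs <- array(0L, dim = shape)
  labs[, 1:4, ] <- 1L
  labs[, 7:10, ] <- 2L
  vol <- array(0, dim = shape)
  vol[labs == 1L] <- 10
  vol[labs == 2L] <- 100

  # constant ROI: any percentile returns the constant
  bg <- compute_background(vol, labs, background_percentile = 37)
  expect_equal(unname(bg$per_roi_value), c(10, 100))

  # pooled global value: linear-interpolation percentile of per-ROI values
  bg95 <- compute_background(vol, labs, global_background = TRUE,
                             global_background_percentile = 95)
  expect_equal(bg95$global_value, 95.5)
  expect_equal(bg95$mode, "global")

  # per-ROI mode keeps each ROI's own value
  bg_local <- compute_background(vol, labs, global_background = FALSE)
  expect_equal(unname(bg_local$per_roi_value), c(10, 100))
  expect_equal(bg_local$mode, "per_roi")
})

test_that("center filtering compares intensity to multiples of background", {
  shape <- c(2L, 10L, 10L)
  labs <- array(0L, dim = shape)
  labs[, 1:8, ] <- 1L
  vol <- array(10, dim = shape)
  vol[1, 3, 3] <- 25
  vol[1, 6, 6] <- 35
  centers <- tibble::tibble(z = c(0L, 0L), y = c(2L, 5L), x = c(2L, 5L),
                            scale_um = 0.5, sigma_um = 0.14,
                            response = c(0.3, 0.4), roi_label = 1L)
  bg <- compute_background(vol, labs)   # median of ROI ~ 10
  kept <- filter_centers(centers, vol, bg, threshold_background = 3)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$y, 5L)   # 35 >= 3 * 10; 25 < 30 removed

  # threshold 0 keeps everything
  expect_equal(nrow(filter_centers(centers, vol, bg, 0)), 2L)
})

test_that("per-ROI background rescues dim cells that a global value misses", {
  # two-cell fixture: a dim cell and a 10x brighter cell, both with one
  # planted punctum at 4x their own light phase
  shape <- c(8L, 40L, 40L)
  labs <- array(0L, dim = shape)
  dim_cell <- ball_mask(shape, c(4, 12, 12), c(3.5, 9, 9))
  bright_cell <- ball_mask(shape, c(4, 12, 30), c(3.5, 9, 9))
  labs[dim_cell] <- 1L
  labs[bright_cell] <- 2L
  vol <- array(0, dim = shape)
  vol[dim_cell] <- 10
  vol[bright_cell] <- 100
  vol[ball_mask(shape, c(4, 12, 12), c(1.5, 3, 3))] <- 40    # dim-cell punctum
  vol[ball_mask(shape, c(4, 12, 30), c(1.5, 3, 3))] <- 400   # bright-cell punctum
  centers <- tibble::tibble(z = c(3L, 3L), y = c(11L, 11L), x = c(11L, 29L),
                            scale_um = 0.6, sigma_um = 0.17,
                            response = c(0.2, 0.9), roi_label = c(1L, 2L))

  bg_local <- compute_background(vol, labs, global_background = FALSE)
  bg_global <- compute_background(vol, labs, global_background = TRUE)
  kept_local <- filter_centers(centers, vol, bg_local, 3)
  kept_global <- filter_centers(centers, vol, bg_global, 3)
  # local background keeps both puncta; the pooled global background
  # (95th percentile of {10, 100}) suppresses the dim cell's punctum
  expect_equal(nrow(kept_local), 2L)
  expect_equal(kept_global$roi_label, 2L)
})

test_that("seeded watershed splits bridged spheres between their seeds", {
  shape <- c(10L, 30L, 50L)
  vol <- array(0, dim = shape)
  a <- ball_mask(shape, c(5, 15, 15), c(3, 6, 6))
  b <- ball_mask(shape, c(5, 15, 35), c(3, 6, 6))
  vol[a] <- 100
  vol[b] <- 100
  vol[5, 15, 21:29] <- 40   # faint bridge
  labs <- array(1L, dim = shape)
  centers <- tibble::tibble(z = c(4L, 4L), y = c(14L, 14L), x = c(14L, 34L),
                            scale_um = 1.2, sigma_um = 0.35,
                            response = c(1, 1), roi_label = 1L)
  # mode 2 with threshold relative to background: use explicit bg of 10
  bg <- compute_background(array(10, dim = shape), labs)
  seg <- segment_puncta(vol, centers, c(0.2, 0.11, 0.11),
                        roi = label_volume(labs, c(0.2, 0.11, 0.11), "roi"),
                        bg = bg, segmentation_mode = 2L,
                        threshold_segmentation = 3)
  expect_equal(n_objects(seg), 2L)
  # each sphere belongs to its own seed; split falls along the bridge
  expect_equal(unique(as.vector(seg$labels[a])), 1L)
  expect_equal(unique(as.vector(seg$labels[b])), 2L)
})

test_that("every punctum contains exactly one surviving seed", {
  sim <- simulate_stack(tiny_sim_params(seed = 71))
  st <- sim$stack
  roi <- segment_rois(st, pipeline_params(channel = 0))
  seg <- run_puncta_segmentation(st, roi, tuned_params())
  pl <- seg$labels_by_channel$puncta
  cent <- seg$centers_by_channel$puncta
  seed_labels <- pl$labels[cbind(cent$z + 1L, cent$y + 1L, cent$x + 1L)]
  seed_labels <- seed_labels[seed_labels > 0L]
  expect_equal(sort(unique(seed_labels)), seq_len(n_objects(pl)))
  expect_equal(anyDuplicated(seed_labels), 0L)
})

test_that("total puncta voxel count is non-increasing in the segmentation threshold", {
  sim <- simulate_stack(tiny_sim_params(seed = 81))
  st <- sim$stack
  roi <- segment_rois(st, pipeline_params(channel = 0))
  counts <- vapply(c(0.02, 0.05, 0.1, 0.2, 0.4), function(ts) {
    seg <- run_puncta_segmentation(st, roi,
                                   tuned_params(threshold_segmentation = ts))
    sum(seg$labels_by_channel$puncta$labels > 0L)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("segmentation modes 1 and 2 demand ROI masks", {
  vol <- array(1, c(4, 8, 8))
  centers <- tibble::tibble(z = integer(0), y = integer(0), x = integer(0),
                            scale_um = numeric(0), sigma_um = numeric(0),
                            response = numeric(0), roi_label = integer(0))
  expect_error(segment_puncta(vol, centers, sp_iso, roi = NULL,
                              segmentation_mode = 1L), "mode 0")
  expect_error(segment_puncta(vol, centers, sp_iso, roi = NULL,
                              segmentation_mode = 2L), "mode 0")
})

test_that("puncta filters remove large puncta and out-of-ROI voxels", {
  shape <- c(30L, 80L, 80L)
  sp <- c(0.2, 0.11, 0.11)
  labs <- array(0L, dim = shape)
  # sphere of radius ~3 um: 15 z-voxels, 27 xy-voxels
  labs[ball_mask(shape, c(15, 40, 40), c(15, 27, 27))] <- 1L
  big <- label_volume(labs, sp, "puncta")
  expect_equal(n_objects(filter_puncta(big, maxrad_um = 2)), 0L)
  expect_equal(n_objects(filter_puncta(big, maxrad_um = NULL)), 1L)

  # punctum straddling an ROI border keeps only its in-ROI voxels
  roi <- array(0L, dim = shape)
  roi[, , 1:40] <- 1L
  p <- array(0L, dim = shape)
  p[ball_mask(shape, c(15, 40, 40), c(5, 9, 9))] <- 1L
  plv <- label_volume(p, sp, "puncta")
  trimmed <- filter_puncta(plv, remove_out_of_roi = TRUE,
                           roi = label_volume(roi, sp, "roi"))
  expect_identical(trimmed$labels > 0L, p > 0L & roi > 0L)
})
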