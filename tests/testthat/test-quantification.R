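test_that("Pearson r and p match closed forms and cor.test", {
  x <- 1:10
  expect_equal(pearson_with_p(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_with_p(x, -x)$r, -1)

  # hand-computed example: r = 0.8, p from t with 2 df
  pp <- pearson_with_p(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(pp$r, 0.8)
  t_stat <- 0.8 * sqrt(2 / (1 - 0.64))
  expect_equal(pp$p, 2 * pt(-t_stat, df = 2))

  # random vectors against the stats::cor.test oracle
  set.seed(13)
  for (i in 1:5) {
    a <- rnorm(50)
    b <- 0.4 * a + rnorm(50)
    got <- pearson_with_p(a, b)
    want <- oracle_pearson(a, b)
    expect_equal(got$r, want$r, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }

  # degenerate inputs yield missing values, not errors
  expect_true(is.na(pearson_with_p(rep(1, 5), rnorm(5))$r))
  expect_true(is.na(pearson_with_p(1:2, 2:1)$r))
})

test_that("entropy and mutual information match brute-force references", {
  expect_equal(intensity_entropy(rep(4, 100)), 0)
  two <- rep(c(0, 1), each = 50)
  expect_equal(intensity_entropy(two, bins = 2), 1)
  four <- rep(c(0, 1, 2, 3), each = 25)
  expect_equal(intensity_entropy(four, bins = 4), 2)

  expect_equal(mutual_information(rep(1, 40), rnorm(40)), 0)
  k <- 4
  x <- rep(seq_len(k), each = 10)
  expect_equal(mutual_information(x, x, bins = k), log2(k))

  # planted 2x2 joint histogram [[2,1],[1,2]] by direct summation
  x2 <- c(0, 0, 0, 1, 1, 1)
  y2 <- c(0, 0, 1, 0, 1, 1)
  direct <- 0
  for (a in 0:1) for (b in 0:1) {
    pab <- sum(x2 == a & y2 == b) / 6
    direct <- direct + pab * log2(pab / (sum(x2 == a) / 6 * sum(y2 == b) / 6))
  }
  expect_equal(direct, 0.08170417, tolerance = 1e-6)
  expect_equal(mutual_information(x2, y2, bins = 2), direct, tolerance = 1e-12)

  set.seed(29)
  for (i in 1:3) {
    a <- rnorm(200)
    b <- a + rnorm(200, sd = 2)
    expect_equal(mutual_information(a, b, bins = 8), oracle_mi(a, b, 8),
                 tolerance = 1e-10)
    expect_equal(intensity_entropy(a, bins = 8), oracle_entropy(a, 8),
                 tolerance = 1e-10)
  }
})

test_that("overlap coefficient is intersection over union", {
  a <- array(FALSE, c(2, 5, 5)); a[1, 1:2, 1] <- TRUE
  b <- a
  expect_equal(overlap_coefficient(a, b), 1)
  d <- array(FALSE, c(2, 5, 5)); d[2, 4:5, 4] <- TRUE
  expect_equal(overlap_coefficient(a, d), 0)
  e <- array(FALSE, c(2, 5, 5)); e[1, 2:3, 1] <- TRUE
  expect_equal(overlap_coefficient(a, e), 1 / 3)
  expect_true(is.na(overlap_coefficient(a & FALSE, d & FALSE)))
})

test_that("distance to the ROI border is anisotropy-aware", {
  shape <- c(25L, 25L, 25L)
  mask <- ball_mask(shape, c(13, 13, 13), 10)  # digital ball, radius 10 px
  sp <- rep(0.11, 3)
  d <- distance_to_border_um(c(12, 12, 12), mask, sp)
  expect_lt(abs(d - 1.1), 0.11)   # within one pixel of 10 px * 0.11 um

  # center outside the mask: 0 by convention
  expect_equal(distance_to_border_um(c(0, 0, 0), mask, sp), 0)

  # a voxel adjacent to the border is one voxel pitch away
  slab <- array(TRUE, dim = c(1L, 8L, 8L))
  expect_equal(distance_to_border_um(c(0, 3, 1), slab, c(0.2, 0.11, 0.11)),
               0.11)
})

test_that("per-punctum measurements report volumes, intensities and pairs", {
  shape <- c(6L, 20L, 20L)
  sp <- c(0.2, 0.11, 0.11)
  vox <- array(2, dim = c(shape, 2))
  p <- array(0L, dim = shape)
  p[2, 5:9, 5] <- 1L                      # 5-voxel punctum
  p[4:6, 10:12, 10:12] <- 2L              # 27-voxel punctum
  vox[, , , 1][p == 1L] <- 10
  vox[, , , 1][p == 2L] <- 31
  vox[, , , 2][p == 2L] <- 7
  st <- multichannel_stack(vox, 0.11, 0.2, channel_names = c("green", "red"),
                           source_name = "img1")
  roi <- label_volume(array(1L, dim = shape), sp, "roi")
  rec <- measure_puncta(st, list(green = label_volume(p, sp, "puncta")), roi)

  expect_equal(nrow(rec), 2L)
  expect_equal(rec$`Puncta volume pix`, c(5, 27))
  expect_equal(rec$`Puncta volume um`[2], 27 * 0.2 * 0.11^2)
  expect_equal(rec$`green mean intensity per puncta`, c(10, 31))
  expect_equal(rec$`green integrated intensity per puncta`, c(50, 27 * 31))
  expect_equal(rec$Channel, c("green", "green"))
  expect_equal(rec$`ROI label`, c(1L, 1L))
  # constant intensities inside the punctum: correlation undefined, MI zero
  expect_true(all(is.na(rec$`Pearson correlation coefficient green vs. red`)))
  expect_equal(rec$`Mutual information green vs. red`, c(0, 0))
})

test_that("self-correlation of a non-constant punctum is exact", {
  shape <- c(4L, 12L, 12L)
  sp <- c(0.2, 0.11, 0.11)
  set.seed(3)
  base <- array(round(runif(prod(shape), 10, 60)), dim = shape)
  vox <- array(0, dim = c(shape, 2))
  vox[, , , 1] <- base
  vox[, , , 2] <- base          # identical second channel
  st <- multichannel_stack(vox, 0.11, 0.2, channel_names = c("a", "b"))
  p <- array(0L, dim = shape)
  p[2:3, 3:8, 3:8] <- 1L
  roi <- label_volume(array(1L, dim = shape), sp, "roi")
  rec <- measure_puncta(st, list(a = label_volume(p, sp, "puncta")), roi)
  expect_equal(rec$`Pearson correlation coefficient a vs. b`, 1)
  expect_lte(rec$`Pearson correlation p value a vs. b`, 0.05)
  # MI of a channel with itself equals the entropy of its binned values
  expect_equal(rec$`Mutual information a vs. b`,
               intensity_entropy(base[p == 1L], 256L), tolerance = 1e-12)
})

test_that("per-ROI dense/light means and background rows behave as defined", {
  shape <- c(4L, 24L, 24L)
  sp <- c(0.2, 0.11, 0.11)
  roi_arr <- array(0L, dim = shape)
  roi_arr[, 2:11, 2:11] <- 1L
  roi_arr[, 14:23, 14:23] <- 2L
  p <- array(0L, dim = shape)
  p[2:3, 4:6, 4:6] <- 1L                 # punctum in ROI 1 only
  vol <- array(1, dim = shape)           # image background intensity 1
  vol[roi_arr > 0L] <- 4
  vol[p > 0L] <- 20
  st <- multichannel_stack(array(vol, c(shape, 1)), 0.11, 0.2,
                           channel_names = "gfp", source_name = "imgA")
  roi <- label_volume(roi_arr, sp, "roi")
  plist <- list(gfp = label_volume(p, sp, "puncta"))
  rr <- measure_rois(st, roi, plist)

  expect_equal(nrow(rr), 2L)
  r1 <- rr[rr$`ROI label` == 1L, ]
  r2 <- rr[rr$`ROI label` == 2L, ]
  expect_equal(r1$`gfp mean intensity inside gfp puncta`, 20)
  expect_equal(r1$`gfp mean intensity outside gfp puncta`, 4)
  expect_equal(r1$`number of gfp puncta`, 1L)
  # ROI without puncta: count 0, inside fields missing, outside = ROI mean
  expect_equal(r2$`number of gfp puncta`, 0L)
  expect_true(is.na(r2$`gfp mean intensity inside gfp puncta`))
  expect_equal(r2$`gfp mean intensity outside gfp puncta`,
               r2$`gfp mean intensity per ROI`)
  # background rows identical across ROIs of one image
  expect_equal(r1$`gfp mean background intensity`,
               r2$`gfp mean background intensity`)
  expect_equal(r1$`gfp mean background intensity`, 1)
})

test_that("two channels with identical puncta masks have overlap 1", {
  shape <- c(3L, 12L, 12L)
  sp <- c(0.2, 0.11, 0.11)
  vox <- array(5, dim = c(shape, 2))
  st <- multichannel_stack(vox, 0.11, 0.2, channel_names = c("c1", "c2"))
  roi <- label_volume(array(1L, dim = shape), sp, "roi")
  p <- array(0L, dim = shape)
  p[2, 4:6, 4:6] <- 1L
  plist <- list(c1 = label_volume(p, sp, "puncta"),
                c2 = label_volume(p, sp, "puncta"))
  rr <- measure_rois(st, roi, plist)
  expect_equal(rr$`Overlap coefficient c1_c2_coloc`, 1)
})

test_that("intensity is conserved between inside- and outside-puncta pools", {
  set.seed(99)
  for (i in 1:5) {
    shape <- c(4L, 16L, 16L)
    sp <- c(0.2, 0.11, 0.11)
    nch <- 2L
    vox <- array(sample(0:500, prod(shape) * nch, replace = TRUE),
                 dim = c(shape, nch))
    st <- multichannel_stack(vox, 0.11, 0.2)
    roi_arr <- array(sample(0:2, prod(shape), replace = TRUE, prob = c(.3, .4, .3)),
                     dim = shape)
    p <- array(0L, dim = shape)
    p[sample(prod(shape), 40)] <- rep(1:4, each = 10)
    roi <- label_volume(roi_arr, sp, "roi")
    plist <- list(ch0 = label_volume(p, sp, "puncta"))
    rr <- measure_rois(st, roi, plist)
    for (r in rr$`ROI label`) {
      row <- rr[rr$`ROI label` == r, ]
      for (ch in st$channel_names) {
        inside <- row[[sprintf("%s integrated intensity inside ch0 puncta", ch)]]
        outside <- row[[sprintf("%s integrated intensity outside ch0 puncta", ch)]]
        total <- row[[sprintf("%s integrated intensity per ROI", ch)]]
        expect_identical(sum(c(inside, outside), na.rm = TRUE), total)
      }
    }
  }
})

test_that("puncta counts reconcile between the per-ROI and per-punctum tables", {
  sim <- simulate_stack(tiny_sim_params(seed = 101))
  st <- sim$stack
  roi <- sim$truth$nucleus_labels
  plist <- list(puncta = sim$truth$puncta_labels)
  pr <- measure_puncta(st, plist, roi)
  rr <- measure_rois(st, roi, plist, puncta_records = pr)
  for (r in rr$`ROI label`) {
    expect_equal(rr$`number of puncta puncta`[rr$`ROI label` == r],
                 sum(pr$`ROI label` == r & pr$Channel == "puncta"))
  }
  expect_equal(sum(rr$`number of puncta puncta`),
               sum(pr$`ROI label` > 0L))
})

test_that("measurement tables carry the standard column names verbatim", {
  sim <- simulate_stack(tiny_sim_params(seed = 103))
  st <- sim$stack
  roi <- sim$truth$nucleus_labels
  plist <- list(puncta = sim$truth$puncta_labels)
  pr <- measure_puncta(st, plist, roi)
  rr <- measure_rois(st, roi, plist, puncta_records = pr)
  expect_true(all(c("Image name", "Puncta label", "ROI label", "Channel",
                    "x", "y", "z", "Puncta volume pix", "Puncta volume um",
                    "Distance to ROI border um",
                    "nuclei mean intensity per puncta",
                    "puncta integrated intensity per puncta",
                    "Pearson correlation coefficient nuclei vs. puncta",
                    "Mutual information nuclei vs. puncta") %in% names(pr)))
  expect_true(all(c("Image name", "ROI label", "ROI volume pix",
                    "ROI volume um", "nuclei mean intensity per ROI",
                    "puncta integrated background intensity",
                    "nuclei entropy", "number of puncta puncta",
                    "average puncta puncta volume um per ROI",
                    "total puncta puncta volume pix per ROI",
                    "average puncta puncta distance to ROI border um per nucleus",
                    "puncta mean intensity inside puncta puncta",
                    "puncta mean intensity outside puncta puncta") %in% names(rr)))
  # CSV writing serializes missing values as empty cells
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_measurements(rr, tmp)
  expect_true(file.exists(tmp))
})
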