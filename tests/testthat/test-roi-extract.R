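# brute-force sphere membership over every voxel in the grid
brute_mask <- function(center, radius, grid) {
  g <- expand.grid(i = 0:(grid$dim[1] - 1), j = 0:(grid$dim[2] - 1),
                   k = 0:(grid$dim[3] - 1))
  mm <- t(grid$affine[1:3, 1:3] %*% t(as.matrix(g)) + grid$affine[1:3, 4])
  keep <- rowSums(sweep(mm, 2, center)^2) <= radius^2 + 1e-9
  m <- as.matrix(g[keep, , drop = FALSE]) + 1L
  m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
}

sort_mask <- function(m) m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]

test_that("sphere masks match an exhaustive voxel scan", {
  gs <- grid_spec(c(21, 21, 21), origin_mni = c(-10, -10, -10))
  got <- sort_mask(sphere_mask(list(center_mni = c(0, 0, 0), radius_mm = 5), gs))
  expect_equal(unname(got), unname(brute_mask(c(0, 0, 0), 5, gs)))
  # center exactly on a voxel center is always included, any radius >= 0
  tiny <- sphere_mask(list(center_mni = c(0, 0, 0), radius_mm = 0), gs)
  expect_equal(unname(tiny), matrix(c(11L, 11L, 11L), 1))
})

test_that("the right-cingulate sphere on a 3x3x4 mm grid matches brute force", {
  gs <- grid_spec(c(40, 40, 30), voxel_mm = c(3, 3, 4),
                  origin_mni = c(-60, -60, -20))
  roi <- roi_table()
  cing <- roi_spec_row(roi, which(roi$name == "cingulate_R"))
  expect_equal(cing$center_mni, c(2, 11, 46))
  got <- sort_mask(sphere_mask(cing, gs))
  expect_equal(unname(got), unname(brute_mask(c(2, 11, 46), 5, gs)))
})

test_that("masks grow with radius and mirror across the midline", {
  gs <- grid_spec(c(31, 31, 31), origin_mni = c(-15, -15, -15))
  sizes <- vapply(c(2, 3.5, 5, 7), function(r)
    nrow(sphere_mask(list(center_mni = c(1, 2, 3), radius_mm = r), gs)),
    numeric(1))
  expect_true(all(diff(sizes) >= 0))
  left <- sphere_mask(list(center_mni = c(-6, 2, 3), radius_mm = 4), gs)
  right <- sphere_mask(list(center_mni = c(6, 2, 3), radius_mm = 4), gs)
  mirrored <- cbind(32L - left[, 1], left[, 2], left[, 3])
  expect_equal(unname(sort_mask(right))[, 1:3],
               unname(sort_mask(mirrored)))
  expect_warning(sphere_mask(list(center_mni = c(-15, 0, 0), radius_mm = 4,
                                  name = "edge"), gs), "truncated")
  expect_error(sphere_mask(list(center_mni = c(900, 0, 0), radius_mm = 2), gs),
               "empty mask")
})

test_that("mean time series averages mask voxels and validates bounds", {
  gs <- grid_spec(c(8, 8, 8))
  vol <- list(data = array(0, c(8, 8, 8, 5)), affine = gs$affine)
  a <- rnorm(5); b <- rnorm(5)
  vol$data[2, 2, 2, ] <- a
  vol$data[3, 2, 2, ] <- b
  expect_equal(mean_timeseries(vol, matrix(c(2, 2, 2), 1)), a)
  expect_equal(mean_timeseries(vol, rbind(c(2, 2, 2), c(3, 2, 2))), (a + b) / 2)
  expect_error(mean_timeseries(vol, matrix(c(9, 1, 1), 1)), "outside")
})

test_that("noise-free volumes round-trip through NIfTI and extraction", {
  rois <- roi_table(radius_mm = 3)
  rois$x <- c(5, 15, 5, 15, 10); rois$y <- c(5, 5, 15, 15, 10)
  rois$z <- rep(10, 5)
  gs <- grid_spec(c(21, 21, 21))
  series <- matrix(rnorm(5 * 30), 30, 5)
  vol <- make_voxel_volume(series, rois, gs, noise_sd = 0, seed = 3)
  path <- file.path(tempdir(), "vol.nii.gz")
  write_volume(vol, path)
  back <- read_volume(path)
  expect_equal(back$data, vol$data, tolerance = 1e-6)
  expect_equal(unname(back$affine[1:3, 4]), c(0, 0, 0))
  for (k in 1:5) {
    mask <- sphere_mask(roi_spec_row(rois, k), gs)
    expect_equal(mean_timeseries(back, mask), series[, k], tolerance = 1e-6)
  }
})

test_that("input vectors mark the TR bins of qualifying onsets only", {
  sch <- data.frame(phase = "transfer",
                    trial_type = c("fixation", "CS1", "recharge",
                                   "fixation", "CS3", "recharge",
                                   "fixation", "CS4", "recharge"),
                    onset = c(0, 10, 14, 20, 26, 30, 36, 40, 44),
                    duration = c(4, 4, 4, 4, 4, 4, 4, 4, 4))
  u <- build_inputs(sch, tr_s = 2, n_trs = 30)
  expect_equal(which(u[, "specific"] == 1), 6)  # onset 10 s -> 0-based bin 5
  expect_equal(which(u[, "general"] == 1), 14)
  expect_equal(sum(u), 2)
  only45 <- sch[sch$trial_type %in% c("fixation", "CS4", "recharge"), ]
  expect_true(all(build_inputs(only45, 2, 30) == 0))
  expect_error(build_inputs(sch, tr_s = 2, n_trs = 5), "exceeds")

  full <- gen_transfer_schedule(task_config(), 8)
  uu <- build_inputs(full, 2, 540)
  expect_equal(sum(uu[, "specific"]), 24)
  expect_equal(sum(uu[, "general"]), 12)
})

test_that("assembled subject matrices have the fixed layout and round-trip", {
  series <- lapply(1:5, function(i) rnorm(540))
  inputs <- cbind(specific = rbinom(540, 1, 0.04),
                  general = rbinom(540, 1, 0.02))
  m <- assemble_matrix(series, inputs, tr_s = 2, subject_id = "s7")
  expect_equal(dim(m), c(540, 7))
  expect_equal(colnames(m), c("putamen_L", "putamen_R", "insula_L",
                              "insula_R", "cingulate_R", "specific", "general"))
  path <- file.path(tempdir(), "mat.tsv")
  write_subject_matrix(m, path)
  back <- read_subject_matrix(path, tr_s = 2, subject_id = "s7")
  expect_equal(unclass(back), unclass(m), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(assemble_matrix(lapply(1:5, function(i) numeric(0)),
                               inputs[0, , drop = FALSE]), "zero time points")
  expect_error(assemble_matrix(series, inputs[-1, , drop = FALSE]), "length")
})
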