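# Pipeline-level checks on the shared default phantom run (cached, see
# helper-phantom.R).

test_that("stage-1 markers are safe: brain marker in, background out", {
  ph <- default_human_phantom(1)
  res <- default_human_run(1)
  tr <- res$trace
  expect_true(any(tr$M_A$data))
  expect_true(all(ph$truth$data[tr$M_A$data]))        # M_A inside the brain
  expect_false(any(tr$N_F$data & ph$truth$data))      # N_F outside
  expect_false(any(tr$N_F$data & tr$M_A$data))
})

test_that("stage-1 mask is conservative and contains its marker", {
  ph <- default_human_phantom(1)
  res <- default_human_run(1)
  expect_gte(overlap(res$stage1_mask, ph$truth)$sensitivity, 0.99)
  expect_true(all(res$stage1_mask$data[res$trace$M_A$data]))
})

test_that("stage-2 markers partition cleanly and stay in their zones", {
  res <- default_human_run(1)
  tr <- res$trace
  expect_false(any(tr$M_2$data & tr$N_2$data))
  # dark markers live in the border zone, inside the stage-1 mask
  expect_true(all(res$stage1_mask$data[tr$N_dark$data]))
  expect_false(any(tr$B_1e$data & tr$N_dark$data))
  # the default phantom has no marrow: no bright markers
  expect_false(any(tr$N_bright$data))
})

test_that("the border zone is the set of voxels within reach of the
          boundary, by the distance-transform definition", {
  d <- c(26, 24, 22)
  m <- array(FALSE, d); m[5:22, 5:20, 5:18] <- TRUE
  bz <- m & !binary_morph(mask3(m), "erode", 4)$data
  # oracle: distance from each mask voxel to the nearest complement voxel
  inside <- which(m, arr.ind = TRUE)
  outside <- which(!m, arr.ind = TRUE)
  dmin <- apply(inside, 1, function(p)
    sqrt(min(colSums((t(outside) - p)^2))))
  expect_identical(as.vector(bz[m]), dmin <= 4)
})

test_that("stage-2 control is clipped and assembled as a voxel-wise max", {
  res <- default_human_run(1)
  tr <- res$trace
  t50 <- quantile_in_mask(tr$R_0, res$stage1_mask, 0.5)
  expect_true(all(tr$R_C$data <= t50 + 1e-12))
  expect_equal(tr$R_2$data, pmax(tr$R_D$data, tr$R_E$data))
  expect_true(all(tr$R_2$data >= 0))
})

test_that("stage-2 output respects the removal and dilation contracts", {
  res <- default_human_run(1)
  expect_false(any(res$stage2_mask$data & res$trace$N_bright$data))
  grown <- binary_morph(res$stage1_mask, "dilate",
                        res$params$final_dilate_mm)
  expect_false(any(res$stage2_mask$data & !grown$data))
})

test_that("stage 2 recovers the brain accurately on the default phantom", {
  ph <- default_human_phantom(1)
  res <- default_human_run(1)
  expect_gte(overlap(res$stage2_smoothed, ph$truth)$dice, 0.95)
  expect_gte(overlap(res$stage2_mask, ph$truth)$dice, 0.95)
})

test_that("all output grids match the input grid", {
  ph <- default_human_phantom(1)
  res <- default_human_run(1)
  for (nm in c("stage1_mask", "stage2_mask", "stage1_smoothed",
               "stage2_smoothed")) {
    expect_identical(dim(res[[nm]]$data), dim(ph$volume$data))
    expect_identical(res[[nm]]$spacing, ph$volume$spacing)
  }
})

test_that("mask smoothing removes spikes, closes slits, and is idempotent", {
  d <- c(44, 44, 44)
  ball <- array(FALSE, d)
  idx <- which(array(TRUE, d), arr.ind = TRUE)
  ball[sqrt(rowSums((idx - 22)^2)) <= 15] <- TRUE
  base <- smooth_mask(mask3(ball), 1)   # open/close fixed point
  expect_gt(sum(base$data & ball) / sum(ball | base$data), 0.95)
  expect_identical(smooth_mask(base, 1)$data, base$data)
  spiked <- base$data
  spiked[21:22, 21:22, 38:42] <- TRUE   # 2 mm spike off the surface
  sm1 <- smooth_mask(mask3(spiked), 1)
  expect_false(any(sm1$data[21:22, 21:22, 40:42]))
  slit <- base$data
  slit[21:23, , ] <- FALSE              # 3 mm slit through the ball
  sm2 <- smooth_mask(mask3(slit), 2)
  expect_true(all(sm2$data[21:23, 22, 22]))
  expect_identical(smooth_mask(sm2, 2)$data, sm2$data)
})

test_that("failures are reported with the stage that produced them", {
  flat <- vol3(array(0, c(20, 20, 20)))
  expect_error(extract_brain_human(flat), "neck crop")
  ph <- default_human_phantom(1)
  bad <- human_params(box_below_com_mm = 400)
  expect_error(extract_brain_human(ph$volume, bad), "stage-1 brain marker")
})

test_that("stage-1-only runs stop after the first watershed", {
  ph <- default_macaque_phantom(1)
  res <- extract_brain_macaque(ph$volume, bias_correct = FALSE, stages = 1)
  expect_null(res$stage2_mask)
  expect_true(any(res$stage1_mask$data))
})
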