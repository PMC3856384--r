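test_that("mm to voxel conversion rounds half up with a 1-voxel floor", {
  expect_identical(mm_to_voxels(2, c(1, 1, 1)), c(2L, 2L, 2L))
  expect_identical(mm_to_voxels(0, c(0.5, 2, 7)), c(0L, 0L, 0L))
  expect_identical(mm_to_voxels(2, c(0.9, 0.9, 3)), c(2L, 2L, 1L))
  expect_identical(mm_to_voxels(0.1, c(5, 5, 5)), c(1L, 1L, 1L))
  expect_error(mm_to_voxels(-1, c(1, 1, 1)), "non-negative")
})

test_that("binary sphere morphology matches the Minkowski oracle", {
  set.seed(101)
  for (i in 1:12) {
    d <- rand_dims()
    sp <- if (i %% 3 == 0) c(0.9, 1.1, 1.6) else c(1, 1, 1)
    m <- rand_mask(d, p = runif(1, 0.3, 0.7), spacing = sp)
    r <- sample(c(1, 1.5, 2, 2.7), 1)
    offs <- ball_offs_oracle(r, sp)
    expect_identical(binary_morph(m, "erode", r)$data,
                     oracle_binary(m$data, offs, "erode"))
    expect_identical(binary_morph(m, "dilate", r)$data,
                     oracle_binary(m$data, offs, "dilate"))
  }
})

test_that("binary morphology degenerate cases and structure", {
  m <- rand_mask(c(8, 8, 8), p = 0.5)
  expect_identical(binary_morph(m, "erode", 0)$data, m$data)
  empty <- mask3(array(FALSE, c(6, 6, 6)))
  expect_false(any(binary_morph(empty, "erode", 2)$data))
  expect_false(any(binary_morph(empty, "dilate", 2)$data))
  # 11^3 solid cube eroded by 2 mm: interior shrinks by 2 voxels per face
  g <- array(FALSE, c(15, 15, 15)); g[3:13, 3:13, 3:13] <- TRUE
  er <- binary_morph(mask3(g), "erode", 2)
  expect_identical(er$data, oracle_binary(g, ball_offs_oracle(2, c(1, 1, 1)),
                                          "erode"))
})

test_that("dilation/erosion duality holds on interior-padded grids", {
  set.seed(7)
  for (i in 1:5) {
    d <- c(14, 14, 14)
    inner <- array(FALSE, d)
    inner[5:10, 5:10, 5:10] <- array(runif(216) < 0.5, c(6, 6, 6))
    m <- mask3(inner)
    r <- sample(c(1, 2), 1)
    dil <- binary_morph(m, "dilate", r)$data
    ero_c <- !binary_morph(mask3(!inner), "erode", r)$data
    expect_identical(dil, ero_c)
  }
})

test_that("binary opening and closing are idempotent", {
  set.seed(11)
  for (i in 1:5) {
    m <- rand_mask(c(12, 12, 12), p = 0.55)
    for (op in c("open", "close")) {
      once <- binary_morph(m, op, 1.5)
      expect_identical(binary_morph(once, op, 1.5)$data, once$data)
    }
  }
})

test_that("grayscale morphology matches the footprint oracle", {
  set.seed(21)
  for (i in 1:10) {
    d <- rand_dims()
    v <- rand_vol(d)
    if (i %% 2 == 0) {
      k <- kernel_box(sample(2:5, 1))
      h <- pmax(1L, as.integer(floor(k$size_mm / 1 + 0.5))) %/% 2L
      offs <- box_offs_oracle(h)
    } else {
      k <- kernel_sphere(sample(c(1, 1.8), 1))
      offs <- ball_offs_oracle(k$size_mm, c(1, 1, 1))
    }
    expect_equal(gray_morph(v, "dilate", k)$data,
                 oracle_gray(v$data, offs, TRUE))
    expect_equal(gray_morph(v, "erode", k)$data,
                 oracle_gray(v$data, offs, FALSE))
  }
})

test_that("grayscale morphology contracts: fixed points and ordering", {
  const <- vol3(array(3.2, c(7, 7, 7)))
  for (op in c("erode", "dilate", "open", "close"))
    expect_equal(gray_morph(const, op, kernel_box(3))$data, const$data)
  v <- vol3(array(0, c(9, 9, 9))); v$data[5, 5, 5] <- 1
  dl <- gray_morph(v, "dilate", kernel_box(3))
  expect_equal(sum(dl$data == 1), 27)
  set.seed(31)
  r <- rand_vol(c(16, 16, 16))
  op <- gray_morph(r, "open", kernel_box(3))
  cl <- gray_morph(r, "close", kernel_box(3))
  expect_true(all(op$data <= r$data + 1e-12))
  expect_true(all(cl$data >= r$data - 1e-12))
  expect_equal(gray_morph(op, "open", kernel_box(3))$data, op$data)
  expect_equal(gray_morph(cl, "close", kernel_box(3))$data, cl$data)
})

test_that("box mean matches the sliding-window oracle", {
  const <- vol3(array(5, c(8, 8, 8)))
  expect_equal(box_mean(const, 2)$data, const$data)
  v <- vol3(array(0, c(11, 11, 11))); v$data[6, 6, 6] <- 10
  bm <- box_mean(v, 2)
  expect_equal(bm$data[6, 6, 6], 10 / 125)
  set.seed(41)
  for (i in 1:8) {
    d <- rand_dims(12, 6)
    vv <- rand_vol(d)
    r <- sample(1:3, 1)
    expect_equal(box_mean(vv, r)$data, oracle_box_mean(vv$data, rep(r, 3)))
  }
})

test_that("masked mean matches its oracle and reduces to box mean", {
  set.seed(51)
  d <- c(10, 10, 10)
  v <- rand_vol(d)
  allm <- mask3(array(TRUE, d))
  expect_equal(masked_mean(v, allm, kernel_box(5))$data,
               box_mean(v, 2)$data)
  one <- array(FALSE, d); one[4, 5, 6] <- TRUE
  mm <- masked_mean(v, mask3(one), kernel_box(5))
  reach <- oracle_masked_mean(v$data, one, c(2, 2, 2))
  expect_equal(mm$data, reach)
  expect_equal(mm$data[4, 5, 6], v$data[4, 5, 6])
  for (i in 1:8) {
    m <- rand_mask(d, p = 0.4)
    expect_equal(masked_mean(v, m, kernel_box(7))$data,
                 oracle_masked_mean(v$data, m$data, c(3, 3, 3)))
  }
})

test_that("Otsu threshold matches the exhaustive scan", {
  v <- vol3(array(c(rep(10, 50), rep(90, 50)), c(10, 10, 1)))
  t <- otsu_threshold(v)
  expect_gt(t, 10); expect_lt(t, 90)
  expect_error(otsu_threshold(vol3(array(4, c(5, 5, 5)))), "constant")
  set.seed(61)
  for (i in 1:20) {
    d <- rand_dims(12, 6)
    vv <- rand_vol(d)
    reg <- rand_mask(d, p = 0.7)
    expect_equal(otsu_threshold(vv, reg), oracle_otsu(vv$data[reg$data]))
  }
})

test_that("Otsu threshold is affine-covariant within one bin", {
  set.seed(71)
  v <- rand_vol(c(12, 12, 12))
  t0 <- otsu_threshold(v)
  a <- 3.7; b <- 11
  t1 <- otsu_threshold(vol3(a * v$data + b))
  bin <- a * (max(v$data) - min(v$data)) / 128
  expect_lt(abs(t1 - (a * t0 + b)), bin + 1e-9)
})

test_that("nearest-rank quantiles", {
  v <- vol3(array(as.double(sample(1:100)), c(10, 10, 1)))
  all <- mask3(array(TRUE, c(10, 10, 1)))
  expect_equal(quantile_in_mask(v, all, 0), 1)
  expect_equal(quantile_in_mask(v, all, 0.5), 50)
  expect_equal(quantile_in_mask(v, all, 1), 100)
  set.seed(81)
  for (i in 1:20) {
    n <- sample(5:200, 1)
    vals <- runif(n)
    q <- runif(1)
    vv <- vol3(array(vals, c(n, 1, 1)))
    expect_equal(quantile_in_mask(vv, NULL, q),
                 sort(vals)[max(1, ceiling(q * n))])
  }
  expect_error(quantile_in_mask(v, mask3(array(FALSE, c(10, 10, 1))), 0.5),
               "empty")
})

test_that("connected-component filtering by size, volume and touch", {
  d <- c(12, 12, 12)
  m <- array(FALSE, d)
  m[2:4, 2:4, 2:4] <- TRUE          # 27 voxels
  m[8:9, 8:9, 8] <- TRUE            # 4 voxels
  m[12, 12, 12] <- TRUE             # 1 voxel
  mm <- mask3(m)
  big <- cc_filter(mm, "keep_largest")
  expect_equal(sum(big$data), 27)
  expect_true(all(which(big$data) %in% which(m)))
  # min_volume at 2 mm spacing: voxel volume 8 mm^3, cutoff 10 mm^3
  mm2 <- mask3(m, spacing = c(2, 2, 2))
  kept <- cc_filter(mm2, "min_volume", min_mm3 = 10)
  expect_equal(sum(kept$data), 31)  # 1-voxel component (8 mm^3) dropped
  ref <- array(FALSE, d); ref[8, 8, 8] <- TRUE
  touch <- cc_filter(mm, "keep_touching", touching = mask3(ref))
  expect_equal(sum(touch$data), 4)
  empty <- mask3(array(FALSE, d))
  expect_false(any(cc_filter(empty, "keep_largest")$data))
  # labelling agrees with a flood-fill oracle
  set.seed(91)
  for (i in 1:6) {
    rm <- rand_mask(c(9, 9, 9), p = 0.35)
    lab_o <- oracle_label(rm$data)
    keep <- cc_filter(rm, "keep_largest")
    sizes <- tabulate(lab_o[lab_o > 0])
    expect_equal(sum(keep$data), max(sizes))
    expect_true(all(lab_o[keep$data] == lab_o[keep$data][1]))
  }
})

test_that("smoothed gradient: flat images, positivity, oracle", {
  const <- vol3(array(2, c(8, 8, 8)))
  expect_equal(gradient_smooth(const, 1)$data, array(0, c(8, 8, 8)))
  set.seed(95)
  v <- rand_vol(c(10, 10, 10))
  g <- gradient_smooth(v, 1.5)
  expect_true(all(g$data >= 0))
  # step edge: direct unit-footprint + convolution oracle
  v2 <- vol3(array(rep(c(0, 0, 0, 0, 1, 1, 1, 1), each = 1), c(8, 8, 8)))
  step <- vol3(array(0, c(8, 8, 8)))
  step$data[5:8, , ] <- 1
  g2 <- gradient_smooth(step, 1)
  offs <- rbind(c(0, 0, 0), c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
                c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  dil <- oracle_gray(step$data, offs, TRUE)
  ero <- oracle_gray(step$data, offs, FALSE)
  expect_equal(g2$data, oracle_gauss(dil - ero, c(1, 1, 1)))
  expect_gt(g2$data[4, 4, 4], g2$data[2, 4, 4])
  # masked gradient sees no edge at the mask border of a constant region
  m <- array(FALSE, c(8, 8, 8)); m[3:6, 3:6, 3:6] <- TRUE
  gm <- gradient_smooth(const, 1, within = mask3(m))
  expect_equal(gm$data, array(0, c(8, 8, 8)))
})
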