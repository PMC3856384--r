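test_that("1D flooding: plateau tie goes to the first-queued flood", {
  ctrl <- vol3(array(c(0, 1, 5, 1, 0), c(5, 1, 1)))
  mk <- array(0L, c(5, 1, 1)); mk[1, 1, 1] <- 1L; mk[5, 1, 1] <- 2L
  ws <- watershed_markers(ctrl, mk)
  expect_identical(as.vector(ws$data), c(1L, 1L, 1L, 2L, 2L))
})

test_that("a single marker floods the whole image", {
  set.seed(1)
  ctrl <- rand_vol(c(7, 7, 7))
  mk <- array(0L, c(7, 7, 7)); mk[4, 4, 4] <- 1L
  ws <- watershed_markers(ctrl, mk)
  expect_true(all(ws$data == 1L))
})

test_that("markers are preserved and every voxel is labelled", {
  set.seed(2)
  for (i in 1:25) {
    d <- c(12, 12, 12)
    ctrl <- rand_vol(d)
    nlab <- sample(2:4, 1)
    mk <- array(0L, d)
    seeds <- sample(prod(d), nlab * 3)
    mk[seeds] <- rep(seq_len(nlab), each = 3)
    ws <- watershed_markers(ctrl, mk)
    expect_true(all(ws$data > 0L))
    expect_identical(ws$data[seeds], mk[seeds])
  }
})

test_that("marker image validation", {
  ctrl <- rand_vol(c(6, 6, 6))
  b <- array(FALSE, c(6, 6, 6)); b[2, 2, 2] <- TRUE
  g <- array(FALSE, c(6, 6, 6)); g[5, 5, 5] <- TRUE
  mk <- merge_markers(mask3(b), mask3(g))
  expect_identical(sort(unique(as.vector(mk$data))), c(0L, 1L, 2L))
  expect_error(merge_markers(mask3(b), mask3(b)), "overlap")
  empty_bg <- merge_markers(mask3(b), mask3(array(FALSE, c(6, 6, 6))))
  expect_error(watershed_markers(ctrl, empty_bg), "labels 1 and 2")
  expect_error(watershed_markers(ctrl, array(0L, c(6, 6, 6))),
               "at least one marker")
})

test_that("flooding equals the watershed of the minima-imposed surface", {
  set.seed(3)
  for (i in 1:25) {
    d <- c(12, 12, 12)
    ctrl <- rand_vol(d)   # continuous values: ties have measure zero
    nlab <- sample(2:4, 1)
    mk <- array(0L, d)
    seeds <- sample(prod(d), nlab * 2)
    mk[seeds] <- rep(seq_len(nlab), each = 2)
    imp <- impose_minima(ctrl, mask3(array(mk > 0L, d)))
    expect_identical(watershed_markers(ctrl, mk)$data,
                     watershed_markers(imp, mk)$data)
  }
})

test_that("minima imposition leaves minima only at the markers", {
  # full-marker cover: flat minimal surface
  d <- c(5, 5, 5)
  ctrl <- rand_vol(d)
  allm <- mask3(array(TRUE, d))
  imp <- impose_minima(ctrl, allm)
  expect_equal(max(imp$data) - min(imp$data), 0)
  # 1D two-well signal: every regional minimum intersects a marker
  sig <- c(5, 3, 4, 2, 6, 1, 2, 7, 3, 2, 4, 8)
  v1 <- vol3(array(sig, c(length(sig), 1, 1)))
  mkm <- array(FALSE, c(length(sig), 1, 1))
  mkm[c(2, 9), 1, 1] <- TRUE
  imp1 <- impose_minima(v1, mask3(mkm))
  mins <- regional_minima(imp1)
  expect_true(any(mins$data))
  expect_true(all(mkm[mins$data]))
  # reconstruction bounds: basins fill, so the imposed surface sits at or
  # above the control off the markers and below it only at the marker wells
  expect_true(all(imp1$data[!mkm] >= v1$data[!mkm] - 1e-12))
  expect_true(all(imp1$data[mkm] < min(v1$data)))
  set.seed(4)
  for (i in 1:10) {
    ctrl <- rand_vol(c(9, 9, 9))
    mk <- rand_mask(c(9, 9, 9), p = 0.05)
    if (!any(mk$data)) next
    imp <- impose_minima(ctrl, mk)
    mins <- regional_minima(imp)
    expect_true(all(mk$data[mins$data]))
    expect_true(all(imp$data[!mk$data] >= ctrl$data[!mk$data] - 1e-12))
  }
})
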