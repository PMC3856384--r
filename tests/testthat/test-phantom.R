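test_that("phantom generation is deterministic per seed", {
  a <- make_phantom(macaque_phantom_spec(seed = 9, bias_amplitude = 0.2))
  b <- make_phantom(macaque_phantom_spec(seed = 9, bias_amplitude = 0.2))
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth$data, b$truth$data)
  c <- make_phantom(macaque_phantom_spec(seed = 10, bias_amplitude = 0.2))
  expect_false(identical(a$volume$data, c$volume$data))
})

test_that("phantom generation leaves the caller's RNG state alone", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(make_phantom(macaque_phantom_spec(seed = 5)))
  expect_identical(runif(1), before)
})

test_that("noise-free, bias-free phantom is piecewise constant", {
  ph <- make_phantom(human_phantom_spec(seed = 1, noise_sd = 0))
  vals <- unique(as.vector(ph$volume$data))
  expect_lte(length(vals), 10)
  ints <- ph$spec$intensities
  expect_true(all(abs(ph$volume$data[ph$tissues == 7] - ints$white) < 1e-12))
  expect_true(all(abs(ph$volume$data[ph$tissues == 5] - ints$csf) < 1e-12))
})

test_that("brain truth volume approximates the analytic ellipsoid volume", {
  ph <- make_phantom(human_phantom_spec(seed = 1, noise_sd = 0))
  semi <- ph$spec$brain_semi_mm
  analytic <- 4 / 3 * pi * prod(semi)
  # truth = ellipsoid plus the brain-stem extension below it
  lev <- attr(ph$tissues, "levels")
  ell_vox <- sum(ph$tissues %in% lev[c("gray", "white", "ventricle",
                                       "deepgray")])
  expect_lt(abs(ell_vox * prod(ph$volume$spacing) - analytic) / analytic,
            0.02)
})

test_that("bias field spans the requested amplitude", {
  ph <- make_phantom(human_phantom_spec(seed = 4, bias_amplitude = 0.5))
  expect_equal(max(ph$bias_field), 1.5, tolerance = 0.02)
  expect_gte(min(ph$bias_field), 0.5 - 1e-9)
})

test_that("overlap scores: identity, disjoint, counted example", {
  d <- c(10, 10, 10)
  a <- array(FALSE, d); a[2:4, 2:4, 2:4] <- TRUE
  s <- overlap(mask3(a), mask3(a))
  expect_equal(s$dice, 1); expect_equal(s$jaccard, 1)
  expect_equal(s$sensitivity, 1); expect_equal(s$specificity, 1)
  b <- array(FALSE, d); b[7:9, 7:9, 7:9] <- TRUE
  expect_equal(overlap(mask3(a), mask3(b))$dice, 0)
  # 3x3x3 cube inside a 3x3x5 box: dice = 54/72
  box <- array(FALSE, d); box[2:4, 2:4, 2:6] <- TRUE
  s2 <- overlap(mask3(a), mask3(box))
  expect_equal(s2$dice, 54 / 72)
  expect_equal(s2$jaccard, 27 / 45)
  expect_error(overlap(mask3(array(FALSE, d)), mask3(array(FALSE, d))),
               "empty")
})

test_that("jaccard and dice satisfy j = d / (2 - d)", {
  set.seed(17)
  for (i in 1:10) {
    p <- rand_mask(c(8, 8, 8), p = 0.4)
    t <- rand_mask(c(8, 8, 8), p = 0.4)
    if (!any(p$data) && !any(t$data)) next
    s <- overlap(p, t)
    expect_equal(s$jaccard, s$dice / (2 - s$dice), tolerance = 1e-12)
  }
})
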