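test_that("Hessian eigenfields vanish on constant images and reject tiny scales", {
  ef <- hessian_eigen(matrix(0.7, 64, 64), 2)
  expect_true(all(abs(ef$lambda1) < 1e-10))
  expect_true(all(abs(ef$lambda2) < 1e-10))
  expect_error(hessian_eigen(matrix(0, 8, 8), 0.3), ">= 0.5")
})

test_that("a dark ridge is strongest on its centreline with positive sign", {
  n <- 64
  img <- matrix(1, n, n)
  w <- 4
  img[(n / 2 - w / 2 + 1):(n / 2 + w / 2), ] <- 0   # dark horizontal band
  ef <- hessian_eigen(img, w / 2)
  mid_cols <- 20:44
  peak_rows <- apply(ef$lambda1[, mid_cols], 2, which.max)
  expect_true(all(abs(peak_rows - n / 2) <= 1.5))
  expect_true(all(ef$sign1[n / 2, mid_cols] > 0))
  # the eigenfields commute with exact 90-degree rotation
  rot <- t(img)[, n:1]
  ef_r <- hessian_eigen(rot, w / 2)
  back <- t(ef_r$lambda1[, n:1])
  expect_lt(max(abs(back - ef$lambda1)), 1e-6)
})

test_that("vesselness suppresses blobs relative to equal-contrast ridges", {
  n <- 96
  blob <- matrix(1, n, n)
  d2 <- fundusfd:::pixel_dist2(n, n, c(n / 2, n / 2))
  blob <- 1 - 0.8 * exp(-d2 / (2 * 3^2))              # isotropic dark blob
  ridge <- matrix(1, n, n)
  rr <- matrix((seq_len(n) - 1) - n / 2, n, n)
  ridge <- 1 - 0.8 * exp(-rr^2 / (2 * 3^2))           # dark ridge, same depth
  params <- frangi_params(scales = c(2, 3, 4))
  # compare peak responses on a common composite image so the shared
  # [0,1] rescaling cannot hide the difference
  both <- cbind(ridge, blob)
  v <- frangi_vesselness(both, params)
  peak_ridge <- max(v[, 1:n])
  peak_blob <- max(v[, (n + 1):(2 * n)])
  expect_lt(peak_blob, 0.5 * peak_ridge)
  # constant image gives an identically zero map
  expect_true(all(frangi_vesselness(matrix(1, 64, 64), params) == 0))
})

test_that("thresholding is a nested family with exact boundary cases", {
  b <- get_default_seg()
  pm <- b$pm
  expect_true(all(threshold_map(pm, 0)))
  expect_equal(sum(threshold_map(pm, 1)), sum(pm == 1))
  t1 <- threshold_map(pm, 0.2); t2 <- threshold_map(pm, 0.4)
  expect_true(all(t2 <= t1))
  expect_error(threshold_map(pm, 1.1), "\\[0, 1\\]")
})

test_that("MCC matches its closed form and boundary values", {
  m <- matrix(FALSE, 10, 10)
  truth <- m; truth[1:3, ] <- TRUE
  q <- segmentation_quality(truth, truth)
  expect_equal(q$MCC, 1)
  q2 <- segmentation_quality(!truth, truth)
  expect_equal(q2$MCC, -1)
  # constructed 100-pixel confusion: TP=6 TN=85 FP=5 FN=4.
  # Brute-force Eq. evaluation: (6*85 - 5*4)/sqrt(11*10*90*89)
  pred <- c(rep(TRUE, 6), rep(FALSE, 4), rep(TRUE, 5), rep(FALSE, 85))
  gt <- c(rep(TRUE, 10), rep(FALSE, 90))
  q3 <- segmentation_quality(matrix(pred, 10), matrix(gt, 10))
  expect_equal(q3$TP, 6); expect_equal(q3$FN, 4); expect_equal(q3$FP, 5)
  expect_equal(q3$MCC, (6 * 85 - 5 * 4) / sqrt(11 * 10 * 90 * 89),
               tolerance = 1e-12)
  # all-negative prediction has a zero denominator factor
  q4 <- segmentation_quality(matrix(FALSE, 10, 10), matrix(gt, 10))
  expect_true(q4$degenerate)
  expect_equal(q4$MCC, 0)
  expect_error(segmentation_quality(truth, truth, matrix(FALSE, 10, 10)),
               "empty")
})

test_that("MCC equals the Pearson correlation of indicator vectors", {
  set.seed(77)
  for (i in 1:25) {
    a <- matrix(runif(64 * 64) < runif(1, 0.05, 0.5), 64)
    b <- matrix(runif(64 * 64) < runif(1, 0.05, 0.5), 64)
    q <- segmentation_quality(a, b)
    expect_equal(q$MCC, suppressWarnings(stats::cor(as.numeric(a),
                                                    as.numeric(b))),
                 tolerance = 1e-12)
  }
})

test_that("threshold sweeps cover the canonical grid deterministically", {
  b <- get_default_seg()
  sw <- threshold_sweep(b$pm, b$bundle$truth_vessels, b$bundle$fov_mask)
  expect_equal(nrow(sw), 21)
  expect_equal(sw$t, seq(0.15, 0.35, by = 0.01))
  expect_true(all(diff(sw$TP + sw$FP) <= 0))   # vessel count shrinks with t
  # truth fed back as its own probability map scores perfectly at any t
  tm <- b$bundle$truth_vessels * 1
  sw2 <- threshold_sweep(tm, b$bundle$truth_vessels, b$bundle$fov_mask,
                         0.2, 0.8, 0.2)
  expect_true(all(sw2$MCC == 1))
  expect_error(threshold_sweep(tm, b$bundle$truth_vessels, NULL, 0.5, 0.2),
               "t_min < t_max")
})

test_that("the default phantom is segmentable to MCC >= 0.7", {
  b <- get_default_seg()
  sw <- threshold_sweep(b$pm, b$bundle$truth_vessels, b$bundle$fov_mask)
  expect_gte(max(sw$MCC), 0.7)
})
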