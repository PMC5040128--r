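test_that("the Gaussian color transform matches its matrix exactly", {
  px <- function(r, g, b) array(c(r, g, b), dim = c(1, 1, 3))
  z <- gaussian_color_transform(px(0, 0, 0))
  expect_equal(c(z$e, z$e_lambda, z$e_lambda_lambda), c(0, 0, 0))
  w <- gaussian_color_transform(px(1, 1, 1))
  expect_equal(c(w$e, w$e_lambda, w$e_lambda_lambda), c(1.00, 0.00, -0.16))
  r <- gaussian_color_transform(px(1, 0, 0))
  expect_equal(c(r$e, r$e_lambda, r$e_lambda_lambda), c(0.06, 0.19, 0.22))
  g <- gaussian_color_transform(px(0, 1, 0))
  expect_equal(c(g$e, g$e_lambda, g$e_lambda_lambda), c(0.63, 0.18, -0.44))
  b <- gaussian_color_transform(px(0, 0, 1))
  expect_equal(c(b$e, b$e_lambda, b$e_lambda_lambda), c(0.31, -0.37, 0.06))
  expect_error(gaussian_color_transform(matrix(0, 4, 4)), "3-channel")
})

test_that("the color transform is exactly linear", {
  set.seed(5)
  X <- array(runif(12 * 12 * 3), dim = c(12, 12, 3))
  Y <- array(runif(12 * 12 * 3), dim = c(12, 12, 3))
  lhs <- gaussian_color_transform(2 * X + 3 * Y)
  rx <- gaussian_color_transform(X); ry <- gaussian_color_transform(Y)
  for (p in names(lhs)) {
    expect_equal(lhs[[p]], 2 * rx[[p]] + 3 * ry[[p]], tolerance = 1e-12)
  }
})

test_that("ellipse fitting is exact on noiseless conics", {
  th <- seq(0, 2 * pi, length.out = 40)[-40]
  circ <- cbind(100 + 30 * cos(th), 80 + 30 * sin(th))
  f <- fit_ellipse(circ)
  expect_equal(f$major_radius, 30, tolerance = 1e-6)
  expect_equal(f$minor_radius, 30, tolerance = 1e-6)
  expect_equal(f$center, c(100, 80), tolerance = 1e-6)

  ell <- cbind(50 + 50 * cos(th), 60 + 40 * sin(th))
  fe <- fit_ellipse(ell)
  expect_equal((fe$major_radius + fe$minor_radius) / 2, 45, tolerance = 1e-6)
  expect_error(fit_ellipse(circ[1:5, ]), "under-determined")
})

test_that("optic disc radius is recovered from rendered discs", {
  # clean synthetic bright, yellowish disc of radius 40 on a flat background
  n <- 192
  d2 <- fundusfd:::pixel_dist2(n, n, c(96, 96))
  soft <- pmin(pmax((40 + 1 - sqrt(d2)) / 2, 0), 1)
  img <- array(0, dim = c(n, n, 3))
  img[, , 1] <- 0.75 + 0.2 * soft
  img[, , 2] <- 0.70 + 0.18 * soft
  img[, , 3] <- 0.33 - 0.05 * soft
  g <- estimate_od_geometry(img, c(95, 95), 80)
  expect_lt(abs(g$od_radius - 40) / 40, 0.03)
  expect_lt(sqrt(sum((g$center - c(96, 96))^2)), 3)

  for (b in get_phantoms(3)) {
    gg <- estimate_od_geometry(b$image, b$od_geometry$center,
                               2 * b$od_geometry$radius)
    expect_lt(abs(gg$od_radius - b$od_geometry$radius) /
                b$od_geometry$radius, 0.05)
  }
})

test_that("fovea detection finds the darkest large-scale ring structure", {
  # uniform ring with one dark dot
  n <- 256
  img <- matrix(0.8, n, n)
  od <- list(center = c(128, 40), od_radius = 16)
  img[100, 120] <- 0   # sole dark spot; 85 px from the OD, inside 4-6 ODr
  fv <- detect_fovea(img, od)
  expect_lt(sqrt(sum((fv - c(99, 119))^2)), 0.25 * 16)

  b <- get_phantoms(1)[[1]]
  fv2 <- detect_fovea(b$image, b$od_geometry, b$truth_vessels, b$fov_mask)
  expect_lt(sqrt(sum((fv2 - b$fovea_center)^2)), 0.25 * b$od_geometry$radius)
  tiny <- list(center = c(5000, 5000), od_radius = 100)
  expect_error(detect_fovea(img, tiny), "outside")
})

test_that("inpainting fills vessels with values bounded by their neighbours", {
  set.seed(8)
  img <- matrix(runif(64 * 64, 0.4, 0.6), 64, 64)
  v <- matrix(FALSE, 64, 64); v[30:33, 10:50] <- TRUE
  filled <- inpaint_vessels(img, v)
  expect_identical(filled[!v], img[!v])
  band <- img[26:37, 8:52]
  expect_true(all(filled[v] >= min(band) - 1e-6 &
                    filled[v] <= max(band) + 1e-6))
})

test_that("circular ROI masks have exact geometry and nest in k", {
  m <- circular_roi_mask(list(center = c(10, 10), radius_px = 0.5), c(21, 21))
  expect_equal(sum(m), 1)
  expect_true(m[11, 11])

  big <- circular_roi_mask(list(center = c(150, 150), radius_px = 100),
                           c(301, 301))
  expect_lt(abs(sum(big) - pi * 100^2) / (pi * 100^2), 0.01)

  sp4 <- roi_spec(c(150, 150), 4, 20); sp5 <- roi_spec(c(150, 150), 5, 20)
  sp6 <- roi_spec(c(150, 150), 6, 20)
  m4 <- circular_roi_mask(sp4, c(301, 301))
  m5 <- circular_roi_mask(sp5, c(301, 301))
  m6 <- circular_roi_mask(sp6, c(301, 301))
  expect_true(all(m4 <= m5) && all(m5 <= m6))
  expect_lt(abs(sum(m5) / sum(m4) - (5 / 4)^2), 0.02)
  expect_equal(sp5$radius_px, 100)
})
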