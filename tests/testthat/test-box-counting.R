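test_that("box schedules follow the geometric progression and its limits", {
  expect_equal(build_box_schedule(512), c(2L, 4L, 8L, 16L, 32L, 64L, 128L))
  expect_error(build_box_schedule(12), "feasible box sizes")
  cfg <- box_schedule_config(min_box_px = 3, base = 3, max_box_fraction = 0.5)
  s <- build_box_schedule(200, cfg)
  expect_true(all(diff(s) > 0))
  expect_true(all(s <= 100))
  expect_error(box_schedule_config(min_box_px = 1), ">= 2")
  expect_error(box_schedule_config(max_box_fraction = 0), "in \\(0, 1\\]")
})

test_that("scan statistics are exact on complete tilings and single pixels", {
  sq <- matrix(TRUE, 64, 64)
  sc <- box_counting_scan(sq, sizes = c(2, 4, 8, 16))
  expect_equal(sc$N, (64 / c(2, 4, 8, 16))^2)
  expect_equal(sc$H, log(sc$N))              # uniform mass
  expect_equal(sc$C, 1 / sc$N)

  px <- matrix(FALSE, 64, 64); px[10, 20] <- TRUE
  sc1 <- box_counting_scan(px, sizes = c(2, 4, 8, 16))
  expect_equal(sc1$N, rep(1, 4))
  expect_equal(sc1$H, rep(0, 4))
  expect_equal(sc1$C, rep(1, 4))
})

test_that("scan invariants hold on generated vessel maps", {
  for (b in get_phantoms(3)) {
    sc <- box_counting_scan(b$truth_vessels, roi5(b))
    expect_true(all(diff(sc$N) <= 0))              # N non-increasing in r
    expect_true(all(sc$H >= -1e-12 & sc$H <= log(sc$N) + 1e-12))
    expect_true(all(sc$C >= 1 / sc$N - 1e-12 & sc$C <= 1 + 1e-12))
  }
  expect_error(box_counting_scan(matrix(FALSE, 32, 32)), "no vessel pixels")
})

test_that("slope estimators are exact on exactly scaling counts", {
  sq <- matrix(TRUE, 64, 64)
  sc <- box_counting_scan(sq, sizes = c(2, 4, 8, 16))
  est <- estimate_dimension(sc, "box")
  expect_equal(est$D, 2, tolerance = 1e-12)
  expect_equal(est$r_squared, 1, tolerance = 1e-12)

  s <- make_analytic_fractal("sierpinski_triangle", depth = 7, grid_size = 128)
  fd <- compute_fd(s)
  expect_lt(abs(fd$D_B - log(3) / log(2)), 1e-9)
  expect_equal(fd$diagnostics$box$r_squared, 1, tolerance = 1e-9)
  # uniform-mass construction: entropy equals log N at every scale, so the
  # information dimension is algebraically identical to the box dimension
  expect_lt(abs(fd$D_I - fd$D_B), 1e-12)
  expect_lt(abs(fd$D_C - fd$D_B), 1e-12)
})

test_that("compute_fd recovers analytic dimensions of simple geometry", {
  ln <- make_analytic_fractal("line", grid_size = 256)
  expect_lt(abs(compute_fd(ln)$D_B - 1), 0.05)
  disc <- fundusfd:::disc_mask(512, 512, c(256, 256), 240)
  fd <- compute_fd(disc, disc)
  expect_true(fd$D_B > 1.9 && fd$D_B <= 2.0)
  expect_true(fd$D_I > 1.9 && fd$D_I <= 2.0)
  expect_true(fd$D_C > 1.9 && fd$D_C <= 2.0)
})

test_that("translation changes D_B little when offsets are averaged", {
  s <- make_analytic_fractal("sierpinski_triangle", depth = 6, grid_size = 64)
  big <- matrix(FALSE, 96, 96)
  big[10 + 1:64, 10 + 1:64] <- s
  shifted <- fundusfd:::shift_matrix(big, 1, 1)
  cfg <- box_schedule_config(offset_averaging = TRUE)
  d0 <- compute_fd(big, cfg = cfg)$D_B
  d1 <- compute_fd(shifted, cfg = cfg)$D_B
  expect_lt(abs(d0 - d1), 0.03)
})

test_that("degenerate regressions are rejected", {
  sq <- matrix(TRUE, 64, 64)
  sc <- box_counting_scan(sq, sizes = c(2, 4, 8, 16))
  expect_error(estimate_dimension(sc[1:3, ], "box"), ">= 4 scales")
})

test_that("skeletonization reduces thick strokes to unit width", {
  m <- matrix(FALSE, 48, 48); m[20:26, 5:44] <- TRUE
  sk <- fundusfd:::thin_mask(m)
  expect_true(all(sk <= m))
  expect_lt(sum(sk), 0.25 * sum(m))
  expect_gt(sum(sk), 30)
})
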