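test_that("observer emulation removes thin strokes and keeps thick ones", {
  m <- matrix(FALSE, 64, 64)
  m[10, 5:60] <- TRUE          # 1 px stroke
  m[30:34, 5:60] <- TRUE       # 5 px stroke
  expect_identical(emulate_observer(m, 0), m)
  o <- emulate_observer(m, 3)
  expect_equal(sum(o[10, ]), 0)
  expect_equal(sum(o[30:34, 5:60]), 5 * 56)
})

test_that("observer emulation is anti-extensive and monotone in caliber", {
  b <- get_phantoms(1)[[1]]
  o2 <- emulate_observer(b$truth_vessels, 2)
  o4 <- emulate_observer(b$truth_vessels, 4)
  expect_true(all(o2 <= b$truth_vessels))
  expect_true(all(o4 <= o2))
  expect_error(emulate_observer(b$truth_vessels, -1), ">= 0")
})

test_that("missing the thinnest vessels lowers the box dimension", {
  b <- get_phantoms(1)[[1]]
  roi <- roi5(b)
  d_full <- compute_fd(b$truth_vessels, roi)$D_B
  d_obs <- compute_fd(emulate_observer(b$truth_vessels, 2), roi)$D_B
  expect_lt(d_obs, d_full)
})

test_that("probability map rendering honours its degenerate and seeded cases", {
  b <- get_phantoms(1)[[1]]
  expect_identical(render_probability_map(b$truth_vessels, 0, 0),
                   b$truth_vessels * 1)
  p1 <- render_probability_map(b$truth_vessels, 1.5, 0.05, seed = 7)
  p2 <- render_probability_map(b$truth_vessels, 1.5, 0.05, seed = 7)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 1))
  # blur at 1.5 px drops sub-pixel twigs below the 0.5 level, so the score
  # sits below a noise-free rethreshold but stays high
  q <- segmentation_quality(threshold_map(p1, 0.5), b$truth_vessels)
  expect_gt(q$MCC, 0.8)
  q0 <- segmentation_quality(threshold_map(
    render_probability_map(b$truth_vessels, 0.8, 0.02, seed = 7), 0.5),
    b$truth_vessels)
  expect_gt(q0$MCC, 0.9)
})

test_that("a neutral camera profile is the identity", {
  b <- get_phantoms(1)[[1]]
  bb <- emulate_camera(b, camera_profile("neutral"), 1)
  expect_identical(bb$image, b$image)
  expect_identical(bb$truth_vessels, b$truth_vessels)
  expect_equal(bb$od_geometry$radius, b$od_geometry$radius)
})

test_that("resolution scaling halves rasters and geometry together", {
  b <- get_phantoms(1)[[1]]
  bh <- emulate_camera(b, camera_profile("half", resolution_scale = 0.5), 1)
  expect_equal(dim(bh$truth_vessels), dim(b$truth_vessels) / 2)
  expect_equal(bh$od_geometry$radius, b$od_geometry$radius / 2)
  expect_equal(bh$fovea_center, b$fovea_center / 2)
  expect_error(camera_profile("bad", resolution_scale = 0), "\\(0, 2\\]")
})

test_that("acquisition jitter gives distinct but seeded small translations", {
  b <- get_phantoms(1)[[1]]
  pr <- camera_profile("jit", acquisition_jitter_px = 2)
  acqs <- lapply(1:5, function(i) emulate_camera(b, pr, i))
  imgs <- lapply(acqs, `[[`, "image")
  expect_gt(length(unique(lapply(imgs, function(x) x[, , 2]))), 1)
  for (a in acqs) {
    expect_true(all(abs(a$camera$jitter) <= 2))
    # truth differs from the original only by that translation
    back <- fundusfd:::shift_matrix(a$truth_vessels, -a$camera$jitter[1],
                                    -a$camera$jitter[2], FALSE)
    inner <- matrix(FALSE, 512, 512); inner[5:508, 5:508] <- TRUE
    expect_identical(back[inner], b$truth_vessels[inner])
  }
  expect_identical(emulate_camera(b, pr, 3)$image, acqs[[3]]$image)
  expect_error(emulate_camera(b, pr, 0), ">= 1")
})
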