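# Studies run here at reduced size (tiny_config); the full-scale runs live
# in the analysis scripts and the acceptance checks.

test_that("unknown study ids and config merging are handled", {
  expect_error(run_study(7), "unknown study_id")
  cfg <- fundusfd:::merge_config(study_config(),
                                 list(phantom = list(image_size = 256L)))
  expect_equal(cfg$phantom$image_size, 256L)
  expect_equal(cfg$study2$n_phantoms, 20L)   # untouched defaults survive
})

test_that("study 1 reports group dispersion and pairwise comparisons", {
  rep <- run_study(1, tiny_config(), seed = 3)
  gd <- rep$statistics$group_dispersion
  expect_equal(nrow(gd), 4)
  expect_true(all(gd$rsd_fov > 0))
  expect_equal(nrow(rep$tests$anova_fov), choose(4, 2))
  expect_true(all(rep$tests$anova_fov$p_value >= 0 &
                    rep$tests$anova_fov$p_value <= 1))
})

test_that("study 2 with a zero-caliber observer has exactly zero errors", {
  cfg <- tiny_config()
  cfg$study2$min_caliber_px <- 0
  rep <- run_study(2, cfg, seed = 3)
  expect_equal(rep$statistics$relative_error$max_re, rep(0, 3))
  expect_equal(rep$condition_table$D_B, rep$condition_table$D_B_obs)
})

test_that("study 2 observer errors are positive at caliber 2", {
  rep <- run_study(2, tiny_config(), seed = 3)
  re <- rep$statistics$relative_error
  expect_true(all(re$mean_re > 0))
  expect_true(all(re$max_re >= re$mean_re))
  expect_true(all(vapply(rep$tests, function(t) t$r, numeric(1)) > 0))
})

test_that("study 3 selects one dataset threshold per parameterization", {
  rep <- run_study(3, tiny_config(), seed = 3)
  tab <- rep$condition_table
  expect_equal(sort(unique(tab$method)),
               sort(names(study_config()$study3$methods)))
  expect_true(all(tab$t_opt > 0 & tab$t_opt < 1))
  expect_equal(length(unique(tab$t_opt[tab$method == tab$method[1]])), 1)
})

test_that("study 4 reports per-ROI dimensions and their association", {
  rep <- run_study(4, tiny_config(), seed = 3)
  expect_true(all(c("D_B_k4", "D_B_k5", "D_B_k6") %in%
                    names(rep$condition_table)))
  expect_equal(rep$statistics$relative_error$reference_k, c(6, 6))
  expect_true(all(vapply(rep$tests, function(t) t$p_value, numeric(1)) < 1))
})

test_that("study 5 reproduces the quality-vs-error trade-off", {
  rep <- run_study(5, list(phantom = list(image_size = 512L, od_radius = 40),
                           study5 = list(n_phantoms = 1L)), seed = 1)
  agg <- rep$statistics$sweep
  expect_equal(nrow(agg), 21)
  best <- which.max(agg$mean_mcc)
  # the paper-grade pattern: error at the MCC-optimal threshold is smaller
  # than at both sweep ends, and quality anticorrelates with error
  expect_lt(agg$mean_re[best], agg$mean_re[1] + 1e-12)
  expect_lt(agg$mean_re[best], agg$mean_re[21])
  expect_lt(rep$tests$spearman_mcc_re, 0)
})

test_that("study 6 repeatability is zero for a noiseless, jitter-free camera", {
  cfg <- tiny_config()
  cfg$study6 <- list(
    n_subjects = 2L, n_acquisitions = 2L,
    profiles = list(
      fixed = list(resolution_scale = 1, contrast_gain = 1, gamma = 1,
                   noise_sigma = 0, acquisition_jitter_px = 0),
      shaky = list(resolution_scale = 1, contrast_gain = 1, gamma = 1,
                   noise_sigma = 0.02, acquisition_jitter_px = 2)))
  rep <- run_study(6, cfg, seed = 3)
  rp <- rep$statistics$repeatability
  expect_equal(rp$mean_rsd[rp$camera == "fixed"], 0)
  expect_gt(rp$mean_rsd[rp$camera == "shaky"], 0)
})

test_that("reports serialize to CSV and JSON", {
  dir <- withr::local_tempdir()
  rep <- run_study(4, tiny_config(), seed = 3)
  paths <- write_report(rep, dir)
  expect_true(all(file.exists(paths)))
  back <- utils::read.csv(paths[["csv"]])
  expect_equal(back$D_B_k5, rep$condition_table$D_B_k5, tolerance = 1e-12)
  js <- jsonlite::read_json(paths[["json"]])
  expect_equal(js$study_id, 4)
  expect_equal(js$seed, 3)
})
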