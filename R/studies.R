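#' Default configuration for the stability studies
#'
#' Desk-scale study sizes: large enough for the directional statistics,
#' small enough to run on one CPU in minutes. Every knob can be overridden
#' by passing a partial list to [run_study()].
#'
#' @param image_size phantom raster side in pixels.
#' @param od_radius phantom optic-disc radius in pixels.
#' @return Nested configuration list.
#' @export
study_config <- function(image_size = 512L, od_radius = image_size / 12.8) {
  list(
    phantom = list(image_size = as.integer(image_size),
                   od_radius = od_radius),
    segment = list(scales = c(1, 2, 4, 8), alpha = 0.5, beta = 15,
                   threshold = 0.25),
    roi = list(k = 5),
    fd = list(min_box_px = 2L, max_box_fraction = 0.25),
    study1 = list(
      n_per_group = 8L,
      groups = list(
        G0 = list(branch_prob = 0.25, min_width_px = 1.2),
        G1 = list(branch_prob = 0.22, min_width_px = 1.2),
        G2 = list(branch_prob = 0.19, min_width_px = 1.4),
        G3 = list(branch_prob = 0.16, min_width_px = 1.6))),
    study2 = list(n_phantoms = 20L, min_caliber_px = 2),
    study3 = list(
      n_phantoms = 8L,
      methods = list(
        frangi_fine = list(scales = c(1, 2, 4), alpha = 0.5, beta = 15),
        frangi_default = list(scales = c(1, 2, 4, 8), alpha = 0.5, beta = 15),
        frangi_smooth = list(scales = c(2, 4, 8), alpha = 1, beta = 8))),
    study4 = list(n_phantoms = 20L, ks = c(4, 5, 6), reference_k = 6),
    study5 = list(n_phantoms = 5L, t_min = 0.15, t_max = 0.35, t_step = 0.01),
    study6 = list(
      n_subjects = 3L, n_acquisitions = 5L,
      profiles = list(
        cam_ref = list(resolution_scale = 1, contrast_gain = 1, gamma = 1,
                       noise_sigma = 0.01, acquisition_jitter_px = 1),
        cam_lowres = list(resolution_scale = 0.7, contrast_gain = 0.9,
                          gamma = 1.1, noise_sigma = 0.02,
                          acquisition_jitter_px = 2),
        cam_contrast = list(resolution_scale = 1, contrast_gain = 1.3,
                            gamma = 0.9, noise_sigma = 0.03,
                            acquisition_jitter_px = 2))))
}

merge_config <- function(base, override) {
  if (is.null(override)) return(base)
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(override[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

study_phantom <- function(cfg, seed, ...) {
  make_vascular_phantom(phantom_spec(
    seed = seed, image_size = cfg$phantom$image_size,
    od_radius = cfg$phantom$od_radius, ...))
}

fd_cfg <- function(cfg) {
  box_schedule_config(min_box_px = cfg$fd$min_box_px,
                      max_box_fraction = cfg$fd$max_box_fraction)
}

# FD of a binary map in the circular ROI at k ODr around the fovea.
phantom_fd <- function(bundle, vessels, k, cfg, anchor = "fovea") {
  center <- if (anchor == "fovea") bundle$fovea_center else
    bundle$od_geometry$center
  roi <- circular_roi_mask(
    roi_spec(center, k, bundle$od_geometry$radius, anchor),
    dim(vessels))
  compute_fd(vessels, roi, cfg = fd_cfg(cfg))
}

# Normalized green channel -> vesselness probability map.
segment_phantom <- function(bundle, cfg, method = NULL) {
  m <- if (is.null(method)) cfg$segment else method
  norm <- normalize_luminosity_contrast(bundle$image[, , 2],
                                        fov_mask = bundle$fov_mask)
  params <- frangi_params(scales = m$scales, alpha = m$alpha, beta = m$beta)
  pm <- frangi_vesselness(norm$image, params)
  pm[!bundle$fov_mask] <- 0
  pm
}

fd3 <- function(fd) c(D_B = fd$D_B, D_I = fd$D_I, D_C = fd$D_C)

#' Run one stability study on synthetic phantoms
#'
#' The six studies probe, in order: (1) inter-/intra-group variation across
#' phantom groups of differing branching complexity; (2) observer
#' disagreement on the thinnest vessels; (3) different segmentation
#' parameterizations against ground truth; (4) the analysis ROI (4, 5, 6
#' ODr around the fovea); (5) the binarization threshold, traded against
#' segmentation quality (MCC); (6) camera differences and
#' repeated-acquisition repeatability. Every number in the report is a
#' deterministic function of `(config, seed)`.
#'
#' @param study_id integer 1..6.
#' @param config partial override of [study_config()].
#' @param seed master seed; all phantom/camera randomness derives from it.
#' @return A `stability_report`: list with `study_id`, `condition_table`
#'   (data frame), `statistics`, `tests`, `config`, `seed`.
#' @export
run_study <- function(study_id, config = NULL, seed = 1L) {
  if (!study_id %in% 1:6) stop("unknown study_id: must be 1..6",
                               call. = FALSE)
  cfg <- merge_config(study_config(), config)
  res <- switch(study_id,
                study1(cfg, seed), study2(cfg, seed), study3(cfg, seed),
                study4(cfg, seed), study5(cfg, seed), study6(cfg, seed))
  structure(c(list(study_id = study_id, seed = seed), res,
              list(config = cfg)),
            class = "stability_report")
}

study1 <- function(cfg, seed) {
  s1 <- cfg$study1
  rows <- list()
  for (g in names(s1$groups)) {
    pars <- s1$groups[[g]]
    for (i in seq_len(s1$n_per_group)) {
      b <- study_phantom(cfg, derive_seed(seed, paste0("s1_", g, "_", i)),
                         branch_prob = pars$branch_prob,
                         min_width_px = pars$min_width_px)
      fd_fov <- compute_fd(b$truth_vessels, b$fov_mask, cfg = fd_cfg(cfg))
      fd_roi <- phantom_fd(b, b$truth_vessels, cfg$roi$k, cfg)
      rows[[length(rows) + 1]] <- data.frame(
        group = g, phantom = i,
        D_B_fov = fd_fov$D_B, D_B_roi = fd_roi$D_B)
    }
  }
  tab <- do.call(rbind, rows)
  grp_stats <- do.call(rbind, lapply(split(tab, tab$group), function(d) {
    data.frame(group = d$group[1], n = nrow(d),
               mean_fov = mean(d$D_B_fov), sd_fov = stats::sd(d$D_B_fov),
               rsd_fov = rsd(d$D_B_fov),
               mean_roi = mean(d$D_B_roi), sd_roi = stats::sd(d$D_B_roi),
               rsd_roi = rsd(d$D_B_roi))
  }))
  rownames(grp_stats) <- NULL
  tests <- list(
    anova_fov = pairwise_anova(split(tab$D_B_fov, tab$group)),
    anova_roi = pairwise_anova(split(tab$D_B_roi, tab$group)))
  list(condition_table = tab,
       statistics = list(group_dispersion = grp_stats), tests = tests)
}

study2 <- function(cfg, seed) {
  s2 <- cfg$study2
  rows <- lapply(seq_len(s2$n_phantoms), function(i) {
    b <- study_phantom(cfg, derive_seed(seed, paste0("s2_", i)))
    obs <- emulate_observer(b$truth_vessels, s2$min_caliber_px)
    ref <- phantom_fd(b, b$truth_vessels, cfg$roi$k, cfg)
    alt <- phantom_fd(b, obs, cfg$roi$k, cfg)
    data.frame(phantom = i, t(fd3(ref)), t(setNames(fd3(alt),
               c("D_B_obs", "D_I_obs", "D_C_obs"))))
  })
  tab <- do.call(rbind, rows)
  dims <- c("D_B", "D_I", "D_C")
  stats_ <- do.call(rbind, lapply(dims, function(d) {
    re <- relative_error(tab[[paste0(d, "_obs")]], tab[[d]])
    data.frame(dimension = d, max_re = max(re), mean_re = mean(re))
  }))
  tests <- lapply(setNames(dims, dims), function(d) {
    pearson_test(tab[[d]], tab[[paste0(d, "_obs")]])
  })
  list(condition_table = tab,
       statistics = list(relative_error = stats_), tests = tests)
}

study3 <- function(cfg, seed) {
  s3 <- cfg$study3
  bundles <- lapply(seq_len(s3$n_phantoms), function(i)
    study_phantom(cfg, derive_seed(seed, paste0("s3_", i))))
  ref <- t(vapply(bundles, function(b)
    fd3(phantom_fd(b, b$truth_vessels, cfg$roi$k, cfg)), numeric(3)))
  rows <- list(); stats_ <- list(); tests <- list()
  for (mname in names(s3$methods)) {
    maps <- lapply(bundles, segment_phantom, cfg = cfg,
                   method = s3$methods[[mname]])
    # dataset-optimal threshold: maximize mean MCC over all phantoms
    ts <- seq(0.15, 0.6, by = 0.05)
    mean_mcc <- vapply(ts, function(t) {
      mean(mapply(function(m, b) {
        segmentation_quality(threshold_map(m, t), b$truth_vessels,
                             b$fov_mask)$MCC
      }, maps, bundles))
    }, numeric(1))
    t_opt <- ts[which.max(mean_mcc)]
    fds <- t(mapply(function(m, b)
      fd3(phantom_fd(b, threshold_map(m, t_opt) & b$fov_mask,
                     cfg$roi$k, cfg)), maps, bundles))
    rows[[mname]] <- data.frame(method = mname,
                                phantom = seq_len(s3$n_phantoms),
                                t_opt = t_opt, fds,
                                D_B_ref = ref[, "D_B"])
    re <- abs(fds - ref) / ref
    stats_[[mname]] <- data.frame(
      method = mname, t_opt = t_opt,
      max_re_db = max(re[, "D_B"]), mean_re_db = mean(re[, "D_B"]),
      max_re_di = max(re[, "D_I"]), mean_re_di = mean(re[, "D_I"]),
      max_re_dc = max(re[, "D_C"]), mean_re_dc = mean(re[, "D_C"]))
    tests[[mname]] <- pearson_test(ref[, "D_B"], fds[, "D_B"])
  }
  list(condition_table = do.call(rbind, rows),
       statistics = list(relative_error = do.call(rbind, stats_)),
       tests = tests)
}

study4 <- function(cfg, seed) {
  s4 <- cfg$study4
  rows <- lapply(seq_len(s4$n_phantoms), function(i) {
    b <- study_phantom(cfg, derive_seed(seed, paste0("s4_", i)))
    vals <- vapply(s4$ks, function(k)
      phantom_fd(b, b$truth_vessels, k, cfg)$D_B, numeric(1))
    stats::setNames(data.frame(i, t(vals)),
                    c("phantom", paste0("D_B_k", s4$ks)))
  })
  tab <- do.call(rbind, rows)
  ref_col <- paste0("D_B_k", s4$reference_k)
  others <- setdiff(s4$ks, s4$reference_k)
  stats_ <- do.call(rbind, lapply(others, function(k) {
    re <- relative_error(tab[[paste0("D_B_k", k)]], tab[[ref_col]])
    data.frame(k = k, reference_k = s4$reference_k,
               max_re = max(re), mean_re = mean(re))
  }))
  tests <- lapply(stats::setNames(others, paste0("k", others)), function(k)
    pearson_test(tab[[paste0("D_B_k", k)]], tab[[ref_col]]))
  means <- colMeans(tab[, paste0("D_B_k", s4$ks)])
  list(condition_table = tab,
       statistics = list(relative_error = stats_, roi_means = means),
       tests = tests)
}

study5 <- function(cfg, seed) {
  s5 <- cfg$study5
  per_t <- NULL
  for (i in seq_len(s5$n_phantoms)) {
    b <- study_phantom(cfg, derive_seed(seed, paste0("s5_", i)))
    pm <- segment_phantom(b, cfg)
    ref <- phantom_fd(b, b$truth_vessels, cfg$roi$k, cfg)$D_B
    sw <- threshold_sweep(pm, b$truth_vessels, b$fov_mask,
                          s5$t_min, s5$t_max, s5$t_step)
    sw$D_B <- vapply(sw$t, function(t)
      phantom_fd(b, threshold_map(pm, t) & b$fov_mask, cfg$roi$k, cfg)$D_B,
      numeric(1))
    sw$re <- relative_error(sw$D_B, ref)
    sw$phantom <- i
    per_t <- rbind(per_t, sw)
  }
  agg <- do.call(rbind, lapply(split(per_t, per_t$t), function(d)
    data.frame(t = d$t[1], mean_mcc = mean(d$MCC), mean_re = mean(d$re),
               mean_db = mean(d$D_B))))
  rownames(agg) <- NULL
  t_best <- agg$t[which.max(agg$mean_mcc)]
  tests <- list(spearman_mcc_re = stats::cor(agg$mean_mcc, agg$mean_re,
                                             method = "spearman"),
                t_argmax_mcc = t_best,
                re_at_argmax = agg$mean_re[agg$t == t_best],
                min_re = min(agg$mean_re))
  list(condition_table = per_t, statistics = list(sweep = agg),
       tests = tests)
}

study6 <- function(cfg, seed) {
  s6 <- cfg$study6
  rows <- list()
  half <- cfg$phantom$image_size / 2
  for (subj in seq_len(s6$n_subjects)) {
    # OD-centred acquisition: disc at the FOV centre, fovea 5 ODr temporal
    b <- study_phantom(cfg, derive_seed(seed, paste0("s6_subj", subj)),
                       od_center = c(half, half),
                       fovea_center = c(half, half + 5 * cfg$phantom$od_radius))
    for (cam in names(s6$profiles)) {
      pr <- do.call(camera_profile, c(list(name = cam), s6$profiles[[cam]]))
      for (acq in seq_len(s6$n_acquisitions)) {
        bb <- emulate_camera(b, pr, acq)
        pm <- segment_phantom(bb, cfg)
        vessels <- threshold_map(pm, cfg$segment$threshold) & bb$fov_mask
        fd <- phantom_fd(bb, vessels, 4, cfg, anchor = "od_center")
        rows[[length(rows) + 1]] <- data.frame(
          subject = subj, camera = cam, acquisition = acq, D_B = fd$D_B)
      }
    }
  }
  tab <- do.call(rbind, rows)
  rep_by_cam <- do.call(rbind, lapply(split(tab, tab$camera), function(d) {
    rp <- repeatability(split(d$D_B, d$subject))
    data.frame(camera = d$camera[1], max_rsd = rp$max_rsd,
               mean_rsd = rp$mean_rsd)
  }))
  rownames(rep_by_cam) <- NULL
  cam_means <- vapply(split(tab$D_B, tab$camera), mean, numeric(1))
  cams <- names(cam_means)
  pair_diff <- do.call(rbind, lapply(utils::combn(cams, 2, simplify = FALSE),
    function(p) data.frame(
      camera1 = p[1], camera2 = p[2],
      mean_relative_difference =
        abs(cam_means[[p[1]]] - cam_means[[p[2]]]) /
        mean(c(cam_means[[p[1]]], cam_means[[p[2]]])))))
  list(condition_table = tab,
       statistics = list(repeatability = rep_by_cam,
                         camera_means = cam_means,
                         between_cameras = pair_diff),
       tests = list())
}

#' Write a stability report to CSV + JSON
#'
#' `report.csv` holds the per-condition table; `report.json` the full
#' report (statistics, tests, config, seed). Identical `(config, seed)`
#' produce byte-identical files.
#'
#' @param report a `stability_report` from [run_study()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "stability_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, "report.csv")
  jsn <- file.path(dir, "report.json")
  utils::write.csv(report$condition_table, csv, row.names = FALSE)
  payload <- report
  payload$condition_table <- NULL
  jsonlite::write_json(payload, jsn, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(c(csv = csv, json = jsn))
}
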