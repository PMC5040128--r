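#' Emulate an observer who misses the thinnest vessels
#'
#' Human annotators disagree mostly on the tiniest vessels; this operation
#' removes from a binary vessel map every segment whose local caliber is
#' below `min_caliber_px`. Caliber is defined through the Euclidean
#' distance transform: a vessel pixel's caliber is twice the largest
#' distance-to-background among the vessel pixels whose inscribed disc
#' covers it, and the result is the morphological opening of the map by a
#' disc of radius `min_caliber_px / 2` — the union of all inscribed discs
#' of at least that radius. One- and two-pixel twigs vanish at caliber 2;
#' a 5-px stroke survives caliber 3 intact. The output is always a subset
#' of the input, and larger `min_caliber_px` gives a subset of smaller.
#'
#' @param truth binary vessel map (logical or 0/1 matrix).
#' @param min_caliber_px minimum surviving caliber in pixels (>= 0;
#'   0 and 1 are the identity: every representable vessel is >= 1 px).
#' @return Logical matrix, `output <= truth` pixelwise.
#' @export
emulate_observer <- function(truth, min_caliber_px) {
  stopifnot_binary(truth)
  if (min_caliber_px < 0) stop("`min_caliber_px` must be >= 0", call. = FALSE)
  v <- as_binary(truth)
  r <- min_caliber_px / 2
  if (min_caliber_px <= 1) return(v)   # every representable vessel is >= 1 px
  dt <- EBImage::distmap(v * 1, metric = "euclidean")
  eroded <- dt > r
  if (!any(eroded)) return(matrix(FALSE, nrow(v), ncol(v)))
  dt_back <- EBImage::distmap((!eroded) * 1, metric = "euclidean")
  opened <- dt_back <= r
  opened & v
}

#' Render a soft segmentation from a ground-truth vessel map
#'
#' Emulates the probability maps produced by vessel enhancement filters:
#' the binary truth is Gaussian-blurred (soft edges at thin vessels) and
#' perturbed with Gaussian noise, then clipped to `[0, 1]`.
#'
#' @param truth binary vessel map.
#' @param blur_sigma Gaussian blur in pixels (0 = none).
#' @param noise_sigma Gaussian noise sd (0 = none).
#' @param seed integer; same seed gives an identical map.
#' @return Numeric matrix in `[0, 1]`.
#' @export
render_probability_map <- function(truth, blur_sigma = 1.5,
                                   noise_sigma = 0.05, seed = 1L) {
  stopifnot_binary(truth)
  if (blur_sigma < 0 || noise_sigma < 0) {
    stop("blur and noise sigmas must be >= 0", call. = FALSE)
  }
  p <- as_binary(truth) * 1
  if (blur_sigma > 0) p <- EBImage::gblur(p, sigma = blur_sigma)
  if (noise_sigma > 0) {
    p <- p + with_local_seed(derive_seed(seed, "probmap"),
                             matrix(rnorm(length(p), 0, noise_sigma),
                                    nrow(p), ncol(p)))
  }
  clip01(p)
}

#' Camera profile for acquisition emulation
#'
#' Describes how one fundus camera differs from the reference: spatial
#' resolution, contrast transfer, sensor noise and the small repositioning
#' jitter between repeated acquisitions of the same eye.
#'
#' @param name camera label.
#' @param resolution_scale raster rescale factor, in (0, 2].
#' @param contrast_gain multiplicative contrast about mid-grey (> 0).
#' @param gamma display gamma (> 0).
#' @param noise_sigma additive Gaussian noise sd (>= 0).
#' @param acquisition_jitter_px max translation (pixels) between repeated
#'   acquisitions (>= 0).
#' @return A `camera_profile` list.
#' @export
camera_profile <- function(name, resolution_scale = 1, contrast_gain = 1,
                           gamma = 1, noise_sigma = 0,
                           acquisition_jitter_px = 0) {
  if (resolution_scale <= 0 || resolution_scale > 2) {
    stop("`resolution_scale` must be in (0, 2]", call. = FALSE)
  }
  if (contrast_gain <= 0 || gamma <= 0) {
    stop("`contrast_gain` and `gamma` must be > 0", call. = FALSE)
  }
  if (noise_sigma < 0 || acquisition_jitter_px < 0) {
    stop("noise and jitter must be >= 0", call. = FALSE)
  }
  structure(list(name = name, resolution_scale = resolution_scale,
                 contrast_gain = contrast_gain, gamma = gamma,
                 noise_sigma = noise_sigma,
                 acquisition_jitter_px = acquisition_jitter_px),
            class = "camera_profile")
}

#' Emulate one acquisition of a phantom with a given camera
#'
#' Resamples the bundle's rasters by the profile's resolution scale
#' (bilinear for the image, nearest-neighbour for masks), applies gamma and
#' contrast about mid-grey, adds sensor noise, and translates the whole
#' scene by an integer jitter drawn per `acquisition_index` — so repeated
#' acquisitions of the same subject with the same camera differ the way
#' repeat photographs do. Geometry (OD centre/radius, fovea) is transformed
#' consistently. Deterministic given (bundle seed, profile name,
#' acquisition index).
#'
#' @param bundle a `phantom_bundle` from [make_vascular_phantom()].
#' @param profile a [camera_profile()].
#' @param acquisition_index acquisition number (>= 1); with jitter > 0,
#'   different indices give different translations.
#' @return A `phantom_bundle` with transformed rasters and geometry.
#' @export
emulate_camera <- function(bundle, profile, acquisition_index = 1L) {
  stopifnot(inherits(bundle, "phantom_bundle"),
            inherits(profile, "camera_profile"))
  if (acquisition_index < 1) stop("`acquisition_index` must be >= 1",
                                  call. = FALSE)
  s <- profile$resolution_scale
  n_old <- dim(bundle$truth_vessels)[1]
  n_new <- as.integer(round(n_old * s))
  scale_eff <- n_new / n_old

  resize_img <- function(m) clip01(EBImage::resize(m, w = n_new, h = n_new,
                                                   filter = "bilinear"))
  resize_mask <- function(m) EBImage::resize(m * 1, w = n_new, h = n_new,
                                             filter = "none") > 0.5
  img <- bundle$image
  if (n_new != n_old) {
    img <- array(c(resize_img(img[, , 1]), resize_img(img[, , 2]),
                   resize_img(img[, , 3])), dim = c(n_new, n_new, 3))
    truth <- resize_mask(bundle$truth_vessels)
    fov <- resize_mask(bundle$fov_mask)
  } else {
    truth <- bundle$truth_vessels
    fov <- bundle$fov_mask
  }

  tone <- function(ch) clip01((ch^profile$gamma - 0.5) * profile$contrast_gain + 0.5)
  if (profile$gamma != 1 || profile$contrast_gain != 1) {
    img <- array(apply(img, 3, tone), dim = dim(img))
  }

  acq_seed <- derive_seed(derive_seed(bundle$spec$seed, profile$name),
                          paste0("acq", acquisition_index))
  jit <- c(0L, 0L)
  if (profile$acquisition_jitter_px > 0) {
    jit <- with_local_seed(acq_seed, {
      as.integer(round(runif(2, -profile$acquisition_jitter_px,
                             profile$acquisition_jitter_px)))
    })
  }
  if (any(jit != 0)) {
    img <- array(c(shift_matrix(img[, , 1], jit[1], jit[2], 0.03),
                   shift_matrix(img[, , 2], jit[1], jit[2], 0.03),
                   shift_matrix(img[, , 3], jit[1], jit[2], 0.03)),
                 dim = dim(img))
    truth <- shift_matrix(truth, jit[1], jit[2], FALSE)
    fov <- shift_matrix(fov, jit[1], jit[2], FALSE)
  }
  if (profile$noise_sigma > 0) {
    img <- with_local_seed(derive_seed(acq_seed, "noise"), {
      clip01(img + array(rnorm(length(img), 0, profile$noise_sigma), dim(img)))
    })
  }

  out <- bundle
  out$image <- img
  out$truth_vessels <- truth
  out$fov_mask <- fov
  out$od_geometry <- list(center = bundle$od_geometry$center * scale_eff + jit,
                          radius = bundle$od_geometry$radius * scale_eff)
  out$fovea_center <- bundle$fovea_center * scale_eff + jit
  out$camera <- list(profile = profile, acquisition_index = acquisition_index,
                     jitter = jit)
  out
}
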