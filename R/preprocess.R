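#' Rescale an image or mask to a reference pixel pitch
#'
#' Brings rasters from different cameras to a common pixel size before
#' segmentation and measurement. Intensities are resampled bilinearly,
#' masks with nearest-neighbour.
#'
#' @param image 2-D matrix (intensity or binary mask).
#' @param current_pitch,target_pitch pixel pitch of the input and desired
#'   output, in any common unit (e.g. pixels per optic-disc radius); both
#'   must be > 0. The output size is `input_size * current / target`.
#' @param mask if `TRUE`, nearest-neighbour resampling and a logical result.
#' @return Resampled matrix.
#' @export
rescale_to_reference <- function(image, current_pitch, target_pitch,
                                 mask = FALSE) {
  if (current_pitch <= 0 || target_pitch <= 0) {
    stop("pitches must be > 0", call. = FALSE)
  }
  ratio <- current_pitch / target_pitch
  if (ratio == 1) return(image)
  w <- max(1L, as.integer(round(nrow(image) * ratio)))
  h <- max(1L, as.integer(round(ncol(image) * ratio)))
  if (mask || is.logical(image)) {
    EBImage::resize(image * 1, w = w, h = h, filter = "none") > 0.5
  } else {
    EBImage::resize(image, w = w, h = h, filter = "bilinear")
  }
}

#' Normalize local luminosity and contrast
#'
#' Fundus images are non-uniformly illuminated; vessel filters and
#' threshold choices only transfer between images after the slowly varying
#' background luminosity and contrast are divided out. The background
#' model is estimated from tentative background pixels (pixels below the
#' 90th percentile of a coarse vesselness response, so vessels do not bias
#' it): block-wise local median (luminosity) and scaled median absolute
#' deviation (contrast) on a grid of `window_px` windows, interpolated
#' smoothly to full resolution. The normalized image is
#' `(I - L) / max(C, epsilon)`.
#'
#' @param image 2-D numeric matrix (green channel or luminance).
#' @param window_px estimation window (>= 8); default one eighth of the
#'   image width.
#' @param epsilon contrast floor (> 0) guarding flat regions.
#' @param fov_mask optional logical matrix; pixels outside are ignored in
#'   the background fit and zeroed in the output.
#' @return List: `image` (normalized matrix), `model` (list with `L`, `C`
#'   rasters, `window_px`, `epsilon`, `degenerate` flag). A constant image
#'   returns all zeros with `degenerate = TRUE`.
#' @export
normalize_luminosity_contrast <- function(image, window_px = NULL,
                                          epsilon = 1e-3, fov_mask = NULL) {
  stopifnot(is.matrix(image), is.numeric(image))
  if (epsilon <= 0) stop("`epsilon` must be > 0", call. = FALSE)
  if (is.null(window_px)) window_px <- max(8L, nrow(image) %/% 8L)
  if (window_px < 8) stop("`window_px` must be >= 8", call. = FALSE)
  n <- nrow(image); m <- ncol(image)
  if (is.null(fov_mask)) fov_mask <- matrix(TRUE, n, m)

  rng <- range(image[fov_mask])
  if (diff(rng) == 0) {
    model <- list(L = matrix(rng[1], n, m), C = matrix(0, n, m),
                  window_px = window_px, epsilon = epsilon, degenerate = TRUE)
    return(list(image = matrix(0, n, m), model = model))
  }

  # tentative background: low coarse-vesselness pixels inside the FOV
  vness <- coarse_vesselness(image)
  thr <- stats::quantile(vness[fov_mask], 0.9)
  bg <- fov_mask & (vness <= thr)

  # block grid of robust local statistics over background pixels
  nb <- max(2L, ceiling(n / window_px))
  mb <- max(2L, ceiling(m / window_px))
  Lg <- matrix(NA_real_, nb, mb)
  Cg <- matrix(NA_real_, nb, mb)
  ri <- pmin(((seq_len(n) - 1L) %/% window_px) + 1L, nb)
  ci <- pmin(((seq_len(m) - 1L) %/% window_px) + 1L, mb)
  for (i in seq_len(nb)) {
    rows <- which(ri == i)
    for (j in seq_len(mb)) {
      cols <- which(ci == j)
      vals <- image[rows, cols][bg[rows, cols]]
      if (length(vals) >= 20) {
        Lg[i, j] <- stats::median(vals)
        Cg[i, j] <- stats::mad(vals)   # MAD * 1.4826
      }
    }
  }
  Lg <- fill_na_neighbors(Lg, fallback = stats::median(image[bg]))
  Cg <- fill_na_neighbors(Cg, fallback = stats::mad(image[bg]))

  L <- EBImage::resize(Lg, w = n, h = m, filter = "bilinear")
  C <- EBImage::resize(Cg, w = n, h = m, filter = "bilinear")
  C <- pmax(C, 0)
  out <- (image - L) / pmax(C, epsilon)
  out[!fov_mask] <- 0
  model <- list(L = L, C = C, window_px = window_px, epsilon = epsilon,
                degenerate = FALSE)
  list(image = out, model = model)
}

# Single coarse scale of the ridge filter, used only to exclude probable
# vessels from the background fit.
coarse_vesselness <- function(image) {
  sigma <- max(2, nrow(image) / 256)
  ef <- hessian_eigen(image, sigma)
  ef$lambda1
}

# Replace NA grid cells by the mean of their available 8-neighbours,
# iterating outward; isolated grids fall back to a global value.
fill_na_neighbors <- function(g, fallback) {
  if (!anyNA(g)) return(g)
  for (iter in 1:(nrow(g) + ncol(g))) {
    nas <- which(is.na(g), arr.ind = TRUE)
    if (nrow(nas) == 0) break
    for (k in seq_len(nrow(nas))) {
      i <- nas[k, 1]; j <- nas[k, 2]
      nb <- g[max(1, i - 1):min(nrow(g), i + 1),
              max(1, j - 1):min(ncol(g), j + 1)]
      if (any(!is.na(nb))) g[i, j] <- mean(nb, na.rm = TRUE)
    }
  }
  g[is.na(g)] <- fallback
  g
}
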