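#' Hessian eigen-decomposition of an image at one Gaussian scale
#'
#' Second-order Gaussian derivatives (computed by separable convolution,
#' replicate boundary) with gamma-normalization (derivatives multiplied by
#' `sigma^2`) so ridge responses are comparable across scales. At every
#' pixel the 2x2 Hessian is decomposed into eigenvalue magnitudes ordered
#' `lambda1 >= lambda2 >= 0`, plus the sign of the dominant eigenvalue:
#' positive across a dark ridge on a bright background.
#'
#' @param image 2-D numeric matrix.
#' @param sigma Gaussian scale in pixels (>= 0.5; smaller is unresolvable).
#' @return List: `lambda1`, `lambda2` (magnitudes), `sign1` (sign of the
#'   dominant curvature), `sigma`.
#' @export
hessian_eigen <- function(image, sigma) {
  stopifnot(is.matrix(image), is.numeric(image))
  if (sigma < 0.5) {
    stop("`sigma` must be >= 0.5 px: finer scales are unresolvable",
         call. = FALSE)
  }
  # truncate the kernel to the raster if needed; zero the DC component of
  # the second-derivative tap so constants map to an exactly zero Hessian
  half <- max(1L, min(ceiling(4 * sigma),
                      (min(dim(image)) - 1L) %/% 2L))
  x <- seq(-half, half)
  g <- exp(-x^2 / (2 * sigma^2)); g <- g / sum(g)
  g2 <- (x^2 - sigma^2) / sigma^4 * g
  g2 <- g2 - sum(g2) / length(g2)
  g1 <- -x / sigma^2 * g

  conv <- function(img, kr, kc) {
    k <- outer(kr, kc)
    EBImage::filter2(img, k, boundary = "replicate")
  }
  s2 <- sigma^2                      # gamma-normalization, gamma = 2
  Hrr <- conv(image, g2, g) * s2
  Hcc <- conv(image, g, g2) * s2
  Hrc <- conv(image, g1, g1) * s2

  tr <- Hrr + Hcc
  disc <- sqrt(pmax((Hrr - Hcc)^2 / 4 + Hrc^2, 0))
  mu1 <- tr / 2 + disc               # algebraically larger
  mu2 <- tr / 2 - disc
  swap <- abs(mu2) > abs(mu1)
  dom <- ifelse(swap, mu2, mu1)
  sub <- ifelse(swap, mu1, mu2)
  list(lambda1 = abs(dom), lambda2 = abs(sub),
       sign1 = sign(dom), sigma = sigma)
}

#' Parameters of the multiscale vesselness filter
#'
#' @param scales Gaussian sigmas in pixels, strictly increasing. The
#'   default `{1, 2, 4, 8}` spans twig-to-trunk calibers at the reference
#'   pitch.
#' @param alpha sharpness of the anisotropy term (> 0).
#' @param beta sharpness of the structure (contrast) term (> 0), on
#'   normalized intensities.
#' @param polarity `"dark_vessels"` (fundus photographs: vessels dark on a
#'   bright background) or `"bright_vessels"`.
#' @param variant `"printed"` uses the structure term `S = lambda1 +
#'   lambda2` (sum of curvature magnitudes); `"original"` uses the
#'   Frobenius norm `S = sqrt(lambda1^2 + lambda2^2)` of the classical
#'   formulation.
#' @return A `frangi_params` list.
#' @export
frangi_params <- function(scales = c(1, 2, 4, 8), alpha = 0.5, beta = 15,
                          polarity = c("dark_vessels", "bright_vessels"),
                          variant = c("printed", "original")) {
  polarity <- match.arg(polarity)
  variant <- match.arg(variant)
  if (length(scales) == 0) stop("`scales` must be non-empty", call. = FALSE)
  if (any(diff(scales) <= 0)) {
    stop("`scales` must be strictly increasing", call. = FALSE)
  }
  if (alpha <= 0 || beta <= 0) stop("`alpha`, `beta` must be > 0",
                                    call. = FALSE)
  structure(list(scales = scales, alpha = alpha, beta = beta,
                 polarity = polarity, variant = variant),
            class = "frangi_params")
}

#' Multiscale Hessian vesselness probability map
#'
#' Per scale, the response is
#' `exp(-R_A^2 / (2 alpha^2)) * (1 - exp(-S^2 / (2 beta^2)))`
#' with anisotropy `R_A = lambda2 / lambda1` (0 where `lambda1 = 0`) and
#' structure term `S = lambda1 + lambda2`, gated to zero where the
#' dominant-curvature sign contradicts the requested polarity. The final
#' map is the maximum over scales, rescaled to `[0, 1]` by its own maximum
#' (identically-zero maps stay zero). Apply
#' [normalize_luminosity_contrast()] first so `beta` is comparable across
#' images.
#'
#' @param image 2-D numeric matrix (normalized green channel).
#' @param params a [frangi_params()].
#' @return Numeric matrix in `[0, 1]` with attribute `provenance`.
#' @export
frangi_vesselness <- function(image, params = frangi_params()) {
  stopifnot(inherits(params, "frangi_params"))
  best <- matrix(0, nrow(image), ncol(image))
  want_sign <- if (params$polarity == "dark_vessels") 1 else -1
  for (s in params$scales) {
    ef <- hessian_eigen(image, s)
    ra <- ifelse(ef$lambda1 > 0, ef$lambda2 / pmax(ef$lambda1, .Machine$double.eps), 0)
    S <- if (params$variant == "printed") {
      ef$lambda1 + ef$lambda2
    } else {
      sqrt(ef$lambda1^2 + ef$lambda2^2)
    }
    resp <- exp(-ra^2 / (2 * params$alpha^2)) *
      (1 - exp(-S^2 / (2 * params$beta^2)))
    resp[ef$sign1 != want_sign] <- 0
    best <- pmax(best, resp)
  }
  mx <- max(best)
  if (mx > 0) best <- best / mx
  attr(best, "provenance") <- sprintf(
    "frangi[%s] scales=%s alpha=%g beta=%g %s",
    params$variant, paste(params$scales, collapse = ","),
    params$alpha, params$beta, params$polarity)
  best
}

#' Binarize a probability map at a threshold
#'
#' A pixel is vessel iff its value is `>= t`. No post-processing is
#' applied after thresholding.
#'
#' @param map numeric matrix in `[0, 1]`.
#' @param t threshold in `[0, 1]`.
#' @return Logical matrix.
#' @export
threshold_map <- function(map, t) {
  if (t < 0 || t > 1) stop("`t` must be in [0, 1]", call. = FALSE)
  map >= t
}

#' Score a binary segmentation against truth with MCC
#'
#' Pixel confusion counts restricted to `mask`, and the Matthews
#' correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`,
#' a balanced score usable when vessel and background classes have very
#' different sizes. If any factor of the denominator is zero the MCC is
#' defined as 0 and flagged.
#'
#' @param pred,truth binary matrices of equal shape.
#' @param mask logical matrix of evaluated pixels; `NULL` = all.
#' @param t threshold recorded for provenance (optional).
#' @return List: `TP`, `TN`, `FP`, `FN`, `MCC`, `threshold`, `degenerate`.
#' @export
segmentation_quality <- function(pred, truth, mask = NULL, t = NA_real_) {
  stopifnot_binary(pred); stopifnot_binary(truth)
  stopifnot(identical(dim(pred), dim(truth)))
  p <- as_binary(pred); g <- as_binary(truth)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(p), ncol(p))
  if (!any(mask)) stop("empty evaluation mask", call. = FALSE)
  p <- p[mask]; g <- g[mask]
  TP <- as.numeric(sum(p & g)); TN <- as.numeric(sum(!p & !g))
  FP <- as.numeric(sum(p & !g)); FN <- as.numeric(sum(!p & g))
  den <- sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
  degenerate <- den == 0
  mcc <- if (degenerate) 0 else (TP * TN - FP * FN) / den
  list(TP = TP, TN = TN, FP = FP, FN = FN, MCC = mcc, threshold = t,
       degenerate = degenerate)
}

#' Sweep the binarization threshold and score each setting
#'
#' @param map probability map in `[0, 1]`.
#' @param truth binary ground truth.
#' @param mask logical evaluation mask (`NULL` = all pixels).
#' @param t_min,t_max,t_step sweep range and step; the canonical study
#'   sweep is 0.15 to 0.35 in steps of 0.01 (21 settings).
#' @return Data frame with one row per threshold: `t, TP, TN, FP, FN, MCC`.
#' @export
threshold_sweep <- function(map, truth, mask = NULL,
                            t_min = 0.15, t_max = 0.35, t_step = 0.01) {
  if (t_min >= t_max || t_step <= 0) {
    stop("need t_min < t_max and t_step > 0", call. = FALSE)
  }
  ts <- seq(t_min, t_max, by = t_step)
  rows <- lapply(ts, function(t) {
    q <- segmentation_quality(threshold_map(map, t), truth, mask, t = t)
    data.frame(t = t, TP = q$TP, TN = q$TN, FP = q$FP, FN = q$FN, MCC = q$MCC)
  })
  do.call(rbind, rows)
}
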