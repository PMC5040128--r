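#' Gaussian color model transform of an RGB image
#'
#' Best linear transform from RGB to the Gaussian color model: `e`
#' (luminance-like), `e_lambda` (yellow-blue opponent, 1st spectral
#' derivative) and `e_lambda_lambda` (red-green opponent, 2nd spectral
#' derivative). The optic disc carries a much stronger yellow-blue
#' difference than the surrounding retina, which is what the OD enhancement
#' exploits.
#'
#' @param rgb_image `h x w x 3` numeric array.
#' @return List of matrices `e`, `e_lambda`, `e_lambda_lambda`.
#' @export
gaussian_color_transform <- function(rgb_image) {
  if (length(dim(rgb_image)) != 3 || dim(rgb_image)[3] != 3) {
    stop("`rgb_image` must be a 3-channel array", call. = FALSE)
  }
  M <- gaussian_color_matrix()
  R <- rgb_image[, , 1]; G <- rgb_image[, , 2]; B <- rgb_image[, , 3]
  list(e = M[1, 1] * R + M[1, 2] * G + M[1, 3] * B,
       e_lambda = M[2, 1] * R + M[2, 2] * G + M[2, 3] * B,
       e_lambda_lambda = M[3, 1] * R + M[3, 2] * G + M[3, 3] * B)
}

#' @rdname gaussian_color_transform
#' @export
gaussian_color_matrix <- function() {
  matrix(c(0.06, 0.63, 0.31,
           0.19, 0.18, -0.37,
           0.22, -0.44, 0.06),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("e", "e_lambda", "e_lambda_lambda"),
                         c("R", "G", "B")))
}

#' Direct least-squares ellipse fit
#'
#' Fits a conic constrained to be an ellipse (Fitzgibbon's direct method in
#' the numerically stable Halir-Flusser form) to boundary points, and
#' converts it to centre / semi-axes form.
#'
#' @param points two-column matrix of `(row, col)` coordinates (>= 6 rows).
#' @return List: `center` (row, col), `major_radius`, `minor_radius`,
#'   `residual` (RMS algebraic distance on normalized coefficients).
#' @export
fit_ellipse <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 6) {
    stop("ellipse fit under-determined: need >= 6 boundary points",
         call. = FALSE)
  }
  x <- points[, 1] - mean(points[, 1])   # centre for conditioning
  y <- points[, 2] - mean(points[, 2])
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)), error = function(e) NULL)
  if (is.null(Tm)) stop("degenerate point configuration", call. = FALSE)
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  V <- Re(ev$vectors)
  cond <- 4 * V[1, ] * V[3, ] - V[2, ]^2
  ok <- which(cond > 0)
  if (length(ok) == 0) stop("no ellipse solution for these points",
                            call. = FALSE)
  a1 <- V[, ok[1]]
  coef <- c(a1, Tm %*% a1)   # A B C D E F on centred coordinates
  A <- coef[1]; B <- coef[2]; C <- coef[3]
  D <- coef[4]; E <- coef[5]; Fc <- coef[6]

  den <- 4 * A * C - B^2
  xc <- (B * E - 2 * C * D) / den
  yc <- (B * D - 2 * A * E) / den
  F0 <- A * xc^2 + B * xc * yc + C * yc^2 + D * xc + E * yc + Fc
  M0 <- matrix(c(A, B / 2, B / 2, C), 2, 2) / (-F0)
  lam <- eigen(M0, symmetric = TRUE)$values
  if (any(lam <= 0)) stop("degenerate conic (not an ellipse)", call. = FALSE)
  radii <- sort(1 / sqrt(lam), decreasing = TRUE)
  vals <- cbind(D1, D2) %*% coef
  list(center = c(xc + mean(points[, 1]), yc + mean(points[, 2])),
       major_radius = radii[1], minor_radius = radii[2],
       residual = sqrt(mean(vals^2)) / sqrt(sum(coef^2)))
}

#' Estimate optic-disc geometry from an RGB image
#'
#' Within a patch around an approximate OD centre, builds an OD-enhanced
#' map from the Gaussian color planes
#' (`sqrt(e_lambda^2 + e_lambda_lambda^2) / (e + eps)`, a chromatic
#' contrast normalized against luminance), smooths it, finds the
#' zero-crossings of its Laplacian, keeps the crossings with the strongest
#' gradient support, and fits an ellipse to them. The OD radius is the
#' mean of the fitted major and minor radii.
#'
#' @param rgb_image `h x w x 3` array.
#' @param approx_center `(row, col)` seed near the OD centre (phantoms
#'   carry ground truth; for real images supply a manual seed or a
#'   brightest-region estimate).
#' @param patch_halfwidth half-width of the analysis patch in pixels;
#'   choose it so the whole OD rim lies inside (about 2x the expected
#'   radius).
#' @return An `od_geometry` list: `center` (row, col), `major_radius`,
#'   `minor_radius`, `od_radius` (mean of the two), `fit_residual`,
#'   `n_boundary_points`.
#' @export
estimate_od_geometry <- function(rgb_image, approx_center, patch_halfwidth) {
  d <- dim(rgb_image)
  if (length(d) != 3 || d[3] != 3) {
    stop("`rgb_image` must be a 3-channel array", call. = FALSE)
  }
  r0 <- max(1L, round(approx_center[1] + 1 - patch_halfwidth))
  r1 <- min(d[1], round(approx_center[1] + 1 + patch_halfwidth))
  c0 <- max(1L, round(approx_center[2] + 1 - patch_halfwidth))
  c1 <- min(d[2], round(approx_center[2] + 1 + patch_halfwidth))
  if (r1 - r0 < 8 || c1 - c0 < 8) {
    stop("`approx_center` must lie inside the image", call. = FALSE)
  }
  patch <- rgb_image[r0:r1, c0:c1, , drop = FALSE]
  pl <- gaussian_color_transform(patch)
  enh <- sqrt(pl$e_lambda^2 + pl$e_lambda_lambda^2) / (pl$e + 1e-2)

  sig <- max(2, patch_halfwidth / 15)
  sm <- EBImage::gblur(enh, sigma = sig)
  lap <- EBImage::filter2(sm, matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3),
                          boundary = "replicate")
  gr <- sqrt(((shift_matrix(sm, -1, 0) - shift_matrix(sm, 1, 0)) / 2)^2 +
               ((shift_matrix(sm, 0, -1) - shift_matrix(sm, 0, 1)) / 2)^2)

  zc <- (lap * shift_matrix(lap, -1, 0) < 0) |
    (lap * shift_matrix(lap, 0, -1) < 0)
  # ignore the patch border (boundary effects of the filters)
  zc[c(1:3, nrow(zc) - 0:2), ] <- FALSE
  zc[, c(1:3, ncol(zc) - 0:2)] <- FALSE

  # the rim lies in the outer half of a well-chosen patch; drop crossings
  # right at the seed (vessel cores inside the disc)
  ctr <- c(approx_center[1] + 1 - r0, approx_center[2] + 1 - c0)
  dist <- sqrt(pixel_dist2(nrow(zc), ncol(zc), ctr - 1))
  zc[dist < 0.25 * patch_halfwidth] <- FALSE

  cand <- which(zc, arr.ind = TRUE)
  if (nrow(cand) < 6) stop("fewer than 6 OD boundary points", call. = FALSE)
  strength <- gr[cand]
  # absolute floor guards against numerically flat regions, whose
  # zero-crossings are sign flips of ~1e-16 noise
  keep <- strength >= max(stats::quantile(strength, 0.75),
                          0.1 * max(strength))
  pts <- cand[keep, , drop = FALSE]
  if (nrow(pts) < 6) stop("fewer than 6 OD boundary points", call. = FALSE)

  # robust rim selection: vessel-edge crossings are scattered while the
  # rim clusters at one radius from the seed. Vote for the densest radius
  # (3-px bins), keep points near it, re-centre with a linear circle fit,
  # and iterate before the final ellipse fit.
  seed_ctr <- ctr
  all_pts <- pts
  for (pass in 1:3) {
    dcand <- sqrt((all_pts[, 1] - seed_ctr[1])^2 +
                    (all_pts[, 2] - seed_ctr[2])^2)
    bins <- seq(0, max(dcand) + 3, by = 3)
    counts <- tabulate(findInterval(dcand, bins), nbins = length(bins))
    r_peak <- bins[which.max(counts)] + 1.5
    sel <- abs(dcand - r_peak) <= pmax(4, 0.15 * r_peak)
    if (sum(sel) < 6) break
    pts <- all_pts[sel, , drop = FALSE]
    seed_ctr <- fit_circle_center(pts)
  }

  fit <- fit_ellipse(pts)
  structure(list(center = c(fit$center[1] + r0 - 2, fit$center[2] + c0 - 2),
                 major_radius = fit$major_radius,
                 minor_radius = fit$minor_radius,
                 od_radius = (fit$major_radius + fit$minor_radius) / 2,
                 fit_residual = fit$residual,
                 n_boundary_points = nrow(pts)),
            class = "od_geometry")
}

# Linear least-squares (Kasa) circle fit; returns the centre.
fit_circle_center <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(sol)) colMeans(pts) else sol[1:2]
}

#' Inpaint vessel pixels by neighbourhood diffusion
#'
#' Replaces vessel pixels by iterated averaging of their 4-neighbours
#' (Laplacian diffusion restricted to the vessel set), until relative
#' change falls below `tol` or `max_iter` iterations.
#'
#' @param image 2-D matrix.
#' @param vessels logical matrix of pixels to fill.
#' @param max_iter,tol stopping rule.
#' @return Matrix with vessel pixels replaced by background texture.
#' @export
inpaint_vessels <- function(image, vessels, max_iter = 200L, tol = 1e-4) {
  stopifnot(identical(dim(image), dim(vessels)))
  v <- as_binary(vessels)
  if (!any(v)) return(image)
  out <- image
  out[v] <- mean(image[!v])
  idx <- which(v)
  for (i in seq_len(max_iter)) {
    nb <- (shift_matrix(out, 1, 0, NA) + shift_matrix(out, -1, 0, NA) +
             shift_matrix(out, 0, 1, NA) + shift_matrix(out, 0, -1, NA))
    cnt <- (!is.na(shift_matrix(out, 1, 0, NA))) +
      (!is.na(shift_matrix(out, -1, 0, NA))) +
      (!is.na(shift_matrix(out, 0, 1, NA))) +
      (!is.na(shift_matrix(out, 0, -1, NA)))
    nb[is.na(nb)] <- 0
    upd <- nb[idx] / pmax(cnt[idx], 1)
    delta <- max(abs(upd - out[idx])) / max(abs(out[idx]), 1e-12)
    out[idx] <- upd
    if (delta < tol) break
  }
  out
}

#' Detect the fovea in the ring between 4 and 6 optic-disc radii
#'
#' The fovea is the darkest large-scale structure in the ring centred at
#' the OD centre with inner radius `4 ODr` and outer radius `6 ODr` (the
#' average fovea-to-disc distance is about `5 ODr`). Vessels are first
#' inpainted away, the intensity is blurred at a large Gaussian scale
#' (`0.5 ODr`, resolution-invariant), and the ring's global minimum is
#' returned.
#'
#' @param image 2-D matrix (green channel) or `h x w x 3` array.
#' @param od an `od_geometry` (or `list(center, od_radius)`).
#' @param vessels binary vessel map for inpainting (optional).
#' @param fov_mask logical field-of-view mask; the search ring is
#'   restricted to the FOV eroded by the blur scale, so the dark aperture
#'   border cannot masquerade as the fovea.
#' @return `(row, col)` of the detected fovea centre (0-based).
#' @export
detect_fovea <- function(image, od, vessels = NULL, fov_mask = NULL) {
  if (length(dim(image)) == 3) image <- image[, , 2]
  odr <- if (!is.null(od$od_radius)) od$od_radius else od$radius
  ctr <- od$center
  n <- nrow(image); m <- ncol(image)
  d2 <- pixel_dist2(n, m, ctr)
  ring <- d2 >= (4 * odr)^2 & d2 <= (6 * odr)^2
  if (!is.null(fov_mask)) ring <- ring & fov_mask
  if (!any(ring)) stop("the 4-6 ODr ring lies outside the image",
                       call. = FALSE)
  work <- image
  if (!is.null(vessels)) work <- inpaint_vessels(work, vessels)
  # normalized convolution: blur only FOV evidence, so the dark aperture
  # border does not bleed into the ring
  w <- if (is.null(fov_mask)) matrix(1, n, m) else fov_mask * 1
  sig <- 0.5 * odr
  sm <- EBImage::gblur(work * w, sigma = sig) /
    pmax(EBImage::gblur(w, sigma = sig), 1e-6)
  sm[!ring] <- Inf
  idx <- which.min(sm)
  c((idx - 1) %% n, (idx - 1) %/% n)
}

#' Region-of-interest specification
#'
#' Circular analysis region with radius `k` optic-disc radii, anchored at
#' the fovea (canonical) or the OD centre.
#'
#' @param center `(row, col)` anchor.
#' @param k ROI radius in units of ODr (canonically 4, 5 or 6).
#' @param od_radius ODr in pixels.
#' @param anchor provenance label: `"fovea"` or `"od_center"`.
#' @return An `roi_spec` list with `radius_px = k * od_radius`.
#' @export
roi_spec <- function(center, k, od_radius, anchor = c("fovea", "od_center")) {
  anchor <- match.arg(anchor)
  if (k <= 0 || od_radius <= 0) stop("`k` and `od_radius` must be > 0",
                                     call. = FALSE)
  structure(list(center = center, k = k, od_radius = od_radius,
                 radius_px = k * od_radius, anchor = anchor),
            class = "roi_spec")
}

#' Build a circular ROI mask
#'
#' Pixel set iff its Euclidean distance to the centre is `<= radius_px`;
#' clipped at the image borders.
#'
#' @param spec an [roi_spec()], or any list with `center` and `radius_px`.
#' @param image_shape `c(nrow, ncol)`.
#' @return Logical matrix.
#' @export
circular_roi_mask <- function(spec, image_shape) {
  if (spec$radius_px <= 0) stop("`radius_px` must be > 0", call. = FALSE)
  disc_mask(image_shape[1], image_shape[2], spec$center, spec$radius_px)
}
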