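#' Box schedule configuration
#'
#' Controls the geometric sequence of box side-lengths used by
#' [box_counting_scan()] and where the box grid is anchored.
#'
#' @param min_box_px smallest box side in pixels (>= 2... the default 2 is
#'   the finest scale at which occupancy is meaningful on a binary raster).
#' @param max_box_fraction largest box side as a fraction of the ROI
#'   diameter, in (0, 1]. Default 0.25: boxes larger than a quarter of the
#'   region carry almost no scaling information.
#' @param base geometric progression factor (integer >= 2).
#' @param grid_anchor `"roi_bbox_corner"` (default, deterministic) or
#'   `"roi_center"`.
#' @param offset_averaging if `TRUE`, counts are averaged over the 4 grids
#'   shifted by half a box in each direction, trading determinism of the
#'   grid placement for robustness to translation.
#' @return An object of class `box_schedule_config`.
#' @export
box_schedule_config <- function(min_box_px = 2L, max_box_fraction = 0.25,
                                base = 2L,
                                grid_anchor = c("roi_bbox_corner", "roi_center"),
                                offset_averaging = FALSE) {
  grid_anchor <- match.arg(grid_anchor)
  if (min_box_px < 2) stop("`min_box_px` must be >= 2", call. = FALSE)
  if (max_box_fraction <= 0 || max_box_fraction > 1) {
    stop("`max_box_fraction` must be in (0, 1]", call. = FALSE)
  }
  if (base < 2) stop("`base` must be an integer >= 2", call. = FALSE)
  structure(list(min_box_px = as.integer(min_box_px),
                 max_box_fraction = max_box_fraction,
                 base = as.integer(base),
                 grid_anchor = grid_anchor,
                 offset_averaging = isTRUE(offset_averaging)),
            class = "box_schedule_config")
}

#' Build the sequence of box side-lengths for a region
#'
#' Geometric sequence `min_box_px * base^j` capped at
#' `max_box_fraction * roi_diameter`. At least 4 sizes are required for the
#' log-log regression to be meaningful.
#'
#' @param roi_diameter diameter of the analysis region in pixels (for a
#'   mask, the larger side of its bounding box).
#' @param cfg a [box_schedule_config()].
#' @return Integer vector of strictly increasing box sides.
#' @export
build_box_schedule <- function(roi_diameter, cfg = box_schedule_config()) {
  stopifnot(inherits(cfg, "box_schedule_config"))
  if (roi_diameter < 2 * cfg$min_box_px) {
    stop("ROI diameter must be at least twice the minimum box size",
         call. = FALSE)
  }
  rmax <- cfg$max_box_fraction * roi_diameter
  sizes <- integer(0)
  r <- cfg$min_box_px
  while (r <= rmax) {
    sizes <- c(sizes, as.integer(r))
    r <- r * cfg$base
  }
  if (length(sizes) < 4) {
    stop(sprintf(
      "only %d feasible box sizes in [%d, %.0f]: need >= 4 for a reliable slope",
      length(sizes), cfg$min_box_px, rmax), call. = FALSE)
  }
  sizes
}

#' Box-counting scan of a binary vessel map
#'
#' For each box side `r`, tiles the ROI bounding box with an `r x r` grid
#' and tallies the vessel mass `n_i` falling in each box (restricted to the
#' ROI). From the per-box masses it records the three statistics feeding the
#' generalized-dimension estimators: the occupied-box count `N(r)`, the
#' Shannon entropy `H(r) = -sum p_i log p_i` and the correlation sum
#' `C(r) = sum p_i^2`, with `p_i = n_i / M` and `M` the total vessel mass in
#' the ROI. With `cfg$offset_averaging` the three statistics are averaged
#' over the four half-box-shifted grids.
#'
#' @param vessels binary matrix (vessel = TRUE/1).
#' @param roi_mask logical matrix, same shape; `NULL` means the whole raster.
#' @param sizes integer vector of box sides; default from
#'   [build_box_schedule()] on the ROI bounding box.
#' @param cfg a [box_schedule_config()].
#' @return A `box_counting_scan` object: data frame with columns
#'   `r, N, H, C` plus attributes `M` (mass) and `sizes`.
#' @export
box_counting_scan <- function(vessels, roi_mask = NULL, sizes = NULL,
                              cfg = box_schedule_config()) {
  stopifnot_binary(vessels)
  v <- as_binary(vessels)
  if (is.null(roi_mask)) roi_mask <- matrix(TRUE, nrow(v), ncol(v))
  stopifnot(identical(dim(v), dim(roi_mask)))
  v <- v & roi_mask
  px <- which(v, arr.ind = TRUE)
  if (nrow(px) == 0) {
    stop("no vessel pixels inside the ROI: fractal dimension undefined",
         call. = FALSE)
  }
  roi_px <- which(roi_mask, arr.ind = TRUE)
  r0 <- min(roi_px[, 1]); c0 <- min(roi_px[, 2])
  r1 <- max(roi_px[, 1]); c1 <- max(roi_px[, 2])
  diam <- max(r1 - r0 + 1L, c1 - c0 + 1L)
  if (is.null(sizes)) sizes <- build_box_schedule(diam, cfg)
  stopifnot(all(diff(sizes) > 0))

  M <- nrow(px)
  anchor <- if (cfg$grid_anchor == "roi_bbox_corner") {
    c(r0, c0)
  } else {
    # a box corner sits on the ROI bounding-box centre
    c((r0 + r1) %/% 2L, (c0 + c1) %/% 2L)
  }

  tally <- function(r, off_r, off_c) {
    bi <- (px[, 1] - anchor[1] + off_r) %/% r
    bj <- (px[, 2] - anchor[2] + off_c) %/% r
    # unique box key; ranges are small so this never overflows doubles
    key <- (bi - min(bi)) * (max(bj) - min(bj) + 1) + (bj - min(bj))
    n_i <- as.numeric(table(key))
    p <- n_i / M
    c(N = length(n_i), H = -sum(p * log(p)), C = sum(p^2))
  }

  rows <- lapply(sizes, function(r) {
    if (cfg$offset_averaging) {
      h <- r %/% 2L
      offs <- rbind(c(0L, 0L), c(h, 0L), c(0L, h), c(h, h))
      vals <- apply(offs, 1, function(o) tally(r, o[1], o[2]))
      rowMeans(vals)
    } else {
      tally(r, 0L, 0L)
    }
  })
  scan <- data.frame(r = sizes,
                     N = vapply(rows, `[[`, numeric(1), "N"),
                     H = vapply(rows, `[[`, numeric(1), "H"),
                     C = vapply(rows, `[[`, numeric(1), "C"))
  attr(scan, "M") <- M
  attr(scan, "cfg") <- cfg
  class(scan) <- c("box_counting_scan", class(scan))
  scan
}

#' Estimate one generalized dimension from a box-counting scan
#'
#' Ordinary least-squares slope (natural logs throughout) of:
#' * box dimension: `log N(r)` against `log(1/r)`;
#' * information dimension: `H(r)` against `log(1/r)` (entropy already a
#'   log-scale quantity);
#' * correlation dimension: `log C(r)` against `log r`.
#'
#' @param scan a [box_counting_scan()].
#' @param which `"box"`, `"information"` or `"correlation"`.
#' @return List with `D`, `slope`, `intercept`, `r_squared`, `scales`,
#'   `flag` (`TRUE` if `D` falls outside `[0, 2]`; the value is reported,
#'   not clamped).
#' @export
estimate_dimension <- function(scan,
                               which = c("box", "information", "correlation")) {
  which <- match.arg(which)
  stopifnot(inherits(scan, "box_counting_scan"))
  if (nrow(scan) < 4) stop("need >= 4 scales to estimate a slope", call. = FALSE)
  x <- switch(which,
              box = log(1 / scan$r),
              information = log(1 / scan$r),
              correlation = log(scan$r))
  y <- switch(which,
              box = log(scan$N),
              information = scan$H,
              correlation = log(scan$C))
  if (stats::var(x) == 0) stop("zero variance in regressor", call. = FALSE)
  xb <- mean(x); yb <- mean(y)
  slope <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
  intercept <- yb - slope * xb
  ss_res <- sum((y - intercept - slope * x)^2)
  ss_tot <- sum((y - yb)^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  D <- if (which == "correlation") slope else slope
  list(D = D, slope = slope, intercept = intercept,
       r_squared = max(0, min(1, r2)), scales = scan$r,
       flag = (D < 0 || D > 2))
}

#' Fractal dimensions of a vessel map within a region of interest
#'
#' One box-counting scan, three slope estimates: box dimension `D_B`
#' (occupied-box count), information dimension `D_I` (box-occupancy
#' entropy) and correlation dimension `D_C` (pair-correlation sum). These
#' are the q = 0, 1, 2 members of the generalized (Renyi) dimension family,
#' so `D_B >= D_I >= D_C` up to estimation error.
#'
#' @inheritParams box_counting_scan
#' @param skeletonize if `TRUE`, reduce the map to a 1-px skeleton (via
#'   repeated morphological thinning) before counting. Off by default: the
#'   dimension is measured on the binary vessel map itself.
#' @return An `fd_result` list: `D_B`, `D_I`, `D_C`, per-estimator
#'   diagnostics, the scan, and the schedule configuration.
#' @examples
#' s <- make_analytic_fractal("sierpinski_triangle", depth = 7, grid_size = 128)
#' fd <- compute_fd(s)
#' abs(fd$D_B - log(3) / log(2)) < 1e-9
#' @export
compute_fd <- function(vessels, roi_mask = NULL, sizes = NULL,
                       cfg = box_schedule_config(), skeletonize = FALSE) {
  v <- as_binary(vessels)
  if (isTRUE(skeletonize)) v <- thin_mask(v)
  scan <- box_counting_scan(v, roi_mask, sizes, cfg)
  est <- lapply(c(box = "box", information = "information",
                  correlation = "correlation"),
                function(w) estimate_dimension(scan, w))
  structure(list(D_B = est$box$D, D_I = est$information$D,
                 D_C = est$correlation$D,
                 diagnostics = est, scan = scan, cfg = cfg),
            class = "fd_result")
}

#' @export
print.fd_result <- function(x, ...) {
  cat(sprintf("Fractal dimensions (%d scales, r = %s px)\n",
              nrow(x$scan), paste(x$scan$r, collapse = ", ")))
  cat(sprintf("  D_B = %.4f (R2 = %.4f)\n", x$D_B, x$diagnostics$box$r_squared))
  cat(sprintf("  D_I = %.4f (R2 = %.4f)\n",
              x$D_I, x$diagnostics$information$r_squared))
  cat(sprintf("  D_C = %.4f (R2 = %.4f)\n",
              x$D_C, x$diagnostics$correlation$r_squared))
  invisible(x)
}

# Morphological thinning to a 1-px skeleton (Zhang-Suen). Only used behind
# the optional `skeletonize` flag.
thin_mask <- function(v) {
  img <- v * 1L
  changed <- TRUE
  neighbours <- function(m) {
    list(p2 = shift_matrix(m, -1, 0), p3 = shift_matrix(m, -1, 1),
         p4 = shift_matrix(m, 0, 1),  p5 = shift_matrix(m, 1, 1),
         p6 = shift_matrix(m, 1, 0),  p7 = shift_matrix(m, 1, -1),
         p8 = shift_matrix(m, 0, -1), p9 = shift_matrix(m, -1, -1))
  }
  while (changed) {
    changed <- FALSE
    for (phase in 1:2) {
      nb <- neighbours(img)
      B <- Reduce(`+`, nb)
      seqs <- list(nb$p2, nb$p3, nb$p4, nb$p5, nb$p6, nb$p7, nb$p8, nb$p9, nb$p2)
      A <- Reduce(`+`, lapply(1:8, function(i) {
        (seqs[[i]] == 0) & (seqs[[i + 1]] == 1)
      }))
      if (phase == 1) {
        cond <- img == 1 & B >= 2 & B <= 6 & A == 1 &
          (nb$p2 * nb$p4 * nb$p6 == 0) & (nb$p4 * nb$p6 * nb$p8 == 0)
      } else {
        cond <- img == 1 & B >= 2 & B <= 6 & A == 1 &
          (nb$p2 * nb$p4 * nb$p8 == 0) & (nb$p2 * nb$p6 * nb$p8 == 0)
      }
      if (any(cond)) {
        img[cond] <- 0L
        changed <- TRUE
      }
    }
  }
  img == 1L
}
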