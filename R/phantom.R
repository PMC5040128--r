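#' Specification of a synthetic fundus phantom
#'
#' A phantom emulates the geometry of a fovea-centred fundus photograph:
#' a disc-shaped field of view, a bright optic disc (OD), a darker fovea at
#' 5 optic-disc radii from the OD centre (the average human fovea-to-disc
#' distance of 4.93 mm is about 5 ODr), and a branching vascular tree grown
#' from the OD rim with calibers spanning large trunks down to 1-2 px
#' twigs. Child widths at bifurcations follow Murray's law
#' (`w_parent^3 = sum w_child^3`), which yields a realistic caliber
#' spectrum.
#'
#' Coordinates are `(row, col)`, 0-based, pixel centres at integers; all
#' radii in pixels.
#'
#' @param seed integer seed; identical specs give bit-identical bundles.
#' @param image_size pixels per side.
#' @param od_radius optic disc radius ODr in pixels.
#' @param od_center,fovea_center `(row, col)`; defaults place both on the
#'   horizontal midline, 5 ODr apart, straddling the image centre. The
#'   fovea-to-OD distance must equal `5 * od_radius` within 5%.
#' @param n_roots number of vessel trunks leaving the OD rim.
#' @param branch_prob per-segment bifurcation probability.
#' @param angle_jitter_deg direction jitter per growth step (degrees).
#' @param length_decay multiplicative segment-length decay per bifurcation.
#' @param width_decay multiplicative caliber taper per (non-branching)
#'   growth step.
#' @param min_width_px terminal caliber; must be >= 1 (sub-pixel vessels
#'   are not representable).
#' @param illumination_gradient_strength amplitude of the smooth luminosity
#'   ramp across the field of view (fraction of full scale).
#' @param noise_sigma Gaussian pixel-noise standard deviation.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(seed = 1L,
                         image_size = 512L,
                         od_radius = 40,
                         od_center = NULL,
                         fovea_center = NULL,
                         n_roots = 6L,
                         branch_prob = 0.25,
                         angle_jitter_deg = 8,
                         length_decay = 0.92,
                         width_decay = 0.985,
                         min_width_px = 1.2,
                         illumination_gradient_strength = 0.08,
                         noise_sigma = 0.02) {
  image_size <- as.integer(image_size)
  half <- image_size / 2
  sep <- 5 * od_radius
  # fovea-centred layout (the usual acquisition for FD studies): fovea at
  # the FOV centre, optic disc 5 ODr toward the nasal edge
  if (is.null(fovea_center)) fovea_center <- c(half, half)
  if (is.null(od_center)) od_center <- c(half, half - sep)
  d <- sqrt(sum((od_center - fovea_center)^2))
  if (abs(d - sep) > 0.05 * sep) {
    stop(sprintf(
      "fovea-to-OD distance %.1f px must equal 5 x od_radius = %.1f px within 5%%",
      d, sep), call. = FALSE)
  }
  if (min_width_px < 1) {
    stop("`min_width_px` must be >= 1: sub-pixel vessels are not representable",
         call. = FALSE)
  }
  if (noise_sigma < 0 || illumination_gradient_strength < 0) {
    stop("noise and illumination strengths must be >= 0", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), image_size = image_size,
                 od_radius = od_radius, od_center = od_center,
                 fovea_center = fovea_center, n_roots = as.integer(n_roots),
                 branch_prob = branch_prob,
                 angle_jitter_deg = angle_jitter_deg,
                 length_decay = length_decay, width_decay = width_decay,
                 min_width_px = min_width_px,
                 illumination_gradient_strength = illumination_gradient_strength,
                 noise_sigma = noise_sigma),
            class = "phantom_spec")
}

#' Generate a synthetic fundus phantom
#'
#' Grows a branching vascular tree from `n_roots` points on the optic-disc
#' rim by recursive bifurcation, rasterizes it with anti-aliased strokes,
#' and renders a 3-channel fundus-like image: vessels dark on a bright
#' background in the green channel, bright yellowish optic disc, dark
#' fovea, smooth illumination gradient and Gaussian noise. The exact binary
#' vessel map, OD/fovea geometry and field-of-view mask are returned
#' alongside the image, so every downstream stage can be scored against
#' ground truth.
#'
#' @param spec a [phantom_spec()].
#' @return A `phantom_bundle`: list with `image` (`size x size x 3` array
#'   in `[0,1]`), `truth_vessels` (logical matrix), `od_geometry`
#'   (`list(center, radius)`), `fovea_center`, `fov_mask` (logical matrix)
#'   and `spec`.
#' @examples
#' b <- make_vascular_phantom(phantom_spec(seed = 7, image_size = 256,
#'                                         od_radius = 20))
#' sum(b$truth_vessels & !b$fov_mask) == 0
#' @export
make_vascular_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$image_size
  fov_center <- c(n / 2, n / 2)
  fov_radius <- 0.49 * n
  fov_mask <- disc_mask(n, n, fov_center, fov_radius)

  segs <- with_local_seed(derive_seed(spec$seed, "phantom_tree"),
                          grow_tree(spec, fov_center, fov_radius))
  alpha <- rasterize_strokes(segs, n)
  truth <- (alpha >= 0.5) & fov_mask

  image <- with_local_seed(derive_seed(spec$seed, "phantom_render"),
                           render_fundus(spec, alpha, fov_mask))

  structure(list(image = image, truth_vessels = truth,
                 od_geometry = list(center = spec$od_center,
                                    radius = spec$od_radius),
                 fovea_center = spec$fovea_center,
                 fov_mask = fov_mask, spec = spec),
            class = "phantom_bundle")
}

# Recursive-bifurcation tree growth with retinal-arcade geometry: trunks
# emerge from the optic cup, cross the disc radially, then sweep around
# the fovea (superior/inferior arcades) with a slight outward drift;
# vessels of caliber >= 2 px avoid the macular zone (2 ODr) and nothing
# enters the foveal avascular zone (0.8 ODr). Returns a matrix of strokes
# (r0, c0, r1, c1, width) in 0-based pixel coordinates.
grow_tree <- function(spec, fov_center, fov_radius) {
  od <- spec$od_center
  fov <- spec$fovea_center
  to_fovea <- atan2(fov[1] - od[1], fov[2] - od[2])
  jitter <- spec$angle_jitter_deg * pi / 180
  nr <- spec$n_roots
  side <- rep(c(1, -1), length.out = nr)   # superior / inferior hemifield
  off <- rep(seq(25, 150, length.out = ceiling(nr / 2)),
             each = 2)[seq_len(nr)]
  root_angles <- to_fovea + side * off * pi / 180 +
    runif(nr, -0.5, 0.5) * jitter
  step0 <- 0.45 * spec$od_radius
  arcade_strength <- 0.22                  # per-step pull toward the arcade
  wrap <- function(a) atan2(sin(a), cos(a))

  segs <- vector("list", 8000L)
  n_segs <- 0L
  stack <- lapply(seq_len(nr), function(i) {
    a <- root_angles[i]
    list(pos = od + 0.2 * spec$od_radius * c(sin(a), cos(a)),
         dir = a, width = runif(1, 5.5, 7.5), len = step0, rot = side[i])
  })
  while (length(stack) > 0 && n_segs < 7000L) {
    st <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    repeat {
      if (st$width < spec$min_width_px || n_segs >= 7000L) break
      inside_od <- sqrt(sum((st$pos - od)^2)) < 1.2 * spec$od_radius
      rel <- st$pos - fov
      # arcade target: tangential around the fovea plus outward drift
      tang <- atan2(rel[1], rel[2]) + st$rot * (pi / 2 - 0.25)
      bias <- if (inside_od) 0 else arcade_strength
      ang <- st$dir + bias * wrap(tang - st$dir) + runif(1, -1, 1) * jitter
      nxt <- st$pos + st$len * c(sin(ang), cos(ang))
      # stay inside the field of view (with a margin of the stroke radius)
      if (sqrt(sum((nxt - fov_center)^2)) > fov_radius - st$width / 2 - 1) break
      d_fov <- sqrt(sum((nxt - fov)^2))
      if (d_fov < 0.8 * spec$od_radius) break           # avascular zone
      if (d_fov < 2 * spec$od_radius && st$width >= 2) break  # macular gate
      n_segs <- n_segs + 1L
      segs[[n_segs]] <- c(st$pos, nxt, st$width)
      st$pos <- nxt
      st$dir <- ang
      if (!inside_od && runif(1) < spec$branch_prob) {
        f <- runif(1, 0.35, 0.65)          # flow split; Murray's law widths
        spread <- runif(1, 18, 40) * pi / 180
        child <- list(pos = nxt, dir = ang + spread * (1 - f),
                      width = st$width * (1 - f)^(1 / 3),
                      len = st$len * spec$length_decay,
                      rot = if (runif(1) < 0.9) st$rot else -st$rot)
        stack[[length(stack) + 1L]] <- child
        st$dir <- ang - spread * f
        st$width <- st$width * f^(1 / 3)
        st$len <- st$len * spec$length_decay
      } else {
        st$width <- st$width * spec$width_decay
      }
    }
  }
  if (n_segs == 0L) {
    matrix(numeric(0), ncol = 5)
  } else {
    do.call(rbind, segs[seq_len(n_segs)])
  }
}

# Anti-aliased stroke rasterization: per pixel, coverage is
# clip(w/2 + 0.5 - distance-to-segment); the union over strokes is a max.
rasterize_strokes <- function(segs, n) {
  alpha <- matrix(0, n, n)
  if (nrow(segs) == 0) return(alpha)
  for (i in seq_len(nrow(segs))) {
    p0 <- segs[i, 1:2]; p1 <- segs[i, 3:4]; w <- segs[i, 5]
    pad <- w / 2 + 1.5
    r_lo <- max(1L, floor(min(p0[1], p1[1]) - pad) + 1L)
    r_hi <- min(n, ceiling(max(p0[1], p1[1]) + pad) + 1L)
    c_lo <- max(1L, floor(min(p0[2], p1[2]) - pad) + 1L)
    c_hi <- min(n, ceiling(max(p0[2], p1[2]) + pad) + 1L)
    if (r_lo > r_hi || c_lo > c_hi) next
    rr <- (r_lo:r_hi) - 1           # 0-based pixel centres
    cc <- (c_lo:c_hi) - 1
    v <- p1 - p0
    vv <- sum(v^2)
    pr <- outer(rr - p0[1], rep(1, length(cc)))
    pc <- outer(rep(1, length(rr)), cc - p0[2])
    t <- if (vv == 0) 0 else clip01((pr * v[1] + pc * v[2]) / vv)
    d <- sqrt((pr - t * v[1])^2 + (pc - t * v[2])^2)
    a <- clip01(w / 2 + 0.5 - d)
    blk <- alpha[r_lo:r_hi, c_lo:c_hi]
    alpha[r_lo:r_hi, c_lo:c_hi] <- pmax(blk, a)
  }
  alpha
}

# Compose the 3-channel fundus-like image from vessel coverage.
render_fundus <- function(spec, alpha, fov_mask) {
  n <- spec$image_size
  rows <- matrix((seq_len(n) - 1) - n / 2, n, n)
  cols <- t(rows)
  grad <- spec$illumination_gradient_strength *
    (0.6 * cols + 0.4 * rows) / n
  od_soft <- clip01((spec$od_radius + 1 -
                       sqrt(pixel_dist2(n, n, spec$od_center))) / 2)
  fov_soft <- exp(-pixel_dist2(n, n, spec$fovea_center) /
                    (2 * (0.6 * spec$od_radius)^2))
  lum <- 0.70 + grad + 0.18 * od_soft - 0.12 * fov_soft - 0.35 * alpha

  red <- clip01(0.9 * lum + 0.12 + 0.06 * od_soft)
  green <- clip01(lum)
  blue <- clip01(0.45 * lum - 0.05 * od_soft + 0.02)
  if (spec$noise_sigma > 0) {
    red <- clip01(red + matrix(rnorm(n * n, 0, 0.8 * spec$noise_sigma), n, n))
    green <- clip01(green + matrix(rnorm(n * n, 0, spec$noise_sigma), n, n))
    blue <- clip01(blue + matrix(rnorm(n * n, 0, 0.8 * spec$noise_sigma), n, n))
  }
  bg <- 0.03
  red[!fov_mask] <- bg; green[!fov_mask] <- bg; blue[!fov_mask] <- bg
  array(c(red, green, blue), dim = c(n, n, 3))
}
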