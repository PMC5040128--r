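#' Analytic fractal fixtures with exactly known dimension
#'
#' Generates binary rasters whose Hausdorff dimension is known in closed
#' form, for validating box-counting dimension estimators. Subdivision
#' fractals (Sierpinski triangle, random dust) are built by exact recursive
#' subdivision on dyadic grids, so their occupied-box counts at every dyadic
#' scale are combinatorial, not approximate: the depth-`d` Sierpinski
#' triangle occupies exactly `3^(d-j)` boxes of side `2^j` on its native
#' `2^d` grid.
#'
#' @param kind one of `"line"`, `"filled_square"`, `"single_point"`,
#'   `"sierpinski_triangle"`, `"koch_curve"`, `"random_dust"`.
#' @param depth iteration count of the construction (ignored for the three
#'   trivial kinds).
#' @param grid_size pixels per side; must be a power of 2.
#' @param seed RNG seed, used only by `"random_dust"`.
#' @param retain_prob for `"random_dust"`: probability that each of the 4
#'   child quadrants of an occupied cell survives a subdivision step. The
#'   expected dimension of the limit set is `log2(4 * retain_prob)`.
#' @return A logical `grid_size x grid_size` matrix (`TRUE` = occupied) with
#'   attributes `kind`, `depth` and `true_dimension` (the analytic Hausdorff
#'   dimension of the limit set; expected dimension for random dust).
#' @examples
#' s <- make_analytic_fractal("sierpinski_triangle", depth = 5, grid_size = 32)
#' sum(s) == 3^5
#' attr(s, "true_dimension")  # log(3)/log(2)
#' @export
make_analytic_fractal <- function(kind = c("line", "filled_square",
                                           "single_point",
                                           "sierpinski_triangle",
                                           "koch_curve", "random_dust"),
                                  depth = 0L, grid_size = 256L,
                                  seed = 1L, retain_prob = 0.75) {
  kind <- match.arg(kind)
  grid_size <- as.integer(grid_size)
  depth <- as.integer(depth)
  if (grid_size < 2 || bitwAnd(grid_size, grid_size - 1L) != 0L) {
    stop("`grid_size` must be a power of 2 (>= 2)", call. = FALSE)
  }
  if (depth < 0) stop("`depth` must be non-negative", call. = FALSE)
  m_levels <- as.integer(round(log2(grid_size)))
  if (kind %in% c("sierpinski_triangle", "random_dust") && depth > m_levels) {
    stop(sprintf(
      "depth %d infeasible for grid_size %d: maximum feasible depth is %d",
      depth, grid_size, m_levels), call. = FALSE)
  }

  out <- switch(kind,
    line = {
      z <- matrix(FALSE, grid_size, grid_size)
      z[grid_size %/% 2L, ] <- TRUE
      z
    },
    filled_square = matrix(TRUE, grid_size, grid_size),
    single_point = {
      z <- matrix(FALSE, grid_size, grid_size)
      z[grid_size %/% 2L, grid_size %/% 2L] <- TRUE
      z
    },
    sierpinski_triangle = sierpinski_raster(depth, grid_size),
    koch_curve = koch_raster(depth, grid_size),
    random_dust = dust_raster(depth, grid_size, seed, retain_prob)
  )
  attr(out, "kind") <- kind
  attr(out, "depth") <- depth
  attr(out, "true_dimension") <- switch(kind,
    line = 1,
    filled_square = 2,
    single_point = 0,
    sierpinski_triangle = log(3) / log(2),
    koch_curve = log(4) / log(3),
    random_dust = log2(4 * retain_prob)
  )
  out
}

# Occupied iff the depth-level cell indices satisfy bitwAnd(i, j) == 0:
# the standard right-angled Sierpinski construction, self-similar on the
# dyadic grid. Cells below `depth` are fully filled.
sierpinski_raster <- function(depth, grid_size) {
  cell <- grid_size %/% (2L^depth)
  idx <- (seq_len(grid_size) - 1L) %/% cell     # depth-level cell index
  occ <- outer(idx, idx, function(i, j) bitwAnd(i, j) == 0L)
  occ
}

# Koch curve as a polyline in the complex plane, rasterized by dense
# sampling (sub-pixel steps), 1 px wide.
koch_raster <- function(depth, grid_size) {
  pts <- c(0 + 0i, 1 + 0i)
  rot <- exp(-1i * pi / 3)   # bump upward in (x, y); y later mapped to rows
  for (k in seq_len(depth)) {
    a <- pts[-length(pts)]
    b <- pts[-1]
    d <- (b - a) / 3
    pts <- c(rbind(a, a + d, a + d + d * rot, a + 2 * d), b[length(b)])
  }
  # map x in [0,1], y in [-sqrt(3)/6, 0] onto the grid with a small margin
  margin <- 2
  span <- grid_size - 2 * margin
  x <- Re(pts) * span + margin
  y <- (-Im(pts)) * span + margin + span * sqrt(3) / 6
  z <- matrix(FALSE, grid_size, grid_size)
  for (i in seq_len(length(x) - 1L)) {
    seg_len <- sqrt((x[i + 1] - x[i])^2 + (y[i + 1] - y[i])^2)
    n <- max(2L, ceiling(seg_len / 0.4))
    t <- seq(0, 1, length.out = n)
    rr <- pmin(pmax(round(y[i] + t * (y[i + 1] - y[i])), 1), grid_size)
    cc <- pmin(pmax(round(x[i] + t * (x[i + 1] - x[i])), 1), grid_size)
    z[cbind(rr, cc)] <- TRUE
  }
  z
}

# Fractal percolation: each occupied cell keeps each of its 4 quadrants
# with probability retain_prob (at least one, so the set never dies out).
dust_raster <- function(depth, grid_size, seed, retain_prob) {
  if (retain_prob <= 0 || retain_prob > 1) {
    stop("`retain_prob` must be in (0, 1]", call. = FALSE)
  }
  with_local_seed(derive_seed(seed, "random_dust"), {
    occ <- matrix(TRUE, 1, 1)
    for (k in seq_len(depth)) {
      n <- nrow(occ)
      nxt <- matrix(FALSE, 2L * n, 2L * n)
      cells <- which(occ, arr.ind = TRUE)
      for (i in seq_len(nrow(cells))) {
        keep <- runif(4) < retain_prob
        if (!any(keep)) keep[sample.int(4, 1)] <- TRUE
        r2 <- 2L * cells[i, 1] - 1L
        c2 <- 2L * cells[i, 2] - 1L
        quad <- rbind(c(r2, c2), c(r2, c2 + 1L),
                      c(r2 + 1L, c2), c(r2 + 1L, c2 + 1L))
        nxt[quad[keep, , drop = FALSE]] <- TRUE
      }
      occ <- nxt
    }
    cell <- grid_size %/% (2L^depth)
    occ[rep(seq_len(nrow(occ)), each = cell), rep(seq_len(ncol(occ)), each = cell)]
  })
}
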