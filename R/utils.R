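# Internal helpers shared across modules.

#' Run code with a locally scoped RNG seed
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so generators are pure functions of their seed.
#' @noRd
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and a stream label, staying within
# 32-bit integer range. Stable across platforms (pure integer arithmetic).
derive_seed <- function(seed, label) {
  chars <- utf8ToInt(as.character(label))
  h <- as.double(seed %% 2147483647L)
  for (ch in chars) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

# Squared Euclidean distance of every pixel to a (row, col) center, for an
# nrow x ncol raster with 0-based pixel-center coordinates.
pixel_dist2 <- function(nrow, ncol, center) {
  dr <- (seq_len(nrow) - 1) - center[1]
  dc <- (seq_len(ncol) - 1) - center[2]
  outer(dr^2, dc^2, `+`)
}

# Disc mask: distance to center <= radius (pixels).
disc_mask <- function(nrow, ncol, center, radius) {
  pixel_dist2(nrow, ncol, center) <= radius^2
}

stopifnot_binary <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !(is.logical(x) || all(x %in% c(0, 1)))) {
    stop(sprintf("`%s` must be a binary (logical or 0/1) matrix", name),
         call. = FALSE)
  }
  invisible(TRUE)
}

as_binary <- function(x) {
  if (is.logical(x)) x else matrix(x != 0, nrow(x), ncol(x))
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Shift a matrix by integer (dr, dc), padding with `fill`.
shift_matrix <- function(m, dr, dc, fill = 0) {
  out <- matrix(fill, nrow(m), ncol(m))
  nr <- nrow(m); nc <- ncol(m)
  src_r <- seq_len(nr) - dr
  src_c <- seq_len(nc) - dc
  ok_r <- src_r >= 1 & src_r <= nr
  ok_c <- src_c >= 1 & src_c <= nc
  out[which(ok_r), which(ok_c)] <- m[src_r[ok_r], src_c[ok_c]]
  out
}
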