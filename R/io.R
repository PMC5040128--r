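#' Write a phantom bundle to disk
#'
#' Writes the image as 8-bit PNG (and optionally 16-bit TIFF), the truth
#' vessel map and field-of-view mask as PNGs, and a JSON sidecar holding
#' the generating spec, seed and geometry, so a bundle can be regenerated
#' or audited.
#'
#' @param bundle a `phantom_bundle`.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @param tiff_image also write the image as 16-bit TIFF.
#' @return Invisibly, the written paths.
#' @export
write_bundle <- function(bundle, dir, prefix = "phantom",
                         tiff_image = FALSE) {
  stopifnot(inherits(bundle, "phantom_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    image = file.path(dir, paste0(prefix, "_image.png")),
    truth = file.path(dir, paste0(prefix, "_truth.png")),
    fov = file.path(dir, paste0(prefix, "_fov.png")),
    sidecar = file.path(dir, paste0(prefix, ".json")))
  png::writePNG(clip01(bundle$image), paths[["image"]])
  png::writePNG(bundle$truth_vessels * 1, paths[["truth"]])
  png::writePNG(bundle$fov_mask * 1, paths[["fov"]])
  if (tiff_image) {
    paths <- c(paths, tiff = file.path(dir, paste0(prefix, "_image.tif")))
    tiff::writeTIFF(clip01(bundle$image), paths[["tiff"]],
                    bits.per.sample = 16L)
  }
  sidecar <- list(spec = unclass(bundle$spec),
                  od_geometry = bundle$od_geometry,
                  fovea_center = bundle$fovea_center,
                  camera = bundle$camera)
  jsonlite::write_json(sidecar, paths[["sidecar"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(paths)
}

#' Read a binary mask from a PNG file
#'
#' @param path PNG path (grayscale or RGB; any channel > 0.5 is vessel).
#' @return Logical matrix.
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img > 0.5
}
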