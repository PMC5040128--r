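# Shared fixtures, built once per test run and cached across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# the canonical 20-phantom ensemble (seeds 1..20, default spec)
get_phantoms <- function(n = 20) {
  stopifnot(n <= 20)
  cached("phantoms20", lapply(1:20, function(s)
    make_vascular_phantom(phantom_spec(seed = s))))[seq_len(n)]
}

# 5-ODr fovea-centred ROI for a bundle
roi5 <- function(b, k = 5) {
  circular_roi_mask(
    roi_spec(b$fovea_center, k, b$od_geometry$radius, "fovea"),
    dim(b$truth_vessels))
}

# default phantom segmented with the default vesselness parameters
get_default_seg <- function() {
  cached("default_seg", {
    b <- get_phantoms(1)[[1]]
    norm <- normalize_luminosity_contrast(b$image[, , 2],
                                          fov_mask = b$fov_mask)
    pm <- frangi_vesselness(norm$image, frangi_params())
    pm[!b$fov_mask] <- 0
    list(bundle = b, pm = pm, roi = roi5(b),
         ref_db = compute_fd(b$truth_vessels, roi5(b))$D_B)
  })
}

# reduced-size study configuration used for determinism checks
tiny_config <- function() {
  list(phantom = list(image_size = 256L, od_radius = 20),
       study1 = list(n_per_group = 3L),
       study2 = list(n_phantoms = 4L),
       study3 = list(n_phantoms = 3L),
       study4 = list(n_phantoms = 4L),
       study5 = list(n_phantoms = 1L),
       study6 = list(n_subjects = 2L, n_acquisitions = 2L))
}
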