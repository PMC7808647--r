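#' Photon-statistics model for the simulated measurement
#'
#' @param I0 Incident photons per detector cell per view in the blank scan
#'   (default 1e5).
#' @param r Mean number of background/readout events added to the expected
#'   count before Poisson sampling (default 0).
#' @param seed Integer seed making the Poisson draw reproducible; `NULL`
#'   uses (and advances) the session RNG.
#' @param enabled If `FALSE`, [apply_poisson()] returns the expected counts
#'   unchanged (noiseless simulation).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(I0 = 1e5, r = 0, seed = NULL, enabled = TRUE) {
  if (I0 <= 0) stop("I0 must be positive")
  if (r < 0) stop("r must be non-negative")
  out <- list(I0 = I0, r = r, seed = seed, enabled = isTRUE(enabled))
  class(out) <- "noise_model"
  out
}

#' Per-material path lengths through a phantom
#'
#' Forward projection of each material map, giving the intersection length
#' (mm) of every ray with water, bone and metal.
#'
#' @param phantom A [material_phantom()].
#' @param geometry A [scan_geometry()].
#' @param oversample Detector oversampling factor.
#' @return List of three `"path_length"` [sinogram()]s: `water`, `bone`,
#'   `metal`.  Values are in mm because the maps hold density fractions.
#' @export
material_path_lengths <- function(phantom, geometry, oversample = 1L) {
  maps <- list(water = phantom$water_map, bone = phantom$bone_map,
               metal = phantom$metal_map)
  lapply(maps, forward_project, geometry = geometry,
         oversample = oversample)
}

#' Polychromatic transmitted intensity
#'
#' Spectrum-weighted Beer-Lambert transmission
#' `I = I0 * sum_E Omega(E) * exp(-mu_w(E) d_w - mu_b(E) d_b - mu_m(E) d_m)`
#' for per-material path lengths `d` (mm) and linear attenuations `mu`
#' (mm^-1).  Beam hardening arises from the energy sum: thicker objects
#' attenuate the soft part of the spectrum preferentially, so the log
#' projection grows sub-linearly with thickness.
#'
#' @param paths List of `water`, `bone`, `metal` path-length [sinogram()]s
#'   (entries may be `NULL` for absent materials).
#' @param spectrum An [xray_spectrum()].
#' @param atten An [attenuation_table()] on the spectrum's energies.
#' @param I0 Incident photons per bin.
#' @return An `"intensity"` [sinogram()] with `0 < I <= I0`.
#' @export
polychromatic_intensity <- function(paths, spectrum, atten, I0 = 1e5) {
  stopifnot(length(attr(atten, "energies")) == length(spectrum$energies))
  if (max(abs(attr(atten, "energies") - spectrum$energies)) > 1e-9)
    stop("attenuation table and spectrum energy grids differ")
  ref <- paths$water
  if (is.null(ref)) ref <- paths$bone
  if (is.null(ref)) ref <- paths$metal
  if (is.null(ref)) stop("at least one material path is required")
  get <- function(nm) {
    p <- paths[[nm]]
    if (is.null(p)) return(0)
    if (any(p$values < 0)) stop("path lengths must be non-negative")
    p$values
  }
  dw <- get("water"); db <- get("bone"); dm <- get("metal")
  I <- 0
  for (k in seq_along(spectrum$energies)) {
    I <- I + spectrum$weights[k] *
      exp(-(atten[k, "water"] * dw + atten[k, "bone"] * db +
              atten[k, "metal"] * dm))
  }
  sinogram(I0 * I, ref$geometry, "intensity", oversample = ref$oversample,
           n_extend = ref$n_extend)
}

#' Poisson counting noise
#'
#' Draws `y ~ Poisson(I + r)` independently per sinogram sample.  With a
#' seed in the noise model the draw is reproducible and the session RNG is
#' left untouched.
#'
#' @param intensity An `"intensity"` [sinogram()] of expected counts.
#' @param noise A [noise_model()].
#' @return An `"intensity"` [sinogram()] of integer counts (numeric
#'   storage).
#' @export
apply_poisson <- function(intensity, noise = noise_model()) {
  if (intensity$domain != "intensity")
    stop("apply_poisson expects an intensity-domain sinogram")
  if (!noise$enabled) return(intensity)
  lam <- pmax(intensity$values + noise$r, 0)  # clamp float round-off
  draw <- function() matrix(stats::rpois(length(lam), lam), nrow(lam))
  y <- if (is.null(noise$seed)) draw() else with_seed(noise$seed, draw())
  sinogram(y, intensity$geometry, "intensity",
           oversample = intensity$oversample, n_extend = intensity$n_extend)
}

# evaluate expr under a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Log transform of measured counts
#'
#' `p = -log(y / I0)`; zero counts are floored at `floor_counts` (default
#' 0.5) to keep the projection finite behind dense metal (photon
#' starvation).
#'
#' @param counts An `"intensity"` [sinogram()].
#' @param I0 Blank-scan counts.
#' @param floor_counts Lower clamp applied to the counts before the log.
#' @return A `"log_projection"` [sinogram()].
#' @export
log_projection <- function(counts, I0 = 1e5, floor_counts = 0.5) {
  if (I0 <= 0) stop("I0 must be positive")
  p <- -log(pmax(counts$values, floor_counts) / I0)
  sinogram(p, counts$geometry, "log_projection",
           oversample = counts$oversample, n_extend = counts$n_extend)
}

#' Soft-threshold decomposition of a gray-value image into bone and water
#'
#' The bone weight of a pixel value `x` (HU) is 0 below `T1`, 1 above `T2`
#' and `(x - T1) / (T2 - T1)` in between; the bone fraction is `w(x) * x`
#' and the water fraction `(1 - w(x)) * x`, so the two fractions always sum
#' back to `x`.  Metal pixels must be excluded beforehand.
#'
#' @param image A [recon_image()] in HU, or a plain numeric matrix of HU
#'   values.
#' @param T1 Soft-tissue upper threshold in HU (default 80).
#' @param T2 Bone lower threshold in HU (default 660).
#' @return List with HU matrices `water`, `bone` and the weight matrix `w`.
#' @export
soft_threshold_decompose <- function(image, T1 = 80, T2 = 660) {
  if (T1 >= T2) stop("T1 must be below T2")
  x <- if (inherits(image, "recon_image")) {
    if (image$unit != "HU") stop("decomposition expects an HU image")
    image$values
  } else as.matrix(image)
  w <- pmin(pmax((x - T1) / (T2 - T1), 0), 1)
  list(water = (1 - w) * x, bone = w * x, w = w)
}

#' End-to-end polychromatic measurement simulation
#'
#' Composes [forward_project()] per material, [polychromatic_intensity()],
#' [apply_poisson()] and [log_projection()].  Projection truncation arises
#' naturally when the phantom extends beyond the detector's coverage.
#'
#' @param phantom A [material_phantom()].
#' @param geometry A [scan_geometry()].
#' @param spectrum An [xray_spectrum()] (default [default_spectrum()]).
#' @param atten An [attenuation_table()] on the spectrum energies.
#' @param noise A [noise_model()].
#' @param oversample Detector oversampling for the material projections
#'   (rebinned to the native grid before the intensity model when > 1).
#' @return A `"log_projection"` [sinogram()] on the native detector grid.
#' @export
simulate_measurement <- function(phantom, geometry,
                                 spectrum = default_spectrum(),
                                 atten = attenuation_table(spectrum$energies),
                                 noise = noise_model(),
                                 oversample = 1L) {
  paths <- material_path_lengths(phantom, geometry, oversample)
  if (oversample > 1L)
    paths <- lapply(paths, rebin_detector, factor = oversample)
  I <- polychromatic_intensity(paths, spectrum, atten, noise$I0)
  y <- apply_poisson(I, noise)
  log_projection(y, noise$I0)
}
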