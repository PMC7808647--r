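#' Truncation-correction configuration
#'
#' Symmetric-mirroring truncation correction estimates `N_s` detector
#' samples beyond each truncated sinogram edge by reflecting the innermost
#' `N_ext` measured samples outward and tapering them with a 0-90 degree
#' cosine so the extension decays to zero.  The defaults for `N_ext` follow
#' the two geometry presets: 300 detector pixels for the conventional
#' geometry and 150 for the dental one.
#'
#' @param n_ext Number of edge samples mirrored outward (>= 1).
#' @param n_s Number of samples synthesized per truncated side; defaults
#'   to `n_ext`, which lets the cosine taper reach exactly zero at the
#'   outermost synthesized sample.
#' @param detect_threshold A side counts as truncated when its edge sample
#'   exceeds this fraction of the row maximum.
#' @return An object of class `truncation_config`.
#' @export
truncation_config <- function(n_ext = 300L, n_s = n_ext,
                              detect_threshold = 0.01) {
  n_ext <- as.integer(n_ext); n_s <- as.integer(n_s)
  if (n_ext < 1L) stop("n_ext must be >= 1")
  if (n_s < 0L) stop("n_s must be >= 0")
  out <- list(n_ext = n_ext, n_s = n_s,
              detect_threshold = detect_threshold)
  class(out) <- "truncation_config"
  out
}

#' Default truncation configuration for a geometry
#'
#' Scales the preset mirror length (300 pixels at 1024 detector cells,
#' 150 at 512) with the detector size.
#'
#' @param geometry A [scan_geometry()].
#' @return A [truncation_config()].
#' @export
default_truncation_config <- function(geometry) {
  n_ext <- max(1L, as.integer(round(geometry$n_detectors * 300 / 1024)))
  truncation_config(n_ext = n_ext)
}

#' Cosine taper weight for the mirrored extension
#'
#' Piecewise weight over the index range `0 .. 2*n_ext + n_s - 1`: a
#' rising quarter-cosine `cos((n_ext - N) / n_ext * pi/2)` for
#' `N < n_ext`, a flat unity plateau of length `n_s`, and the mirrored
#' falling quarter-cosine `cos((N - n_s - n_ext + 1) / n_ext * pi/2)`
#' beyond.  The weight is 0 at `N = 0` and 1 at `N = n_ext`.
#'
#' @param N Integer index (vectorized), `0 <= N < 2*n_ext + n_s`.
#' @param cfg A [truncation_config()].
#' @return Weights in `[0, 1]`.
#' @export
truncation_weight <- function(N, cfg) {
  ne <- cfg$n_ext; ns <- cfg$n_s
  if (any(N < 0 | N >= 2L * ne + ns)) stop("index N out of range")
  w <- numeric(length(N))
  lo <- N < ne
  mid <- N >= ne & N < ne + ns
  hi <- N >= ne + ns
  w[lo] <- cos((ne - N[lo]) / ne * pi / 2)
  w[mid] <- 1
  w[hi] <- cos((N[hi] - ns - ne + 1) / ne * pi / 2)
  w
}

# taper applied to the k-th synthesized sample beyond an edge (k 0-based):
# the falling branch of truncation_weight, clamped to 0 past n_ext samples
.extension_weights <- function(cfg) {
  if (cfg$n_s == 0L) return(numeric(0))
  k <- seq_len(cfg$n_s) - 1L
  idx <- pmin(cfg$n_ext + cfg$n_s + k, 2L * cfg$n_ext + cfg$n_s - 1L)
  w <- truncation_weight(idx, cfg)
  w[k >= cfg$n_ext] <- 0
  w
}

#' Extend a truncated sinogram by weighted symmetric mirroring
#'
#' Per view row and per truncated side, `n_s` samples are appended by
#' reflecting the innermost measured samples about the detector edge
#' (half-sample reflection: the k-th synthesized sample copies the k-th
#' sample inward from the edge) and multiplying by the falling cosine
#' branch of [truncation_weight()].  Sides whose edge sample is below the
#' detection threshold are padded with zeros; measured samples are never
#' altered.
#'
#' @param sino A `"log_projection"` (or `"path_length"`) [sinogram()].
#' @param cfg A [truncation_config()]; default derived from the geometry.
#' @return A [sinogram()] with `n_s` extra bins on each side
#'   (`n_extend = n_s`).
#' @export
extend_sinogram <- function(sino, cfg = default_truncation_config(
                              sino$geometry)) {
  if (sino$domain == "intensity")
    stop("extend log-domain sinograms, not intensities")
  if (sino$n_extend > 0L) stop("sinogram is already extended")
  v <- sino$values
  nb <- ncol(v)
  if (cfg$n_ext > nb) stop("n_ext exceeds the detector row length")
  ns <- cfg$n_s
  if (ns == 0L) return(sino)
  w <- .extension_weights(cfg)
  k <- seq_len(ns)
  left <- v[, k, drop = FALSE]              # reflection about left edge
  right <- v[, nb + 1L - k, drop = FALSE]   # reflection about right edge
  rowmax <- apply(abs(v), 1L, max)
  thr <- cfg$detect_threshold * rowmax
  left_trunc <- abs(v[, 1L]) > thr & rowmax > 0
  right_trunc <- abs(v[, nb]) > thr & rowmax > 0
  left <- sweep(left, 2L, w, "*") * left_trunc
  right <- sweep(right, 2L, w, "*") * right_trunc
  # left extension runs outward (leftward), so reverse its column order
  ext <- cbind(left[, rev(k), drop = FALSE], v, right)
  sinogram(ext, sino$geometry, sino$domain, oversample = sino$oversample,
           n_extend = ns)
}

#' Truncation-corrected reconstruction (small-FOV image)
#'
#' [extend_sinogram()] followed by [fbp_reconstruct()] on the widened
#' virtual detector, masked to the scan FOV.  This is the first step of
#' the small-FOV MAR pipeline: it removes the bright-rim truncation bias
#' so the image can be re-projected into a consistent sinogram.
#'
#' @param sino A measured `"log_projection"` [sinogram()].
#' @param geometry A [scan_geometry()]; default the sinogram's.
#' @param cfg A [truncation_config()].
#' @param window FBP apodization window.
#' @return A [recon_image()] in mm^-1, zero outside the FOV.
#' @export
truncation_corrected_recon <- function(sino, geometry = sino$geometry,
                                       cfg = default_truncation_config(
                                         geometry),
                                       window = "hann") {
  ext <- extend_sinogram(sino, cfg)
  fbp_reconstruct(ext, geometry, window = window, mask_fov = TRUE)
}
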