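#' Fan-beam forward projection
#'
#' Ray-driven (Joseph, bilinear) line integrals of a 2-D attenuation image
#' along every source--detector-bin ray.  The detector may be sampled more
#' finely than its physical cells via `oversample`; use [rebin_detector()]
#' to return to the native grid.
#'
#' @param image A [recon_image()] in linear attenuation (mm^-1) or a plain
#'   square matrix on the geometry's grid.
#' @param geometry A [scan_geometry()].
#' @param oversample Integer >= 1; each detector cell is split into this
#'   many sub-bins.
#' @return A [sinogram()] with domain `"path_length"` (dimensionless line
#'   integrals).
#' @export
forward_project <- function(image, geometry, oversample = 1L) {
  vals <- if (inherits(image, "recon_image")) {
    if (abs(image$pixel_size - geometry$pixel_size) >
        1e-6 * geometry$pixel_size)
      stop("image pixel size does not match geometry")
    image$values
  } else as.matrix(image)
  if (nrow(vals) != geometry$image_matrix)
    stop("image matrix size does not match geometry")
  oversample <- as.integer(oversample)
  if (oversample < 1L) stop("oversample must be >= 1")
  u <- detector_u(geometry, oversample)
  p <- cpp_forward_project(vals, geometry$pixel_size, view_angles(geometry),
                           geometry$source_to_iso, geometry$detector_to_iso,
                           u)
  sinogram(p, geometry, "path_length", oversample = oversample)
}

#' Rebin an oversampled detector to a coarser grid
#'
#' Each coarse bin is the mean of its `factor` fine bins.  The domain tag is
#' preserved.
#'
#' @param sino A [sinogram()].
#' @param factor Integer dividing the current bin count.
#' @return A [sinogram()] with `oversample` divided by `factor`.
#' @export
rebin_detector <- function(sino, factor) {
  factor <- as.integer(factor)
  if (factor == 1L) return(sino)
  nb <- ncol(sino$values)
  if (factor < 1L || nb %% factor != 0L)
    stop("rebin factor must divide the detector bin count")
  if (sino$oversample %% factor != 0L)
    stop("rebin factor must divide the oversample factor")
  if (sino$n_extend %% factor != 0L)
    stop("rebin factor must divide the extension length")
  nc <- nb %/% factor
  # mean over blocks of `factor` adjacent columns
  dim3 <- array(t(sino$values), dim = c(factor, nc, nrow(sino$values)))
  coarse <- t(colMeans(dim3))
  sinogram(coarse, sino$geometry, sino$domain,
           oversample = sino$oversample %/% factor,
           n_extend = sino$n_extend %/% factor)
}

# Discrete Ram-Lak kernel (spatial domain) transferred to the frequency
# domain on a zero-padded grid, with optional Hann apodization.  min_len
# keeps the pad length independent of a symmetric detector extension so
# that extending an untruncated sinogram is an exact no-op.
ramp_filter_freq <- function(n_bins, du, window = c("hann", "ramlak"),
                             min_len = 0L) {
  window <- match.arg(window)
  m <- 2L^ceiling(log2(max(2L * n_bins, min_len, 2L)))
  h <- numeric(m)
  h[1] <- 1 / (4 * du^2)
  k <- seq_len(m %/% 2L)
  odd <- k[k %% 2L == 1L]
  h[1L + odd] <- -1 / (pi * odd * du)^2
  h[m + 1L - odd] <- -1 / (pi * odd * du)^2
  H <- Re(stats::fft(h))
  H[H < 0] <- 0  # guard tiny negative round-off
  if (window == "hann") {
    fk <- pmin(seq_len(m) - 1L, m - (seq_len(m) - 1L)) / m  # cycles/sample
    H <- H * 0.5 * (1 + cos(2 * pi * fk))
  }
  H
}

# Apply the ramp filter along detector rows; returns matrix of same shape.
filter_rows <- function(values, du, window, min_len = 0L) {
  nb <- ncol(values)
  H <- ramp_filter_freq(nb, du, window, min_len)
  m <- length(H)
  padded <- matrix(0, m, nrow(values))
  padded[seq_len(nb), ] <- t(values)
  spec <- stats::mvfft(padded) * H
  filt <- Re(stats::mvfft(spec, inverse = TRUE)) / m
  t(filt[seq_len(nb), , drop = FALSE]) * du
}

#' Fan-beam filtered backprojection
#'
#' Standard flat-detector fan-beam FBP: detector coordinates are referenced
#' to the iso-centre line, projections are cosine pre-weighted, ramp
#' filtered (Ram-Lak, default Hann apodized) along detector rows with
#' zero-padding to at least twice the detector length, and backprojected
#' with inverse-square distance weighting.  A full rotation contributes
#' each ray twice, which the view weight accounts for.
#'
#' @param sino A [sinogram()] in domain `"path_length"` or
#'   `"log_projection"` (both are attenuation line integrals).
#' @param geometry Optional [scan_geometry()]; defaults to the sinogram's.
#' @param window Ramp apodization: `"hann"` (default) or `"ramlak"`.
#' @param mask_fov If `TRUE`, zero pixels outside the scan FOV radius.
#' @return A [recon_image()] in mm^-1.
#' @export
fbp_reconstruct <- function(sino, geometry = sino$geometry,
                            window = c("hann", "ramlak"),
                            mask_fov = FALSE) {
  window <- match.arg(window)
  if (sino$domain == "intensity")
    stop("intensity sinograms must be log-transformed before FBP")
  if (nrow(sino$values) != geometry$n_views)
    stop("sinogram view count inconsistent with geometry")
  mag <- iso_scale(geometry)
  du_iso <- geometry$detector_cell_size / sino$oversample * mag
  nb <- ncol(sino$values)
  u_iso <- (seq_len(nb) - 0.5 - nb / 2) * du_iso
  rs <- geometry$source_to_iso
  cosw <- rs / sqrt(rs^2 + u_iso^2)
  weighted <- sweep(sino$values, 2L, cosw, "*")
  native <- nb - 2L * sino$n_extend
  filtered <- filter_rows(weighted, du_iso, window, min_len = 4L * native)
  img <- cpp_backproject_fbp(filtered, view_angles(geometry), rs,
                             u_iso[1], du_iso, geometry$image_matrix,
                             geometry$pixel_size)
  dbeta <- geometry$angular_range / geometry$n_views
  img <- img * dbeta * (2 * pi / geometry$angular_range) / 2
  out <- recon_image(img, geometry$pixel_size, scan_fov_radius(geometry))
  if (mask_fov) out$values[!fov_mask(out)] <- 0
  out
}

#' Unfiltered adjoint backprojection
#'
#' Exact matrix transpose of [forward_project()]; used for algebraic checks
#' and gradient-style computations, not for reconstruction.
#'
#' @param sino A [sinogram()].
#' @param geometry Optional [scan_geometry()]; defaults to the sinogram's.
#' @return A [recon_image()] (arbitrary units).
#' @export
backproject_adjoint <- function(sino, geometry = sino$geometry) {
  if (sino$n_extend > 0L) stop("adjoint of an extended detector is undefined")
  u <- detector_u(geometry, sino$oversample)
  img <- cpp_backproject_adjoint(sino$values, geometry$image_matrix,
                                 geometry$pixel_size, view_angles(geometry),
                                 geometry$source_to_iso,
                                 geometry$detector_to_iso, u)
  recon_image(img, geometry$pixel_size, scan_fov_radius(geometry))
}
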