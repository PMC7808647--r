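#' Fan-beam scan geometry
#'
#' Describes a 2-D flat-detector fan-beam acquisition together with the
#' reconstruction grid.  All lengths are millimetres, angles radians.
#'
#' Two named presets are available through [geometry_preset()]:
#' `"conventional"` (source-to-iso 700 mm, detector-to-iso 500 mm, 720
#' views, 1024 detector cells of 0.388 mm, 512 x 512 image of 358.4 mm
#' extent) and `"dental"` (500 mm, 200 mm, 720 views, 512 cells of
#' 0.388 mm, 512 x 512 image of 143.36 mm extent).
#'
#' @param source_to_iso Source to iso-centre distance (mm).
#' @param detector_to_iso Detector to iso-centre distance (mm).
#' @param n_views Number of projection views over `angular_range`.
#' @param detector_cell_size Width of one detector cell (mm).
#' @param n_detectors Number of detector cells.
#' @param image_extent Side length of the square reconstruction grid (mm).
#' @param image_matrix Number of pixels per image side.
#' @param pixel_size Pixel side length (mm); must equal
#'   `image_extent / image_matrix`.
#' @param angular_range Total angular coverage (radians); default full
#'   rotation.
#' @param fov_diameter Diameter of the (small) field of view (mm); defaults
#'   to `image_extent`.
#' @return An object of class `scan_geometry`.
#' @export
scan_geometry <- function(source_to_iso, detector_to_iso, n_views,
                          detector_cell_size, n_detectors,
                          image_extent, image_matrix,
                          pixel_size = image_extent / image_matrix,
                          angular_range = 2 * pi,
                          fov_diameter = image_extent) {
  num <- c(source_to_iso = source_to_iso, detector_to_iso = detector_to_iso,
           n_views = n_views, detector_cell_size = detector_cell_size,
           n_detectors = n_detectors, image_extent = image_extent,
           image_matrix = image_matrix, pixel_size = pixel_size,
           angular_range = angular_range, fov_diameter = fov_diameter)
  if (any(!is.finite(num)) || any(num <= 0))
    stop("all geometry parameters must be finite and strictly positive")
  if (abs(pixel_size * image_matrix - image_extent) >
      1e-6 * image_extent)
    stop("pixel_size * image_matrix must equal image_extent")
  g <- list(source_to_iso = source_to_iso,
            detector_to_iso = detector_to_iso,
            n_views = as.integer(n_views),
            detector_cell_size = detector_cell_size,
            n_detectors = as.integer(n_detectors),
            image_extent = image_extent,
            image_matrix = as.integer(image_matrix),
            pixel_size = pixel_size,
            angular_range = angular_range,
            fov_diameter = fov_diameter)
  class(g) <- "scan_geometry"
  g
}

#' Named geometry presets
#'
#' @param name `"conventional"` or `"dental"`.
#' @param scale Integer down-scaling factor applied to the discretization
#'   (views, detector cells, image matrix) while keeping every physical
#'   length fixed; `scale = 2` halves the computational size for quick runs.
#' @return A [scan_geometry()].
#' @export
geometry_preset <- function(name = c("conventional", "dental"), scale = 1L) {
  name <- match.arg(name)
  g <- switch(name,
    conventional = scan_geometry(700, 500, 720, 0.388, 1024, 358.4, 512),
    dental       = scan_geometry(500, 200, 720, 0.388, 512, 143.36, 512))
  if (scale != 1L) {
    s <- as.integer(scale)
    if (s < 1L || g$n_detectors %% s != 0L || g$image_matrix %% s != 0L ||
        g$n_views %% s != 0L)
      stop("scale must divide views, detector count and image matrix")
    g <- scan_geometry(g$source_to_iso, g$detector_to_iso, g$n_views %/% s,
                       g$detector_cell_size * s, g$n_detectors %/% s,
                       g$image_extent, g$image_matrix %/% s,
                       angular_range = g$angular_range,
                       fov_diameter = g$fov_diameter)
  }
  g
}

#' Geometry read/write as JSON config
#'
#' @param path File path of a JSON object using the [scan_geometry()] field
#'   names.
#' @return `read_geometry` returns a [scan_geometry()].
#' @export
read_geometry <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(scan_geometry, cfg)
}

#' @rdname read_geometry
#' @param geometry A [scan_geometry()].
#' @export
write_geometry <- function(geometry, path) {
  jsonlite::write_json(unclass(geometry), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat("scan_geometry\n")
  cat(sprintf("  source-to-iso %.1f mm, detector-to-iso %.1f mm\n",
              x$source_to_iso, x$detector_to_iso))
  cat(sprintf("  %d views over %.3f rad, %d cells of %.3f mm\n",
              x$n_views, x$angular_range, x$n_detectors,
              x$detector_cell_size))
  cat(sprintf("  image %d x %d px, %.2f mm extent (%.3f mm px)\n",
              x$image_matrix, x$image_matrix, x$image_extent, x$pixel_size))
  cat(sprintf("  scan FOV radius %.2f mm\n", scan_fov_radius(x)))
  invisible(x)
}

# magnification of the detector onto the iso-centre line
iso_scale <- function(geometry) {
  geometry$source_to_iso / (geometry$source_to_iso + geometry$detector_to_iso)
}

#' Effective scan field-of-view radius
#'
#' Radius (mm) of the region seen by every projection: the smaller of the
#' configured `fov_diameter / 2` and the radius of the circle tangent to
#' the edge rays of the fan, `R_s * h / sqrt(R_s^2 + h^2)` with `h` the
#' detector half-width projected onto the iso-centre line.  Objects beyond
#' this radius cause projection truncation.
#'
#' @param geometry A [scan_geometry()].
#' @return Radius in mm.
#' @export
scan_fov_radius <- function(geometry) {
  h <- geometry$n_detectors * geometry$detector_cell_size / 2 *
    iso_scale(geometry)
  rs <- geometry$source_to_iso
  min(geometry$fov_diameter / 2, rs * h / sqrt(rs^2 + h^2))
}

# physical detector-bin centre coordinates for an oversampled detector
detector_u <- function(geometry, oversample = 1L, n_extend = 0L) {
  cell <- geometry$detector_cell_size / oversample
  nb <- geometry$n_detectors * oversample + 2L * n_extend
  (seq_len(nb) - 0.5 - nb / 2) * cell
}

view_angles <- function(geometry) {
  seq(0, geometry$angular_range, length.out = geometry$n_views + 1L)[
    seq_len(geometry$n_views)]
}

#' Pixel-centre coordinate axes of the reconstruction grid
#'
#' @param geometry A [scan_geometry()].
#' @return Numeric vector of length `image_matrix` with the pixel-centre
#'   coordinate (mm) of each row/column, origin at iso-centre.
#' @export
image_axis <- function(geometry) {
  n <- geometry$image_matrix
  (seq_len(n) - 0.5 - n / 2) * geometry$pixel_size
}

#' Sinogram container
#'
#' A sinogram is an `n_views x n_bins` matrix tied to a geometry, an
#' integer detector oversampling factor and a domain tag telling what the
#' values are: `"path_length"` (line integrals of attenuation,
#' dimensionless), `"intensity"` (photon counts) or `"log_projection"`
#' (`-log(y / I0)`).
#'
#' @param values `n_views x n_bins` numeric matrix.
#' @param geometry A [scan_geometry()].
#' @param domain One of `"path_length"`, `"intensity"`, `"log_projection"`.
#' @param oversample Detector oversampling factor (columns =
#'   `n_detectors * oversample`, plus any symmetric extension).
#' @param n_extend Number of extension bins appended on each detector side
#'   by truncation correction (0 for measured data).
#' @return An object of class `sinogram`.
#' @export
sinogram <- function(values, geometry,
                     domain = c("path_length", "intensity",
                                "log_projection"),
                     oversample = 1L, n_extend = 0L) {
  domain <- match.arg(domain)
  values <- as.matrix(values)
  oversample <- as.integer(oversample)
  if (oversample < 1L) stop("oversample must be >= 1")
  expected <- geometry$n_detectors * oversample + 2L * as.integer(n_extend)
  if (nrow(values) != geometry$n_views || ncol(values) != expected)
    stop(sprintf("sinogram shape %d x %d inconsistent with geometry (%d x %d)",
                 nrow(values), ncol(values), geometry$n_views, expected))
  if (domain == "intensity" && any(values < 0))
    stop("intensity-domain sinogram must be non-negative")
  s <- list(values = values, geometry = geometry, domain = domain,
            oversample = oversample, n_extend = as.integer(n_extend))
  class(s) <- "sinogram"
  s
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("sinogram: %d views x %d bins [%s], oversample %d, extend %d\n",
              nrow(x$values), ncol(x$values), x$domain, x$oversample,
              x$n_extend))
  invisible(x)
}

#' Reconstructed image container
#'
#' @param values Square numeric matrix; columns index x (right), rows y.
#' @param pixel_size Pixel side (mm).
#' @param fov_radius Radius (mm) of the trustworthy field of view.
#' @param unit `"mm^-1"` (linear attenuation) or `"HU"`.
#' @return An object of class `recon_image`.
#' @export
recon_image <- function(values, pixel_size, fov_radius,
                        unit = c("mm^-1", "HU")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("recon_image must be square")
  img <- list(values = values, pixel_size = pixel_size,
              fov_radius = fov_radius, unit = unit)
  class(img) <- "recon_image"
  img
}

#' @export
print.recon_image <- function(x, ...) {
  cat(sprintf("recon_image: %d x %d px of %.3f mm [%s], FOV radius %.1f mm\n",
              nrow(x$values), ncol(x$values), x$pixel_size, x$unit,
              x$fov_radius))
  invisible(x)
}

#' Boolean mask of pixels inside the field of view
#'
#' @param image A [recon_image()].
#' @param fraction Use `fraction * fov_radius` as the mask radius.
#' @return Logical matrix, `TRUE` inside the (scaled) FOV circle.
#' @export
fov_mask <- function(image, fraction = 1) {
  n <- nrow(image$values)
  ax <- (seq_len(n) - 0.5 - n / 2) * image$pixel_size
  r2 <- outer(ax^2, ax^2, "+")  # rows y, cols x
  r2 <= (fraction * image$fov_radius)^2
}
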