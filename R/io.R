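#' Raster I/O: 32-bit float TIFF with a JSON sidecar
#'
#' Arrays are written as 32-bit TIFF pages.  Because the TIFF writer
#' stores values in `[0, 1]`, each page is affinely normalized on write
#' and the `(offset, scale)` pair is recorded in the JSON sidecar
#' (`<path>.json`) together with units, domain tags and geometry, so the
#' read side restores physical values.
#'
#' @param values Numeric matrix (or list of matrices for a multi-page
#'   file).
#' @param path Output TIFF path; the sidecar is written at `<path>.json`.
#' @param meta List of metadata stored in the sidecar.
#' @return Invisibly, `path`.
#' @keywords internal
write_raster <- function(values, path, meta = list()) {
  pages <- if (is.list(values)) values else list(values)
  norm <- lapply(pages, function(m) {
    lo <- min(m); hi <- max(m)
    scale <- if (hi > lo) hi - lo else 1
    list(data = (m - lo) / scale, offset = lo, scale = scale)
  })
  tiff::writeTIFF(lapply(norm, `[[`, "data"), path,
                  bits.per.sample = 32L, reduce = FALSE)
  meta$pages <- lapply(norm, function(p)
    list(offset = p$offset, scale = p$scale))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_raster
#' @keywords internal
read_raster <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"),
                              simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  offs <- meta$pages$offset
  scls <- meta$pages$scale
  data <- lapply(seq_along(pages), function(i)
    pages[[i]] * scls[i] + offs[i])
  list(pages = data, meta = meta)
}

#' Write / read a sinogram as float TIFF + JSON sidecar
#'
#' @param sino A [sinogram()].
#' @param path TIFF file path.
#' @return `read_sinogram` returns the [sinogram()].
#' @export
write_sinogram <- function(sino, path) {
  write_raster(sino$values, path,
               meta = list(type = "sinogram", domain = sino$domain,
                           oversample = sino$oversample,
                           n_extend = sino$n_extend,
                           geometry = unclass(sino$geometry)))
}

#' @rdname write_sinogram
#' @export
read_sinogram <- function(path) {
  r <- read_raster(path)
  g <- do.call(scan_geometry, r$meta$geometry[
    c("source_to_iso", "detector_to_iso", "n_views", "detector_cell_size",
      "n_detectors", "image_extent", "image_matrix", "pixel_size",
      "angular_range", "fov_diameter")])
  sinogram(r$pages[[1]], g, r$meta$domain,
           oversample = r$meta$oversample, n_extend = r$meta$n_extend)
}

#' Write / read a reconstructed image as float TIFF + JSON sidecar
#'
#' @param image A [recon_image()].
#' @param path TIFF file path.
#' @return `read_recon_image` returns the [recon_image()].
#' @export
write_recon_image <- function(image, path) {
  write_raster(image$values, path,
               meta = list(type = "recon_image", unit = image$unit,
                           pixel_size = image$pixel_size,
                           fov_radius = image$fov_radius))
}

#' @rdname write_recon_image
#' @export
read_recon_image <- function(path) {
  r <- read_raster(path)
  recon_image(r$pages[[1]], r$meta$pixel_size, r$meta$fov_radius,
              unit = r$meta$unit)
}

#' Write / read a material phantom as multi-page float TIFF + sidecar
#'
#' One page per material (water, bone, metal); the metadata list
#' round-trips through the JSON sidecar.
#'
#' @param phantom A [material_phantom()].
#' @param path TIFF file path.
#' @return `read_phantom` returns the [material_phantom()].
#' @export
write_phantom <- function(phantom, path) {
  write_raster(list(phantom$water_map, phantom$bone_map,
                    phantom$metal_map), path,
               meta = list(type = "material_phantom",
                           pixel_size = phantom$pixel_size,
                           materials = c("water", "bone", "metal"),
                           metadata = phantom$metadata))
}

#' @rdname write_phantom
#' @export
read_phantom <- function(path) {
  r <- read_raster(path)
  md <- r$meta$metadata
  if (is.null(md)) md <- list()
  material_phantom(r$pages[[1]], r$pages[[2]], r$pages[[3]],
                   r$meta$pixel_size, metadata = md)
}
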