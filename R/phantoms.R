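#' Material phantom container
#'
#' Per-material density-fraction maps on the reconstruction grid.  A value
#' of 1 in `water_map` means one full water density (1 g/cm^3) in that
#' pixel; the maps have disjoint supports when produced by the package
#' generators.
#'
#' @param water_map,bone_map,metal_map Square numeric matrices (same
#'   dimensions), values >= 0.
#' @param pixel_size Pixel side (mm).
#' @param metadata Free-form list (metal positions, radii, ...), preserved
#'   by the TIFF/JSON round-trip.
#' @return An object of class `material_phantom`.
#' @export
material_phantom <- function(water_map, bone_map, metal_map, pixel_size,
                             metadata = list()) {
  dims <- dim(water_map)
  if (!identical(dims, dim(bone_map)) || !identical(dims, dim(metal_map)))
    stop("material maps must share dimensions")
  if (dims[1] != dims[2]) stop("material maps must be square")
  if (min(water_map, bone_map, metal_map) < 0)
    stop("material maps must be non-negative")
  p <- list(water_map = water_map, bone_map = bone_map,
            metal_map = metal_map, pixel_size = pixel_size,
            metadata = metadata)
  class(p) <- "material_phantom"
  p
}

#' @export
print.material_phantom <- function(x, ...) {
  cat(sprintf("material_phantom: %d x %d px of %.3f mm\n",
              nrow(x$water_map), ncol(x$water_map), x$pixel_size))
  for (m in c("water_map", "bone_map", "metal_map"))
    cat(sprintf("  %-10s mass fraction > 0 in %d px\n", sub("_map", "", m),
                sum(x[[m]] > 0)))
  invisible(x)
}

# pixel-centre coordinate grids (mm); rows index y, columns x
.grid_xy <- function(n, h) {
  ax <- (seq_len(n) - 0.5 - n / 2) * h
  list(x = matrix(ax, n, n, byrow = TRUE), y = matrix(ax, n, n))
}

# Anti-aliased raster of an ellipse: per-pixel coverage from the linearized
# signed distance to the boundary, so analytic line integrals through the
# raster are accurate to a small fraction of a pixel.
.raster_ellipse <- function(n, h, cx, cy, a, b, angle = 0) {
  g <- .grid_xy(n, h)
  ca <- cos(angle); sa <- sin(angle)
  xr <- (g$x - cx) * ca + (g$y - cy) * sa
  yr <- -(g$x - cx) * sa + (g$y - cy) * ca
  rho <- sqrt((xr / a)^2 + (yr / b)^2)
  grad <- sqrt((xr / a^2)^2 + (yr / b^2)^2)
  dist <- ifelse(grad > 0, (1 - rho) * rho / grad, min(a, b))
  pmin(pmax(0.5 + dist / h, 0), 1)
}

#' Rasterize a list of ellipses into a material phantom
#'
#' Each ellipse is a list with fields `material` (`"water"`, `"bone"` or
#' `"metal"`), `density` (fraction of the material's nominal density,
#' default 1), `center` (c(x, y) mm), `semiaxes` (c(a, b) mm) and optional
#' `angle` (radians).  Later ellipses overwrite earlier ones where they
#' overlap (later-wins), so inserts are listed after the background.
#'
#' @param ellipses List of ellipse specifications.
#' @param geometry A [scan_geometry()] providing the grid.
#' @return A [material_phantom()].
#' @export
make_ellipse_phantom <- function(ellipses, geometry) {
  n <- geometry$image_matrix
  h <- geometry$pixel_size
  maps <- list(water = matrix(0, n, n), bone = matrix(0, n, n),
               metal = matrix(0, n, n))
  for (e in ellipses) {
    if (!is.list(e) || is.null(e$material))
      stop("each ellipse needs a 'material' field")
    if (!e$material %in% names(maps))
      stop(sprintf("unknown material '%s'", e$material))
    dens <- if (is.null(e$density)) 1 else e$density
    ang <- if (is.null(e$angle)) 0 else e$angle
    cov <- .raster_ellipse(n, h, e$center[1], e$center[2],
                           e$semiaxes[1], e$semiaxes[2], ang)
    inside <- cov > 0
    for (m in names(maps)) maps[[m]][inside] <- 0  # later wins
    maps[[e$material]][inside] <- dens * cov[inside]
  }
  material_phantom(maps$water, maps$bone, maps$metal, h,
                   metadata = list(kind = "ellipse", n_ellipses =
                                     length(ellipses)))
}

#' Disk phantom with peripheral cylinders
#'
#' A water disk (default 250 mm diameter) carrying 32 equally spaced 5 mm
#' cylinders along its perimeter; the requested numbers of cylinders inside
#' and outside the scan field of view are made of metal, the rest of
#' bone-density material.  The disk centre is offset from the iso-centre
#' (default 40 mm along +x) so that the cylinder ring straddles the FOV
#' circle and both inside and outside slots exist.  Slot selection is
#' deterministic under `seed`.
#'
#' @param n_inside_metals,n_outside_metals Metal cylinder counts inside /
#'   outside the scan FOV.
#' @param geometry A [scan_geometry()].
#' @param seed Integer controlling which slots become metal.
#' @param disk_diameter Water disk diameter (mm).
#' @param cyl_diameter Cylinder diameter (mm).
#' @param n_cylinders Total cylinder count.
#' @param center Disk centre offset c(x, y) from iso-centre (mm).
#' @param slot_rotation Angular offset (radians) of slot 1.
#' @return A [material_phantom()] whose metadata records slot positions,
#'   radii and the metal assignment.
#' @export
make_disk_phantom <- function(n_inside_metals, n_outside_metals, geometry,
                              seed = 1L, disk_diameter = 250,
                              cyl_diameter = 5, n_cylinders = 32L,
                              center = c(40, 0), slot_rotation = 0) {
  if (n_inside_metals < 0 || n_outside_metals < 0 ||
      n_inside_metals + n_outside_metals > n_cylinders)
    stop("metal counts must be non-negative and fit the cylinder slots")
  ring_r <- disk_diameter / 2 - cyl_diameter  # centres, small rim margin
  th <- slot_rotation + 2 * pi * (seq_len(n_cylinders) - 1L) / n_cylinders
  sx <- center[1] + ring_r * cos(th)
  sy <- center[2] + ring_r * sin(th)
  fov_r <- scan_fov_radius(geometry)
  inside <- sqrt(sx^2 + sy^2) < fov_r
  if (sum(inside) < n_inside_metals)
    stop(sprintf("only %d cylinder slots inside the FOV", sum(inside)))
  if (sum(!inside) < n_outside_metals)
    stop(sprintf("only %d cylinder slots outside the FOV", sum(!inside)))
  pick <- with_seed(seed, {
    c(sample(which(inside), n_inside_metals),
      sample(which(!inside), n_outside_metals))
  })
  spec <- list(list(material = "water", center = center,
                    semiaxes = rep(disk_diameter / 2, 2)))
  for (k in seq_len(n_cylinders)) {
    mat <- if (k %in% pick) "metal" else "bone"
    spec <- c(spec, list(list(material = mat, center = c(sx[k], sy[k]),
                              semiaxes = rep(cyl_diameter / 2, 2))))
  }
  ph <- make_ellipse_phantom(spec, geometry)
  ph$metadata <- list(kind = "disk",
                      disk_diameter = disk_diameter,
                      cyl_diameter = cyl_diameter,
                      center = center,
                      slot_x = sx, slot_y = sy,
                      slot_inside_fov = inside,
                      metal_slots = sort(pick),
                      n_inside_metals = n_inside_metals,
                      n_outside_metals = n_outside_metals,
                      seed = seed)
  ph
}

smoothstep <- function(x) {
  t <- pmin(pmax(x, 0), 1)
  t * t * (3 - 2 * t)
}

#' Smooth anatomy-like phantom with an optional metal insert
#'
#' A water disk with a smooth (smoothstep-tapered) boundary, an optional
#' soft-edged bone insert and an optional sharp metal insert.  Soft edges
#' make the object band-limited, which is the regime where filtered
#' backprojection and re-projection are mutually consistent; the phantom
#' is used to study the pipelines away from hard-cylinder edge effects.
#'
#' @param geometry A [scan_geometry()].
#' @param radius Water disk outer radius (mm).
#' @param taper Width of the smooth boundary roll-off (mm).
#' @param center Water disk centre c(x, y) (mm).
#' @param bone_center,bone_radius Soft-edged bone insert (set
#'   `bone_center = NULL` to omit); density 0.9 at the core.
#' @param metal_center,metal_radius Sharp metal insert (set
#'   `metal_center = NULL` to omit).
#' @return A [material_phantom()].
#' @export
make_smooth_phantom <- function(geometry, radius = 85, taper = 15,
                                center = c(0, 0),
                                bone_center = c(-35, 20), bone_radius = 12,
                                metal_center = c(30, -15),
                                metal_radius = 2.5) {
  n <- geometry$image_matrix
  g <- .grid_xy(n, geometry$pixel_size)
  rw <- sqrt((g$x - center[1])^2 + (g$y - center[2])^2)
  water <- smoothstep((radius - rw) / taper)
  bone <- matrix(0, n, n)
  if (!is.null(bone_center)) {
    rb <- sqrt((g$x - bone_center[1])^2 + (g$y - bone_center[2])^2)
    bone <- 0.9 * smoothstep((bone_radius - rb) / (bone_radius / 2))
  }
  metal <- matrix(0, n, n)
  if (!is.null(metal_center))
    metal <- .raster_ellipse(n, geometry$pixel_size, metal_center[1],
                             metal_center[2], metal_radius, metal_radius)
  water[metal > 0] <- 0
  bone[metal > 0] <- 0
  water[bone >= 0.5] <- 0
  material_phantom(water, bone, metal, geometry$pixel_size,
                   metadata = list(kind = "smooth",
                                   radius = radius, taper = taper))
}

#' Crop a phantom to the scan field of view and drop the metal
#'
#' @param phantom A [material_phantom()].
#' @param geometry A [scan_geometry()].
#' @param keep_metal If `TRUE` only the FOV crop is applied.
#' @return A [material_phantom()].
#' @export
crop_phantom_to_fov <- function(phantom, geometry, keep_metal = FALSE) {
  n <- nrow(phantom$water_map)
  cov <- .raster_ellipse(n, phantom$pixel_size, 0, 0,
                         scan_fov_radius(geometry),
                         scan_fov_radius(geometry))
  material_phantom(phantom$water_map * cov, phantom$bone_map * cov,
                   if (keep_metal) phantom$metal_map * cov else
                     phantom$metal_map * 0,
                   phantom$pixel_size,
                   metadata = c(phantom$metadata, list(cropped_to_fov = TRUE,
                                                       metal_removed =
                                                         !keep_metal)))
}

#' Truncation-free, metal-free reference reconstruction
#'
#' The ground-truth image the quality metrics compare against: the phantom
#' is cropped to the scan FOV (so no projection is truncated), the metal is
#' removed, and the same polychromatic measurement and FBP chain is run.
#'
#' @inheritParams simulate_measurement
#' @param window FBP apodization window.
#' @return A [recon_image()] in mm^-1, masked to the FOV.
#' @export
make_reference_image <- function(phantom, geometry,
                                 spectrum = default_spectrum(),
                                 atten =
                                   attenuation_table(spectrum$energies),
                                 noise = noise_model(),
                                 window = "hann") {
  cropped <- crop_phantom_to_fov(phantom, geometry, keep_metal = FALSE)
  sino <- simulate_measurement(cropped, geometry, spectrum, atten, noise)
  fbp_reconstruct(sino, geometry, window = window, mask_fov = TRUE)
}
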