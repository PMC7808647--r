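# Small geometries and phantoms shared across test files.  All fixtures are
# generated in code; nothing is read from disk.

# tiny geometry for algebraic tests (64 x 64 image, 90 views, 128 bins)
tiny_geometry <- function(n_views = 90L, n_det = 128L, n_img = 64L) {
  scan_geometry(700, 500, n_views, 0.388 * 1024 / n_det, n_det,
                358.4, n_img)
}

# half-scale conventional preset used for pipeline-level tests
fast_geometry <- function() geometry_preset("conventional", scale = 2L)

# analytic centered disk image (mm^-1) on a geometry grid
disk_image <- function(geometry, radius = 50, mu = 0.02,
                       center = c(0, 0)) {
  ph <- make_ellipse_phantom(list(list(material = "water",
                                       center = center,
                                       semiaxes = rep(radius, 2))),
                             geometry)
  ph$water_map * mu
}

# delta spectrum concentrated at one energy bin of the default grid
delta_spectrum <- function(at_keV = 60) {
  e <- seq(10, 120, by = 10)
  xray_spectrum(e, as.numeric(e == at_keV))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / max(abs(expected), 1e-300), tol)
}
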