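test_that("ellipse rasterization matches the analytic area", {
  g <- geometry_preset("conventional")
  ph <- make_ellipse_phantom(list(list(material = "water",
                                       center = c(10, -20),
                                       semiaxes = c(80, 50),
                                       angle = 0.4)), g)
  area <- sum(ph$water_map) * g$pixel_size^2
  expect_rel_equal(area, pi * 80 * 50, 0.01)
  expect_equal(max(ph$bone_map), 0)
})

test_that("ellipse phantom semantics: empty spec, later wins, unknown name", {
  g <- tiny_geometry()
  empty <- make_ellipse_phantom(list(), g)
  expect_equal(max(empty$water_map, empty$bone_map, empty$metal_map), 0)
  ph <- make_ellipse_phantom(list(
    list(material = "bone", center = c(0, 0), semiaxes = c(30, 30)),
    list(material = "metal", center = c(0, 0), semiaxes = c(10, 10))), g)
  ax <- image_axis(g)
  r <- sqrt(outer(ax^2, ax^2, "+"))
  expect_true(all(ph$metal_map[r < 8] > 0))
  expect_true(all(ph$bone_map[r < 8] == 0))   # metal overwrote bone
  expect_true(all(ph$bone_map[r > 12 & r < 28] > 0))
  expect_error(make_ellipse_phantom(list(list(material = "wood",
                                              center = c(0, 0),
                                              semiaxes = c(5, 5))), g),
               "unknown material")
})

test_that("disk phantom honors the requested metal layout", {
  g <- fast_geometry()
  ph <- make_disk_phantom(3, 1, g, seed = 5)
  md <- ph$metadata
  expect_equal(length(md$metal_slots), 4L)
  expect_equal(sum(md$slot_inside_fov[md$metal_slots]), 3L)
  expect_equal(sum(!md$slot_inside_fov[md$metal_slots]), 1L)
  # slot centre radii: one metal centre beyond the scan FOV radius
  rr <- sqrt(md$slot_x^2 + md$slot_y^2)[md$metal_slots]
  expect_equal(sum(rr > scan_fov_radius(g)), 1L)
  # always 32 cylinders in total (bone + metal)
  expect_equal(length(md$slot_x), 32L)
  # no metal request -> no metal anywhere
  ph0 <- make_disk_phantom(0, 0, g, seed = 5)
  expect_equal(max(ph0$metal_map), 0)
  expect_error(make_disk_phantom(30, 10, g), "fit")
})

test_that("disk phantom generation is deterministic under seed", {
  g <- fast_geometry()
  a <- make_disk_phantom(3, 2, g, seed = 9)
  b <- make_disk_phantom(3, 2, g, seed = 9)
  expect_identical(a$metal_map, b$metal_map)
  c <- make_disk_phantom(3, 2, g, seed = 10)
  expect_false(identical(a$metadata$metal_slots, c$metadata$metal_slots))
})

test_that("rotating the slot layout rotates the phantom maps", {
  g <- fast_geometry()
  a <- make_disk_phantom(0, 0, g, seed = 1, center = c(0, 0),
                         slot_rotation = 0)
  b <- make_disk_phantom(0, 0, g, seed = 1, center = c(0, 0),
                         slot_rotation = pi / 2)
  # quarter-turn of the slot ring = transpose-flip of the bone map for a
  # centred phantom on a square grid
  rot90 <- function(m) t(m)[, rev(seq_len(ncol(m)))]
  expect_lt(mean(abs(b$bone_map - rot90(a$bone_map))),
            1e-3 * max(a$bone_map))
})

test_that("FOV crop removes out-of-FOV material and metal", {
  g <- fast_geometry()
  ph <- make_disk_phantom(2, 2, g, seed = 3)
  cr <- crop_phantom_to_fov(ph, g)
  expect_equal(max(cr$metal_map), 0)
  ax <- image_axis(g)
  r <- sqrt(outer(ax^2, ax^2, "+"))
  expect_equal(max(cr$water_map[r > scan_fov_radius(g) + 2]), 0)
  # inside material untouched
  inner <- r < scan_fov_radius(g) - 2
  expect_equal(cr$water_map[inner], ph$water_map[inner])
})

test_that("reference image is metal-free, truncation-free and seeded", {
  g <- fast_geometry()
  ph <- make_disk_phantom(3, 1, g, seed = 2)
  at <- attenuation_table(metal = "steel")
  ref1 <- make_reference_image(ph, g, atten = at,
                               noise = noise_model(seed = 4))
  ref2 <- make_reference_image(ph, g, atten = at,
                               noise = noise_model(seed = 4))
  expect_identical(ref1$values, ref2$values)
  # nothing at the metal level anywhere in the reference: bone can top
  # 2000 HU under beam hardening, but metal reconstructs an order of
  # magnitude higher (~0.35 mm^-1 for steel)
  thr <- mu_water_at(60) * 5  # 4000 HU
  expect_lt(max(ref1$values), thr)
})

test_that("reference equals plain reconstruction when cropping is a no-op", {
  g <- fast_geometry()
  ph <- make_ellipse_phantom(list(list(material = "water",
                                       center = c(0, 0),
                                       semiaxes = c(70, 70))), g)
  nm <- noise_model(enabled = FALSE)
  ref <- make_reference_image(ph, g, noise = nm)
  plain <- fbp_reconstruct(simulate_measurement(ph, g, noise = nm), g,
                           mask_fov = TRUE)
  expect_equal(ref$values, plain$values, tolerance = 1e-6)
})
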