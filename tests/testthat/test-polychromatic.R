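test_that("spectrum constructor normalizes and validates", {
  s <- xray_spectrum(c(10, 20, 30), c(2, 2, 4))
  expect_equal(sum(s$weights), 1)
  expect_equal(s$weights, c(0.25, 0.25, 0.5))
  expect_error(xray_spectrum(c(10, 10, 30), c(1, 1, 1)), "increasing")
  expect_error(xray_spectrum(c(10, 20), c(1, -1)), "non-negative")
})

test_that("attenuation table obeys the physical ordering invariants", {
  at <- attenuation_table()
  e <- attr(at, "energies")
  expect_true(all(at > 0))
  expect_true(all(at[, "metal"] > at[, "bone"]))
  expect_true(all(at[, "bone"] > at[, "water"]))
  over30 <- e >= 30
  expect_true(all(diff(at[over30, "water"]) < 0))
  expect_true(all(diff(at[over30, "bone"]) < 0))
  # steel alternative keeps ordering too
  st <- attenuation_table(metal = "steel")
  expect_true(all(st[, "metal"] > st[, "bone"]))
})

test_that("polychromatic intensity reduces to closed forms", {
  g <- tiny_geometry()
  zero <- sinogram(matrix(0, g$n_views, g$n_detectors), g, "path_length")
  spec <- default_spectrum()
  at <- attenuation_table(spec$energies)
  # all paths zero -> I0 everywhere
  I <- polychromatic_intensity(list(water = zero), spec, at, I0 = 1e5)
  expect_equal(max(abs(I$values - 1e5)), 0, tolerance = 1e-9)
  # delta spectrum: monochromatic Beer-Lambert
  d <- zero; d$values[] <- 25
  spec60 <- delta_spectrum(60)
  at60 <- attenuation_table(spec60$energies)
  I60 <- polychromatic_intensity(list(water = d), spec60, at60, I0 = 1e5)
  expect_equal(I60$values[1, 1],
               as.numeric(1e5 * exp(-at60[6, "water"] * 25)),
               tolerance = 1e-12)
  # two-bin spectrum equals the mean of the monochromatic intensities
  spec2 <- xray_spectrum(c(40, 80), c(0.5, 0.5))
  at2 <- attenuation_table(spec2$energies)
  I2 <- polychromatic_intensity(list(water = d), spec2, at2, I0 = 1e5)
  oracle <- as.numeric(0.5 * 1e5 * (exp(-at2[1, "water"] * 25) +
                                      exp(-at2[2, "water"] * 25)))
  expect_equal(I2$values[1, 1], oracle, tolerance = 1e-12)
  # intensities invariant under rescaling of raw weights
  spec2b <- xray_spectrum(c(40, 80), c(7, 7))
  expect_equal(polychromatic_intensity(list(water = d), spec2b, at2,
                                       1e5)$values, I2$values)
  dneg <- d; dneg$values[1, 1] <- -1
  expect_error(polychromatic_intensity(list(water = dneg), spec2, at2),
               "non-negative")
})

test_that("Poisson noise is reproducible and has correct moments", {
  g <- tiny_geometry(n_views = 100L, n_det = 1000L)
  I <- sinogram(matrix(1000, 100, 1000), g, "intensity")
  nm <- noise_model(I0 = 1e5, seed = 77)
  y1 <- apply_poisson(I, nm)
  y2 <- apply_poisson(I, nm)
  expect_identical(y1$values, y2$values)
  draws <- as.numeric(y1$values)  # 1e5 draws at I = 1000
  expect_rel_equal(mean(draws), 1000, 0.01)
  expect_rel_equal(var(draws), 1000, 0.05)
  # disabled noise passes expected counts through
  expect_identical(apply_poisson(I, noise_model(enabled = FALSE))$values,
                   I$values)
})

test_that("log transform inverts the exponential and floors zero counts", {
  g <- tiny_geometry()
  y <- sinogram(matrix(1e5, g$n_views, g$n_detectors), g, "intensity")
  expect_equal(max(abs(log_projection(y, 1e5)$values)), 0)
  y$values[] <- 1e5 * exp(-2)
  expect_equal(log_projection(y, 1e5)$values[1, 1], 2, tolerance = 1e-12)
  y$values[] <- 0
  expect_equal(log_projection(y, 1e5, floor_counts = 0.5)$values[1, 1],
               log(2 * 1e5), tolerance = 1e-12)
})

test_that("soft-threshold decomposition matches its defining formula", {
  x <- matrix(c(80, 660, 370, -500, 0, 1000), 2)
  dec <- soft_threshold_decompose(x, T1 = 80, T2 = 660)
  expect_equal(dec$w[1, 1], 0)     # at T1
  expect_equal(dec$bone[1, 1], 0)
  expect_equal(dec$water[1, 1], 80)
  expect_equal(dec$w[2, 1], 1)     # at T2
  expect_equal(dec$bone[2, 1], 660)
  expect_equal(dec$water[2, 1], 0)
  expect_equal(dec$w[1, 2], 0.5)   # midpoint
  expect_equal(dec$bone[1, 2], 185)
  expect_equal(dec$water[1, 2], 185)
  # conservation holds at every pixel, including out-of-range values
  expect_equal(dec$bone + dec$water, x, tolerance = 1e-12)
  expect_error(soft_threshold_decompose(x, T1 = 700, T2 = 660), "below")
})

test_that("monochromatic chain matches an independent single-energy oracle", {
  g <- geometry_preset("conventional", scale = 4L)  # 128 px quick
  ph <- make_ellipse_phantom(list(
    list(material = "water", center = c(0, 0), semiaxes = c(60, 45)),
    list(material = "bone", center = c(20, 0), semiaxes = c(10, 10))),
    g)
  spec <- delta_spectrum(60)
  at <- attenuation_table(spec$energies)
  got <- simulate_measurement(ph, g, spec, at,
                              noise_model(enabled = FALSE))
  # oracle: project the monochromatic attenuation image directly
  mu_img <- ph$water_map * at[6, "water"] + ph$bone_map * at[6, "bone"]
  oracle <- forward_project(mu_img, g)
  expect_equal(got$values, oracle$values, tolerance = 1e-10)
})

test_that("beam hardening makes log projections sub-linear in thickness", {
  g <- tiny_geometry()
  d <- sinogram(matrix(100, g$n_views, g$n_detectors), g, "path_length")
  d2 <- d; d2$values <- d$values * 2
  spec <- default_spectrum()
  at <- attenuation_table(spec$energies)
  p1 <- log_projection(apply_poisson(polychromatic_intensity(
    list(water = d), spec, at, 1e5), noise_model(enabled = FALSE)), 1e5)
  p2 <- log_projection(apply_poisson(polychromatic_intensity(
    list(water = d2), spec, at, 1e5), noise_model(enabled = FALSE)), 1e5)
  expect_lt(p2$values[1, 1], 2 * p1$values[1, 1])
})

test_that("polychromatic water disk shows cupping, absent monochromatically", {
  g <- geometry_preset("conventional", scale = 4L)
  ph <- make_ellipse_phantom(list(list(material = "water",
                                       center = c(0, 0),
                                       semiaxes = c(80, 80))), g)
  spec <- default_spectrum()
  at <- attenuation_table(spec$energies)
  rec_poly <- fbp_reconstruct(simulate_measurement(
    ph, g, spec, at, noise_model(enabled = FALSE)), g)
  ax <- image_axis(g)
  r <- sqrt(outer(ax^2, ax^2, "+"))
  center <- r < 15
  edge <- r > 60 & r < 74
  expect_lt(mean(rec_poly$values[center]), mean(rec_poly$values[edge]))
  spec1 <- delta_spectrum(60)
  rec_mono <- fbp_reconstruct(simulate_measurement(
    ph, g, spec1, attenuation_table(spec1$energies),
    noise_model(enabled = FALSE)), g)
  cup_poly <- mean(rec_poly$values[edge]) - mean(rec_poly$values[center])
  cup_mono <- mean(rec_mono$values[edge]) - mean(rec_mono$values[center])
  expect_lt(abs(cup_mono), 0.1 * cup_poly)
})

test_that("objects wider than the FOV leave signal at the detector edges", {
  g <- geometry_preset("conventional", scale = 2L)
  ph <- make_disk_phantom(0, 0, g, seed = 1)  # 250 mm disk > 232 mm FOV
  meas <- simulate_measurement(ph, g, noise = noise_model(enabled = FALSE))
  expect_gt(max(abs(meas$values[, 1])), 0.5)
  expect_gt(max(abs(meas$values[, ncol(meas$values)])), 0.5)
})
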