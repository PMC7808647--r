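#' X-ray source spectrum
#'
#' A binned photon-fluence spectrum: strictly increasing energies (keV) and
#' non-negative relative weights, normalized to sum to one on construction
#' so that intensities are invariant under rescaling of the raw weights.
#'
#' @param energies Energies in keV, strictly increasing.
#' @param weights Relative fluence per bin, any non-negative scale.
#' @return An object of class `xray_spectrum`.
#' @export
xray_spectrum <- function(energies, weights) {
  if (length(energies) != length(weights))
    stop("energies and weights must have equal length")
  if (any(diff(energies) <= 0)) stop("energies must be strictly increasing")
  if (any(weights < 0)) stop("spectrum weights must be non-negative")
  s <- sum(weights)
  if (s <= 0) stop("spectrum must have positive total weight")
  out <- list(energies = as.numeric(energies),
              weights = as.numeric(weights) / s)
  class(out) <- "xray_spectrum"
  out
}

# NIST mass attenuation of aluminium (cm^2/g) for the inherent-filtration
# model of the default tube spectrum.
.al_mu_rho <- function(energies) {
  e <- c(10, 20, 30, 40, 50, 60, 70, 80, 90, 100, 110, 120)
  v <- c(26.23, 3.441, 1.128, 0.5685, 0.3681, 0.2778, 0.2336, 0.2018,
         0.1856, 0.1704, 0.1632, 0.1570)
  exp(stats::approx(log(e), log(v), xout = log(energies), rule = 2)$y)
}

#' Default 120 kVp tungsten-anode spectrum
#'
#' Analytic bremsstrahlung approximation: Kramers' law photon fluence
#' `(kvp - E) / E` hardened by an aluminium inherent-filtration factor,
#' binned to the requested energies (default twelve 10 keV bins from 10 to
#' 120 keV).  This is a generic stand-in for a measured tube spectrum; any
#' user-supplied table can be used instead via [read_spectrum()].
#'
#' @param kvp Tube voltage (kV); photons above it get zero weight.
#' @param energies Bin energies in keV.
#' @param filtration_mm_al Aluminium-equivalent filtration thickness (mm).
#' @return An [xray_spectrum()].
#' @export
default_spectrum <- function(kvp = 120, energies = seq(10, 120, by = 10),
                             filtration_mm_al = 2.5) {
  w <- pmax(kvp - energies, 0) / energies
  atten <- exp(-.al_mu_rho(energies) * 2.699 * filtration_mm_al / 10)
  xray_spectrum(energies, w * atten)
}

#' @export
print.xray_spectrum <- function(x, ...) {
  cat(sprintf("xray_spectrum: %d bins, %g-%g keV, mean %.1f keV\n",
              length(x$energies), min(x$energies), max(x$energies),
              sum(x$energies * x$weights)))
  invisible(x)
}

#' Read a spectrum from a delimited text table
#'
#' Expects a header line and two columns: energy (keV) and relative weight,
#' whitespace- or comma-delimited; lines starting with `#` are ignored.
#'
#' @param path File path.
#' @return An [xray_spectrum()].
#' @export
read_spectrum <- function(path) {
  tab <- utils::read.table(path, header = TRUE, comment.char = "#",
                           sep = "", stringsAsFactors = FALSE)
  if (ncol(tab) == 1L)
    tab <- utils::read.csv(path, comment.char = "#")
  xray_spectrum(tab[[1]], tab[[2]])
}

#' Per-material linear attenuation table
#'
#' Linear attenuation mu(E) in mm^-1 for the simulation materials, on the
#' spectrum's energy grid.  The shipped default interpolates the packaged
#' NIST-derived mass-attenuation table (water, cortical bone, gold) in
#' log-log space and applies the material densities.
#'
#' @param energies Energies (keV) at which to tabulate.
#' @param metal Which table column plays the metal role: `"gold"`
#'   (default; dense implant metal) or `"steel"` (iron; typical bench-
#'   phantom insert).  Ignored when the table has an explicit `metal`
#'   column.
#' @param densities Named vector of densities in g/cm^3 for `water`,
#'   `bone`, `metal`; the metal density defaults to 19.3 (gold) or 7.87
#'   (steel).
#' @param path Optional path to a mass-attenuation table with a header
#'   naming the materials (first column energy in keV, values in cm^2/g);
#'   defaults to the packaged NIST-derived table.
#' @return An object of class `attenuation_table`: a matrix (energy x
#'   material) in mm^-1 with columns `water`, `bone`, `metal` and an
#'   `energies` attribute.
#' @export
attenuation_table <- function(energies = seq(10, 120, by = 10),
                              metal = c("gold", "steel"),
                              densities = NULL,
                              path = NULL) {
  metal <- match.arg(metal)
  if (is.null(densities))
    densities <- c(water = 1.0, bone = 1.92,
                   metal = if (metal == "steel") 7.87 else 19.3)
  if (is.null(path))
    path <- system.file("extdata", "mass_attenuation.txt",
                        package = "smallfovmar", mustWork = TRUE)
  tab <- utils::read.table(path, header = TRUE, comment.char = "#")
  e0 <- tab[[1]]
  cols <- names(tab)[-1]
  if (length(cols) < 3L) stop("attenuation table needs three materials")
  # map table columns onto the water/bone/metal roles by position if the
  # canonical names are absent
  pick <- function(nm, idx) if (nm %in% cols) tab[[nm]] else tab[[cols[idx]]]
  mass <- cbind(water = pick("water", 1L), bone = pick("bone", 2L),
                metal = if ("metal" %in% cols) tab[["metal"]] else
                  if (metal %in% cols) tab[[metal]] else tab[[cols[3L]]])
  interp <- function(v)
    exp(stats::approx(log(e0), log(v), xout = log(energies), rule = 2)$y)
  mu <- apply(mass, 2L, interp)
  mu <- matrix(mu, nrow = length(energies),
               dimnames = list(NULL, c("water", "bone", "metal")))
  # mass attenuation cm^2/g * density g/cm^3 -> cm^-1 -> mm^-1
  mu <- sweep(mu, 2L, densities[c("water", "bone", "metal")] / 10, "*")
  if (any(mu < 0) || any(!is.finite(mu)))
    stop("attenuation coefficients must be finite and non-negative")
  structure(mu, energies = as.numeric(energies),
            class = c("attenuation_table", "matrix"))
}

#' Linear attenuation of water at a reference energy
#'
#' Used for the HU scale: `HU = 1000 * (mu - mu_water) / mu_water`.
#'
#' @param energy_keV Effective energy (default 60 keV).
#' @return mu_water in mm^-1.
#' @export
mu_water_at <- function(energy_keV = 60) {
  at <- attenuation_table(energies = energy_keV)
  as.numeric(at[1, "water"])
}

#' Convert between linear attenuation and Hounsfield units
#'
#' @param image A [recon_image()].
#' @param energy_keV Effective energy defining `mu_water`.
#' @return A [recon_image()] in the other unit.
#' @export
to_hu <- function(image, energy_keV = 60) {
  if (image$unit == "HU") return(image)
  muw <- mu_water_at(energy_keV)
  recon_image(1000 * (image$values - muw) / muw, image$pixel_size,
              image$fov_radius, unit = "HU")
}

#' @rdname to_hu
#' @export
to_mu <- function(image, energy_keV = 60) {
  if (image$unit == "mm^-1") return(image)
  muw <- mu_water_at(energy_keV)
  recon_image(image$values / 1000 * muw + muw, image$pixel_size,
              image$fov_radius, unit = "mm^-1")
}
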