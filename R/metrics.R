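#' Rectangular region of interest
#'
#' 0-based, half-open pixel rectangle `[row0, row0 + height) x
#' [col0, col0 + width)`.
#'
#' @param row0,col0 Top-left corner (0-based).
#' @param height,width Extent in pixels (> 0).
#' @return An object of class `roi`.
#' @export
roi <- function(row0, col0, height, width) {
  if (height <= 0 || width <= 0) stop("ROI must be non-empty")
  if (row0 < 0 || col0 < 0) stop("ROI origin must be non-negative")
  out <- list(row0 = as.integer(row0), col0 = as.integer(col0),
              height = as.integer(height), width = as.integer(width))
  class(out) <- "roi"
  out
}

#' Default centered ROI covering half the FOV area
#'
#' A centred square whose area equals half of the FOV disk, the default
#' region for NMSE/SSIM when no study-specific ROI is given.
#'
#' @param image A [recon_image()].
#' @param fraction Fraction of the FOV disk area the square covers.
#' @return An [roi()].
#' @export
default_roi <- function(image, fraction = 0.5) {
  n <- nrow(image$values)
  side_mm <- image$fov_radius * sqrt(fraction * pi)
  side <- min(n, max(2L, as.integer(round(side_mm / image$pixel_size))))
  o <- as.integer((n - side) %/% 2L)
  roi(o, o, side, side)
}

#' Dilate a logical mask by a square structuring element
#'
#' @param mask Logical matrix.
#' @param k Dilation radius in pixels (Chebyshev distance).
#' @return Logical matrix.
#' @export
dilate_mask <- function(mask, k = 1L) {
  out <- mask
  n <- nrow(mask); m <- ncol(mask)
  for (di in -k:k) for (dj in -k:k) {
    if (di == 0L && dj == 0L) next
    ri <- pmin(pmax(seq_len(n) + di, 1L), n)
    cj <- pmin(pmax(seq_len(m) + dj, 1L), m)
    out <- out | mask[ri, cj]
  }
  out
}

.roi_values <- function(image, region) {
  v <- if (inherits(image, "recon_image")) image$values else
    as.matrix(image)
  if (region$row0 + region$height > nrow(v) ||
      region$col0 + region$width > ncol(v))
    stop("ROI exceeds image bounds")
  v[region$row0 + seq_len(region$height),
    region$col0 + seq_len(region$width)]
}

#' Normalized mean squared error
#'
#' `NMSE = mean((f - f_ref)^2) / (mean(f) * mean(f_ref))` over the ROI.
#' The normalization divides by the product of the two ROI means, so the
#' metric is invariant under a common positive rescaling of both images;
#' it is intended for strictly positive (linear-attenuation) images.
#'
#' @param f,f_ref Target and reference [recon_image()]s (or matrices) on
#'   congruent grids.
#' @param region An [roi()]; default [default_roi()] of the reference.
#' @param exclude Optional logical matrix on the image grid; `TRUE` pixels
#'   (e.g. the known metal support, which the metal-free reference cannot
#'   match) are dropped from the statistics.
#' @return Non-negative scalar; 0 iff the ROIs are identical.
#' @export
nmse <- function(f, f_ref, region = NULL, exclude = NULL) {
  if (is.null(region)) {
    if (!inherits(f_ref, "recon_image"))
      stop("a region is required for plain matrices")
    region <- default_roi(f_ref)
  }
  a <- .roi_values(f, region)
  b <- .roi_values(f_ref, region)
  if (!is.null(exclude)) {
    keep <- !.roi_values(exclude, region)
    a <- a[keep]; b <- b[keep]
  }
  denom <- mean(a) * mean(b)
  if (!is.finite(denom) || denom == 0)
    stop("NMSE undefined: product of ROI means is zero")
  mean((a - b)^2) / denom
}

#' Structural similarity (single-window)
#'
#' Global-statistics SSIM over the ROI:
#' `(2 mu_A mu_B + C1)(2 cov_AB + C2) /
#'  ((mu_A^2 + mu_B^2 + C1)(var_A + var_B + C2))`,
#' with the conventional constants `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`
#' where `L` is the dynamic range of the reference ROI.  This is the
#' one-window form (a single mean/variance/covariance over the whole ROI),
#' not the sliding-window image map.
#'
#' @inheritParams nmse
#' @param C1,C2 Stabilization constants; defaults derived from `L`.
#' @param dynamic_range Value of `L`; default the joint value range of
#'   both ROIs (symmetric in the two images, so `ssim(A, B) = ssim(B, A)`
#'   holds with default constants).
#' @return Scalar in (0, 1] for non-negative images; 1 iff identical ROIs.
#' @export
ssim <- function(f, f_ref, region = NULL, C1 = NULL, C2 = NULL,
                 dynamic_range = NULL, exclude = NULL) {
  if (is.null(region)) {
    if (!inherits(f_ref, "recon_image"))
      stop("a region is required for plain matrices")
    region <- default_roi(f_ref)
  }
  a <- .roi_values(f, region)
  b <- .roi_values(f_ref, region)
  if (!is.null(exclude)) {
    keep <- !.roi_values(exclude, region)
    a <- a[keep]; b <- b[keep]
  }
  if (is.null(dynamic_range)) dynamic_range <- diff(range(a, b))
  if (dynamic_range <= 0) dynamic_range <- max(abs(b), 1e-12)
  if (is.null(C1)) C1 <- (0.01 * dynamic_range)^2
  if (is.null(C2)) C2 <- (0.03 * dynamic_range)^2
  if (C1 <= 0 || C2 <= 0) stop("C1 and C2 must be positive")
  n <- length(a)
  mu_a <- mean(a); mu_b <- mean(b)
  va <- sum((a - mu_a)^2) / (n - 1)
  vb <- sum((b - mu_b)^2) / (n - 1)
  vab <- sum((a - mu_a) * (b - mu_b)) / (n - 1)
  (2 * mu_a * mu_b + C1) * (2 * vab + C2) /
    ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
}

#' Paired pipeline comparison on the disk phantom
#'
#' Regenerates the disk-phantom experiment: for each requested number of
#' outside-FOV metals and each noise seed, a measurement is simulated,
#' both MAR pipelines are run with both inpainting methods, and NMSE/SSIM
#' against the truncation-free metal-free reference are recorded.
#'
#' @param geometry A [scan_geometry()].
#' @param n_outside Vector of outside-FOV metal counts (default 1:3).
#' @param n_inside Inside-FOV metal count (default 3).
#' @param seeds Noise seeds (default 1:5).
#' @param pipelines Subset of `c("previous", "proposed")`.
#' @param methods Subset of `c("lmar", "nmar")`.
#' @param spectrum,atten,trunc_cfg,cfg Simulation and MAR configuration;
#'   the default attenuation table uses steel cylinders (a typical bench-
#'   phantom insert metal).
#' @param I0 Blank-scan photons per detector cell.
#' @param noise_enabled Set `FALSE` for a noiseless comparison.
#' @param region Optional [roi()]; default [default_roi()].
#' @param progress Print one line per completed case.
#' @details Because the reference removes the metal, the (dilated) true
#'   metal support is excluded from the metric statistics: those pixels
#'   hold the implant, not artifact.
#' @return A data frame with columns `phantom_variant`,
#'   `n_outside_metals`, `pipeline`, `method`, `seed`, `nmse`, `ssim`.
#' @export
run_comparison <- function(geometry = geometry_preset("conventional"),
                           n_outside = 1:3, n_inside = 3L, seeds = 1:5,
                           pipelines = c("previous", "proposed"),
                           methods = c("lmar", "nmar"),
                           spectrum = default_spectrum(),
                           atten = attenuation_table(spectrum$energies,
                                                     metal = "steel"),
                           trunc_cfg = default_truncation_config(geometry),
                           cfg = mar_config(), I0 = 1e5,
                           noise_enabled = TRUE, region = NULL,
                           progress = FALSE) {
  rows <- list()
  for (n_out in n_outside) {
    for (sd in seeds) {
      ph <- make_disk_phantom(n_inside, n_out, geometry, seed = sd)
      nm <- noise_model(I0 = I0, seed = sd * 1000L + n_out,
                        enabled = noise_enabled)
      ref <- make_reference_image(ph, geometry, spectrum, atten,
                                  noise = noise_model(
                                    I0 = I0, seed = sd * 1000L + n_out +
                                      500L, enabled = noise_enabled))
      reg <- if (is.null(region)) default_roi(ref) else region
      excl <- dilate_mask(ph$metal_map > 0, 2L)
      measured <- simulate_measurement(ph, geometry, spectrum, atten, nm)
      small_fov <- truncation_corrected_recon(measured, geometry,
                                              trunc_cfg)
      metal <- segment_metal(small_fov, cfg)
      trace <- compute_trace(metal, geometry, cfg)
      synth <- NULL
      for (pl in pipelines) {
        if (pl == "proposed" && is.null(synth))
          synth <- rebin_detector(
            forward_project(small_fov, geometry, cfg$oversample),
            cfg$oversample)
        for (me in methods) {
          res <- if (pl == "proposed")
            proposed_pipeline(measured, geometry, method = me,
                              trunc_cfg = trunc_cfg, cfg = cfg,
                              small_fov = small_fov, synthesized = synth,
                              metal_mask = metal, trace = trace)
          else
            previous_pipeline(measured, geometry, method = me,
                              trunc_cfg = trunc_cfg, cfg = cfg,
                              small_fov = small_fov,
                              metal_mask = metal, trace = trace)
          rows[[length(rows) + 1L]] <- data.frame(
            phantom_variant = "disk",
            n_outside_metals = n_out, pipeline = pl, method = me,
            seed = sd, nmse = nmse(res$image, ref, reg, exclude = excl),
            ssim = ssim(res$image, ref, reg, exclude = excl),
            stringsAsFactors = FALSE)
          if (progress)
            message(sprintf(
              "outside=%d seed=%d %s/%s: NMSE %.4f SSIM %.4f",
              n_out, sd, pl, me, rows[[length(rows)]]$nmse,
              rows[[length(rows)]]$ssim))
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Summarize a comparison table
#'
#' Mean NMSE and SSIM per (outside-metal count, method, pipeline), shaped
#' like a results table with previous/proposed columns side by side.
#'
#' @param results Data frame from [run_comparison()].
#' @return A data frame with one row per (count, method) and mean metric
#'   columns per pipeline.
#' @export
summarize_comparison <- function(results) {
  agg <- stats::aggregate(cbind(nmse, ssim) ~ n_outside_metals + method +
                            pipeline, data = results, FUN = mean)
  wide <- stats::reshape(agg, direction = "wide",
                         idvar = c("n_outside_metals", "method"),
                         timevar = "pipeline")
  wide[order(wide$n_outside_metals, wide$method), , drop = FALSE]
}
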