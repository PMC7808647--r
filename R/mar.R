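#' MAR configuration
#'
#' @param metal_threshold_hu Metal segmentation threshold (HU, default
#'   2000; separates dense implant metals from cortical bone).
#' @param bone_threshold_hu Pixels above this (HU) keep their value in the
#'   NMAR prior (default 660, the bone threshold of the soft-threshold
#'   decomposition).
#' @param air_threshold_hu Pixels below this (HU) are set to air (0 mm^-1)
#'   in the prior (default -300).
#' @param soft_clean_band_hu Soft-tissue pixels whose value deviates more
#'   than this from the soft-tissue median are considered artifact-
#'   corrupted and excluded from the prior's soft-tissue average
#'   (default 100).
#' @param prior_delta_rel Additive stabilization of the NMAR
#'   normalization, as a fraction of the prior sinogram's maximum
#'   (default 0.1): the sinogram is flattened as
#'   `(s + delta) / (prior + delta)`, which tends to `s / prior` where the
#'   prior is large and to 1 where both vanish, so the division stays
#'   bounded where the metal trace approaches the edge of the prior's
#'   support (unavoidable in small-FOV geometry).
#' @param oversample Detector oversampling factor for sinogram synthesis
#'   and trace projection (default 5).
#' @param trace_dilate Dilation of the metal trace along the detector
#'   direction, in native bins (default 1).
#' @param trace_floor Minimum metal path length (mm) for a sample to join
#'   the trace (default 1e-3).
#' @param reinsert_metal Paste the segmented metal pixels back into the
#'   final image (default `TRUE`).
#' @param hu_energy_kev Effective energy defining the HU scale.
#' @return An object of class `mar_config`.
#' @export
mar_config <- function(metal_threshold_hu = 2000,
                       bone_threshold_hu = 660,
                       air_threshold_hu = -300,
                       soft_clean_band_hu = 100,
                       prior_delta_rel = 0.1,
                       oversample = 5L,
                       trace_dilate = 1L,
                       trace_floor = 1e-3,
                       reinsert_metal = TRUE,
                       hu_energy_kev = 60) {
  if (air_threshold_hu >= bone_threshold_hu ||
      bone_threshold_hu >= metal_threshold_hu)
    stop("thresholds must satisfy air < bone < metal")
  if (prior_delta_rel <= 0) stop("prior_delta_rel must be positive")
  out <- list(metal_threshold_hu = metal_threshold_hu,
              bone_threshold_hu = bone_threshold_hu,
              air_threshold_hu = air_threshold_hu,
              soft_clean_band_hu = soft_clean_band_hu,
              prior_delta_rel = prior_delta_rel,
              oversample = as.integer(oversample),
              trace_dilate = as.integer(trace_dilate),
              trace_floor = trace_floor,
              reinsert_metal = isTRUE(reinsert_metal),
              hu_energy_kev = hu_energy_kev)
  class(out) <- "mar_config"
  out
}

#' Segment metal by simple thresholding
#'
#' @param image A [recon_image()] (mm^-1 images are converted to HU
#'   internally).
#' @param cfg A [mar_config()].
#' @return Logical matrix, `TRUE` at metal pixels.
#' @export
segment_metal <- function(image, cfg = mar_config()) {
  hu <- to_hu(image, cfg$hu_energy_kev)
  hu$values > cfg$metal_threshold_hu
}

#' Metal trace in the sinogram domain
#'
#' Forward projection of the binary metal mask; samples whose metal path
#' length exceeds a small floor belong to the trace, optionally dilated
#' along the detector direction to absorb segmentation and discretization
#' mismatch.
#'
#' @param metal_mask Logical matrix on the image grid.
#' @param geometry A [scan_geometry()].
#' @param cfg A [mar_config()].
#' @param n_extend Extension bins per side if the target sinogram is an
#'   extended one.
#' @return Logical `n_views x n_bins` matrix on the native detector grid
#'   (plus any extension).
#' @export
compute_trace <- function(metal_mask, geometry, cfg = mar_config(),
                          n_extend = 0L) {
  proj <- forward_project(metal_mask * 1.0, geometry, cfg$oversample)
  proj <- rebin_detector(proj, cfg$oversample)
  tr <- proj$values > cfg$trace_floor
  if (cfg$trace_dilate > 0L && any(tr)) {
    d <- cfg$trace_dilate
    acc <- tr
    for (s in seq_len(d)) {
      nb <- ncol(tr)
      acc[, seq_len(nb - s)] <- acc[, seq_len(nb - s)] |
        tr[, s + seq_len(nb - s)]
      acc[, s + seq_len(nb - s)] <- acc[, s + seq_len(nb - s)] |
        tr[, seq_len(nb - s)]
    }
    tr <- acc
  }
  if (n_extend > 0L) {
    pad <- matrix(FALSE, nrow(tr), n_extend)
    tr <- cbind(pad, tr, pad)
  }
  tr
}

# linear inpainting of TRUE runs within one numeric vector
.inpaint_row <- function(x, mask) {
  if (!any(mask)) return(x)
  n <- length(x)
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in which(r$values)) {
    s <- starts[i]; e <- ends[i]
    lv <- if (s > 1L) x[s - 1L] else NA_real_
    rv <- if (e < n) x[e + 1L] else NA_real_
    if (is.na(lv) && is.na(rv)) next  # fully masked row handled upstream
    if (is.na(lv)) lv <- rv
    if (is.na(rv)) rv <- lv
    k <- seq_len(e - s + 1L)
    x[s:e] <- lv + (rv - lv) * k / (e - s + 2L)
  }
  x
}

#' Linear-interpolation MAR (LMAR) inpainting
#'
#' Within each view row, every maximal run of trace samples is replaced by
#' linear interpolation between the adjacent non-trace samples (nearest-
#' value extrapolation at row ends).  Non-trace samples are returned
#' bit-exactly unchanged.  A fully traced row falls back to per-bin linear
#' interpolation along the view direction, with a warning.
#'
#' @param sino A [sinogram()].
#' @param trace Logical matrix congruent with `sino$values`.
#' @return A [sinogram()] of the same domain and shape.
#' @export
lmar_inpaint <- function(sino, trace) {
  if (!identical(dim(trace), dim(sino$values)))
    stop("trace shape must match the sinogram")
  v <- sino$values
  full <- rowSums(!trace) == 0L
  for (i in which(!full & rowSums(trace) > 0L))
    v[i, ] <- .inpaint_row(v[i, ], trace[i, ])
  if (any(full)) {
    warning(sprintf("%d fully traced view(s); interpolating along views",
                    sum(full)))
    for (j in seq_len(ncol(v))) {
      col_mask <- full  # these rows lack any in-row support at this bin
      v[, j] <- .inpaint_row(v[, j], col_mask)
    }
  }
  out <- sino
  out$values <- v
  out
}

#' Build the NMAR prior image
#'
#' From an initial (LMAR-corrected) reconstruction: bone pixels keep their
#' values, air pixels become 0, metal pixels and all remaining soft-tissue
#' pixels are set to one constant -- the mean of the soft-tissue pixels
#' judged free of metal artifact (those within `soft_clean_band_hu` of the
#' soft-tissue median).
#'
#' @param lmar_image A [recon_image()] (mm^-1 or HU).
#' @param cfg A [mar_config()].
#' @param metal_mask Optional logical matrix of metal pixels to exclude.
#' @return A [recon_image()] in mm^-1 (the prior).
#' @export
build_prior <- function(lmar_image, cfg = mar_config(),
                        metal_mask = NULL) {
  hu <- to_hu(lmar_image, cfg$hu_energy_kev)
  x <- hu$values
  inside <- fov_mask(hu)
  consider <- inside
  if (!is.null(metal_mask)) consider <- consider & !metal_mask
  soft <- consider & x > cfg$air_threshold_hu & x < cfg$bone_threshold_hu
  if (!any(soft)) stop("no soft-tissue pixels found for the prior")
  med <- stats::median(x[soft])
  clean <- soft & abs(x - med) <= cfg$soft_clean_band_hu
  if (!any(clean)) clean <- soft
  soft_value <- mean(x[clean])
  prior <- x
  prior[x <= cfg$air_threshold_hu] <- -1000        # air
  prior[soft] <- soft_value
  if (!is.null(metal_mask)) prior[metal_mask] <- soft_value
  prior[!inside] <- -1000
  out <- to_mu(recon_image(prior, hu$pixel_size, hu$fov_radius,
                           unit = "HU"), cfg$hu_energy_kev)
  out$values[out$values < 0] <- 0
  out
}

#' Normalized MAR (NMAR) inpainting
#'
#' The sinogram is flattened by the prior sinogram, LMAR-inpainted within
#' the trace, and denormalized.  The normalization is stabilized
#' additively, `s_norm = (s + delta) / (prior + delta)` with
#' `delta = prior_delta_rel * max(prior)`, so it equals `s / prior` where
#' the prior is well supported and stays bounded where the trace reaches
#' the edge of the prior's support.  Because linear interpolation commutes
#' with affine maps, a constant prior makes NMAR coincide exactly with
#' LMAR, and a prior equal to the true sinogram gives exact recovery
#' (the flattened sinogram is 1 across the trace).  Samples outside the
#' trace are returned bit-exactly unchanged.
#'
#' @param sino A [sinogram()].
#' @param prior_sino A [sinogram()] of the forward-projected prior, same
#'   shape.
#' @param trace Logical matrix congruent with the sinogram.
#' @param cfg A [mar_config()].
#' @return A [sinogram()].
#' @export
nmar_inpaint <- function(sino, prior_sino, trace, cfg = mar_config()) {
  if (!identical(dim(prior_sino$values), dim(sino$values)))
    stop("prior sinogram shape must match the sinogram")
  delta <- cfg$prior_delta_rel * max(prior_sino$values)
  if (delta <= 0) delta <- cfg$prior_delta_rel
  pr <- prior_sino$values + delta
  norm <- sino
  norm$values <- (sino$values + delta) / pr
  filled <- lmar_inpaint(norm, trace)
  out <- sino
  out$values[trace] <- (filled$values * pr - delta)[trace]
  out
}

# shared step 3: inpaint `target` sinogram given the segmentation image
.inpaint_mar <- function(target, seg_image, geometry, cfg, method,
                         metal = NULL, trace = NULL) {
  if (is.null(metal)) metal <- segment_metal(seg_image, cfg)
  if (is.null(trace))
    trace <- compute_trace(metal, geometry, cfg,
                           n_extend = target$n_extend)
  lmar <- lmar_inpaint(target, trace)
  if (method == "lmar")
    return(list(sino = lmar, metal = metal, trace = trace))
  lmar_img <- fbp_reconstruct(lmar, geometry, mask_fov = TRUE)
  prior <- build_prior(lmar_img, cfg, metal_mask = metal)
  prior_sino <- rebin_detector(
    forward_project(prior, geometry, cfg$oversample), cfg$oversample)
  if (target$n_extend > 0L) {
    pv <- prior_sino$values
    pad <- matrix(0, nrow(pv), target$n_extend)
    prior_sino <- sinogram(cbind(pad, pv, pad), geometry, "path_length",
                           oversample = prior_sino$oversample,
                           n_extend = target$n_extend)
  }
  nmar <- nmar_inpaint(target, prior_sino, trace, cfg)
  list(sino = nmar, metal = metal, trace = trace, prior = prior)
}

.finalize_image <- function(image, metal, seg_image, cfg) {
  if (cfg$reinsert_metal && any(metal))
    image$values[metal] <- seg_image$values[metal]
  image
}

#' Baseline MAR pipeline (inpainting the measured sinogram)
#'
#' The conventional small-FOV workflow: the metal is segmented on the
#' truncation-corrected reconstruction, its trace is computed, and the
#' originally measured sinogram is inpainted (LMAR, or NMAR with a prior
#' built from the LMAR result).  The inpainted measured sinogram is then
#' truncation-extended and reconstructed.  Metal objects outside the FOV
#' are invisible to the segmentation, so their traces remain in the
#' measured data and corrupt the interpolation -- the failure mode the
#' synthesized-sinogram pipeline removes.
#'
#' @param measured A measured `"log_projection"` [sinogram()].
#' @param geometry A [scan_geometry()].
#' @param method `"lmar"` or `"nmar"`.
#' @param trunc_cfg A [truncation_config()].
#' @param cfg A [mar_config()].
#' @param window FBP apodization window.
#' @param small_fov Optional precomputed truncation-corrected
#'   reconstruction of `measured` (avoids recomputation when running
#'   several methods on one measurement).
#' @param metal_mask,trace Optional precomputed metal segmentation and
#'   native-grid trace (shared across methods and pipelines for one
#'   measurement).
#' @return A list: `image` (final [recon_image()], mm^-1), `inpainted`
#'   (sinogram), `metal`, `trace`, `small_fov` (the truncation-corrected
#'   segmentation image) and `prior` (NMAR only).
#' @export
previous_pipeline <- function(measured, geometry = measured$geometry,
                              method = c("lmar", "nmar"),
                              trunc_cfg = default_truncation_config(
                                geometry),
                              cfg = mar_config(), window = "hann",
                              small_fov = NULL, metal_mask = NULL,
                              trace = NULL) {
  method <- match.arg(method)
  if (is.null(small_fov))
    small_fov <- truncation_corrected_recon(measured, geometry, trunc_cfg,
                                            window)
  res <- .inpaint_mar(measured, small_fov, geometry, cfg, method,
                      metal = metal_mask, trace = trace)
  ext <- extend_sinogram(res$sino, trunc_cfg)
  img <- fbp_reconstruct(ext, geometry, window = window, mask_fov = TRUE)
  img <- .finalize_image(img, res$metal, small_fov, cfg)
  list(image = img, inpainted = res$sino, metal = res$metal,
       trace = res$trace, small_fov = small_fov, prior = res$prior)
}

#' Small-FOV MAR pipeline (inpainting the synthesized sinogram)
#'
#' Three steps: (1) truncation-corrected reconstruction of the measured
#' sinogram gives the small-FOV image; (2) that image is forward projected
#' with a finely sampled detector (5x by default) and rebinned to the
#' native grid, yielding a consistent, truncation-free synthesized
#' sinogram; (3) metal is segmented on the small-FOV image and the
#' synthesized sinogram is inpainted (LMAR, or NMAR with a prior built
#' from the LMAR result) and reconstructed.
#'
#' @inheritParams previous_pipeline
#' @param synthesized Optional precomputed step-2 sinogram.
#' @return A list as in [previous_pipeline()], plus `synthesized` (the
#'   step-2 sinogram).
#' @export
proposed_pipeline <- function(measured, geometry = measured$geometry,
                              method = c("lmar", "nmar"),
                              trunc_cfg = default_truncation_config(
                                geometry),
                              cfg = mar_config(), window = "hann",
                              small_fov = NULL, synthesized = NULL,
                              metal_mask = NULL, trace = NULL) {
  method <- match.arg(method)
  if (is.null(small_fov))
    small_fov <- truncation_corrected_recon(measured, geometry, trunc_cfg,
                                            window)
  synth <- if (is.null(synthesized)) rebin_detector(
    forward_project(small_fov, geometry, cfg$oversample), cfg$oversample)
  else synthesized
  res <- .inpaint_mar(synth, small_fov, geometry, cfg, method,
                      metal = metal_mask, trace = trace)
  img <- fbp_reconstruct(res$sino, geometry, window = window,
                         mask_fov = TRUE)
  img <- .finalize_image(img, res$metal, small_fov, cfg)
  list(image = img, inpainted = res$sino, metal = res$metal,
       trace = res$trace, small_fov = small_fov, synthesized = synth,
       prior = res$prior)
}
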