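#' Preprocessing configuration for CT lesion volumes
#'
#' Defaults mirror standard contrast-enhanced-CT radiomics practice: resample
#' to 1 mm isotropic voxels, clip intensities to the [-100, 200] HU soft-tissue
#' window, discretize with a 25 HU bin width (12 bins over the default
#' window), crop 1 mm around the lesion, and compute Laplacian-of-Gaussian
#' channels at sigma 1-5 mm.
#'
#' @param target_spacing_mm output voxel size (mm, length 3 or scalar).
#' @param clip_lo_hu,clip_hi_hu intensity clipping window (HU).
#' @param bin_width_hu discretization bin width (HU).
#' @param crop_margin_mm margin kept around the lesion bounding box (mm).
#' @param log_sigmas_mm sigmas (mm) of the Laplacian-of-Gaussian channels.
#' @return object of class `crlm_preprocess_config`.
#' @export
preprocess_config <- function(target_spacing_mm = c(1, 1, 1),
                              clip_lo_hu = -100,
                              clip_hi_hu = 200,
                              bin_width_hu = 25,
                              crop_margin_mm = 1,
                              log_sigmas_mm = c(1, 2, 3, 4, 5)) {
  target_spacing_mm <- rep(as.numeric(target_spacing_mm), length.out = 3L)
  assert_that(all(target_spacing_mm > 0), "target_spacing_mm must be > 0",
    class = "crlmrad_config_error")
  assert_that(clip_lo_hu < clip_hi_hu, "clip_lo_hu must be < clip_hi_hu",
    class = "crlmrad_config_error")
  assert_that(bin_width_hu > 0, "bin_width_hu must be > 0",
    class = "crlmrad_config_error")
  assert_that(crop_margin_mm >= 0, "crop_margin_mm must be >= 0",
    class = "crlmrad_config_error")
  assert_that(length(log_sigmas_mm) == 0 || all(log_sigmas_mm > 0),
    "log_sigmas_mm must all be > 0", class = "crlmrad_config_error")
  structure(
    list(target_spacing_mm = target_spacing_mm,
      clip_lo_hu = clip_lo_hu, clip_hi_hu = clip_hi_hu,
      bin_width_hu = bin_width_hu, crop_margin_mm = crop_margin_mm,
      log_sigmas_mm = as.numeric(log_sigmas_mm)),
    class = "crlm_preprocess_config"
  )
}

# Trilinear (degree-1 B-spline) resampling of a crlm_volume onto an
# isotropic-or-not target spacing over the same physical extent.  Voxel
# centers sit at (i - 0.5) * spacing; out-of-range samples clamp to the edge.
resample_volume <- function(vol, target_spacing, method = c("linear", "nearest")) {
  method <- match.arg(method)
  sp_in <- spacing_of(vol)
  d_in <- dim(vol)
  d_out <- pmax(1L, as.integer(round(d_in * sp_in / target_spacing)))
  if (all(d_out == d_in) && all(abs(sp_in - target_spacing) < 1e-12)) {
    return(vol)
  }
  # continuous input index of each output voxel center: (j-0.5)*sp_out/sp_in + 0.5
  ix <- (voxel_centers(d_out[1], target_spacing[1])) / sp_in[1] + 0.5
  iy <- (voxel_centers(d_out[2], target_spacing[2])) / sp_in[2] + 0.5
  iz <- (voxel_centers(d_out[3], target_spacing[3])) / sp_in[3] + 0.5
  arr <- array(as.numeric(vol), dim = d_in)
  out <- array(0, dim = d_out)
  if (method == "nearest") {
    rx <- pmin(pmax(round(ix), 1L), d_in[1])
    ry <- pmin(pmax(round(iy), 1L), d_in[2])
    rz <- pmin(pmax(round(iz), 1L), d_in[3])
    out <- arr[rx, ry, rz, drop = FALSE]
    dim(out) <- d_out
  } else {
    clamp <- function(v, n) pmin(pmax(v, 1), n)
    x0 <- clamp(floor(ix), d_in[1]); x1 <- clamp(x0 + 1, d_in[1])
    y0 <- clamp(floor(iy), d_in[2]); y1 <- clamp(y0 + 1, d_in[2])
    z0 <- clamp(floor(iz), d_in[3]); z1 <- clamp(z0 + 1, d_in[3])
    fx <- pmin(pmax(ix - floor(ix), 0), 1)
    fy <- pmin(pmax(iy - floor(iy), 0), 1)
    fz <- pmin(pmax(iz - floor(iz), 0), 1)
    # accumulate the 8 corner contributions with separable weights
    wx <- list(`0` = 1 - fx, `1` = fx)
    wy <- list(`0` = 1 - fy, `1` = fy)
    wz <- list(`0` = 1 - fz, `1` = fz)
    xs <- list(`0` = x0, `1` = x1)
    ys <- list(`0` = y0, `1` = y1)
    zs <- list(`0` = z0, `1` = z1)
    for (a in c("0", "1")) for (b in c("0", "1")) for (cc in c("0", "1")) {
      sub <- arr[xs[[a]], ys[[b]], zs[[cc]], drop = FALSE]
      dim(sub) <- d_out
      w <- outer(outer(wx[[a]], wy[[b]]), wz[[cc]])
      out <- out + w * sub
    }
  }
  crlm_volume(out, target_spacing)
}

mask_bbox <- function(mask) {
  idx <- which(mask == 1L, arr.ind = TRUE)
  assert_that(nrow(idx) > 0, "mask is empty", class = "crlmrad_degenerate_error")
  list(lo = apply(idx, 2, min), hi = apply(idx, 2, max))
}

#' Resample, clip and crop an image/mask pair
#'
#' Resamples the image (trilinear) and mask (nearest-neighbour, so labels stay
#' binary) to the target spacing, clips the image to the HU window, and crops
#' both to the mask bounding box dilated by the crop margin.
#'
#' @param image,mask `crlm_volume`s sharing dimensions and spacing; mask is
#'   binary (nonzero = lesion).
#' @param config a `crlm_preprocess_config`.
#' @return list with cropped `image` and `mask` volumes at the target spacing.
#' @export
preprocess <- function(image, mask, config = preprocess_config()) {
  assert_that(inherits(config, "crlm_preprocess_config"),
    "config must be a crlm_preprocess_config", class = "crlmrad_config_error")
  assert_that(identical(dim(image), dim(mask)),
    "image and mask dimensions differ", class = "crlmrad_format_error")
  sp_i <- spacing_of(image); sp_m <- spacing_of(mask)
  assert_that(all(abs(sp_i - sp_m) < 1e-9),
    "image and mask spacing differ", class = "crlmrad_format_error")
  if (!any(mask > 0)) {
    stop_crlmrad("empty lesion mask", "crlmrad_degenerate_error")
  }
  tgt <- config$target_spacing_mm
  img <- resample_volume(image, tgt, "linear")
  msk <- resample_volume(
    crlm_volume(array(as.integer(mask > 0), dim = dim(mask)), sp_m),
    tgt, "nearest")
  msk_arr <- array(as.integer(msk > 0.5), dim = dim(msk))
  if (!any(msk_arr == 1L)) {
    stop_crlmrad("lesion vanished after resampling", "crlmrad_degenerate_error")
  }
  img_arr <- pmin(pmax(array(as.numeric(img), dim = dim(img)),
    config$clip_lo_hu), config$clip_hi_hu)
  dim(img_arr) <- dim(img)
  bb <- mask_bbox(msk_arr)
  margin <- ceiling(config$crop_margin_mm / tgt)
  lo <- pmax(bb$lo - margin, 1L)
  hi <- pmin(bb$hi + margin, dim(msk_arr))
  sl <- lapply(1:3, function(a) seq.int(lo[a], hi[a]))
  list(
    image = crlm_volume(img_arr[sl[[1]], sl[[2]], sl[[3]], drop = FALSE], tgt),
    mask = crlm_volume(msk_arr[sl[[1]], sl[[2]], sl[[3]], drop = FALSE], tgt)
  )
}

#' Discretize clipped intensities into fixed-width bins
#'
#' `bin(v) = floor((v - clip_lo_hu) / bin_width_hu) + 1`, with values at the
#' upper clip bound assigned the top bin (12 bins for the default window).
#'
#' @param values numeric vector (or array) of already-clipped intensities.
#' @param config a `crlm_preprocess_config`.
#' @return integer bin labels with an `n_bins` attribute.
#' @export
discretize <- function(values, config = preprocess_config()) {
  n_bins <- as.integer(ceiling(
    (config$clip_hi_hu - config$clip_lo_hu) / config$bin_width_hu))
  b <- floor((as.numeric(values) - config$clip_lo_hu) / config$bin_width_hu) + 1
  b <- as.integer(pmin(pmax(b, 1L), n_bins))
  if (is.array(values)) dim(b) <- dim(values)
  structure(b, n_bins = n_bins)
}

#' Laplacian-of-Gaussian filter
#'
#' Smooths an isotropic volume with a Gaussian of the given sigma (mm, equal
#' to voxels after 1 mm resampling), applies the discrete 3-D Laplacian, and
#' multiplies by sigma^2 (scale normalization, so responses are comparable
#' across the sigma grid).  Reflective boundary handling; linear in the input.
#'
#' @param vol a `crlm_volume`.
#' @param sigma_mm Gaussian scale in mm (> 0).
#' @return filtered `crlm_volume`.
#' @export
log_filter <- function(vol, sigma_mm) {
  assert_that(is.numeric(sigma_mm) && length(sigma_mm) == 1 && sigma_mm > 0,
    "sigma_mm must be a single positive number", class = "crlmrad_param_error")
  sp <- spacing_of(vol)
  arr <- array(as.numeric(vol), dim = dim(vol))
  arr <- gaussian_smooth3d(arr, sigma_mm / sp)
  lap <- array(0, dim = dim(arr))
  for (a in 1:3) {
    lap <- lap + convolve_axis(arr, c(1, -2, 1), a) / sp[a]^2
  }
  crlm_volume(sigma_mm^2 * lap, sp)
}
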