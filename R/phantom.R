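#' A spatially calibrated 3-D volume
#'
#' Light wrapper tying a 3-D numeric array to its voxel spacing in mm.
#'
#' @param data 3-D numeric array.
#' @param spacing_mm per-axis voxel size in mm (length 3, recycled).
#' @return object of class `crlm_volume` (a 3-D array with a `spacing_mm`
#'   attribute).
#' @export
crlm_volume <- function(data, spacing_mm = c(1, 1, 1)) {
  assert_that(is.array(data) && length(dim(data)) == 3L,
    "data must be a 3-D array")
  spacing_mm <- rep(as.numeric(spacing_mm), length.out = 3L)
  assert_that(all(spacing_mm > 0), "spacing_mm must be > 0")
  structure(data, spacing_mm = spacing_mm, class = "crlm_volume")
}

#' @exportS3Method base::print
print.crlm_volume <- function(x, ...) {
  cat(sprintf("crlm_volume %s voxels, spacing %s mm\n",
    paste(dim(x), collapse = "x"),
    paste(signif(attr(x, "spacing_mm"), 4), collapse = "x")))
  invisible(x)
}

spacing_of <- function(vol) {
  sp <- attr(vol, "spacing_mm")
  if (is.null(sp)) {
    stop_crlmrad("volume has no spacing metadata", "crlmrad_format_error")
  }
  sp
}

#' Specification of a synthetic lesion phantom
#'
#' Describes a small CT-like volume containing one ellipsoidal lesion with
#' controllable texture, used as a test substrate for feature extraction.
#'
#' @param grid_shape voxels per axis (length 3).
#' @param spacing_mm voxel size per axis in mm.
#' @param background_hu list with `mean` and `sd` of the background noise.
#' @param center_mm lesion center in mm from the volume origin.
#' @param radii_mm ellipsoid semi-axes in mm.
#' @param lesion_hu mean lesion intensity (HU).
#' @param texture list with `amplitude` (SD of the in-lesion texture, HU; 0
#'   gives a homogeneous lesion) and `scale_mm` (correlation length of the
#'   texture noise).
#' @return object of class `crlm_phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(40L, 40L, 40L),
                         spacing_mm = c(1, 1, 1),
                         background_hu = list(mean = 40, sd = 10),
                         center_mm = NULL,
                         radii_mm = c(8, 8, 8),
                         lesion_hu = 100,
                         texture = list(amplitude = 15, scale_mm = 2)) {
  grid_shape <- rep(as.integer(grid_shape), length.out = 3L)
  spacing_mm <- rep(as.numeric(spacing_mm), length.out = 3L)
  assert_that(all(grid_shape >= 3L), "grid_shape must be >= 3 voxels per axis",
    class = "crlmrad_spec_error")
  assert_that(all(spacing_mm > 0), "spacing_mm must be > 0",
    class = "crlmrad_spec_error")
  radii_mm <- rep(as.numeric(radii_mm), length.out = 3L)
  assert_that(all(radii_mm > 0), "radii_mm must be > 0",
    class = "crlmrad_spec_error")
  extent <- grid_shape * spacing_mm
  if (is.null(center_mm)) center_mm <- extent / 2
  center_mm <- rep(as.numeric(center_mm), length.out = 3L)
  if (any(center_mm - radii_mm < 0) || any(center_mm + radii_mm > extent)) {
    stop_crlmrad("lesion ellipsoid does not fit inside the grid",
      "crlmrad_spec_error")
  }
  structure(
    list(grid_shape = grid_shape, spacing_mm = spacing_mm,
      background_hu = background_hu, center_mm = center_mm,
      radii_mm = radii_mm, lesion_hu = lesion_hu, texture = texture),
    class = "crlm_phantom_spec"
  )
}

# Voxel-center coordinates (mm) along one axis: centers at (i - 0.5) * spacing.
voxel_centers <- function(n, spacing) (seq_len(n) - 0.5) * spacing

#' Generate a phantom image/mask pair
#'
#' Builds a 3-D volume in HU containing an ellipsoidal lesion with correlated
#' Gaussian texture, plus the binary voxelization of the ellipsoid as mask.
#' The geometry (and hence the mask) depends only on the spec; the noise
#' realization depends on the seed.
#'
#' @param spec a `crlm_phantom_spec`.
#' @param seed integer seed for the noise.
#' @return list with `image` and `mask`, both `crlm_volume`s (mask is 0/1).
#' @export
generate_phantom <- function(spec, seed = 1L) {
  assert_that(inherits(spec, "crlm_phantom_spec"),
    "spec must be created by phantom_spec()", class = "crlmrad_spec_error")
  set.seed(seed)
  d <- spec$grid_shape
  sp <- spec$spacing_mm
  cx <- voxel_centers(d[1], sp[1])
  cy <- voxel_centers(d[2], sp[2])
  cz <- voxel_centers(d[3], sp[3])
  u2 <- outer(((cx - spec$center_mm[1]) / spec$radii_mm[1])^2,
    ((cy - spec$center_mm[2]) / spec$radii_mm[2])^2, `+`)
  mask <- array(0L, dim = d)
  for (k in seq_len(d[3])) {
    mask[, , k] <- (u2 + ((cz[k] - spec$center_mm[3]) / spec$radii_mm[3])^2) <= 1
  }
  img <- array(
    stats::rnorm(prod(d), spec$background_hu$mean, spec$background_hu$sd),
    dim = d
  )
  amp <- spec$texture$amplitude
  inmask <- mask == 1L
  if (amp > 0) {
    noise <- array(stats::rnorm(prod(d)), dim = d)
    noise <- gaussian_smooth3d(noise, spec$texture$scale_mm / sp)
    s <- stats::sd(noise)
    if (s > 0) noise <- noise / s
    img[inmask] <- spec$lesion_hu + amp * noise[inmask]
  } else {
    img[inmask] <- spec$lesion_hu
  }
  list(
    image = crlm_volume(img, sp),
    mask = crlm_volume(array(as.integer(mask), dim = d), sp)
  )
}

#' Read / write calibrated volumes as NIfTI
#'
#' @param vol a `crlm_volume`.
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume` returns a `crlm_volume`; `write_volume` returns
#'   `path` invisibly.
#' @export
write_volume <- function(vol, path) {
  sp <- spacing_of(vol)
  img <- RNifti::asNifti(array(as.numeric(vol), dim = dim(vol)))
  RNifti::pixdim(img) <- sp
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  crlm_volume(array(as.numeric(img), dim = dim(img)[1:3]), sp)
}
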