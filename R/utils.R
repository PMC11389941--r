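# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_crlmrad <- function(msg, class, call. = FALSE) {
  cond <- structure(
    class = c(class, "crlmrad_error", "error", "condition"),
    list(message = msg, call = NULL)
  )
  stop(cond)
}

assert_that <- function(ok, msg, class = "crlmrad_invalid") {
  if (!isTRUE(ok)) stop_crlmrad(msg, class)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)
}

is_prob <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x <= 1

#' @noRd
gaussian_kernel_1d <- function(sigma, radius = max(1L, ceiling(4 * sigma))) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Reflective (mirror) padding along one margin of a 3-D array.
reflect_index <- function(i, n) {
  # maps out-of-range indices into 1..n by mirroring about the edges
  i <- abs(i - 1L) %% (2L * n - 2L)
  ifelse(i >= n, 2L * n - 2L - i, i) + 1L
}

# Separable 1-D convolution of a 3-D array along dimension `dim` with
# reflective boundaries.  Kernel must have odd length.
convolve_axis <- function(arr, kernel, dim) {
  d <- dim(arr)
  n <- d[dim]
  radius <- (length(kernel) - 1L) / 2L
  out <- array(0, dim = d)
  for (j in seq_along(kernel)) {
    off <- j - radius - 1L
    idx <- reflect_index(seq_len(n) + off, n)
    slab <- switch(dim,
      arr[idx, , , drop = FALSE],
      arr[, idx, , drop = FALSE],
      arr[, , idx, drop = FALSE]
    )
    out <- out + kernel[j] * slab
  }
  out
}

# Gaussian smoothing of a 3-D array, sigma given in voxels per axis.
gaussian_smooth3d <- function(arr, sigma) {
  sigma <- rep(sigma, length.out = 3L)
  for (dim in 1:3) {
    if (sigma[dim] > 0) arr <- convolve_axis(arr, gaussian_kernel_1d(sigma[dim]), dim)
  }
  arr
}

# The 13 unique 3-D direction offsets (one of each antipodal pair) used for
# distance-1 texture matrices.
direction_offsets_13 <- function() {
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  keep <- offs$dz > 0 | (offs$dz == 0 & offs$dy > 0) |
    (offs$dz == 0 & offs$dy == 0 & offs$dx > 0)
  as.matrix(offs[keep, , drop = FALSE])
}
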