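# Half-sample symmetric ("reflect") index extension: ... c b a | a b c d | d c b ...
# Valid for any pad width; periodic with period 2n.
reflect_index <- function(i, n) {
  j <- (i - 1) %% (2L * n)
  j <- ifelse(j < 0, j + 2L * n, j)
  ifelse(j < n, j + 1L, 2L * n - j)
}

# Convolve along one array axis with a 1D kernel, reflect boundary.
# Works by permuting the target axis first, padding, then shift-adding
# kernel taps over the whole (axis x rest) matrix — no per-voxel loops.
convolve_axis <- function(arr, kernel, axis) {
  r <- (length(kernel) - 1L) %/% 2L
  if (r == 0L) return(arr * kernel)
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  n <- d[axis]
  m <- prod(d[-axis])
  a <- matrix(a, n, m)
  pad <- a[reflect_index(seq.int(1L - r, n + r), n), , drop = FALSE]
  out <- matrix(0, n, m)
  for (t in seq_along(kernel))
    out <- out + kernel[t] * pad[seq.int(t, t + n - 1L), , drop = FALSE]
  out <- array(out, d[perm])
  aperm(out, order(perm))
}

gaussian_kernel_1d <- function(sigma_vox, truncate = 4) {
  r <- as.integer(ceiling(truncate * sigma_vox))
  if (r < 1L) r <- 1L
  x <- seq.int(-r, r)
  k <- exp(-0.5 * (x / sigma_vox)^2)
  k / sum(k)
}

#' Gaussian smoothing in physical units
#'
#' Smooths an SUV volume with an isotropic Gaussian of standard deviation
#' `sigma_mm` in *millimetres*: the per-axis sigma in voxels is
#' `sigma_mm / spacing_mm[axis]`, so anisotropic voxels are handled
#' correctly. The separable kernel is truncated at 4 sigma and normalized
#' to unit sum (constants are exact fixed points); boundaries are handled
#' by half-sample symmetric reflection.
#'
#' @param suv an `suv_map` (any `image_volume` is accepted).
#' @param sigma_mm standard deviation in mm; `0` returns the input
#'   unchanged.
#' @param truncate kernel truncation radius in sigmas.
#' @return A volume of the same class and grid as the input.
#' @examples
#' v <- suv_map(array(1, c(8, 8, 8)), c(2, 2, 2))
#' all(gaussian_smooth(v, 2)$values == 1)
#' @export
gaussian_smooth <- function(suv, sigma_mm, truncate = 4) {
  stopifnot(inherits(suv, "image_volume"))
  if (!is.numeric(sigma_mm) || length(sigma_mm) != 1L || is.na(sigma_mm) ||
      sigma_mm < 0)
    stop("'sigma_mm' must be a single non-negative number", call. = FALSE)
  if (sigma_mm == 0) return(suv)
  out <- suv$values
  for (axis in 1:3) {
    k <- gaussian_kernel_1d(sigma_mm / suv$spacing_mm[axis], truncate)
    out <- convolve_axis(out, k, axis)
  }
  out[out < 0] <- 0  # guard tiny negative round-off on non-negative input
  res <- suv
  res$values <- out
  res
}
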