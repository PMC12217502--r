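# Internal numerical helpers shared across modules.

#' Evaluate an expression with a temporary RNG state
#'
#' Runs `code` after `set.seed(seed)` and restores the caller's
#' `.Random.seed` afterwards, so simulation functions are deterministic per
#' seed without clobbering the global stream.
#'
#' @param seed integer scalar.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single finite number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# 1D Gaussian kernel for a standard deviation given in voxels; radius 3 sigma.
gauss_kernel_1d <- function(sigma_vox) {
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-0.5 * ((-r:r) / sigma_vox)^2)
  k / sum(k)
}

# Convolve a 3D array along one dimension with a symmetric kernel,
# replicating edge voxels (constant padding with the edge value keeps flat
# background regions flat under the blur).
convolve_axis <- function(a, kernel, axis) {
  r <- (length(kernel) - 1L) %/% 2L
  d <- dim(a)
  out <- array(0, d)
  n <- d[axis]
  idx_all <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  for (j in seq_along(kernel)) {
    off <- j - r - 1L
    src <- pmin(pmax(seq_len(n) + off, 1L), n)
    idx <- idx_all
    idx[[axis]] <- src
    out <- out + kernel[j] * do.call(`[`, c(list(a), idx, list(drop = FALSE)))
  }
  out
}

#' Separable 3D Gaussian blur
#'
#' @param a 3D numeric array.
#' @param fwhm_mm full width at half maximum of the Gaussian, mm.
#' @param voxel_size voxel edge length, mm (isotropic).
#' @return blurred array, same dimensions.
#' @keywords internal
#' @noRd
gaussian_blur_3d <- function(a, fwhm_mm, voxel_size) {
  if (fwhm_mm <= 0) return(a)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size
  k <- gauss_kernel_1d(sigma_vox)
  for (axis in 1:3) a <- convolve_axis(a, k, axis)
  a
}

# Rician (magnitude) noise: the magnitude of a complex signal whose real part
# is the image and whose two quadrature components carry iid Gaussian noise.
add_rician_noise <- function(a, sigma) {
  if (sigma <= 0) return(a)
  n <- length(a)
  re <- a + stats::rnorm(n, 0, sigma)
  im <- stats::rnorm(n, 0, sigma)
  array(sqrt(re^2 + im^2), dim(a))
}

# Otsu's threshold on a numeric vector (maximizes between-class variance over
# a 256-bin histogram).
otsu_threshold <- function(x, nbins = 256L) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, breaks, all.inside = TRUE), nbins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(nbins + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

# Clamp to the audiometric 5-dB lattice within [-10, 120] dB HL.
quantize_db <- function(x) pmin(120, pmax(-10, 5 * round(x / 5)))

`%||%` <- function(a, b) if (is.null(a)) b else a
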