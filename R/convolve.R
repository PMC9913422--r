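# Linear 3D convolution via FFT with zero padding. Kernel dimensions must
# be odd so the kernel has a well-defined centre voxel. Used for the SPECT
# blur emulation and the dose-point-kernel engine.
convolve3d <- function(x, kernel) {
  dx <- dim(x); dk <- dim(kernel)
  stopifnot(length(dx) == 3L, length(dk) == 3L)
  if (any(dk %% 2 == 0)) stop("kernel dimensions must be odd")
  if (all(dk == 1L)) return(x * kernel[1, 1, 1])
  if (any(dk > dx))
    stop("kernel support exceeds grid extent")
  n <- vapply(dx + dk - 1L, stats::nextn, integer(1), factors = c(2L, 3L))
  xp <- array(0, n); xp[seq_len(dx[1]), seq_len(dx[2]), seq_len(dx[3])] <- x
  kp <- array(0, n); kp[seq_len(dk[1]), seq_len(dk[2]), seq_len(dk[3])] <- kernel
  y <- Re(stats::fft(stats::fft(xp) * stats::fft(kp), inverse = TRUE)) / prod(n)
  h <- (dk - 1L) %/% 2L
  out <- y[h[1] + seq_len(dx[1]), h[2] + seq_len(dx[2]), h[3] + seq_len(dx[3])]
  # FFT round-off can leave tiny negatives on a non-negative field
  eps <- 1e-12 * max(abs(out))
  out[out < 0 & out > -eps] <- 0
  array(out, dx)
}

# Normalized 3D Gaussian kernel for a given FWHM (mm) on a given spacing.
# Truncated at 4 sigma per axis; returns a 1x1x1 identity for fwhm = 0.
gaussian_kernel3d <- function(fwhm_mm, spacing) {
  if (fwhm_mm < 0) stop("'fwhm_mm' must be >= 0")
  if (fwhm_mm == 0) return(array(1, c(1, 1, 1)))
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  ks <- lapply(1:3, function(ax) {
    h <- max(1L, ceiling(4 * sigma / spacing[ax]))
    x <- (-h:h) * spacing[ax]
    k <- exp(-x^2 / (2 * sigma^2))
    k / sum(k)
  })
  k3 <- outer(outer(ks[[1]], ks[[2]]), ks[[3]])
  array(k3, c(length(ks[[1]]), length(ks[[2]]), length(ks[[3]])))
}
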