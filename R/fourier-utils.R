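## Internal Fourier helpers shared by the curtaining, FRC and synthetic
## modules. Frequencies follow the usual DFT layout (0, +, -) in cycles per
## pixel; "normalized frequency" scales so that 1 = Nyquist (0.5 cyc/px).

.fftfreq <- function(n) {
  c(seq.int(0L, floor((n - 1) / 2)), seq.int(-floor(n / 2), -1L)) / n
}

## normalized radial frequency grid for an h x w spectrum (1 = Nyquist)
.radius_grid <- function(h, w) {
  fy <- 2 * .fftfreq(h)
  fx <- 2 * .fftfreq(w)
  sqrt(outer(fy^2, fx^2, `+`))
}

## raised-cosine (Tukey) taper; alpha = total tapered fraction
.tukey1 <- function(n, alpha) {
  if (alpha <= 0 || n < 2) return(rep(1, n))
  x <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  a2 <- alpha / 2
  lo <- x < a2
  hi <- x > 1 - a2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * x[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (1 - x[hi]) / alpha - 1)))
  w
}

.tukey2 <- function(h, w, alpha) outer(.tukey1(h, alpha), .tukey1(w, alpha))

## isotropic Gaussian smoothing by FFT (periodic boundary), sigma in px
.gauss_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  h <- nrow(m); w <- ncol(m)
  fy <- .fftfreq(h); fx <- .fftfreq(w)
  g <- exp(-2 * pi^2 * sigma^2 * outer(fy^2, fx^2, `+`))
  Re(fft(fft(m) * g, inverse = TRUE)) / (h * w)
}

## smoothed Gaussian random field with unit variance
.smooth_noise <- function(h, w, sigma_px) {
  z <- .gauss_smooth(matrix(rnorm(h * w), h, w), sigma_px)
  z / sd(z)
}
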