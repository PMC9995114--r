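## Seed-deterministic synthetic fixtures with ground truth, standing in for
## acquired serial FIB/SEM volumes. Every generator is a pure function of
## its arguments (seed included) and returns enough truth to score the
## matching analysis without re-derivation.

#' Generate a curtained SEM image
#'
#' Builds a single image whose target ROI carries strictly vertical stripes
#' (constant along y) covering a prescribed fraction of the columns, over a
#' flat or smoothed-noise background. Emulates the vertical differential-
#' milling streaks ("curtains") scored by [curtain_score()].
#'
#' @param shape `c(H, W)` image size in pixels.
#' @param stripe_fraction fraction of columns covered by stripes, in 0..1.
#' @param amplitude stripe contrast in grey units (>= 0); each stripe gets a
#'   random sign so curtains modulate both brighter and darker.
#' @param stripe_width_px nominal stripe width in pixels.
#' @param background `"smooth"` (Gaussian-smoothed white noise, the default,
#'   emulating cytoplasmic texture) or `"flat"`.
#' @param bg_mean,bg_sd,bg_smooth_px background mean grey, texture standard
#'   deviation and smoothing length.
#' @param seed integer seed; identical seeds give identical arrays.
#' @return list with `stack` (1-slice [image_stack()]), `mask` (binary
#'   matrix marking exactly the stripe pixels) and `stripe_columns`.
#' @export
gen_curtain_image <- function(shape, stripe_fraction, amplitude,
                              stripe_width_px = 4L,
                              background = c("smooth", "flat"),
                              bg_mean = 100, bg_sd = 5, bg_smooth_px = 3,
                              seed = 1L) {
  background <- match.arg(background)
  stopifnot(length(shape) == 2L, all(shape >= 8))
  if (stripe_fraction < 0 || stripe_fraction > 1)
    stop("stripe_fraction must be in [0, 1]")
  if (amplitude < 0) stop("amplitude must be >= 0")
  H <- as.integer(shape[1]); W <- as.integer(shape[2])
  n_cols <- round(stripe_fraction * W)
  if (stripe_fraction > 0 && n_cols < 1)
    stop("stripe_fraction too small for image width: no stripe possible")
  set.seed(seed)
  img <- matrix(bg_mean, H, W)
  if (background == "smooth" && bg_sd > 0)
    img <- img + bg_sd * .smooth_noise(H, W, bg_smooth_px)
  cols <- logical(W)
  if (n_cols >= 1) {
    # place stripes of ~stripe_width_px until exactly n_cols columns covered
    widths <- rep(stripe_width_px, n_cols %/% stripe_width_px)
    if (n_cols %% stripe_width_px > 0) widths <- c(widths,
                                                   n_cols %% stripe_width_px)
    widths <- as.list(widths)
    while (length(widths)) {
      wd <- widths[[1]]; widths <- widths[-1]
      free <- which(!cols)
      # candidate starts whose wd-wide run is free and not adjacent to a stripe
      ok <- free[vapply(free, function(s) {
        s + wd - 1L <= W && all(!cols[max(1L, s - 1L):min(W, s + wd)])
      }, logical(1))]
      if (!length(ok)) { # fall back: allow adjacency rather than fail
        ok <- free[vapply(free, function(s)
          s + wd - 1L <= W && all(!cols[s:(s + wd - 1L)]), logical(1))]
      }
      if (!length(ok)) {
        if (wd > 1L) { # fragmented free space: split into narrower stripes
          widths <- c(widths, as.list(rep(1L, wd)))
          next
        }
        stop("cannot place stripes; lower stripe_fraction")
      }
      s <- ok[sample.int(length(ok), 1L)]
      cols[s:(s + wd - 1L)] <- TRUE
    }
    sgn <- sample(c(-1, 1), sum(cols), replace = TRUE)
    img[, cols] <- img[, cols] + rep(sgn * amplitude, each = H)
  }
  mask <- matrix(FALSE, H, W)
  mask[, cols] <- TRUE
  list(stack = image_stack(img, pixel_nm = 1),
       mask = mask, stripe_columns = which(cols))
}

#' Generate a band-limited noisy image pair for FRC testing
#'
#' Two images share one isotropically band-limited Gaussian random signal
#' (hard radial low-pass at `cutoff`, in normalized frequency, 1 = Nyquist)
#' and carry independent white noise scaled so that
#' `sd(signal)/sd(noise) = snr`. This emulates repeated SEM exposures of the
#' same field of view used to calibrate the one-image FRC.
#'
#' @param shape `c(H, W)` or a single side length.
#' @param cutoff normalized band edge in (0, 1].
#' @param snr signal-to-noise ratio (> 0); `Inf` gives identical images.
#' @param signal_sd grey-level standard deviation of the shared signal.
#' @param mean_grey mean grey level.
#' @param seed integer seed.
#' @return list with matrices `a`, `b` and the shared `signal`.
#' @export
gen_frc_pair <- function(shape, cutoff, snr, signal_sd = 10,
                         mean_grey = 100, seed = 1L) {
  if (length(shape) == 1L) shape <- c(shape, shape)
  stopifnot(all(shape >= 16))
  if (cutoff <= 0 || cutoff > 1) stop("cutoff must be in (0, 1]")
  if (!(snr > 0)) stop("snr must be > 0")
  H <- as.integer(shape[1]); W <- as.integer(shape[2])
  set.seed(seed)
  z <- matrix(rnorm(H * W), H, W)
  Fz <- fft(z)
  Fz[.radius_grid(H, W) > cutoff] <- 0
  s <- Re(fft(Fz, inverse = TRUE)) / (H * W)
  s <- signal_sd * s / sd(s)
  noise_sd <- if (is.finite(snr)) signal_sd / snr else 0
  a <- mean_grey + s + matrix(rnorm(H * W, sd = noise_sd), H, W)
  b <- mean_grey + s + matrix(rnorm(H * W, sd = noise_sd), H, W)
  list(a = a, b = b, signal = mean_grey + s)
}

#' Generate an image with charging artifacts
#'
#' Each charging centre is a dark disk (Gaussian dip of depth `3 A`, FWHM
#' equal to the disk diameter) whose rows additionally carry the asymmetric
#' scan-direction tails [tail_left()] (approaching the centre from the left)
#' and [tail_right()] (recovering to the right), with the inflection points
#' `x0` at the disk edges. The returned mask covers only the disks, matching
#' a segmentation of the charged centres but not the streaking.
#'
#' @param shape `c(H, W)`.
#' @param centres data frame with columns `y`, `x`, `diameter_px`, `A`,
#'   `sigma_px` and optionally `left_extent`, `right_extent` (tail extents
#'   in px; default the full row).
#' @param baseline `"flat"` or `"smooth"` background texture.
#' @param bg_mean,bg_sd,bg_smooth_px background parameters as in
#'   [gen_curtain_image()].
#' @param noise_sd additive white-noise standard deviation.
#' @param seed integer seed.
#' @return list with `stack`, `mask` (integer labels, one per centre) and
#'   `truth` (per-centre tail parameters incl. `x0_left`, `x0_right`).
#' @export
gen_charge_image <- function(shape, centres, baseline = c("flat", "smooth"),
                             bg_mean = 100, bg_sd = 5, bg_smooth_px = 4,
                             noise_sd = 0, seed = 1L) {
  baseline <- match.arg(baseline)
  stopifnot(length(shape) == 2L)
  H <- as.integer(shape[1]); W <- as.integer(shape[2])
  centres <- as.data.frame(centres)
  need <- c("y", "x", "diameter_px", "A", "sigma_px")
  if (!all(need %in% names(centres)))
    stop("centres needs columns ", paste(need, collapse = ", "))
  if (any(centres$diameter_px < 1)) stop("diameter_px must be >= 1")
  if (any(centres$A < 0)) stop("A must be >= 0")
  if (any(centres$sigma_px <= 0)) stop("sigma_px must be > 0")
  r <- centres$diameter_px / 2
  if (any(centres$y - r < 1 | centres$y + r > H |
          centres$x - r < 1 | centres$x + r > W))
    stop("centres must lie fully inside the image")
  set.seed(seed)
  img <- matrix(bg_mean, H, W)
  if (baseline == "smooth" && bg_sd > 0)
    img <- img + bg_sd * .smooth_noise(H, W, bg_smooth_px)
  mask <- matrix(0L, H, W)
  xs <- seq_len(W)
  truth <- centres
  truth$x0_left <- centres$x - r
  truth$x0_right <- centres$x + r
  for (i in seq_len(nrow(centres))) {
    ci <- centres[i, ]
    d <- ci$diameter_px
    x0l <- truth$x0_left[i]; x0r <- truth$x0_right[i]
    rows <- which(abs(seq_len(H) - ci$y) <= d / 2)
    lext <- if (!is.null(centres$left_extent)) centres$left_extent[i] else Inf
    rext <- if (!is.null(centres$right_extent)) centres$right_extent[i]
            else Inf
    left_cols <- xs[xs < x0l & xs >= ci$x - lext]
    right_cols <- xs[xs > x0r & xs <= ci$x + rext]
    for (rr in rows) {
      img[rr, left_cols] <- img[rr, left_cols] +
        tail_left(left_cols, ci$A, x0l, ci$sigma_px)
      img[rr, right_cols] <- img[rr, right_cols] +
        tail_right(right_cols, ci$A, x0r, ci$sigma_px)
    }
    # dark disk: Gaussian dip (depth 3A, FWHM = diameter) truncated to the
    # disk, so the baseline outside the mask carries only the tails
    dist2 <- outer((seq_len(H) - ci$y)^2, (xs - ci$x)^2, `+`)
    gsd <- d / (2 * sqrt(2 * log(2)))
    disk <- dist2 <= (d / 2)^2
    img <- img - 3 * ci$A * exp(-dist2 / (2 * gsd^2)) * disk
    if (any(mask[disk] != 0L))
      stop("overlapping charging centres are not supported")
    mask[disk] <- i
  }
  if (noise_sd > 0) img <- img + matrix(rnorm(H * W, sd = noise_sd), H, W)
  list(stack = image_stack(img, pixel_nm = 1), mask = mask, truth = truth)
}

## analytic sphere cross-section area in nm^2 at depth `depth_nm`
.sphere_section_area <- function(d_nm, z_c_nm, depth_nm) {
  pmax(0, (d_nm / 2)^2 - (depth_nm - z_c_nm)^2) * pi
}

#' Generate a milled bead stack
#'
#' Rasterizes spherical beads into a serial stack whose slices are milled at
#' the *realized* step `true_step_nm`, while the stack metadata carries the
#' *nominal* step. Slice z (1-based) sits at depth `(z - 1) * true_step_nm +
#' offset_nm`; a bead of diameter d centred at depth z_c shows a filled disk
#' of area `pi * max(0, (d/2)^2 - (depth - z_c)^2)` nm^2, rasterized by
#' pixel-centre inclusion. Emulates the bead stacks used to verify the
#' milling step, where a fitted thickness coefficient `alpha =
#' true_step / nominal_step` exposes any discrepancy (see [fit_bead()]).
#'
#' @param beads data frame with columns `d_nm`, `z_c_nm` (true depth of the
#'   bead centre, nm), `y`, `x` (pixel coordinates of the bead axis).
#' @param true_step_nm realized milling step (nm).
#' @param nominal_step_nm programmed milling step (nm), stored in metadata.
#' @param pixel_nm lateral pixel size (nm).
#' @param shape `c(n_slices, H, W)`.
#' @param offset_nm depth of the first slice (nm).
#' @param bead_grey,bg_grey grey levels of bead and background.
#' @param noise_sd additive white-noise standard deviation.
#' @param seed integer seed (used only when `noise_sd > 0`).
#' @return list with `stack` ([image_stack()] carrying `nominal_step_nm`),
#'   `mask` (3D integer labels, one per bead) and `truth` (per-bead table
#'   plus `true_step_nm`).
#' @export
gen_bead_stack <- function(beads, true_step_nm, nominal_step_nm = 50,
                           pixel_nm = 20, shape = NULL, offset_nm = 0,
                           bead_grey = 150, bg_grey = 50, noise_sd = 0,
                           seed = 1L) {
  beads <- as.data.frame(beads)
  stopifnot(all(c("d_nm", "z_c_nm", "y", "x") %in% names(beads)))
  if (any(beads$d_nm <= 0)) stop("bead diameters must be positive")
  if (true_step_nm <= 0 || nominal_step_nm <= 0) stop("steps must be positive")
  if (is.null(shape)) {
    nz <- ceiling((max(beads$z_c_nm + beads$d_nm / 2) + offset_nm) /
                    true_step_nm) + 2L
    half_px <- max(beads$d_nm / 2) / pixel_nm
    H <- ceiling(max(beads$y) + half_px + 2)
    W <- ceiling(max(beads$x) + half_px + 2)
    shape <- c(nz, H, W)
  }
  nz <- as.integer(shape[1]); H <- as.integer(shape[2])
  W <- as.integer(shape[3])
  r_px <- beads$d_nm / 2 / pixel_nm
  if (any(beads$y - r_px < 1 | beads$y + r_px > H |
          beads$x - r_px < 1 | beads$x + r_px > W))
    stop("bead larger than field or outside it")
  vox <- array(bg_grey, c(nz, H, W))
  mask <- array(0L, c(nz, H, W))
  for (z in seq_len(nz)) {
    depth <- (z - 1) * true_step_nm + offset_nm
    for (i in seq_len(nrow(beads))) {
      area <- .sphere_section_area(beads$d_nm[i], beads$z_c_nm[i], depth)
      if (area <= 0) next
      rad_px <- sqrt(area / pi) / pixel_nm
      dy2 <- (seq_len(H) - beads$y[i])^2
      dx2 <- (seq_len(W) - beads$x[i])^2
      disk <- outer(dy2, dx2, `+`) <= rad_px^2   # pixel-centre inclusion
      sl <- vox[z, , ]; sl[disk] <- bead_grey; vox[z, , ] <- sl
      ml <- mask[z, , ]; ml[disk] <- i; mask[z, , ] <- ml
    }
  }
  if (noise_sd > 0) {
    set.seed(seed)
    vox <- vox + array(rnorm(length(vox), sd = noise_sd), dim(vox))
  }
  truth <- beads
  truth$true_step_nm <- true_step_nm
  list(stack = image_stack(vox, pixel_nm = pixel_nm,
                           step_nm = nominal_step_nm),
       mask = mask, truth = truth)
}
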