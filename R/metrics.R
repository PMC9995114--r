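## Stage-drift statistics, bead-based Z-step calibration, 2D shape metrics,
## tilt foreshortening, FWHM and electron dose.

#' Stage-drift report from landmark pairs
#'
#' Euclidean distance between each pair of matched landmarks, normalized by
#' the diagonal length of the field of view so that images of different
#' sizes compare fairly.
#'
#' @param pairs data frame with columns `x1`, `y1`, `x2`, `y2` (px).
#' @param fov_shape `c(H, W)` of the field of view in px.
#' @param pixel_nm pixel size in nm.
#' @return object of class `drift_report`: data frame `pairs` with `d_px`,
#'   `d_nm`, `normalized`, plus `mean_nm`, `sd_nm`, `mean_normalized`,
#'   `diagonal_px`.
#' @export
landmark_drift <- function(pairs, fov_shape, pixel_nm) {
  pairs <- as.data.frame(pairs)
  if (!nrow(pairs)) stop("empty pair list")
  stopifnot(all(c("x1", "y1", "x2", "y2") %in% names(pairs)))
  H <- fov_shape[1]; W <- fov_shape[2]
  d_px <- sqrt((pairs$x2 - pairs$x1)^2 + (pairs$y2 - pairs$y1)^2)
  diag_px <- sqrt(H^2 + W^2)
  out <- cbind(pairs, d_px = d_px, d_nm = d_px * pixel_nm,
               normalized = d_px / diag_px)
  structure(list(pairs = out, mean_nm = mean(out$d_nm),
                 sd_nm = if (nrow(out) > 1) sd(out$d_nm) else 0,
                 mean_normalized = mean(out$normalized),
                 diagonal_px = diag_px, pixel_nm = pixel_nm),
            class = "drift_report")
}

#' @export
print.drift_report <- function(x, ...) {
  cat(sprintf("drift_report: %d pairs, %.1f +/- %.1f nm (%.3f%% of FOV diagonal)\n",
              nrow(x$pairs), x$mean_nm, x$sd_nm, 100 * x$mean_normalized))
  invisible(x)
}

#' Per-slice bead cross-section areas
#'
#' Collects, for each labelled bead, the 2D area of its cross-section on
#' every slice where it appears. A binary 3D mask is labelled first
#' (26-connectivity) so the slices of one bead share an id; a 2D mask is
#' treated as a single slice with 8-connected components as beads.
#'
#' @param mask 3D (z, y, x) or 2D label/binary array.
#' @param pixel_nm lateral pixel size in nm.
#' @return data frame with columns `bead`, `slice` (1-based), `n_px`,
#'   `area_nm2`. Slices where a bead is absent produce no row.
#' @export
bead_areas <- function(mask, pixel_nm) {
  if (inherits(mask, "image_stack")) mask <- mask$voxels
  if (is.matrix(mask)) mask <- array(mask, c(1L, dim(mask)))
  if (!any(mask > 0)) stop("empty mask")
  if (all(mask %in% c(0, 1))) mask <- label_components(mask > 0)
  mask <- label_mask(mask)
  ids <- sort(unique(mask[mask > 0L]))
  rows <- list()
  for (z in seq_len(dim(mask)[1])) {
    sl <- mask[z, , ]
    present <- ids[ids %in% sl]
    for (id in present) {
      n <- sum(sl == id)
      rows[[length(rows) + 1L]] <- data.frame(bead = id, slice = z,
                                              n_px = n,
                                              area_nm2 = n * pixel_nm^2)
    }
  }
  do.call(rbind, rows)
}

## forward model: cross-section area vs slice index
.bead_area_model <- function(par, z, nominal_step_nm) {
  d <- par[1]; z_c <- par[2]; alpha <- par[3]
  pi * pmax(0, (d / 2)^2 - (alpha * (z * nominal_step_nm - z_c))^2)
}

#' Fit the sphere cross-section model to one bead's areas
#'
#' Least-squares fit of
#' `A(z) = pi * max(0, (d/2)^2 - (alpha * (z * step - z_c))^2)` with the
#' bead diameter `d`, centre depth `z_c` and milling-thickness coefficient
#' `alpha` free. In a perfectly calibrated instrument `alpha = 1`; the
#' realized milling step is `alpha * nominal_step_nm`. The quadratic
#' `A/pi = a + b z + c z^2` is solved linearly for the starting values
#' (exact for noiseless data), then polished with Nelder-Mead on the
#' truncated model.
#'
#' @param areas data frame with columns `slice` (1-based index) and
#'   `area_nm2`, as from [bead_areas()].
#' @param nominal_step_nm programmed milling step (nm).
#' @return object of class `bead_fit`: `d_nm`, `z_c_nm`, `alpha`,
#'   `realized_step_nm`, `rms`, `n_slices`, `ok`.
#' @export
fit_bead <- function(areas, nominal_step_nm) {
  areas <- as.data.frame(areas)
  stopifnot(all(c("slice", "area_nm2") %in% names(areas)))
  areas <- areas[areas$area_nm2 > 0, ]
  fail <- structure(list(d_nm = NA_real_, z_c_nm = NA_real_,
                         alpha = NA_real_, realized_step_nm = NA_real_,
                         rms = NA_real_, n_slices = nrow(areas),
                         ok = FALSE), class = "bead_fit")
  if (nrow(areas) < 4) return(fail)
  if (diff(range(areas$area_nm2)) == 0) return(fail)
  ## slice index measured in *nominal* depth units; zero-based grid is fine,
  ## a shift in slice origin only shifts z_c
  z <- areas$slice
  y <- areas$area_nm2 / pi
  X <- cbind(1, z, z^2)
  cf <- tryCatch(qr.solve(X, y), error = function(e) NULL)
  if (is.null(cf) || cf[3] >= 0) {
    ## no downward curvature: initialize from peak geometry instead
    d0 <- 2 * sqrt(max(y))
    z0 <- z[which.max(y)]
    start <- c(d0, z0 * nominal_step_nm, 1)
  } else {
    alpha0 <- sqrt(-cf[3]) / nominal_step_nm
    z_c0 <- cf[2] / (2 * alpha0^2 * nominal_step_nm)      # in nm
    d0 <- 2 * sqrt(max(cf[1] + alpha0^2 * z_c0^2, max(y)))
    start <- c(d0, z_c0, alpha0)
  }
  obj <- function(p) {
    if (p[1] <= 0 || p[3] <= 0) return(1e30)
    sum((.bead_area_model(p, z, nominal_step_nm) - areas$area_nm2)^2)
  }
  opt <- optim(start, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  p <- opt$par
  rms <- sqrt(opt$value / nrow(areas))
  structure(list(d_nm = p[1], z_c_nm = p[2], alpha = p[3],
                 realized_step_nm = p[3] * nominal_step_nm, rms = rms,
                 n_slices = nrow(areas), ok = TRUE),
            class = "bead_fit")
}

#' @export
print.bead_fit <- function(x, ...) {
  if (!x$ok) { cat("bead_fit: failed (degenerate areas)\n"); return(invisible(x)) }
  cat(sprintf(
    "bead_fit: d = %.1f nm, z_c = %.1f nm, alpha = %.4f (realized step %.2f nm), rms %.3g\n",
    x$d_nm, x$z_c_nm, x$alpha, x$realized_step_nm, x$rms))
  invisible(x)
}

#' Fit all beads of a labelled stack
#'
#' @param mask 3D bead label mask (or binary; see [bead_areas()]).
#' @param pixel_nm lateral pixel size (nm).
#' @param nominal_step_nm programmed milling step (nm).
#' @return data frame with one row per bead: `bead`, `d_nm`, `z_c_nm`,
#'   `alpha`, `realized_step_nm`, `rms`, `n_slices`, `ok`.
#' @export
fit_beads <- function(mask, pixel_nm, nominal_step_nm) {
  ar <- bead_areas(mask, pixel_nm)
  out <- lapply(split(ar, ar$bead), function(a) {
    f <- fit_bead(a, nominal_step_nm)
    data.frame(bead = a$bead[1], d_nm = f$d_nm, z_c_nm = f$z_c_nm,
               alpha = f$alpha, realized_step_nm = f$realized_step_nm,
               rms = f$rms, n_slices = f$n_slices, ok = f$ok)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

## Moore-neighbour boundary trace (clockwise, Jacob's stopping criterion);
## returns chain move counts. Revisiting pixels is correct for thin shapes:
## both sides of a 1-px line belong to the boundary.
.trace_boundary <- function(mask) {
  ## pad to avoid bound checks
  m <- matrix(FALSE, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  idx <- which(m, arr.ind = TRUE)
  start <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE][1, ]
  ## directions 0..7 clockwise starting W (y down, x right)
  dy <- c(0, -1, -1, -1, 0, 1, 1, 1)
  dx <- c(-1, -1, 0, 1, 1, 1, 0, -1)
  scan_from <- 0L                       # first scan starts toward W
  cur <- start
  n_axial <- 0L; n_diag <- 0L
  first <- NULL                         # first move (pixel + direction)
  for (safety in seq_len(8L * sum(m) + 8L)) {
    j <- NA_integer_
    for (k in 0:7) {
      cand <- (scan_from + k) %% 8L
      ny <- cur[1] + dy[cand + 1L]; nx <- cur[2] + dx[cand + 1L]
      if (m[ny, nx]) { j <- cand; break }
    }
    if (is.na(j)) break                 # isolated pixel: no moves
    move <- c(cur[1] + dy[j + 1L], cur[2] + dx[j + 1L], j)
    if (!is.null(first) && all(cur == start) && j == first[3]) break
    if (is.null(first)) first <- move
    if (abs(dy[j + 1L]) + abs(dx[j + 1L]) == 2L) n_diag <- n_diag + 1L
    else n_axial <- n_axial + 1L
    cur <- move[1:2]
    scan_from <- (j + 6L) %% 8L         # back up two steps counter-clockwise
  }
  list(n_axial = n_axial, n_diag = n_diag)
}

#' 2D shape metrics of a single segmented object
#'
#' Circularity `4 pi area / perimeter^2`, aspect ratio (major/minor axis of
#' the second-moment ellipse) and roundness `4 area / (pi major^2)`; all
#' equal 1 for a perfect circle. The perimeter is an 8-connected boundary
#' chain length with corner-corrected weights (0.948 per axial step, 1.340
#' per diagonal step), which is unbiased for smooth boundaries, where the
#' raw (1, sqrt 2) weights overestimate a digital circle's perimeter by
#' ~5%.
#'
#' @param mask2d binary matrix containing exactly one 8-connected
#'   component.
#' @return object of class `shape_metrics`: `area_px`, `perimeter_px`,
#'   `circularity`, `aspect_ratio`, `roundness`, `major_px`, `minor_px`.
#' @export
shape_metrics <- function(mask2d) {
  mask2d <- mask2d > 0
  if (!any(mask2d)) stop("empty mask")
  lab <- label_components(mask2d)
  if (max(lab) != 1L) stop("mask must contain a single connected component")
  area <- sum(mask2d)
  ch <- .trace_boundary(mask2d)
  perim <- 0.948 * ch$n_axial + 1.340 * ch$n_diag
  if (perim <= 0) perim <- 0.948 * 4     # isolated pixel
  px <- which(mask2d, arr.ind = TRUE)
  ## central second moments with the 1/12 px^2 term for finite pixel extent
  mu <- cov(px) * (nrow(px) - 1) / nrow(px) + diag(2) / 12
  ev <- sort(eigen(mu, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  major <- 4 * sqrt(ev[1]); minor <- 4 * sqrt(ev[2])
  structure(list(area_px = area, perimeter_px = perim,
                 circularity = 4 * pi * area / perim^2,
                 aspect_ratio = major / minor,
                 roundness = 4 * area / (pi * major^2),
                 major_px = major, minor_px = minor),
            class = "shape_metrics")
}

#' @export
print.shape_metrics <- function(x, ...) {
  cat(sprintf(
    "shape_metrics: area %d px, perimeter %.1f px, circularity %.3f, AR %.3f, roundness %.3f\n",
    x$area_px, x$perimeter_px, x$circularity, x$aspect_ratio, x$roundness))
  invisible(x)
}

#' Tilt foreshortening correction
#'
#' Imaging a surface tilted at angle `tilt_deg` to the beam shortens
#' features along y by `sin(tilt)`; the true length is
#' `measured / sin(tilt)`.
#'
#' @param length_measured measured length (any unit).
#' @param tilt_deg imaging angle in degrees, in (0, 90].
#' @return corrected length.
#' @export
tilt_foreshortening <- function(length_measured, tilt_deg) {
  if (any(tilt_deg <= 0) || any(tilt_deg > 90))
    stop("tilt_deg must be in (0, 90]")
  length_measured / sin(tilt_deg * pi / 180)
}

#' Rescale the y axis to undo tilt foreshortening
#'
#' Stretches the image along y by `1 / sin(tilt)` with linear
#' interpolation, restoring isotropic sampling of a surface imaged at
#' `tilt_deg`.
#'
#' @param image 2D numeric matrix.
#' @param tilt_deg imaging angle in degrees, in (0, 90].
#' @return matrix with `round(nrow / sin(tilt))` rows.
#' @export
stretch_image <- function(image, tilt_deg) {
  image <- .as_image_matrix(image)
  if (tilt_deg <= 0 || tilt_deg > 90) stop("tilt_deg must be in (0, 90]")
  s <- sin(tilt_deg * pi / 180)
  H <- nrow(image)
  H2 <- max(2L, round(H / s))
  ys <- seq(1, H, length.out = H2)
  apply(image, 2, function(col) stats::approx(seq_len(H), col, xout = ys)$y)
}

#' Full width at half maximum of a peak profile
#'
#' The baseline is the median of the outer 10% of samples on each end; the
#' peak is the extremum of largest deviation from that baseline (dips are
#' handled like peaks). The width is measured between the two half-maximum
#' crossings adjacent to the peak, linearly interpolated.
#'
#' @param profile numeric vector with a single dominant extremum.
#' @return width in samples.
#' @export
fwhm <- function(profile) {
  n <- length(profile)
  if (n < 5) stop("profile too short")
  k <- max(1L, floor(0.1 * n))
  baseline <- median(c(head(profile, k), tail(profile, k)))
  dev <- profile - baseline
  ip <- which.max(abs(dev))
  peak <- dev[ip]
  if (abs(peak) <= .Machine$double.eps^0.5) stop("no peak found")
  half <- peak / 2
  ## walk outward from the peak to the first crossing on each side
  cross <- function(side) {
    idx <- if (side == "left") seq(ip, 1L) else seq(ip, n)
    below <- which(if (peak > 0) dev[idx] < half else dev[idx] > half)
    if (!length(below)) stop("no half-maximum crossing on the ", side)
    i2 <- idx[below[1]]; i1 <- idx[below[1] - 1L]
    i1 + (half - dev[i1]) * (i2 - i1) / (dev[i2] - dev[i1])
  }
  xr <- cross("right"); xl <- cross("left")
  xr - xl
}

#' Electron dose of an SEM exposure
#'
#' `N = I / e` electrons per second hit the sample; each pixel is exposed
#' for `dwell_ns * line_integration` (the `"total"` convention) or
#' `dwell_ns` alone (`"single_pass"`), and the dose is the electron count
#' per pixel area. Printed dose tables built from nominal rather than
#' Faraday-cup currents may not be reproducible under either convention,
#' which is why both are exposed.
#'
#' @param params an [imaging_params()].
#' @param convention `"total"` (dwell x line integration, default) or
#'   `"single_pass"`.
#' @return list: `e_per_nm2`, `e_per_A2`, `electrons_per_pixel`,
#'   `convention`.
#' @export
electron_dose <- function(params, convention = c("total", "single_pass")) {
  convention <- match.arg(convention)
  e_charge <- 1.602176634e-19
  N_per_s <- params$current_pA * 1e-12 / e_charge
  t_s <- params$dwell_ns * 1e-9 *
    if (convention == "total") params$line_integration else 1
  e_px <- N_per_s * t_s
  e_nm2 <- e_px / params$pixel_nm^2
  list(e_per_nm2 = e_nm2, e_per_A2 = e_nm2 / 100,
       electrons_per_pixel = e_px, convention = convention)
}

#' Dice overlap coefficient of two binary masks
#'
#' `2 |A and B| / (|A| + |B|)`; two empty masks are defined to agree
#' perfectly (1.0).
#'
#' @param a,b binary arrays of identical shape.
#' @return Dice score in `[0, 1]`.
#' @export
dice <- function(a, b) {
  a <- a > 0; b <- b > 0
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1.0)
  2 * sum(a & b) / (sa + sb)
}
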