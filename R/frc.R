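## Fourier ring correlation: two-image reference, calibrated one-image
## estimate, patchwise local-resolution maps and depth-of-field grouping.

.frc_curve <- function(freq, corr, n, ring_width) {
  structure(list(freq = freq, corr = corr, n = n, ring_width = ring_width),
            class = "frc_curve")
}

#' @export
print.frc_curve <- function(x, ...) {
  cat(sprintf("frc_curve: %d rings, corr[1] = %.3f, crossing(0.143) = %.3f\n",
              length(x$freq), x$corr[1],
              as.numeric(crossing_frequency(x))))
  invisible(x)
}

## shared ring accumulation over spectra Fa, Fb at the samples `keep`
.ring_correlate <- function(Fa, Fb, r, keep, nb) {
  bin <- findInterval(r, seq(0, 1, length.out = nb + 1),
                      rightmost.closed = TRUE)
  keep <- keep & bin >= 1L & bin <= nb
  b <- bin[keep]
  num <- tapply(Re(Fa * Conj(Fb))[keep], b, sum)
  da <- tapply(abs(Fa[keep])^2, b, sum)
  db <- tapply(abs(Fb[keep])^2, b, sum)
  n <- tapply(rep(1, sum(keep)), b, sum)
  den <- sqrt(da * db)
  corr <- ifelse(den > 0, num / den, 0)
  idx <- as.integer(names(num))
  .frc_curve(freq = (idx - 0.5) / nb, corr = as.numeric(corr),
             n = as.integer(n), ring_width = NA_real_)
}

#' Two-image Fourier ring correlation
#'
#' Cross-correlates the Fourier transforms of two images of the same field
#' of view within radial frequency rings:
#' `corr(ring) = Re sum(Fa conj(Fb)) / sqrt(sum|Fa|^2 sum|Fb|^2)`.
#' Frequencies are normalized to the Nyquist frequency (1 = Nyquist), so
#' curves from images of different sizes are directly comparable.
#'
#' @param a,b 2D numeric matrices of identical shape.
#' @param ring_width ring width in frequency samples (of the shorter axis).
#' @param apodize apply a Tukey(0.25) taper (after mean removal) before the
#'   FFT; kept consistent between calibration and application.
#' @return an object of class `frc_curve` with fields `freq`, `corr`, `n`
#'   (samples per ring) and `ring_width`.
#' @export
frc_two_image <- function(a, b, ring_width = 1, apodize = TRUE) {
  a <- .as_image_matrix(a); b <- .as_image_matrix(b)
  if (!identical(dim(a), dim(b))) stop("images must have the same shape")
  h <- nrow(a); w <- ncol(a)
  if (apodize) {
    wn <- .tukey2(h, w, 0.25)
    a <- (a - mean(a)) * wn
    b <- (b - mean(b)) * wn
  }
  r <- .radius_grid(h, w)
  nb <- max(1L, floor(min(h, w) / 2 / ring_width))
  cv <- .ring_correlate(fft(a), fft(b), r, keep = r > 0, nb = nb)
  cv$ring_width <- ring_width
  cv
}

#' Threshold crossing of an FRC curve
#'
#' First normalized frequency at which the correlation falls below the
#' threshold, linearly interpolated between the two adjacent rings. If the
#' curve never crosses, 1.0 is returned with attribute `at_nyquist = TRUE`;
#' if already below the threshold at the first ring, the first frequency is
#' returned with attribute `unreliable = TRUE`.
#'
#' @param curve an `frc_curve`.
#' @param threshold correlation threshold (default 0.143).
#' @return normalized crossing frequency with attributes `at_nyquist` and
#'   `unreliable`.
#' @export
crossing_frequency <- function(curve, threshold = 0.143) {
  stopifnot(length(curve$freq) > 0)
  below <- which(curve$corr < threshold)
  if (!length(below))
    return(structure(1.0, at_nyquist = TRUE, unreliable = FALSE))
  i <- below[1]
  if (i == 1L)
    return(structure(curve$freq[1], at_nyquist = FALSE, unreliable = TRUE))
  f0 <- curve$freq[i - 1]; f1 <- curve$freq[i]
  c0 <- curve$corr[i - 1]; c1 <- curve$corr[i]
  structure(f0 + (f1 - f0) * (c0 - threshold) / (c0 - c1),
            at_nyquist = FALSE, unreliable = FALSE)
}

#' Checkerboard split into diagonal sub-lattices
#'
#' Returns the two stride-2 diagonal sub-images: `a` from (even row, even
#' column) pixels and `b` from (odd row, odd column) pixels, 0-based; each
#' is half-size along both axes. Odd trailing rows/columns are cropped.
#'
#' @param image 2D numeric matrix, at least 2x2.
#' @return list of matrices `a` and `b`.
#' @export
checkerboard_split <- function(image) {
  image <- .as_image_matrix(image)
  if (nrow(image) < 2 || ncol(image) < 2) stop("image smaller than 2x2")
  h <- 2L * (nrow(image) %/% 2L); w <- 2L * (ncol(image) %/% 2L)
  image <- image[seq_len(h), seq_len(w), drop = FALSE]
  list(a = image[seq(1L, h, 2L), seq(1L, w, 2L), drop = FALSE],
       b = image[seq(2L, h, 2L), seq(2L, w, 2L), drop = FALSE])
}

## parity (quincunx) one-image FRC on the full grid: FRC between the two
## zero-filled checkerboard-parity halves. Each half is de-meaned on its
## own support (the parity masks otherwise carry large opposite-sign DC
## terms that leak into the lowest rings), and ring samples nearer to the
## Nyquist-corner alias centre than to DC are excluded, removing the
## contribution of the parity-modulation fold.
.frc_one_parity <- function(image, ring_width = 1, apodize = TRUE) {
  h <- nrow(image); w <- ncol(image)
  if (apodize) image <- (image - mean(image)) * .tukey2(h, w, 0.25)
  M <- outer(seq_len(h), seq_len(w), function(y, x) (y + x) %% 2L == 0L)
  a1 <- image * M; a2 <- image * !M
  a1 <- a1 - (sum(a1) / sum(M)) * M
  a2 <- a2 - (sum(a2) / sum(!M)) * !M
  fy <- 2 * .fftfreq(h); fx <- 2 * .fftfreq(w)
  r <- sqrt(outer(fy^2, fx^2, `+`))
  dy <- pmin(abs(fy - 1), abs(fy + 1))
  dx <- pmin(abs(fx - 1), abs(fx + 1))
  dcorner <- sqrt(outer(dy^2, dx^2, `+`))
  nb <- max(1L, floor(min(h, w) / 2 / ring_width))
  cv <- .ring_correlate(fft(a1), fft(a2), r, keep = r > 0 & dcorner > r,
                        nb = nb)
  cv$ring_width <- ring_width
  cv
}

#' One-image FRC with optional calibration
#'
#' Estimates the FRC crossing from a single image by splitting it into two
#' half-data images with independent noise and correlating them. The
#' default `"parity"` method compares the two zero-filled checkerboard-
#' parity halves on the full grid, which preserves frequency support up to
#' Nyquist (fold-contaminated ring samples are excluded); `"sublattice"`
#' correlates the two half-size diagonal sub-images of
#' [checkerboard_split()], whose frequency axis is rescaled by the sampling
#' lattice, and relies entirely on the calibration to undo that bias.
#' The raw crossing `r_co1` is mapped through the calibration model when
#' one is supplied (identity otherwise).
#'
#' @param image 2D numeric matrix, at least 32x32.
#' @param model a `frc_calibration` from [fit_calibration()], or `NULL`.
#' @param method `"parity"` (default) or `"sublattice"`.
#' @param ring_width,apodize passed to the underlying FRC.
#' @param threshold crossing threshold.
#' @return list with `r_co1` (raw crossing), `r_corrected` (calibrated),
#'   `curve` and `method`.
#' @export
frc_one_image <- function(image, model = NULL,
                          method = c("parity", "sublattice"),
                          ring_width = 1, apodize = TRUE,
                          threshold = 0.143) {
  image <- .as_image_matrix(image)
  method <- match.arg(method)
  if (nrow(image) < 32 || ncol(image) < 32) stop("image must be >= 32x32")
  curve <- if (method == "parity") {
    .frc_one_parity(image, ring_width, apodize)
  } else {
    sp <- checkerboard_split(image)
    frc_two_image(sp$a, sp$b, ring_width, apodize)
  }
  r_co1 <- crossing_frequency(curve, threshold)
  r_corr <- if (is.null(model)) as.numeric(r_co1)
            else apply_calibration(model, as.numeric(r_co1))
  list(r_co1 = as.numeric(r_co1), r_corrected = r_corr, curve = curve,
       method = method, at_nyquist = isTRUE(attr(r_co1, "at_nyquist")))
}

#' Fit the one-image FRC calibration
#'
#' Least-squares fit of the ratio `r_co1 / r_ref` as a polynomial g in
#' `r_co1`, from paired crossings measured on images for which both the
#' one-image and the gold-standard two-image FRC are available. The
#' corrected crossing is `r_co1 / g(r_co1)`.
#'
#' @param pairs data frame (or list) with columns/fields `r_co1`, `r_ref`.
#' @param degree polynomial degree of g (default 2, quadratic).
#' @param method the split method the pairs were measured with; stored as
#'   provenance and enforced when the model is applied.
#' @return object of class `frc_calibration`: `coefficients`, `degree`,
#'   `residual_rms` (of corrected vs reference crossings), `n_pairs`,
#'   `domain`, `method`.
#' @export
fit_calibration <- function(pairs, degree = 2L, method = "parity") {
  pairs <- as.data.frame(pairs)
  stopifnot(all(c("r_co1", "r_ref") %in% names(pairs)))
  if (nrow(pairs) < 3) stop("need at least 3 calibration pairs")
  if (any(pairs$r_ref <= 0)) stop("pairs with r_ref <= 0 are invalid")
  if (diff(range(pairs$r_co1)) <= 0)
    stop("calibration pairs must span a range of r_co1")
  X <- outer(pairs$r_co1, 0:degree, `^`)
  ratio <- pairs$r_co1 / pairs$r_ref
  fit <- lm.fit(X, ratio)
  if (fit$rank < degree + 1L)
    stop("rank-deficient calibration fit; vary the pairs or lower degree")
  cf <- fit$coefficients
  model <- structure(list(coefficients = as.numeric(cf),
                          degree = as.integer(degree),
                          n_pairs = nrow(pairs),
                          domain = range(pairs$r_co1),
                          method = method,
                          residual_rms = NA_real_),
                     class = "frc_calibration")
  corrected <- apply_calibration(model, pairs$r_co1)
  model$residual_rms <- sqrt(mean((corrected - pairs$r_ref)^2))
  model
}

#' Apply an FRC calibration model to raw crossings
#'
#' @param model a `frc_calibration`.
#' @param r_co1 numeric vector of raw one-image crossings.
#' @return corrected crossing frequencies (clamped to be positive).
#' @export
apply_calibration <- function(model, r_co1) {
  stopifnot(inherits(model, "frc_calibration"))
  g <- drop(outer(r_co1, 0:model$degree, `^`) %*% model$coefficients)
  g <- pmax(g, 1e-6)
  pmax(r_co1 / g, 1e-6)
}

#' @export
print.frc_calibration <- function(x, ...) {
  cat(sprintf(
    "frc_calibration (%s split): degree %d, %d pairs, residual RMS %.4f\n",
    x$method, x$degree, x$n_pairs, x$residual_rms))
  invisible(x)
}

#' Save / load a calibration model (bit-exact JSON round trip)
#'
#' Coefficients are serialized as C99 hex-float strings so that the
#' reloaded model is bit-identical to the saved one.
#'
#' @param model a `frc_calibration`.
#' @param path JSON file path.
#' @return `write_calibration`: `path` invisibly; `read_calibration`: the
#'   model.
#' @export
write_calibration <- function(model, path) {
  stopifnot(inherits(model, "frc_calibration"))
  payload <- list(
    type = "frc_calibration",
    coefficients_hex = sprintf("%a", model$coefficients),
    degree = model$degree, n_pairs = model$n_pairs,
    domain_hex = sprintf("%a", model$domain),
    method = model$method,
    residual_rms_hex = sprintf("%a", model$residual_rms))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @param path JSON file path.
#' @export
read_calibration <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$type, "frc_calibration"))
    stop("not a calibration file: ", path)
  parse_hex <- function(s) vapply(s, as.numeric, numeric(1), USE.NAMES = FALSE)
  structure(list(coefficients = parse_hex(p$coefficients_hex),
                 degree = as.integer(p$degree),
                 n_pairs = as.integer(p$n_pairs),
                 domain = parse_hex(p$domain_hex),
                 method = p$method,
                 residual_rms = parse_hex(p$residual_rms_hex)),
            class = "frc_calibration")
}

#' Convert a normalized crossing frequency to a resolution in nm
#'
#' The crossing frequency is a fraction of Nyquist; its period is
#' `2 * pixel_nm / crossing`, so a crossing of 1 gives the Nyquist period
#' of two pixels. Resolution can therefore never be better than
#' `2 * pixel_nm`.
#'
#' @param crossing normalized frequency in (0, 1] (values above 1 are
#'   clamped).
#' @param pixel_nm pixel size in nm.
#' @return resolution in nm.
#' @export
resolution_nm <- function(crossing, pixel_nm) {
  if (any(crossing <= 0)) stop("crossing must be positive")
  2 * pixel_nm / pmin(crossing, 1)
}

#' Patchwise local-resolution map
#'
#' Splits the image into a non-overlapping grid of `patch_size` patches
#' (trailing partial patches dropped), computes the calibrated one-image
#' FRC resolution of each patch, and summarizes the included patches.
#' Patches overlapping `exclude_mask` by more than 50% (e.g. the
#' organoplatinum protective layer) are marked excluded and left out of the
#' summary.
#'
#' @param image 2D numeric matrix larger than `patch_size` in both axes.
#' @param pixel_nm pixel size in nm.
#' @param model optional `frc_calibration`.
#' @param patch_size patch side in pixels (default 256).
#' @param exclude_mask optional binary matrix, same shape as `image`.
#' @param ... passed to [frc_one_image()].
#' @return object of class `resolution_map`: data frame `patches`
#'   (`patch_y`, `patch_x`, 0-based origins, `r_co1`, `r_corrected`,
#'   `resolution_nm`, `excluded`), `patch_size`, `pixel_nm`,
#'   `mean_resolution_nm`, `sd_resolution_nm`.
#' @export
local_resolution_map <- function(image, pixel_nm, model = NULL,
                                 patch_size = 256L, exclude_mask = NULL,
                                 ...) {
  image <- .as_image_matrix(image)
  h <- nrow(image); w <- ncol(image)
  if (h < patch_size || w < patch_size)
    stop("image must be larger than patch_size in both axes")
  ys <- seq(1L, h - patch_size + 1L, by = patch_size)
  xs <- seq(1L, w - patch_size + 1L, by = patch_size)
  grid <- expand.grid(y = ys, x = xs)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    y <- grid$y[i]; x <- grid$x[i]
    patch <- image[y:(y + patch_size - 1L), x:(x + patch_size - 1L)]
    excluded <- FALSE
    if (!is.null(exclude_mask)) {
      ov <- mean(exclude_mask[y:(y + patch_size - 1L),
                              x:(x + patch_size - 1L)] > 0)
      excluded <- ov > 0.5
    }
    fr <- frc_one_image(patch, model = model, ...)
    data.frame(patch_y = y - 1L, patch_x = x - 1L, r_co1 = fr$r_co1,
               r_corrected = fr$r_corrected,
               resolution_nm = resolution_nm(fr$r_corrected, pixel_nm),
               excluded = excluded)
  })
  patches <- do.call(rbind, rows)
  inc <- patches[!patches$excluded, ]
  structure(list(patches = patches, patch_size = as.integer(patch_size),
                 pixel_nm = pixel_nm,
                 mean_resolution_nm = mean(inc$resolution_nm),
                 sd_resolution_nm = sd(inc$resolution_nm)),
            class = "resolution_map")
}

#' @export
print.resolution_map <- function(x, ...) {
  cat(sprintf(
    "resolution_map: %d patches of %d px, resolution %.1f +/- %.1f nm (%d excluded)\n",
    nrow(x$patches), x$patch_size, x$mean_resolution_nm,
    x$sd_resolution_nm, sum(x$patches$excluded)))
  invisible(x)
}

#' Depth of field from a through-focus resolution series
#'
#' Finds the stage position with the lowest mean resolution (best focus)
#' and tests every other position against it with a two-tailed, two-sample
#' equal-variance t-test at alpha = 0.05; positions with p >= 0.05 are
#' "similar". The depth of field is the contiguous run of similar
#' positions containing the best one. Since each stage position represents
#' one focus increment, the span is the run extent plus one median
#' inter-position spacing (n x spacing for a uniform grid). Exactly tied
#' samples are treated as similar.
#'
#' @param series data frame with columns `position_um` and `resolution_nm`
#'   (several resolution samples, e.g. patch values, per position).
#' @param alpha significance level.
#' @return list: `span_um`, `positions` (members of the run), `best`
#'   (position of minimum mean resolution), `p_values` per position.
#' @export
depth_of_field <- function(series, alpha = 0.05) {
  series <- as.data.frame(series)
  stopifnot(all(c("position_um", "resolution_nm") %in% names(series)))
  pos <- sort(unique(series$position_um))
  if (length(pos) < 3) stop("need at least 3 stage positions")
  groups <- split(series$resolution_nm, series$position_um)
  groups <- groups[order(as.numeric(names(groups)))]
  if (any(vapply(groups, length, 1L) < 2))
    stop("need at least 2 resolution samples per position")
  means <- vapply(groups, mean, numeric(1))
  ib <- which.min(means)
  ref <- groups[[ib]]
  pv <- vapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    if (i == ib) return(1)
    if (identical(sort(g), sort(ref))) return(1)        # exact ties
    if (sd(g) == 0 && sd(ref) == 0)
      return(if (mean(g) == mean(ref)) 1 else 0)
    t.test(g, ref, var.equal = TRUE)$p.value
  }, numeric(1))
  similar <- pv >= alpha
  lo <- ib; while (lo > 1L && similar[lo - 1L]) lo <- lo - 1L
  hi <- ib; while (hi < length(pos) && similar[hi + 1L]) hi <- hi + 1L
  members <- pos[lo:hi]
  spacing <- if (length(pos) > 1) median(diff(pos)) else 0
  span <- diff(range(members)) + spacing
  list(span_um = span, positions = members, best = pos[ib],
       p_values = setNames(pv, pos))
}
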