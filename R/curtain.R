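## Curtaining score: isolate vertical-stripe energy with a Fourier wedge,
## threshold its magnitude by minimum cross entropy, report the percentage
## of curtain pixels inside the milled ROI.

#' Fourier wedge filter isolating vertical-stripe structure
#'
#' Keeps only the spectral samples within `wedge_half_angle_deg` of the
#' horizontal frequency axis (the axis that encodes horizontal variation,
#' i.e. vertical real-space stripes), mirrored in both half-planes so the
#' result stays real. Equivalent to subtracting from the image its inverse
#' FFT after removal of the wedge. The DC sample and a one-sample guard
#' around it are always excluded, so the mean intensity never counts as
#' stripe energy.
#'
#' @param image 2D numeric matrix (or 1-slice [image_stack()]), >= 8x8.
#' @param wedge_half_angle_deg half-angle of the wedge in degrees,
#'   in (0, 45). The default 2.5 makes a wedge of 5 degrees total angle.
#' @param apodize apply a Tukey(0.1) taper before the FFT to suppress
#'   edge-discontinuity leakage into the wedge. Disable for exact oracle
#'   comparisons on periodic patterns.
#' @return numeric matrix of the same size containing (to numerical
#'   precision) only vertical-stripe structure.
#' @export
stripe_image <- function(image, wedge_half_angle_deg = 2.5, apodize = TRUE) {
  image <- .as_image_matrix(image)
  if (nrow(image) < 8 || ncol(image) < 8) stop("image must be at least 8x8")
  if (wedge_half_angle_deg <= 0 || wedge_half_angle_deg >= 45)
    stop("wedge_half_angle_deg must be in (0, 45)")
  h <- nrow(image); w <- ncol(image)
  if (apodize) image <- (image - mean(image)) * .tukey2(h, w, 0.1)
  fy <- .fftfreq(h); fx <- .fftfreq(w)
  ang <- atan2(abs(outer(fy, rep(1, w))), abs(outer(rep(1, h), fx)))
  wedge <- ang <= wedge_half_angle_deg * pi / 180
  iy <- pmin(seq_len(h) - 1L, h - (seq_len(h) - 1L))  # wrapped index distance
  ix <- pmin(seq_len(w) - 1L, w - (seq_len(w) - 1L))
  guard <- outer(iy <= 1L, ix <= 1L, `&`)             # DC + 1-sample guard
  wedge[guard] <- FALSE
  Re(fft(fft(image) * wedge, inverse = TRUE)) / (h * w)
}

#' Minimum cross-entropy (Li) threshold
#'
#' Minimizes the Li & Lee cross-entropy criterion
#' `-M0 log(mu0) - M1 log(mu1)` (with `M`, `mu` the first moments and
#' means of the two classes split at the threshold). The classic
#' mean-ratio fixed-point update `(mu0 - mu1) / (log mu0 - log mu1)` is
#' only locally convergent, so the criterion is minimized exactly by a
#' vectorized scan over all distinct split points; the returned value is
#' the midpoint of the optimal split. For a constant input the value
#' itself is returned with attribute `degenerate = TRUE`.
#'
#' @param values numeric vector/matrix of non-negative grey values.
#' @return the threshold (numeric scalar), with attribute `degenerate`.
#' @export
li_threshold <- function(values) {
  v <- as.numeric(values)
  v <- v[is.finite(v)]
  if (!length(v)) stop("empty input")
  if (any(v < 0)) stop("values must be non-negative")
  if (diff(range(v)) == 0)
    return(structure(v[1], degenerate = TRUE))
  eps <- max(min(v[v > 0]), .Machine$double.eps) / 2
  vs <- sort(v)
  n <- length(vs)
  cs <- cumsum(vs)
  splits <- which(diff(vs) > 0)              # low class = vs[1..i]
  m0 <- pmax(cs[splits] / splits, eps)
  m1 <- pmax((cs[n] - cs[splits]) / (n - splits), eps)
  crit <- -cs[splits] * log(m0) - (cs[n] - cs[splits]) * log(m1)
  i <- splits[which.min(crit)]
  structure((vs[i] + vs[i + 1L]) / 2, degenerate = FALSE)
}

#' Curtaining score of an SEM image
#'
#' Curtains are strictly vertical (they run along the milling direction),
#' so the wedge-filtered stripe magnitude is pooled along y into per-column
#' medians before thresholding - a matched aggregation that makes the score
#' insensitive to edge-taper attenuation and to isolated noise pixels.
#' Columns whose pooled magnitude exceeds the Li minimum cross-entropy
#' threshold are curtain columns; the score is the percentage of ROI pixels
#' lying in curtain columns. The threshold is derived from the whole
#' image's columns (the ROI only localizes the count), so a fully
#' curtained milling window still scores near 100. A robust noise floor of
#' `noise_floor_k` times the half-normal scale estimate of the pooled
#' magnitudes (median / 0.6745) guards against the degenerate stripe-free
#' case, where a unimodal noise distribution would otherwise be split near
#' its bulk; a degenerate threshold yields score 0.
#'
#' @param image 2D numeric matrix or 1-slice [image_stack()].
#' @param roi binary matrix marking the milled region to score (default:
#'   whole image). Must be non-empty and the same shape as `image`.
#' @param wedge_half_angle_deg passed to [stripe_image()].
#' @param apodize passed to [stripe_image()]. Off by default here: the
#'   wedge is much narrower than a taper's spectral mainlobe, so windowing
#'   smears genuine stripe energy out of the wedge and attenuates curtains;
#'   with column pooling, the un-windowed wrap-around leakage affects at
#'   most the outermost columns.
#' @param noise_floor_k multiple of the robust noise scale below which
#'   columns are never classified as curtain when the Li threshold does
#'   not separate two magnitude classes.
#' @return object of class `curtain_report`: `score_percent`, `threshold`,
#'   `curtain_mask`, `wedge_half_angle_deg`, `roi_pixel_count`,
#'   `degenerate`.
#' @export
curtain_score <- function(image, roi = NULL, wedge_half_angle_deg = 2.5,
                          apodize = FALSE, noise_floor_k = 3) {
  image <- .as_image_matrix(image)
  if (is.null(roi)) roi <- matrix(TRUE, nrow(image), ncol(image))
  roi <- roi > 0
  if (!identical(dim(roi), dim(image))) stop("roi shape must match image")
  if (!any(roi)) stop("empty ROI")
  s <- abs(stripe_image(image, wedge_half_angle_deg, apodize = apodize))
  col_mag <- apply(s, 2, median)
  th <- li_threshold(col_mag)
  degenerate <- isTRUE(attr(th, "degenerate"))
  if (degenerate) {
    mask <- matrix(FALSE, nrow(image), ncol(image))
    score <- 0
  } else {
    thv <- as.numeric(th)
    hi <- col_mag > thv
    # a genuine curtain population sits across an empty margin from the
    # background columns; a unimodal noise continuum does not
    separated <- any(hi) && any(!hi) &&
      (min(col_mag[hi]) - max(col_mag[!hi])) > 0.25 * thv
    curtain_cols <- if (separated) hi else {
      floor_th <- noise_floor_k * median(col_mag) / 0.6745
      col_mag > max(thv, floor_th)
    }
    mask <- roi & matrix(curtain_cols, nrow(image), ncol(image),
                         byrow = TRUE)
    score <- 100 * sum(mask) / sum(roi)
  }
  structure(list(score_percent = score, threshold = as.numeric(th),
                 curtain_mask = mask,
                 wedge_half_angle_deg = wedge_half_angle_deg,
                 roi_pixel_count = sum(roi), degenerate = degenerate),
            class = "curtain_report")
}

#' @export
print.curtain_report <- function(x, ...) {
  cat(sprintf(
    "curtain_report: score %.2f%% (threshold %.4g, wedge half-angle %g deg, %d ROI px)\n",
    x$score_percent, x$threshold, x$wedge_half_angle_deg,
    x$roi_pixel_count))
  invisible(x)
}
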