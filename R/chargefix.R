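## Charging-artifact suppression: given a mask of charge centres, estimate
## and subtract the asymmetric scan-direction tails row by row, fitting
## smooth Fermi-type sigmoids on either side of each centre.

#' Charging tail functions
#'
#' The left tail `A * (1/(exp((x - x0)/sigma) + 1) - 1)` decays to 0 far
#' left of the centre and to `-A` at the centre; the right tail
#' `A * (-1/(exp((x - x0)/sigma) + 1))` is `-A` at the centre and recovers
#' to 0 far right. Both equal `-A/2` at `x = x0`.
#'
#' @param x column positions (px).
#' @param A tail depth in grey units (>= 0 by convention).
#' @param x0 inflection column (px).
#' @param sigma tail width (px), > 0.
#' @return numeric vector of tail values (<= 0 for A >= 0).
#' @export
tail_left <- function(x, A, x0, sigma) {
  stopifnot(sigma > 0)
  A * (1 / (exp((x - x0) / sigma) + 1) - 1)
}

#' @rdname tail_left
#' @export
tail_right <- function(x, A, x0, sigma) {
  stopifnot(sigma > 0)
  A * (-1 / (exp((x - x0) / sigma) + 1))
}

## one-sided bounded sigmoid fit on (row - background); returns a TailFit
.fit_tail <- function(cols, resid, side, x0_init, sigma_init, win) {
  empty <- list(side = side, A = 0, x0 = x0_init, sigma = sigma_init,
                rms = NA_real_, converged = FALSE, skipped = TRUE)
  if (length(cols) < 5L) return(empty)
  f <- if (side == "left") tail_left else tail_right
  edge_idx <- if (side == "left") which.max(cols) else which.min(cols)
  A_init <- max(1e-3, -2 * resid[edge_idx])
  dat <- data.frame(x = cols, y = resid)
  ## x0 is fitted but constrained to within one pixel of the mask edge:
  ## the inflection physically sits at the segmented centre's boundary,
  ## and a freer x0 is nearly collinear with A on the half-sigmoid the
  ## window exposes (strong bias under noise). A short multi-start over
  ## sigma avoids boundary-trapped local minima of the flat valley.
  best <- NULL
  for (s0 in unique(pmax(0.6, sigma_init * c(1, 3, 6)))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ f(x, A, x0, sigma), data = dat,
        start = list(A = A_init, x0 = x0_init, sigma = s0),
        lower = c(A = 0, x0 = x0_init - 1, sigma = 0.5),
        upper = c(A = Inf, x0 = x0_init + 1, sigma = diff(win) + 1),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-13,
                                             ptol = 1e-13)),
      error = function(e) NULL)
    if (!is.null(fit) &&
        (is.null(best) || stats::deviance(fit) < stats::deviance(best)))
      best <- fit
  }
  if (is.null(best))
    return(utils::modifyList(empty, list(skipped = FALSE)))
  cf <- coef(best)
  list(side = side, A = unname(cf["A"]), x0 = unname(cf["x0"]),
       sigma = unname(cf["sigma"]),
       rms = sqrt(mean(stats::residuals(best)^2)), converged = TRUE,
       skipped = FALSE)
}

#' Fit left/right charging tails on one image row
#'
#' Nonlinear least squares of [tail_left()] on the columns left of the
#' masked interval and [tail_right()] on the columns right of it, applied
#' to `row - background`. Parameters are bounded (`A >= 0`,
#' `sigma in [0.5, window width]`, `x0` within one pixel of the mask edge,
#' where the inflection physically sits) and initialized from the
#' geometry: `x0` at the mask edges, `A` from the residual depth there,
#' `sigma` at a quarter of the centre diameter.
#'
#' @param row numeric vector of grey values.
#' @param mask_interval `c(x_lo, x_hi)` columns of the masked centre in
#'   this row (1-based, inclusive).
#' @param background numeric vector, same length as `row`.
#' @param window_px fit window width on each side of the mask (clipped at
#'   the image edge). Defaults to 4.5x the interval width.
#' @param sigma_init initial sigma (default interval width / 4).
#' @return list with elements `left` and `right`, each a TailFit: `side`,
#'   `A`, `x0`, `sigma`, `rms`, `converged`, `skipped`. Sides with fewer
#'   than 5 available columns are skipped.
#' @export
fit_row_tails <- function(row, mask_interval, background,
                          window_px = NULL, sigma_init = NULL) {
  stopifnot(length(background) == length(row))
  x_lo <- mask_interval[1]; x_hi <- mask_interval[2]
  d <- x_hi - x_lo + 1
  if (is.null(window_px)) window_px <- ceiling(4.5 * d)
  if (is.null(sigma_init)) sigma_init <- max(0.6, d / 4)
  resid <- row - background
  lcols <- seq(max(1L, floor(x_lo - window_px)), x_lo - 1L)
  lcols <- lcols[lcols >= 1L]
  rcols <- seq(x_hi + 1L, min(length(row), ceiling(x_hi + window_px)))
  rcols <- rcols[rcols <= length(row)]
  left <- .fit_tail(lcols, resid[lcols], "left", x0_init = x_lo,
                    sigma_init = sigma_init,
                    win = c(min(lcols, x_lo), x_hi))
  right <- .fit_tail(rcols, resid[rcols], "right", x0_init = x_hi,
                     sigma_init = sigma_init,
                     win = c(x_lo, max(rcols, x_hi)))
  list(left = left, right = right)
}

## mean of up to n_rows rows above (dir = -1) or below (dir = +1) the
## component extent, per column, with pixels inside any centre mask excluded
.pass_background <- function(image, any_mask, row_range, dir, n_rows) {
  H <- nrow(image)
  rows <- if (dir < 0) seq(row_range[1] - n_rows, row_range[1] - 1L)
          else seq(row_range[2] + 1L, row_range[2] + n_rows)
  rows <- rows[rows >= 1L & rows <= H]
  if (!length(rows)) return(NULL)
  block <- image[rows, , drop = FALSE]
  block[any_mask[rows, , drop = FALSE]] <- NA
  bg <- colMeans(block, na.rm = TRUE)
  if (anyNA(bg)) {     # columns fully masked: interpolate from neighbours
    idx <- seq_along(bg)
    ok <- !is.na(bg)
    if (!any(ok)) return(NULL)
    bg <- stats::approx(idx[ok], bg[ok], xout = idx, rule = 2)$y
  }
  bg
}

#' Suppress charging artifacts around segmented centres
#'
#' For each labelled charge centre, the rows intersecting its vertical
#' extent are corrected in two passes: a top pass using the mean of the
#' `n_background_rows` rows immediately above the centre as background, and
#' a bottom pass using the rows immediately below (pixels inside any centre
#' mask are excluded from both means). In each pass, [fit_row_tails()]
#' estimates the left/right sigmoid tails on `row - background` (inflection
#' constrained to within one pixel of the mask edge) and the fitted tails
#' are subtracted from the raw row; the final correction is the average of
#' the available passes. Pixels inside the centre mask are
#' copied unchanged, since there is no information to recover there.
#' `corrected + artifact == image` holds exactly everywhere.
#'
#' @param image 2D numeric matrix or 1-slice [image_stack()].
#' @param centres integer label matrix (one label per centre) or binary
#'   mask (connected components are labelled 8-connected).
#' @param n_background_rows rows averaged for the background (default 20).
#' @param window_factor fit window on each side of a centre, as a multiple
#'   of its equivalent-circle diameter (default 4.5, matching a 9x-wide
#'   profile box).
#' @return list: `corrected`, `artifact` (= image - corrected) and
#'   `artifacts`, a list of per-centre records (`id`, `centroid`,
#'   `diameter_px`, `rows`, `fits` with one left/right TailFit pair per
#'   row per pass).
#' @export
suppress_charging <- function(image, centres, n_background_rows = 20L,
                              window_factor = 4.5) {
  image <- .as_image_matrix(image)
  if (!identical(dim(centres), dim(image)))
    stop("centres mask shape must match image")
  labels <- centres
  if (is.logical(labels) || all(labels %in% c(0, 1)))
    labels <- label_components(labels > 0)
  labels <- label_mask(labels)
  corrected <- image
  any_mask <- labels > 0L
  ids <- sort(unique(labels[labels > 0L]))
  artifacts <- list()
  H <- nrow(image); W <- ncol(image)
  for (id in ids) {
    px <- which(labels == id, arr.ind = TRUE)
    row_range <- range(px[, 1])
    col_range <- range(px[, 2])
    area <- nrow(px)
    diameter <- 2 * sqrt(area / pi)
    win_px <- ceiling(window_factor * diameter)
    bg_top <- .pass_background(image, any_mask, row_range, -1L,
                               n_background_rows)
    bg_bot <- .pass_background(image, any_mask, row_range, +1L,
                               n_background_rows)
    if (is.null(bg_top) && is.null(bg_bot)) {
      warning("component ", id, " touches both image edges; skipped")
      next
    }
    fits <- list()
    for (r in seq(row_range[1], row_range[2])) {
      ## the streak inflection sits at the centre's widest extent, not at
      ## the narrower chord the mask shows in off-centre rows
      interval <- col_range
      row_corr <- numeric(W)
      n_pass <- 0L
      for (pass in c("top", "bottom")) {
        bg <- if (pass == "top") bg_top else bg_bot
        if (is.null(bg)) next
        tf <- fit_row_tails(image[r, ], interval, bg, window_px = win_px,
                            sigma_init = max(0.6, diameter / 4))
        pass_corr <- numeric(W)
        if (tf$left$converged) {
          lc <- seq(max(1L, interval[1] - win_px), interval[1] - 1L)
          lc <- lc[lc >= 1L]
          pass_corr[lc] <- tail_left(lc, tf$left$A, tf$left$x0,
                                     tf$left$sigma)
        }
        if (tf$right$converged) {
          rc <- seq(interval[2] + 1L, min(W, interval[2] + win_px))
          rc <- rc[rc <= W]
          pass_corr[rc] <- tail_right(rc, tf$right$A, tf$right$x0,
                                      tf$right$sigma)
        }
        row_corr <- row_corr + pass_corr
        n_pass <- n_pass + 1L
        fits[[length(fits) + 1L]] <- list(row = r, pass = pass,
                                          left = tf$left, right = tf$right)
      }
      if (n_pass > 0L) {
        row_corr <- row_corr / n_pass
        row_corr[labels[r, ] == id] <- 0    # centre pixels untouched
        corrected[r, ] <- corrected[r, ] - row_corr
      }
    }
    artifacts[[length(artifacts) + 1L]] <- list(
      id = id, centroid = colMeans(px)[c("row", "col")],
      diameter_px = diameter, rows = seq(row_range[1], row_range[2]),
      fits = fits)
  }
  list(corrected = corrected, artifact = image - corrected,
       artifacts = artifacts)
}

#' Averaged line profiles through a charging centre
#'
#' The horizontal profile is the column-wise mean over a box 1 diameter
#' high and 9 diameters wide centred on the charge centre; the vertical
#' profile is the row-wise mean over a box 9 diameters high and 1 wide.
#' Boxes are clipped at the image edge, in which case the `clipped` flag is
#' set and the profile shortened.
#'
#' @param image 2D numeric matrix.
#' @param centre `c(y, x)` centre position (px).
#' @param diameter_px charging-centre diameter (>= 1).
#' @return list with `horizontal`, `vertical` (named numeric vectors,
#'   names = image coordinates along the profile), `clipped_h`,
#'   `clipped_v`.
#' @export
line_profiles <- function(image, centre, diameter_px) {
  image <- .as_image_matrix(image)
  stopifnot(diameter_px >= 1)
  H <- nrow(image); W <- ncol(image)
  y <- centre[1]; x <- centre[2]
  if (y < 1 || y > H || x < 1 || x > W) stop("centre outside image")
  d <- diameter_px
  half <- function(k) k / 2
  clip <- function(lo, hi, n) c(max(1L, round(lo)), min(n, round(hi)))
  hy <- clip(y - half(d), y + half(d), H)
  hx <- clip(x - half(9 * d), x + half(9 * d), W)
  vy <- clip(y - half(9 * d), y + half(9 * d), H)
  vx <- clip(x - half(d), x + half(d), W)
  horiz <- colMeans(image[hy[1]:hy[2], hx[1]:hx[2], drop = FALSE])
  vert <- rowMeans(image[vy[1]:vy[2], vx[1]:vx[2], drop = FALSE])
  names(horiz) <- hx[1]:hx[2]
  names(vert) <- vy[1]:vy[2]
  list(horizontal = horiz, vertical = vert,
       clipped_h = (hx[2] - hx[1] + 1L) < round(9 * d),
       clipped_v = (vy[2] - vy[1] + 1L) < round(9 * d))
}

#' Naive dark-blob charge-centre detector (convenience only)
#'
#' A simple fallback that thresholds dark pixels and size-filters the
#' connected components. This is a convenience helper, not the trained
#' segmentation used to produce curated centre masks; for quantitative
#' work supply a proper mask to [suppress_charging()].
#'
#' @param image 2D numeric matrix.
#' @param quantile_dark grey quantile below which pixels are candidate
#'   centre pixels.
#' @param min_px,max_px component size limits in pixels.
#' @return integer label matrix.
#' @export
detect_charge_centres <- function(image, quantile_dark = 0.005,
                                  min_px = 9L, max_px = Inf) {
  image <- .as_image_matrix(image)
  th <- quantile(image, quantile_dark)
  lab <- label_components(image <= th)
  keep <- which(tabulate(lab[lab > 0L]) >= min_px &
                  tabulate(lab[lab > 0L]) <= max_px)
  out <- matrix(0L, nrow(image), ncol(image))
  for (i in seq_along(keep)) out[lab == keep[i]] <- i
  out
}
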