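# Drift, bead fits, shape metrics, tilt, FWHM, dose, Dice.

test_that("landmark drift distances and normalization are exact", {
  d0 <- landmark_drift(data.frame(x1 = 3, y1 = 4, x2 = 3, y2 = 4),
                       c(100, 100), pixel_nm = 2)
  expect_equal(d0$pairs$d_px, 0)
  d1 <- landmark_drift(data.frame(x1 = 0, y1 = 0, x2 = 3, y2 = 4),
                       c(30, 40), pixel_nm = 2)
  expect_equal(d1$pairs$d_px, 5)
  expect_equal(d1$pairs$d_nm, 10)
  expect_equal(d1$pairs$normalized, 5 / 50)
  expect_error(landmark_drift(data.frame(), c(10, 10), 1), "empty")
})

test_that("drift summary matches a known shift under noise", {
  set.seed(17)
  n <- 100
  x1 <- runif(n, 10, 90); y1 <- runif(n, 10, 90)
  pairs <- data.frame(x1 = x1, y1 = y1,
                      x2 = x1 + 2 + rnorm(n), y2 = y1 + 1 + rnorm(n))
  d <- landmark_drift(pairs, c(100, 100), pixel_nm = 1)
  # Rician mean of |(2,1) + N(0, I)| is close to sqrt(5), slightly above
  expect_lt(abs(d$mean_nm - sqrt(5)), 0.5)
  # normalized values invariant to uniform rescaling of px coordinates
  d2 <- landmark_drift(pairs * 2, c(200, 200), pixel_nm = 1)
  expect_equal(d2$pairs$normalized, d$pairs$normalized)
})

test_that("bead areas count pixels in physical units", {
  m <- matrix(FALSE, 30, 30)
  m[raster_disk(30, 30, 15, 15, 5.6)] <- TRUE   # 100 px? count whatever
  n_px <- sum(m)
  ar <- bead_areas(m, pixel_nm = 2)
  expect_equal(ar$area_nm2, n_px * 4)
  expect_equal(ar$slice, 1)
  expect_error(bead_areas(matrix(FALSE, 5, 5), 2), "empty")
})

test_that("bead areas match the analytic sphere sections", {
  g <- gen_bead_stack(data.frame(d_nm = 1000, z_c_nm = 575, y = 32, x = 32),
                      true_step_nm = 50, nominal_step_nm = 50,
                      pixel_nm = 20, shape = c(24, 64, 64))
  ar <- bead_areas(g$mask, pixel_nm = 20)
  depths <- (ar$slice - 1) * 50
  analytic <- pi * pmax(0, 500^2 - (depths - 575)^2)
  # rasterization tolerance: half the perimeter in pixel areas
  tol <- (2 * pi * sqrt(analytic / pi) / 20 / 2 + 2) * 400
  expect_true(all(abs(ar$area_nm2 - analytic) <= tol))
  # no rows for slices without bead pixels
  expect_true(all(tapply(ar$area_nm2, ar$slice, sum) > 0))
})

test_that("bead fit recovers noiseless forward-model parameters exactly", {
  z <- 1:21
  d <- 1000; z_c <- 525; alpha <- 1
  areas <- data.frame(slice = z,
                      area_nm2 = pi * pmax(0, (d / 2)^2 -
                                             (alpha * (z * 50 - z_c))^2))
  f <- fit_bead(areas, nominal_step_nm = 50)
  expect_true(f$ok)
  expect_lt(abs(f$d_nm - d) / d, 1e-3)
  expect_lt(abs(f$alpha - 1), 1e-3)
  expect_lt(abs(f$z_c_nm - z_c) / z_c, 1e-3)
})

test_that("bead fit is invariant to the slice origin", {
  mk <- function(z0) {
    z <- z0 + (0:20)
    data.frame(slice = z, area_nm2 = pi * pmax(0, 500^2 -
                                                 (0.96 * (z * 50 - 600 -
                                                            z0 * 48))^2))
  }
  f1 <- fit_bead(mk(0), 50)
  f2 <- fit_bead(mk(7), 50)
  expect_equal(f1$d_nm, f2$d_nm, tolerance = 1e-5)
  expect_equal(f1$alpha, f2$alpha, tolerance = 1e-5)
})

test_that("bead fit flags degenerate input", {
  expect_false(fit_bead(data.frame(slice = 1:6, area_nm2 = rep(5, 6)),
                        50)$ok)
  expect_false(fit_bead(data.frame(slice = 1:3, area_nm2 = c(1, 2, 1)),
                        50)$ok)
})

test_that("bead fit tolerates multiplicative area noise", {
  z <- 1:21
  true_area <- pi * pmax(0, 500^2 - (0.962 * (z * 50 - 520))^2)
  errs <- vapply(1:20, function(s) {
    set.seed(s)
    a <- data.frame(slice = z,
                    area_nm2 = true_area * (1 + rnorm(21, sd = 0.05)))
    abs(fit_bead(a, 50)$alpha - 0.962) / 0.962
  }, numeric(1))
  expect_lt(median(errs), 0.03)
})

test_that("shape metrics are ~1 for a disk and track ellipse geometry", {
  disk <- raster_disk(120, 120, 60, 60, 50)
  s <- shape_metrics(disk)
  expect_lt(abs(s$circularity - 1), 0.05)
  expect_lt(abs(s$roundness - 1), 0.05)
  expect_lt(abs(s$aspect_ratio - 1), 0.05)

  ell <- raster_ellipse(140, 140, 70, 70, 30, 60)
  se <- shape_metrics(ell)
  expect_lt(abs(se$aspect_ratio - 2), 0.1)
  expect_lt(abs(se$roundness - 0.5), 0.03)

  line <- matrix(FALSE, 20, 120)
  line[10, 11:110] <- TRUE
  sl <- shape_metrics(line)
  expect_lt(sl$circularity, 0.1)

  two <- matrix(FALSE, 20, 20)
  two[3, 3] <- TRUE; two[15, 15] <- TRUE
  expect_error(shape_metrics(two), "single connected")
})

test_that("tilt foreshortening inverts the sin(alpha) compression", {
  expect_equal(tilt_foreshortening(7.3, 90), 7.3)
  expect_equal(tilt_foreshortening(0.788, 52), 1.000, tolerance = 1e-3)
  # round trip exact to numerical precision
  l <- 12.345
  expect_equal(tilt_foreshortening(l * sin(52 * pi / 180), 52), l,
               tolerance = 1e-12)
  expect_error(tilt_foreshortening(1, 0), "tilt")
})

test_that("stretching the image restores circular shapes", {
  s52 <- sin(52 * pi / 180)
  ell <- raster_ellipse(160, 160, 80, 80, 50 * s52, 50)
  stretched <- stretch_image(ell * 1, 52) > 0.5
  sm <- shape_metrics(stretched)
  expect_lt(abs(sm$aspect_ratio - 1), 0.06)
})

test_that("fwhm matches analytic widths", {
  x <- seq_len(201)
  gauss <- 10 + 50 * exp(-(x - 101)^2 / (2 * 10^2))
  expect_lt(abs(fwhm(gauss) - 2 * sqrt(2 * log(2)) * 10) /
              (2 * sqrt(2 * log(2)) * 10), 0.02)
  tophat <- c(rep(0, 60), rep(10, 20), rep(0, 60))
  expect_lt(abs(fwhm(tophat) - 20), 1 + 1e-9)
  # dips are treated like peaks
  expect_lt(abs(fwhm(-gauss) - fwhm(gauss)), 1e-9)
  expect_error(fwhm(seq(0, 1, length.out = 50)), "crossing|peak")
})

test_that("electron dose follows N t / A with both conventions", {
  p <- imaging_params(1.2, 6.25, 100, 1, 1)
  d <- electron_dose(p)
  manual <- 6.25e-12 / 1.602176634e-19 * 100e-9 / 1
  expect_equal(d$e_per_nm2, manual, tolerance = 1e-9)
  expect_equal(d$e_per_nm2, 3.901, tolerance = 1e-3)
  expect_equal(d$e_per_A2, 0.03901, tolerance = 1e-3)

  # dose scales linearly in current; the zero-current limit is zero
  d_zero <- electron_dose(list(current_pA = 0, dwell_ns = 100,
                               line_integration = 1, pixel_nm = 1))
  expect_equal(d_zero$e_per_nm2, 0)

  vero <- imaging_params(1.2, 6.25, 100, 100, 1.927)
  single <- electron_dose(vero, convention = "single_pass")
  manual_single <- 6.25e-12 / 1.602176634e-19 * 100e-9 / 1.927^2 / 100
  expect_equal(single$e_per_A2, manual_single, tolerance = 1e-9)
  total <- electron_dose(vero, convention = "total")
  expect_equal(total$e_per_A2, 100 * single$e_per_A2)
})

test_that("dice overlap has its closed-form values and symmetry", {
  a <- matrix(FALSE, 20, 20); a[1:10, 1:10] <- TRUE
  expect_equal(dice(a, a), 1)
  b <- matrix(FALSE, 20, 20); b[11:20, 11:20] <- TRUE
  expect_equal(dice(a, b), 0)
  # |a| = |b| = 100, overlap 50
  c2 <- matrix(FALSE, 20, 20); c2[1:10, 6:15] <- TRUE
  expect_equal(dice(a, c2), 0.5)
  expect_equal(dice(a, c2), dice(c2, a))
  expect_equal(dice(matrix(FALSE, 3, 3), matrix(FALSE, 3, 3)), 1)
  expect_error(dice(a, matrix(FALSE, 5, 5)), "shape")
})
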