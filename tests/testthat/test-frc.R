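# FRC curves, crossings, checkerboard splits, calibration, maps, DOF.

test_that("two-image FRC self-correlation is 1 and symmetric", {
  set.seed(1)
  a <- matrix(rnorm(64 * 64), 64, 64)
  cv <- frc_two_image(a, a)
  expect_true(all(abs(cv$corr - 1) < 1e-9))
  b <- matrix(rnorm(64 * 64), 64, 64)
  expect_equal(frc_two_image(a, b)$corr, frc_two_image(b, a)$corr)
  expect_error(frc_two_image(a, matrix(0, 32, 32)), "same shape")
})

test_that("independent white noise decorrelates within the null bound", {
  set.seed(2)
  a <- matrix(rnorm(128 * 128), 128, 128)
  b <- matrix(rnorm(128 * 128), 128, 128)
  cv <- frc_two_image(a, b)
  beyond <- seq_along(cv$corr) > 1
  expect_true(all(abs(cv$corr[beyond]) < 3 / sqrt(cv$n[beyond])))
})

test_that("crossing frequency interpolates linearly and sets flags", {
  cv <- structure(list(freq = c(0, 0.33, 0.66, 1),
                       corr = c(1, 0.8, 0.1, 0), n = rep(10L, 4)),
                  class = "frc_curve")
  x <- crossing_frequency(cv)
  expect_equal(as.numeric(x), 0.33 + 0.33 * (0.8 - 0.143) / (0.8 - 0.1),
               tolerance = 1e-12)
  all1 <- structure(list(freq = c(0.25, 0.75), corr = c(1, 1)),
                    class = "frc_curve")
  x1 <- crossing_frequency(all1)
  expect_equal(as.numeric(x1), 1.0)
  expect_true(attr(x1, "at_nyquist"))
  low <- structure(list(freq = c(0.25, 0.75), corr = c(0.1, 0.05)),
                   class = "frc_curve")
  xl <- crossing_frequency(low)
  expect_equal(as.numeric(xl), 0.25)
  expect_true(attr(xl, "unreliable"))
})

test_that("checkerboard split takes the two diagonal sub-lattices", {
  m <- matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE)
  sp <- checkerboard_split(m)
  expect_identical(sp$a, matrix(1, 1, 1))
  expect_identical(sp$b, matrix(4, 1, 1))

  cm <- matrix(5, 6, 6)
  spc <- checkerboard_split(cm)
  expect_identical(spc$a, spc$b)

  # parity checkerboard: both diagonal sub-lattices sit on even parity,
  # so both halves are constant +1 (enumerated oracle)
  cb <- outer(0:5, 0:5, function(y, x) (-1)^(y + x))
  spb <- checkerboard_split(cb)
  expect_true(all(spb$a == 1) && all(spb$b == 1))
  # row-alternating pattern separates the sub-lattices into +1 / -1
  rows <- outer(0:5, 0:5, function(y, x) (-1)^y)
  spr <- checkerboard_split(rows)
  expect_true(all(spr$a == 1) && all(spr$b == -1))
  expect_error(checkerboard_split(matrix(1, 1, 3)), "2x2")
})

test_that("one-image FRC is deterministic and flags clean images", {
  p <- gen_frc_pair(128, cutoff = 0.3, snr = Inf, seed = 3)
  # noiseless: the two sub-lattice halves are nearly identical, the FRC
  # never crosses and the estimate saturates at Nyquist
  f1 <- frc_one_image(p$a, method = "sublattice")
  f2 <- frc_one_image(p$a, method = "sublattice")
  expect_identical(f1$r_co1, f2$r_co1)
  expect_true(f1$at_nyquist)
  expect_equal(f1$r_co1, 1.0)

  pn <- gen_frc_pair(256, cutoff = 0.4, snr = 10, seed = 4)
  fr <- frc_one_image(pn$a)
  expect_lt(abs(fr$r_co1 - 0.4), 0.08)
  frs <- frc_one_image(pn$a, method = "sublattice")
  expect_true(is.finite(frs$r_co1))
})

test_that("calibration is identity on perfect pairs and recovers a factor", {
  pairs <- data.frame(r_co1 = seq(0.2, 0.8, 0.1),
                      r_ref = seq(0.2, 0.8, 0.1))
  m <- fit_calibration(pairs)
  expect_equal(apply_calibration(m, pairs$r_co1), pairs$r_ref,
               tolerance = 1e-9)

  pairs2 <- data.frame(r_co1 = seq(0.24, 0.96, 0.12))
  pairs2$r_ref <- pairs2$r_co1 / 1.2
  m2 <- fit_calibration(pairs2)
  expect_equal(apply_calibration(m2, 0.6), 0.5, tolerance = 0.01)

  expect_error(fit_calibration(data.frame(r_co1 = c(0.5, 0.5, 0.5),
                                          r_ref = c(0.4, 0.4, 0.4))),
               "span a range")
  expect_error(fit_calibration(data.frame(r_co1 = c(0.2, 0.4, 0.6),
                                          r_ref = c(0.2, 0, 0.6))),
               "r_ref")
})

test_that("calibration serializes and reloads bit-exactly", {
  set.seed(5)
  pairs <- data.frame(r_co1 = runif(10, 0.2, 0.9))
  pairs$r_ref <- pairs$r_co1 / (1.1 + 0.3 * pairs$r_co1) +
    rnorm(10, sd = 0.005)
  m <- fit_calibration(pairs)
  p <- file.path(tempdir(), "model.json")
  write_calibration(m, p)
  m2 <- read_calibration(p)
  expect_identical(m$coefficients, m2$coefficients)
  expect_identical(m$domain, m2$domain)
  expect_identical(m$residual_rms, m2$residual_rms)
  expect_identical(apply_calibration(m, 0.55), apply_calibration(m2, 0.55))
})

test_that("crossing frequencies convert to nm", {
  expect_equal(resolution_nm(1.0, 5), 10)
  expect_equal(resolution_nm(0.5, 6.745), 26.98)
  expect_equal(resolution_nm(0.25, 1.927), 15.416)
  expect_error(resolution_nm(0, 5), "positive")
})

test_that("local resolution map is uniform on homogeneous fields and
           degrades on blurred regions", {
  p <- gen_frc_pair(256, cutoff = 0.5, snr = 10, seed = 6)
  m <- local_resolution_map(p$a, pixel_nm = 5, patch_size = 64)
  vals <- m$patches$resolution_nm
  expect_true(all(abs(vals - mean(vals)) <= 3 * sd(vals) + 1e-9))
  expect_true(all(vals >= 2 * 5 - 1e-9))     # Nyquist bound

  # blur the *signal* of the right half, then add noise, so the right
  # half genuinely carries less resolvable detail
  p7 <- gen_frc_pair(c(128, 256), cutoff = 0.9, snr = Inf, seed = 7)
  sig <- p7$signal
  sig[, 129:256] <- fibsemqc:::.gauss_smooth(sig, 2)[, 129:256]
  set.seed(77)
  blurred <- sig + matrix(rnorm(length(sig), sd = sd(sig) / 10),
                          nrow(sig), ncol(sig))
  mm <- local_resolution_map(blurred, pixel_nm = 5, patch_size = 64)
  left_mean <- mean(mm$patches$resolution_nm[mm$patches$patch_x < 128])
  right_mean <- mean(mm$patches$resolution_nm[mm$patches$patch_x >= 128])
  expect_gt(right_mean, left_mean)
})

test_that("excluded patches are dropped from the map summary", {
  p <- gen_frc_pair(192, cutoff = 0.5, snr = 10, seed = 8)
  excl <- matrix(FALSE, 192, 192)
  excl[1:64, ] <- TRUE
  m <- local_resolution_map(p$a, pixel_nm = 5, patch_size = 64,
                            exclude_mask = excl)
  expect_true(all(m$patches$excluded[m$patches$patch_y == 0]))
  inc <- m$patches[!m$patches$excluded, ]
  expect_equal(m$mean_resolution_nm, mean(inc$resolution_nm))
})

test_that("estimated resolution degrades monotonically with noise", {
  res <- vapply(c(2, 5, 10, 50), function(snr) {
    mean(vapply(1:3, function(s) {
      p <- gen_frc_pair(128, cutoff = 0.6, snr = snr, seed = 100 + s)
      as.numeric(crossing_frequency(frc_two_image(p$a, p$b)))
    }, numeric(1)))
  }, numeric(1))
  # higher snr => larger crossing => better (smaller) resolution
  expect_true(all(diff(res) >= -1e-9))
})

test_that("depth of field groups statistically similar positions", {
  # identical distributions everywhere: the whole range is in focus
  set.seed(9)
  pos <- seq(0, 30, by = 5)
  flat <- do.call(rbind, lapply(pos, function(p)
    data.frame(position_um = p, resolution_nm = 50 + rnorm(8, sd = 2))))
  d <- depth_of_field(flat)
  expect_setequal(d$positions, pos)
  expect_equal(d$span_um, 35)

  # V-shaped profile with 4 indistinguishable central positions
  set.seed(10)
  mk <- function(p, mu) data.frame(position_um = p,
                                   resolution_nm = mu + rnorm(15, sd = 2))
  v <- rbind(mk(0, 90), mk(5, 70), mk(10, 50.4), mk(15, 50), mk(20, 50.2),
             mk(25, 50.5), mk(30, 75), mk(35, 95))
  dv <- depth_of_field(v)
  expect_equal(dv$span_um, 20, tolerance = 0.26)
  expect_setequal(dv$positions, c(10, 15, 20, 25))

  # an accidental far similar position is excluded by contiguity
  v2 <- rbind(v, mk(40, 50.4))
  dv2 <- depth_of_field(v2)
  expect_false(40 %in% dv2$positions)
})
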