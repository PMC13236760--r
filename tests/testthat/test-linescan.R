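test_that("profiles reproduce analytic sections of a Gaussian spot", {
  f <- make_spot_frame(101, spots = list(c(2.3, 2.3, 1000, 0.35)))
  p <- extract_profile(f, c(2.3, 2.3), angle_deg = 0, width_px = 1)
  analytic <- 1000 * exp(-4 * log(2) * p$x_um^2 / 0.35^2)
  expect_lt(max(abs(p$values - analytic)) / 1000, 0.01)
  # column-constant image gives a constant horizontal profile
  fc <- matrix(rep(seq(10, 20, length.out = 101), each = 101), 101, 101)
  pc <- extract_profile(fc, c(2.3, 2.3), angle_deg = 90)
  expect_lt(diff(range(pc$values)), 1e-6)
  expect_error(extract_profile(f, c(0.1, 0.1), length_px = 50),
               "exits the image")
})

test_that("FWHM is rotation invariant for an isotropic spot", {
  f <- make_spot_frame(101, spots = list(c(2.3, 2.3, 1000, 0.35)))
  w0 <- fit_gaussian(extract_profile(f, c(2.3, 2.3), 0))$fwhm_um
  w45 <- fit_gaussian(extract_profile(f, c(2.3, 2.3), 45))$fwhm_um
  expect_equal(w45, w0, tolerance = 0.02)
})

test_that("background subtraction and centring behave per the ROI rule", {
  flat <- make_profile(A = 0, offset = 100)
  fs <- suppressWarnings(subtract_background_and_center(flat))
  expect_lt(max(abs(fs$values)), 1e-9)
  p <- make_profile(A = 800, W = 0.35, offset = 200, shift_um = 0.092)
  ps <- subtract_background_and_center(p)
  expect_equal(ps$background, 200, tolerance = 1e-2)
  expect_identical(which.max(ps$values),
                   which(abs(ps$x_um) < 1e-9))
  expect_equal(ps$center_shift_um, 0.092, tolerance = 1e-9)
  # maximum in the edge region is flagged
  edge <- make_profile(A = 800, W = 0.35, shift_um = -1.0)
  expect_warning(subtract_background_and_center(edge), "suspect")
})

test_that("the Gaussian fit is exact on noiseless profiles", {
  p <- make_profile(A = 1000, W = 0.35, subtracted = TRUE)
  fit <- fit_gaussian(p)
  expect_equal(fit$amplitude, 1000, tolerance = 1e-6)
  expect_equal(fit$fwhm_um, 0.35, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(unname(coef(fit)["W"]), fit$fwhm_um)
  expect_equal(predict(fit, 0), fit$amplitude, tolerance = 1e-6)
  expect_lt(max(abs(residuals(fit))), 1e-4)
})

test_that("the fit tolerates realistic noise and flags pure noise", {
  fits <- lapply(1:5, function(s)
    fit_gaussian(make_profile(A = 1000, W = 0.35, noise_sd = 50,
                              seed = s)))
  w <- vapply(fits, `[[`, numeric(1), "fwhm_um")
  expect_equal(median(w), 0.35, tolerance = 0.05)
  expect_gte(median(vapply(fits, `[[`, numeric(1), "r")), 0.94)
  expect_lt(max(vapply(fits, `[[`, numeric(1), "p_value")), 1e-4)
  set.seed(9)
  noise <- make_profile(A = 0, noise_sd = 20)
  noise$values <- noise$values + rnorm(50, 0, 20)
  fitn <- suppressWarnings(fit_gaussian(noise))
  expect_true(fitn$suspect || !fitn$converged)
  if (fitn$converged) expect_lt(fitn$r_squared, 0.3)
})

test_that("the W estimator is unbiased over noisy replicates", {
  w <- vapply(seq_len(500), function(s) {
    fit_gaussian(make_profile(A = 1000, W = 0.35, noise_sd = 30,
                              seed = 1000 + s))$fwhm_um
  }, numeric(1))
  expect_equal(mean(w), 0.35, tolerance = 0.01)
})

test_that("orthogonal scans give the oval footprint area", {
  f <- make_spot_frame(101, spots = list(c(2.3, 2.3, 1000, 0.35)))
  o <- orthogonal_fwhm(f, c(2.3, 2.3))
  expect_equal(o$w1_um, 0.35, tolerance = 0.01)
  expect_equal(o$w2_um, o$w1_um, tolerance = 0.01)
  expect_equal(o$oval_area_um2, pi * 0.35^2 / 4, tolerance = 0.03)
  # anisotropic spot: area of the 0.38 x 0.48 oval
  fa <- make_spot_frame(101, spots = list(c(2.3, 2.3, 1000, 0.38, 0.48)))
  oa <- orthogonal_fwhm(fa, c(2.3, 2.3))
  expect_equal(oa$w1_um, 0.38, tolerance = 0.01)
  expect_equal(oa$w2_um, 0.48, tolerance = 0.01)
  expect_equal(oa$oval_area_um2, pi * 0.38 * 0.48 / 4, tolerance = 0.03)
  # 90-degree rotation of the image swaps the two widths
  ot <- orthogonal_fwhm(t(fa), c(2.3, 2.3))
  expect_equal(ot$w1_um, oa$w2_um, tolerance = 0.01)
  expect_equal(ot$w2_um, oa$w1_um, tolerance = 0.01)
})

test_that("tracking follows an immobile spot and truncates a lost one", {
  cfg <- sim_config(n_frames = 6, n_prepulse = 0, background = 100,
                    seed = 3)
  om <- optical_model()
  tr <- make_grid_truth(6e5, n_frames = 6)[1]
  class(tr) <- "vesicle_truth"
  tr[[1]]$x_um <- rep(5, 6); tr[[1]]$y_um <- rep(5, 6)
  tr[[1]]$z_nm <- rep(0, 6)
  r <- render_stack(tr, om, cfg, noise = FALSE)
  ts <- track_freckle_fwhm(r$stack, c(5, 5))
  expect_identical(nrow(ts), 6L)
  expect_lt(diff(range(ts$A)) / median(ts$A), 0.01)
  expect_lt(diff(range(ts$W_um)) / median(ts$W_um), 0.01)
  expect_null(attr(ts, "truncated"))
  # spot leaves the evanescent zone mid-series
  tr[[1]]$z_nm <- c(0, 0, 0, 800, 800, 800)
  r2 <- render_stack(tr, om, cfg, noise = FALSE)
  ts2 <- track_freckle_fwhm(r2$stack, c(5, 5), min_peak = 50)
  expect_lt(nrow(ts2), 6L)
  expect_match(attr(ts2, "truncated"), "below")
})
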