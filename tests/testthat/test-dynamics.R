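test_that("motion classification hits the trivial limits", {
  f <- 100 + make_spot_frame(151, spots = list(
    c(2, 2, 800, 0.35), c(5, 5, 800, 0.35)))
  d <- detect_freckles(f)
  m_same <- classify_motion(d, d)
  expect_equal(m_same$fraction_stationary, 1)
  expect_identical(m_same$disappeared, 0L)
  f2 <- 100 + make_spot_frame(151, spots = list(
    c(3.5, 3.5, 800, 0.35)))
  d2 <- detect_freckles(f2)
  m_disj <- classify_motion(d, d2)
  expect_equal(m_disj$fraction_stationary, 0)
  expect_identical(m_disj$moved_or_new, 1L)
  expect_identical(m_disj$disappeared, 2L)
  # empty reference: everything is moved-or-new, fraction undefined
  d0 <- detect_freckles(matrix(100, 151, 151))
  m0 <- classify_motion(d0, d)
  expect_identical(m0$moved_or_new, 2L)
  expect_true(is.na(m0$fraction_stationary))
})

test_that("motion classification is invariant to object order", {
  f <- 100 + make_spot_frame(151, spots = list(
    c(2, 2, 800, 0.35), c(5, 5, 800, 0.35), c(2, 5, 800, 0.35)))
  g <- 100 + make_spot_frame(151, spots = list(
    c(2, 2, 800, 0.35), c(4, 4, 800, 0.35)))
  da <- detect_freckles(f); db <- detect_freckles(g)
  m <- classify_motion(da, db)
  # reverse the order of the new objects (rows and masks together)
  db_rev <- db[rev(seq_len(nrow(db))), ]
  attr(db_rev, "masks") <- rev(attr(db, "masks"))
  attr(db_rev, "dim_px") <- attr(db, "dim_px")
  m_rev <- classify_motion(da, db_rev)
  expect_identical(m$stationary, m_rev$stationary)
  expect_identical(m$moved_or_new, m_rev$moved_or_new)
  expect_identical(m$disappeared, m_rev$disappeared)
  # centroid rule agrees on this clearly separated scene
  mc <- classify_motion(da, db, rule = "centroid", centroid_threshold_px = 3)
  expect_identical(mc$stationary, m$stationary)
})

test_that("a half-immobile population stays put about half the time", {
  cfg <- sim_config(seed = 12, lag_s = 0, emergence_rate = 0.8,
                    n_frames = 4, n_prepulse = 1, immobile_fraction = 0.5,
                    lateral_step_sd_um = 1.5, axial_rate = 0,
                    axial_sd_nm = 0, load_mean = 5e5)
  r <- render_stack(simulate_vesicles(cfg), optical_model(), cfg)
  d3 <- detect_freckles(r$stack$frames[[3]], 46)
  d4 <- detect_freckles(r$stack$frames[[4]], 46)
  m <- classify_motion(d3, d4)
  expect_gt(m$fraction_stationary, 0.3)
  expect_lt(m$fraction_stationary, 0.75)
})

test_that("object colocalization is asymmetric, bounded and exact at limits", {
  f <- 100 + make_spot_frame(151, spots = list(
    c(2, 2, 800, 0.35), c(5, 5, 800, 0.35)))
  d <- detect_freckles(f)
  expect_equal(object_colocalization(d, d), 100)
  f2 <- 100 + make_spot_frame(151, spots = list(c(3.5, 3.5, 800, 0.35)))
  d2 <- detect_freckles(f2)
  expect_equal(object_colocalization(d, d2), 0)
  # partial overlap: both directions in [0, 100], generally different
  f3 <- 100 + make_spot_frame(151, spots = list(
    c(2.1, 2.0, 800, 0.35)))
  d3 <- detect_freckles(f3)
  ab <- object_colocalization(d, d3)
  ba <- object_colocalization(d3, d)
  expect_true(ab >= 0 && ab <= 100 && ba >= 0 && ba <= 100)
  expect_gt(ba, ab)  # d3's single object is mostly inside d's
  d0 <- detect_freckles(matrix(100, 151, 151))
  expect_message(v <- object_colocalization(d0, d), "undefined")
  expect_true(is.na(v))
})

test_that("delta-F/F follows its defining formula", {
  mk <- function(vals, bg = 0) {
    tirf_stack(lapply(vals, function(v) {
      m <- matrix(bg, 20, 20); m[6:15, 6:15] <- v; m
    }), 46, 10)
  }
  cell <- matrix(FALSE, 20, 20); cell[6:15, 6:15] <- TRUE
  bgro <- matrix(FALSE, 20, 20); bgro[1:3, 1:3] <- TRUE
  # constant stack: identically zero
  tr <- delta_f_over_f(mk(rep(50, 5)), cell, bgro, pulse_frame = 3)
  expect_true(all(tr$dF_percent == 0))
  expect_equal(attr(tr, "F0"), 50)
  # doubling F gives +100%
  tr2 <- delta_f_over_f(mk(c(50, 50, 100)), cell, bgro, pulse_frame = 3)
  expect_equal(tr2$dF_percent, c(0, 0, 100))
  # F0 <= 0 errors
  expect_error(delta_f_over_f(mk(c(0, 0, 10)), cell, bgro, 3), "F0")
})

test_that("delta-F/F is invariant to affine gain with background subtraction", {
  set.seed(4)
  vals <- 100 + c(0, 0, 40 * exp(-(0:5) / 2))
  frames <- lapply(vals, function(v) {
    m <- matrix(20, 30, 30); m[10:20, 10:20] <- v; m
  })
  st <- tirf_stack(frames, 46, 10)
  st_gain <- st
  st_gain$frames <- lapply(st$frames, function(f) 3.7 * f + 250)
  cell <- matrix(FALSE, 30, 30); cell[10:20, 10:20] <- TRUE
  bgro <- matrix(FALSE, 30, 30); bgro[1:5, 1:5] <- TRUE
  t1 <- delta_f_over_f(st, cell, bgro, pulse_frame = 3)
  t2 <- delta_f_over_f(st_gain, cell, bgro, pulse_frame = 3)
  expect_equal(t1$dF_percent, t2$dF_percent, tolerance = 1e-9)
})

test_that("a closed-form transient is recovered at its injected peak", {
  # F rises instantaneously by 80% then decays exponentially
  t_post <- 0:9
  f_vals <- c(rep(100, 3), 100 * (1 + 0.8 * exp(-t_post / 4)))
  frames <- lapply(f_vals, function(v) matrix(v, 15, 15))
  st <- tirf_stack(frames, 46, 10)
  cell <- matrix(TRUE, 15, 15)
  tr <- delta_f_over_f(st, cell, NULL, pulse_frame = 4)
  expect_equal(max(tr$dF_percent), 80, tolerance = 0.02 * 80)
})
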