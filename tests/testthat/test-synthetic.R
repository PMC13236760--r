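test_that("simulation is deterministic given config and seed", {
  cfg <- sim_preset("ns400", seed = 4, n_frames = 10)
  t1 <- simulate_vesicles(cfg)
  t2 <- simulate_vesicles(cfg)
  expect_identical(t1, t2)
  om <- optical_model()
  r1 <- render_stack(t1, om, cfg)
  r2 <- render_stack(t2, om, cfg)
  expect_identical(r1$stack$frames, r2$stack$frames)
})

test_that("zero emergence rate yields no vesicles and pure background", {
  cfg <- sim_config(emergence_rate = 0, n_frames = 3, seed = 1)
  truth <- simulate_vesicles(cfg)
  expect_length(truth, 0)
  r <- render_stack(truth, optical_model(), cfg, noise = FALSE)
  expect_true(all(vapply(r$stack$frames,
                         function(f) all(f == cfg$background), TRUE)))
  # with noise the mean stays at the background level
  rn <- render_stack(truth, optical_model(), cfg, noise = TRUE)
  expect_equal(mean(rn$stack$frames[[1]]), cfg$background, tolerance = 0.01)
})

test_that("emergence counts follow the lag + Poisson expectation", {
  # lag 60 s, rate 0.4 per 10 s over a 100 um^2 field, horizon 300 s:
  # expected count = rate * (300 - 60)
  counts <- vapply(seq_len(200), function(s) {
    cfg <- sim_config(lag_s = 60, emergence_rate = 0.04, fov_um = 10,
                      n_frames = 31, n_prepulse = 0, frame_interval_s = 10,
                      seed = s)
    length(simulate_vesicles(cfg))
  }, numeric(1))
  expected <- 0.04 * (300 - 60)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se + 1e-9)
})

test_that("truth trajectories respect the contract", {
  cfg <- sim_preset("us20", seed = 2, n_frames = 20)
  truth <- simulate_vesicles(cfg)
  expect_gt(length(truth), 0)
  tt <- frame_times(cfg)
  for (v in truth) {
    expect_true(all(v$z_nm >= 0))
    expect_gt(v$diameter_nm, 0)
    expect_gte(v$emergence_time_s, 0)
    # trajectory defined only from the emergence frame on
    expect_true(all(tt[v$frame] >= v$emergence_time_s))
    expect_length(v$x_um, length(v$frame))
  }
  df <- as.data.frame(truth)
  expect_true(all(c("id", "frame", "z_nm", "diameter_nm") %in% names(df)))
})

test_that("integrated spot signal equals load x sphere-averaged attenuation", {
  cfg <- sim_config(n_frames = 1, n_prepulse = 0, fov_um = 10,
                    background = 0, seed = 1)
  truth <- make_grid_truth(2e5, diameter_nm = 200, z_nm = 40)
  truth[[1]]$x_um <- 5; truth[[1]]$y_um <- 5
  for (psf in c(289, 500)) {
    om <- optical_model(psf_fwhm_nm = c(red = psf))
    r <- render_stack(truth, om, cfg, noise = FALSE)
    got <- sum(r$stack$frames[[1]])
    want <- 2e5 * freckletrace:::sphere_attenuation(40, 200, 100)
    expect_equal(got, want, tolerance = 0.01)
    expect_equal(r$truth$signal, want, tolerance = 1e-9)
  }
})

test_that("a vesicle at the half-intensity height is half as bright", {
  cfg <- sim_config(n_frames = 1, n_prepulse = 0, background = 0, seed = 1)
  om <- optical_model()
  t0 <- make_grid_truth(2e5, z_nm = 0)[1]
  class(t0) <- "vesicle_truth"
  t0[[1]]$x_um <- 5; t0[[1]]$y_um <- 5
  t1 <- t0
  t1[[1]]$z_nm <- 100 * log(2)
  s0 <- sum(render_stack(t0, om, cfg, noise = FALSE)$stack$frames[[1]])
  s1 <- sum(render_stack(t1, om, cfg, noise = FALSE)$stack$frames[[1]])
  expect_equal(s0 / s1, 2, tolerance = 0.05)
})

test_that("axial motion changes brightness but not fitted width", {
  cfg <- sim_config(n_frames = 1, n_prepulse = 0, background = 100,
                    seed = 1)
  om <- optical_model()
  zs <- c(0, 40, 80, 120, 160)
  res <- lapply(zs, function(z) {
    tr <- make_grid_truth(6e5, diameter_nm = 200, z_nm = z)[1]
    class(tr) <- "vesicle_truth"
    tr[[1]]$x_um <- 5; tr[[1]]$y_um <- 5
    r <- render_stack(tr, om, cfg, noise = FALSE)
    fit_gaussian(extract_profile(r$stack$frames[[1]], c(5, 5)))
  })
  A <- vapply(res, `[[`, numeric(1), "amplitude")
  W <- vapply(res, `[[`, numeric(1), "fwhm_um")
  expect_gte(max(A) / min(A), 4)
  expect_lte((max(W) - min(W)) / median(W), 0.10)
})

test_that("rendered bead fields are isolated and match the forward FWHM", {
  om <- optical_model()
  b1 <- render_beads(1, om, seed = 1)
  d1 <- detect_freckles(b1$stack$frames[[1]], om$pixel_size_nm)
  expect_identical(nrow(d1), 1L)
  b <- render_beads(12, om, seed = 2)
  expect_identical(nrow(b$positions), 12L)
  dd <- as.matrix(dist(b$positions[, c("x_um", "y_um")]))
  diag(dd) <- Inf
  expect_gte(min(dd), 10 * 289 / 1000 - 0.1)
  fw <- vapply(seq_len(12), function(i) {
    f <- fit_gaussian(extract_profile(
      b$stack$frames[[1]], c(b$positions$x_um[i], b$positions$y_um[i])))
    f$fwhm_um * 1000
  }, numeric(1))
  expect_equal(mean(fw), 308, tolerance = 0.02)
})

test_that("two-channel assignment hits the trivial colocalization limits", {
  cfg <- sim_config(seed = 3, lag_s = 0, emergence_rate = 0.3,
                    n_frames = 6, n_prepulse = 1, load_mean = 5e5)
  tw1 <- simulate_two_channel(cfg, coloc_fraction = 1, bleedthrough = 0)
  expect_true(all(tw1$assignment$channel == "both"))
  last <- length(tw1$stacks[[1]]$frames)
  da <- detect_freckles(tw1$stacks$red$frames[[last]], 46)
  db <- detect_freckles(tw1$stacks$green$frames[[last]], 46)
  expect_gte(object_colocalization(da, db), 95)
  tw0 <- simulate_two_channel(cfg, coloc_fraction = 0, bleedthrough = 0)
  expect_false(any(tw0$assignment$channel == "both"))
  da0 <- detect_freckles(tw0$stacks$red$frames[[last]], 46)
  db0 <- detect_freckles(tw0$stacks$green$frames[[last]], 46)
  expect_lte(object_colocalization(da0, db0), 5)
})

test_that("out-of-field vesicles are omitted with a message", {
  cfg <- sim_config(n_frames = 1, n_prepulse = 0, seed = 1)
  tr <- make_grid_truth(2e5)[1]
  class(tr) <- "vesicle_truth"
  tr[[1]]$x_um <- -3
  expect_message(r <- render_stack(tr, optical_model(), cfg, noise = FALSE),
                 "outside the field")
  expect_identical(r$omitted, 1L)
  expect_identical(nrow(r$truth), 0L)
})
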