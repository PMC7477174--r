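# Two-step inversion and Beer's-law conversion.

test_that("Beer step: printed sheep coefficients round-trip to machine precision", {
  eps <- sheep_extinction()
  # independent cofactor-expansion determinant before trusting the solve
  det2 <- eps[1, 1] * eps[2, 2] - eps[1, 2] * eps[2, 1]
  expect_gt(abs(det2), 0.1)
  # forward multiply by hand (direct matrix product oracle), then invert
  conc_mM <- c(o2hb = 0.050, hhb = 0.030)  # 50 / 30 uM
  mua_mm <- c(eps %*% conc_mM) / 10
  hb <- mua_to_hemoglobin(mua_mm, eps)
  expect_equal(unname(hb), c(50, 30), tolerance = 1e-12)
  expect_equal(unname(mua_to_hemoglobin(c(0, 0), eps)), c(0, 0))
  # decadic convention scales concentrations by ln(10)
  hb_dec <- mua_to_hemoglobin(mua_mm, eps, scale = "decadic")
  expect_equal(unname(hb_dec * log(10)), c(50, 30), tolerance = 1e-12)
  expect_error(mua_to_hemoglobin(c(0.01, 0.01), matrix(1, 2, 2)), "singular")
})

test_that("upper inversion: zero in, zero out; noiseless round trip", {
  base <- sheep_medium()
  dod <- make_dod_series(rep(0, 5), rep(0, 5), base)
  up <- invert_upper(dod, base, 10)
  expect_true(all(abs(up$dmua_up) < 1e-12))
  dod2 <- make_dod_series(rep(5e-4, 5), rep(0, 5), base)
  up2 <- invert_upper(dod2, base, 10)
  expect_equal(unname(up2$dmua_up), matrix(5e-4, 5, 2), tolerance = 1e-4)
  expect_true(all(up2$converged))
})

test_that("upper inversion under white OD noise recovers the mean within 5%", {
  base <- sheep_medium()
  truth <- 5e-4
  dod <- make_dod_series(rep(truth, 100), rep(0, 100), base)
  set.seed(12)
  dod$delta_od <- dod$delta_od + matrix(rnorm(length(dod$delta_od), 0, 1e-3),
                                        nrow(dod$delta_od))
  up <- invert_upper(dod, base, 10)
  expect_equal(mean(up$dmua_up[, 1]), truth, tolerance = 0.05)
  expect_equal(mean(up$dmua_up[, 2]), truth, tolerance = 0.05)
})

test_that("lower inversion round trips and handles the superficial-only case", {
  base <- sheep_medium()
  # deep-only perturbation with exact zero upper supplied
  dod <- make_dod_series(rep(0, 5), rep(1e-3, 5), base)
  up0 <- invert_upper(make_dod_series(rep(0, 5), rep(0, 5), base), base, 10)
  lo <- invert_lower(dod, up0, base, 30)
  expect_equal(unname(lo$dmua_down), matrix(1e-3, 5, 2), tolerance = 1e-4)
  # superficial-only: correct upper supplied, recovered deep change ~ 0
  dod_sup <- make_dod_series(rep(5e-4, 5), rep(0, 5), base,
                             short_model = "homogeneous")
  up_exact <- up0
  up_exact$dmua_up <- matrix(5e-4, 5, 2)
  # rebuild the long channels with a pure superficial truth
  lo_sup <- invert_lower(dod_sup, up_exact, base, 30)
  expect_true(all(abs(lo_sup$dmua_down) < 1e-6))
  # mismatched time bases are rejected
  up_bad <- up0
  up_bad$time_rel <- up0$time_rel + 1
  expect_error(invert_lower(dod, up_bad, base, 30), "time bases")
})

test_that("a biased upper estimate pushes the lower estimate the other way", {
  base <- sheep_medium()
  # mixed perturbation, truth: up 5e-4, down 1e-3
  dod <- make_dod_series(rep(5e-4, 3), rep(1e-3, 3), base,
                         short_model = "two_layer")
  up_exact <- list(time_rel = dod$time_rel, wavelengths = c(751, 839),
                   dmua_up = matrix(5e-4, 3, 2))
  up_biased <- up_exact
  up_biased$dmua_up <- up_exact$dmua_up * 1.2
  lo_exact <- invert_lower(dod, up_exact, base, 30)
  lo_biased <- invert_lower(dod, up_biased, base, 30)
  # overestimated superficial absorption forces an underestimated deep one
  expect_true(all(lo_biased$dmua_down < lo_exact$dmua_down))
})

test_that("noiseless two-step inversion recovers a 5x5 perturbation grid", {
  base <- sheep_medium()
  grid <- expand.grid(up = seq(-4e-4, 4e-4, length.out = 5),
                      down = seq(-1e-3, 1e-3, length.out = 5))
  dod <- make_dod_series(grid$up, grid$down, base,
                         short_model = "homogeneous")
  upf <- invert_upper(dod, base, 10)
  lof <- invert_lower(dod, upf, base, 30)
  expect_lt(max(abs(upf$dmua_up - grid$up)), 1e-3 * 4e-4 + 1e-9)
  expect_lt(max(abs(lof$dmua_down - grid$down)), 1e-3 * 1e-3 + 1e-9)
})

test_that("recovered absorption scales linearly in the small-perturbation limit", {
  base <- sheep_medium()
  injected <- seq(1e-4, 1e-3, length.out = 8)
  dod <- make_dod_series(rep(0, 8), injected, base)
  up0 <- invert_upper(make_dod_series(rep(0, 8), rep(0, 8), base), base, 10)
  lo <- invert_lower(dod, up0, base, 30)
  fit <- summary(lm(lo$dmua_down[, 1] ~ injected))
  expect_gt(fit$r.squared, 0.999)
})

test_that("block inversion composes the chain and re-references the baseline", {
  base <- sheep_medium()
  n <- 80
  dod <- make_dod_series(rep(0, n), rep(0, n), base)
  hb <- run_block_inversion(dod, base, probe_config(), sheep_extinction())
  expect_true(all(abs(hb$do2hb) < 1e-9))
  expect_true(all(abs(hb$dhhb) < 1e-9))
  # absolute concentrations correspond to the baseline absorption
  expect_true(all(hb$o2hb > 0))
  expect_error(run_block_inversion(
    structure(dod[names(dod) != "delta_od"], class = "delta_od_series"),
    base, probe_config(), sheep_extinction()), "channel")
})

test_that("cortical-only synthetic block is recovered with clean layer separation", {
  # noise-free stated world: measures the short-channel approximation bias
  # and the layer crosstalk of the two-step method in isolation
  tr <- ground_truth(mayer_amp = 0, drift = 0, noise_od = 0)
  gb <- generate_block(tr, sheep_medium(), probe_config(), seed = 9,
                       hemispheres = "left")
  sl <- segment_blocks(gb$recording, gb$schedule)
  dod <- compute_delta_od(sl[[1]])
  hb <- run_block_inversion(dod, sheep_medium(), probe_config(),
                            sheep_extinction(), "left")
  expect_equal(max(hb$do2hb[, "down"]), 1.0, tolerance = 0.15)
  expect_equal(min(hb$dhhb[, "down"]), -0.3, tolerance = 0.15)
  expect_lt(max(abs(hb$do2hb[, "up"])), 0.1)
  expect_lt(max(abs(hb$dhhb[, "up"])), 0.1)
})

test_that("superficial-only synthetic block: upper layer reproduced, lower bounded", {
  tr <- ground_truth(peak_do2hb = 0, peak_dhhb = 0, mayer_amp = 0.5,
                     drift = 0, noise_od = 0)
  gb <- generate_block(tr, sheep_medium(), probe_config(), seed = 10,
                       hemispheres = "left")
  sl <- segment_blocks(gb$recording, gb$schedule)
  dod <- compute_delta_od(sl[[1]])
  hb <- run_block_inversion(dod, sheep_medium(), probe_config(),
                            sheep_extinction(), "left")
  # upper-layer Mayer wave amplitude recovered within 10%
  expect_equal(max(hb$do2hb[, "up"]) - min(hb$do2hb[, "up"]),
               max(gb$truth$concentrations$upper_o2hb) -
                 min(gb$truth$concentrations$upper_o2hb),
               tolerance = 0.1)
  # crosstalk into the cerebral layer stays below the superficial amplitude
  expect_lt(max(abs(hb$do2hb[, "down"])), 0.5 * max(abs(hb$do2hb[, "up"])))
})
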