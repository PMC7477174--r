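# Forward photon-diffusion models: CW homogeneous, CW two-layer, time-resolved,
# delta-OD prediction and DPF.

test_that("homogeneous CW reflectance matches an independent spatial-frequency oracle", {
  # oracle: adaptive numeric inverse Hankel transform of the q-space solution
  # of the same boundary-value problem (stats::integrate, not the package's
  # Gauss-Legendre machinery), matched boundary
  p <- optical_properties(0.01, 1.0)
  for (rho in c(10, 30)) {
    dp <- ovifnirs:::diffusion_params(p, 1.0, 1.0)
    oracle <- integrate(function(q) {
      k <- sqrt(q^2 + p$mua * 3 * p$musp)
      # overflow-safe cosh(k zb) exp(-k (z0 + zb))
      0.5 * (exp(-k * dp$z0) + exp(-k * (dp$z0 + 2 * dp$zb))) *
        besselJ(q * rho, 0) * q
    }, 0, 2e3, rel.tol = 1e-12, subdivisions = 2000L)$value / (2 * pi)
    expect_equal(cw_reflectance_homog(rho, p, 1.0, 1.0), oracle,
                 tolerance = 1e-6)
  }
})

test_that("homogeneous CW reflectance decays with distance and absorption", {
  p1 <- optical_properties(0.01, 1.0)
  p2 <- optical_properties(0.02, 1.0)
  expect_lt(cw_reflectance_homog(30, p1), cw_reflectance_homog(10, p1))
  expect_lt(cw_reflectance_homog(30, p2), cw_reflectance_homog(30, p1))
  expect_error(cw_reflectance_homog(-1, p1), "positive")
  expect_error(optical_properties(-0.01, 1), "positive")
})

test_that("two-layer reflectance reduces to the homogeneous solution", {
  p <- optical_properties(0.01, 1.0)
  m <- layered_medium(10, p, p)
  expect_equal(cw_reflectance_two_layer(30, m), cw_reflectance_homog(30, p),
               tolerance = 1e-3)
  # thick slab: the lower layer becomes invisible
  m_thick <- layered_medium(100, p, optical_properties(0.05, 1.0))
  expect_equal(cw_reflectance_two_layer(30, m_thick),
               cw_reflectance_homog(30, p), tolerance = 1e-3)
})

test_that("two-layer equals homogeneous for 20 random identical-layer media", {
  set.seed(20)
  for (i in 1:20) {
    p <- optical_properties(runif(1, 0.002, 0.05), runif(1, 0.5, 2.0))
    s <- runif(1, 5, 20)
    m <- layered_medium(s, p, p)
    rho <- sample(c(10, 20, 30), 1)
    expect_equal(cw_reflectance_two_layer(rho, m),
                 cw_reflectance_homog(rho, p), tolerance = 1e-3)
  }
})

test_that("two-layer reflectance decreases when lower-layer absorption rises", {
  up <- optical_properties(0.01, 1.0)
  r <- vapply(c(0.01, 0.02, 0.03), function(mua_low)
    cw_reflectance_two_layer(30, layered_medium(10, up,
                                                optical_properties(mua_low, 1.0))),
    numeric(1))
  expect_true(all(diff(r) < 0))
})

test_that("all reflectances are positive and finite over the physiological range", {
  for (mua in c(0.002, 0.01, 0.05)) for (musp in c(0.5, 1.0, 2.0)) {
    p <- optical_properties(mua, musp)
    r <- cw_reflectance_homog(c(5, 20, 40), p)
    expect_true(all(is.finite(r) & r > 0))
    if (1 / musp < 5) {  # two-layer model needs the source inside the slab
      r2 <- cw_reflectance_two_layer(20, layered_medium(5, p, p))
      expect_true(is.finite(r2) && r2 > 0)
    }
  }
})

test_that("delta-OD forward model: identity, sign, MBLL limit, partial volume", {
  base <- sheep_medium(mua = 0.01)
  expect_identical(delta_od_forward(10, "homogeneous", base, 0, 0), 0)
  expect_identical(delta_od_forward(30, "two_layer", base, 0, 0), 0)
  # reciprocity of perturbation sign, both models
  expect_gt(delta_od_forward(10, "homogeneous", base, 1e-3), 0)
  expect_lt(delta_od_forward(10, "homogeneous", base, -1e-3), 0)
  expect_gt(delta_od_forward(30, "two_layer", base, 0, 1e-3), 0)
  expect_lt(delta_od_forward(30, "two_layer", base, 0, -1e-3), 0)
  # first-order modified Beer-Lambert consistency at small perturbation
  p <- optical_properties(0.01, 1.0, 751)
  dmua <- 1e-4
  dod <- delta_od_forward(10, "homogeneous", base, dmua, wavelength = 751)
  expect_equal(dod, dpf(10, p) * 10 * dmua / log(10), tolerance = 0.02)
  # partial volume: a deep-only perturbation produces less delta-OD than the
  # same perturbation applied everywhere
  dod_deep <- delta_od_forward(30, "two_layer", base, 0, 1e-3, wavelength = 751)
  dod_all <- delta_od_forward(30, "homogeneous", base, 1e-3, wavelength = 751)
  expect_gt(dod_deep, 0)
  expect_lt(dod_deep, dod_all)
  expect_error(delta_od_forward(10, "homogeneous", base, -0.02), "mua")
})

test_that("time-resolved curve integrates to CW and factorizes absorption", {
  for (mua in c(0.005, 0.01, 0.02)) for (musp in c(0.8, 1.0, 1.5)) {
    p <- optical_properties(mua, musp)
    cw <- integrate(function(t) tr_reflectance_homog(30, t, p), 0, Inf,
                    rel.tol = 1e-9)$value
    expect_equal(cw, cw_reflectance_homog(30, p), tolerance = 1e-3)
  }
  # exp(+mua v t) removes all absorption dependence
  t <- c(0.1, 0.5, 1, 2)
  v <- 299.792458 / 1.4
  p1 <- optical_properties(0.01, 1.0)
  p2 <- optical_properties(0.03, 1.0)
  expect_equal(tr_reflectance_homog(30, t, p1) * exp(0.01 * v * t),
               tr_reflectance_homog(30, t, p2) * exp(0.03 * v * t),
               tolerance = 1e-12)
  expect_error(tr_reflectance_homog(30, -1, p1), "positive")
})

test_that("mean time of flight obeys the CW log-derivative moment identity", {
  v <- 299.792458 / 1.4
  for (mua in c(0.005, 0.01, 0.02)) for (musp in c(0.8, 1.0, 1.5)) {
    tmean <- ovifnirs:::mean_time_of_flight(30, optical_properties(mua, musp))
    d <- 1e-6
    dlnR <- (log(cw_reflectance_homog(30, optical_properties(mua - d, musp))) -
             log(cw_reflectance_homog(30, optical_properties(mua + d, musp)))) / (2 * d)
    expect_equal(tmean, dlnR / v, tolerance = 0.01)
  }
})

test_that("DPF exceeds 1, grows with scattering, and matches the CW derivative", {
  for (rho in c(10, 30)) for (mua in c(0.005, 0.02)) {
    p <- optical_properties(mua, 1.0)
    expect_gt(dpf(rho, p), 1)
    expect_gt(dpf(rho, optical_properties(mua, 2.0)), dpf(rho, p))
    d <- 1e-6
    L <- (log(cw_reflectance_homog(rho, optical_properties(mua - d, 1.0))) -
          log(cw_reflectance_homog(rho, optical_properties(mua + d, 1.0)))) / (2 * d)
    expect_equal(dpf(rho, p), L / rho, tolerance = 0.01)
  }
})

test_that("DTOF fitting recovers optical properties", {
  p <- optical_properties(0.01, 1.0)
  t <- seq(0.02, 8, by = 0.02)
  curve <- tr_reflectance_homog(30, t, p)
  # exact self-fit
  f0 <- fit_dtof(t, curve * 1e9, rho = 30)
  expect_equal(f0$mua, 0.01, tolerance = 1e-4)
  expect_equal(f0$musp, 1.0, tolerance = 1e-4)
  # Poisson noise at 1e6 total counts
  set.seed(3)
  counts <- rpois(length(t), curve / sum(curve) * 1e6)
  f1 <- fit_dtof(t, counts, rho = 30)
  expect_equal(f1$mua, 0.01, tolerance = 0.05)
  expect_equal(f1$musp, 1.0, tolerance = 0.05)
  # the tail slope carries mua: a peak-to-tail window changes it little
  f2 <- fit_dtof(t, counts, rho = 30, rise_frac = 1.0)
  expect_equal(f2$mua, f1$mua, tolerance = 0.03)
  expect_error(fit_dtof(c(1, 2), c(5, 0), rho = 30), "degenerate")
})
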