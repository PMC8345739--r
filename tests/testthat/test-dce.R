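prot <- default_protocol()

test_that("SPGR signal has the right limits and scalar value", {
  expect_equal(spgr_signal(1e6, 1000, 15, 7), 1000 * sin(15 * pi / 180),
               tolerance = 1e-12)
  expect_equal(spgr_signal(0, 1000, 15, 7), 0)
  a <- 15 * pi / 180; e1 <- exp(-0.007)
  expect_equal(spgr_signal(1, 1000, 15, 7),
               1000 * sin(a) * (1 - e1) / (1 - e1 * cos(a)))
})

test_that("variable-flip-angle T1 estimation inverts noiseless SPGR", {
  s <- spgr_signal(1 / 1.4, 1200, c(5, 15, 30), 7)
  fit <- estimate_t10(s, 7, c(5, 15, 30))
  expect_equal(fit$t10, 1.4, tolerance = 1e-6)
  expect_equal(fit$m0, 1200, tolerance = 1e-4)
  expect_false(estimate_t10(c(50, 50, 50), 7, c(5, 15, 30))$converged)
})

test_that("noisy T1 estimation stays accurate", {
  set.seed(5)
  s0 <- spgr_signal(1 / 1.4, 1000, c(5, 15, 30), 7)
  sigma <- spgr_signal(1 / 1.4, 1000, 15, 7) / 100
  errs <- replicate(200, {
    fit <- estimate_t10(s0 + rnorm(3, 0, sigma), 7, c(5, 15, 30))
    abs(fit$t10 - 1.4) / 1.4
  })
  expect_lt(median(errs, na.rm = TRUE), 0.03)
})

test_that("Tofts concentration is zero without input and linear in Ktrans", {
  zero <- aif_measured(c(0, 400), c(0, 0))
  tt <- seq(0, 400, 8)
  expect_equal(tofts_concentration(0.18, 0.32, zero, tt), rep(0, length(tt)))
  aif <- aif_biexponential(bolus_arrival_s = 40)
  ct1 <- tofts_concentration(0.18, 0.32, aif, tt)
  ct2 <- tofts_concentration(0.36, 0.64, aif, tt)  # same kep, double Ktrans
  expect_equal(ct2, 2 * ct1, tolerance = 1e-12)
})

test_that("Tofts numerics match the analytic exponential convolution", {
  m_s <- 0.002  # 1/s
  tt <- seq(0, 600, 4)
  aif <- aif_measured(seq(0, 600, 0.05), exp(-m_s * seq(0, 600, 0.05)))
  ct <- tofts_concentration(0.18, 0.32, aif, tt, dt_fine = 0.05)
  oracle <- tofts_exp_oracle(0.18, 0.18 / 0.32, 1, m_s * 60, tt / 60)
  expect_lt(max(abs(ct[-1] - oracle[-1]) / oracle[-1]), 1e-8)
})

test_that("FXR relaxation rate: no-contrast value, FXL limit, eigenvalue branch", {
  # no contrast, equal pools
  p <- fxr_params(0.18, 0.32, 0.670, r10 = 1 / 1.4)
  expect_equal(fxr_longitudinal_rate(p, 0), 1 / 1.4, tolerance = 1e-12)
  # FXL limit: population-weighted mean of the two pool rates
  p0 <- fxr_params(0.18, 0.32, 1e-7)
  r1e <- p0$r10e + 3.7 * 1 / 0.32
  fxl <- (1 - 0.32) * p0$r1i + 0.32 * r1e
  expect_lt(abs(fxr_longitudinal_rate(p0, 1) - fxl) / fxl, 1e-6)
  # direct scalar evaluation of the eigenvalue formula at Ct = 1 mM
  ps <- fxr_params(0.18, 0.32, 0.670, r10 = 1 / 1.4)
  kie <- 1 / 0.670; kei <- kie * (1 - 0.32) / 0.32
  r1e1 <- 1 / 1.4 + 3.7 * 1 / 0.32
  a <- 1 / 1.4 + kie; bb <- r1e1 + kei
  byhand <- 0.5 * ((a + bb) - sqrt((a - bb)^2 + 4 * kie * kei))
  expect_equal(fxr_longitudinal_rate(ps, 1), byhand, tolerance = 1e-12)
  # bounded between min pool rate and population-weighted mean, monotone in Ct
  ct <- seq(0, 3, 0.01)
  r1t <- fxr_longitudinal_rate(ps, ct)
  expect_true(all(diff(r1t) >= 0))
  expect_true(all(r1t >= pmin(ps$r1i, ps$r10e + 3.7 * ct / 0.32) - 1e-12))
  wmean <- (1 - 0.32) * ps$r1i + 0.32 * (ps$r10e + 3.7 * ct / 0.32)
  expect_true(all(r1t <= wmean + 1e-12))
})

test_that("FXR fit recovers a noiseless forward-generated series", {
  truth <- list(Ktrans = 0.18, ve = 0.32, tau_i = 0.670)
  aif <- aif_biexponential(bolus_arrival_s = 48)
  sim <- generate_dce_signal(truth, prot, aif, snr = Inf)
  fit <- fit_fxr(sim$signals[1, ], aif, 1.4, prot)
  expect_equal(fit$ktrans, 0.18, tolerance = 1e-4)
  expect_equal(fit$ve, 0.32, tolerance = 1e-4)
  expect_equal(fit$tau_i, 0.670, tolerance = 1e-4)
  expect_equal(fit$kep, fit$ktrans / fit$ve)
  expect_identical(fit$flag, "ok")
})

test_that("zero-enhancement series is flagged at the Ktrans bound", {
  zero <- aif_measured(c(0, 400), c(0, 0))
  s <- rep(spgr_signal(1 / 1.4, 1000, 15, 7), prot$n_dynamics)
  fit <- fit_fxr(s, zero, 1.4, prot)
  expect_identical(fit$flag, "no_enhancement")
})

test_that("fitting FXL-generated data drives tau_i to its lower bound", {
  aif <- aif_biexponential(bolus_arrival_s = 48)
  sim <- generate_dce_signal(list(Ktrans = 0.18, ve = 0.32, tau_i = 1e-6),
                             prot, aif, snr = Inf)
  fit <- fit_fxr(sim$signals[1, ], aif, 1.4, prot)
  expect_lte(fit$tau_i, 0.051)
  expect_equal(fit$ktrans, 0.18, tolerance = 0.02)
})
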