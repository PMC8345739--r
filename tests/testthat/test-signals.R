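prot <- default_protocol()

test_that("DWI generator degenerates to monoexponential when f = 0", {
  truth <- list(D = 0.93e-3, Dstar = 9.02e-3, f = 0)
  sim <- generate_dwi_signal(truth, prot, n_voxels = 1, snr = Inf)
  expect_equal(sim$signals[1, ], 100 * exp(-prot$b_values * 0.93e-3))
})

test_that("DWI generator evaluates the biexponential decay exactly", {
  truth <- list(D = 0.67e-3, Dstar = 9.02e-3, f = 0.16)
  sim <- generate_dwi_signal(truth, prot, n_voxels = 1, snr = Inf)
  ratio <- sim$signals[1, prot$b_values == 2000] / sim$signals[1, 1]
  expected <- 0.16 * exp(-2000 * 9.02e-3) + 0.84 * exp(-2000 * 0.67e-3)
  expect_equal(ratio, expected, tolerance = 1e-12)
})

test_that("DWI Rician noise is calibrated to the requested SNR", {
  truth <- list(D = 0.67e-3, Dstar = 9.02e-3, f = 0.16)
  sim <- generate_dwi_signal(truth, prot, n_voxels = 500, snr = 50, seed = 2)
  emp <- sd(sim$signals[, 1]) / 100
  expect_lt(abs(emp - 1 / 50) / (1 / 50), 0.10)
})

test_that("DCE signal is flat without contrast and enhances with it", {
  truth <- list(Ktrans = 0.18, ve = 0.32, tau_i = 0.670)
  zero_aif <- aif_measured(c(0, 400), c(0, 0))
  sim0 <- generate_dce_signal(truth, prot, zero_aif, snr = Inf)
  expect_equal(diff(range(sim0$signals[1, ])), 0)
  aif <- aif_biexponential(bolus_arrival_s = 48)
  sim <- generate_dce_signal(truth, prot, aif, snr = Inf)
  s <- sim$signals[1, ]
  expect_equal(sd(s[1:prot$n_baseline]), 0)
  expect_true(all(s >= s[1] - 1e-9))
})

test_that("FXR forward signal approaches the fast-exchange limit as tau_i -> 0", {
  aif <- aif_biexponential(bolus_arrival_s = 48)
  times <- dce_times(prot)
  ct <- tofts_concentration(0.18, 0.32, aif, times)
  s_fxl <- spgr_signal(1 / 1.4 + 3.7 * ct, 1000, 15, 7)
  s_fxr <- generate_dce_signal(list(Ktrans = 0.18, ve = 0.32, tau_i = 1e-6),
                               prot, aif, snr = Inf)$signals[1, ]
  expect_lt(max(abs(s_fxr - s_fxl) / s_fxl), 1e-6)
})

test_that("2TC tissue curve reduces to vb times blood when K1 = 0", {
  ifm <- input_function_triphasic()
  tt <- seq(0, 1800, 5)
  ct <- simulate_2tc(0, 0.3, 0.01, 0.05, ifm, tt)
  expect_equal(ct, 0.05 * ifm$cb(tt))
})

test_that("2TC free compartment reaches the K1/k2 steady state", {
  ifc <- input_function_sampled(c(0, 36000), c(10, 10))  # constant blood
  tt <- seq(0, 36000, 60)
  ct <- simulate_2tc(0.33, 0.33 / 0.89, 0, 0, ifc, tt)
  expect_equal(ct[length(tt)] / 10, 0.89, tolerance = 1e-6)
})

test_that("frame-averaged TAC matches the closed-form exponential oracle", {
  ifc <- input_function_sampled(seq(0, 10800, 0.5),
                                30 * exp(-0.01 * seq(0, 10800, 0.5) / 60))
  tt <- seq(0, 10800, 0.5)
  ct <- simulate_2tc(0.33, 0.33 / 0.89, 0.0087, 0.05, ifc, tt)
  oracle <- tc2_exp_oracle(0.33, 0.33 / 0.89, 0.0087, 0.05, 30, 0.01, tt / 60)
  expect_lt(max(abs(ct[-1] - oracle[-1]) / oracle[-1]), 1e-6)
})

test_that("PET noise SD scales as 1/sqrt(frame duration)", {
  truth <- list(K1 = 0.33, k2 = 0.33 / 0.89, k3max = 0.0087, vb = 0.05)
  ifm <- input_function_triphasic()
  tacs <- vapply(1:400, function(i)
    generate_fmiso_tac(truth, ifm, prot, snr = 50, seed = 100 + i)$tac,
    numeric(nrow(prot$frames)))
  tac0 <- generate_fmiso_tac(truth, ifm, prot, snr = Inf)$tac_true
  sds <- apply(tacs, 1, sd)
  ipk <- which.max(tac0)
  expect_equal(sds[ipk], tac0[ipk] / 50, tolerance = 0.15)
  # a 600 s frame vs a 60 s frame: sqrt(10) noise ratio
  i60 <- which(prot$frames[, "duration"] == 60)[1]
  i600 <- which(prot$frames[, "duration"] == 600)[1]
  expect_equal(sds[i60] / sds[i600], sqrt(10), tolerance = 0.25)
})

test_that("signal generators are deterministic given a seed", {
  truth <- list(D = 0.67e-3, Dstar = 9.02e-3, f = 0.16,
                Ktrans = 0.18, ve = 0.32, tau_i = 0.670,
                K1 = 0.33, k2 = 0.33 / 0.89, k3max = 0.0087, vb = 0.05)
  expect_identical(generate_dwi_signal(truth, prot, 5, 50, seed = 9),
                   generate_dwi_signal(truth, prot, 5, 50, seed = 9))
  expect_identical(generate_fmiso_tac(truth, snr = 20, seed = 9),
                   generate_fmiso_tac(truth, snr = 20, seed = 9))
})
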