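# Rician magnitude noise: sqrt((s + n1)^2 + n2^2), n ~ N(0, sigma)
add_rician <- function(s, sigma) {
  if (sigma == 0) return(s)
  sqrt((s + rnorm(length(s), 0, sigma))^2 + rnorm(length(s), 0, sigma)^2)
}

#' Simulate multi-b-value diffusion signals
#'
#' Noiseless voxel signal follows the IVIM biexponential
#' `S(b) = S0 [ f exp(-b D*) + (1 - f) exp(-b D) ]` (monoexponential when
#' `f = 0`); magnitude noise is Rician with `sigma = S0 / snr`, so the
#' requested SNR is the b = 0 signal-to-noise ratio.
#'
#' @param truth One-row data.frame (or list) with `D`, `Dstar`, `f`.
#' @param protocol A [default_protocol()] (b-value ladder).
#' @param n_voxels Number of voxels to simulate.
#' @param snr Signal-to-noise ratio at b = 0; `Inf` for noiseless.
#' @param seed Integer seed.
#' @param s0 Baseline signal.
#' @return List with `b_values` and `signals` (n_voxels x n_b matrix).
#' @export
generate_dwi_signal <- function(truth, protocol = default_protocol(),
                                n_voxels = 1, snr = Inf, seed = 1L,
                                s0 = 100) {
  stopifnot(snr > 0, n_voxels >= 1)
  set.seed(seed)
  b <- protocol$b_values
  s <- s0 * (truth$f * exp(-b * truth$Dstar) +
             (1 - truth$f) * exp(-b * truth$D))
  sigma <- if (is.finite(snr)) s0 / snr else 0
  signals <- t(vapply(seq_len(n_voxels), function(i) add_rician(s, sigma),
                      numeric(length(b))))
  list(b_values = b, signals = signals)
}

#' Simulate dynamic contrast-enhanced SPGR signals
#'
#' Forward chain: Tofts tissue concentration from the AIF, EES concentration
#' `Ce = Ct/ve`, FXR two-site water-exchange relaxation rate, SPGR signal at
#' the dynamic flip angle. Gaussian noise on the signal with
#' `sigma = pre-contrast signal / snr`.
#'
#' @param truth One-row data.frame (or list) with `Ktrans`, `ve`, `tau_i`.
#' @param protocol A [default_protocol()].
#' @param aif AIF object; its bolus arrival should fall after the
#'   `n_baseline` pre-contrast frames.
#' @param snr Pre-contrast signal-to-noise ratio; `Inf` for noiseless.
#' @param seed Integer seed.
#' @param n_voxels Number of voxels.
#' @param t10 Pre-contrast T1, s.
#' @param m0 Equilibrium magnetization.
#' @param relaxivity Contrast relaxivity, 1/(s mM).
#' @return List with `times_s`, `signals` (n_voxels x n_frames), `t10`,
#'   `m0`, plus the noiseless `vfa_signals` at the T1-mapping flip angles
#'   (one row per voxel, noise at the same SNR).
#' @export
generate_dce_signal <- function(truth, protocol = default_protocol(),
                                aif = aif_biexponential(
                                  bolus_arrival_s =
                                    protocol$n_baseline * protocol$dt_dynamic),
                                snr = Inf, seed = 1L, n_voxels = 1,
                                t10 = 1.4, m0 = 1000, relaxivity = 3.7) {
  stopifnot(snr > 0, t10 > 0)
  set.seed(seed)
  times <- dce_times(protocol)
  if (aif$form == "measured") aif$cp(times)  # errors on mismatch
  s <- fxr_forward(truth$Ktrans, truth$ve, truth$tau_i, aif, times, m0,
                   t10, protocol$dynamic_flip_deg, protocol$tr,
                   relaxivity = relaxivity)
  pre <- s[1]
  sigma <- if (is.finite(snr)) pre / snr else 0
  signals <- t(vapply(seq_len(n_voxels),
                      function(i) s + rnorm(length(s), 0, sigma),
                      numeric(length(s))))
  vfa <- spgr_signal(1 / t10, m0, protocol$flip_angles_deg, protocol$tr)
  vfa_signals <- t(vapply(seq_len(n_voxels),
                          function(i) vfa + rnorm(length(vfa), 0, sigma),
                          numeric(length(vfa))))
  list(times_s = times, signals = signals, t10 = t10, m0 = m0,
       vfa_signals = vfa_signals)
}

#' Simulate a frame-averaged FMISO time-activity curve
#'
#' Frame values are time-averages of the instantaneous two-tissue
#' compartment model over each frame. Noise is Gaussian with a
#' frame-duration-weighted standard deviation,
#' `sigma_j = (peak / snr) sqrt(d_peak / d_j)`, so the empirical SNR at the
#' peak frame equals the request and variance scales as 1/duration.
#'
#' @param truth One-row data.frame (or list) with `K1`, `k2`, `k3max`
#'   (used as the lesion trapping rate) and `vb`; a `k3` field overrides
#'   `k3max` if present.
#' @param if_model Input function object.
#' @param protocol A [default_protocol()] (frame schedule).
#' @param snr Peak-frame signal-to-noise ratio; `Inf` for noiseless.
#' @param seed Integer seed.
#' @return List with `frames`, `tac` (kBq/mL) and the noiseless `tac_true`.
#' @export
generate_fmiso_tac <- function(truth, if_model = input_function_triphasic(),
                               protocol = default_protocol(),
                               snr = Inf, seed = 1L) {
  stopifnot(snr > 0)
  set.seed(seed)
  frames <- protocol$frames
  k3 <- if (!is.null(truth$k3)) truth$k3 else truth$k3max
  tac_true <- tac_frame_means(truth$K1, truth$k2, k3, truth$vb,
                              if_model, frames)
  if (is.finite(snr)) {
    ipk <- which.max(tac_true)
    sigma <- (tac_true[ipk] / snr) *
      sqrt(frames[ipk, "duration"] / frames[, "duration"])
    tac <- tac_true + rnorm(length(tac_true), 0, sigma)
  } else {
    tac <- tac_true
  }
  list(frames = frames, tac = tac, tac_true = tac_true)
}
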