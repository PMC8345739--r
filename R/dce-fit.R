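#' FXR model parameters
#'
#' Bundles the fast-exchange-regime (shutter-speed) DCE parameters and the
#' rates derived from them: `kep = Ktrans/ve`, the intra-to-extracellular
#' water exchange rate `kie = 1/tau_i`, and its reverse `kei` from the
#' two-site population balance with negligible vascular space,
#' `kei = kie (1 - ve) / ve`.
#'
#' @param ktrans Volume transfer constant, 1/min.
#' @param ve Extravascular-extracellular volume fraction, in (0, 1).
#' @param tau_i Mean intracellular water lifetime, s.
#' @param r10 Pre-contrast tissue longitudinal relaxation rate, 1/s.
#' @param r10e Pre-contrast EES relaxation rate, 1/s; defaults to `r10`.
#' @param r1i Intracellular relaxation rate, 1/s; the fitting convention
#'   sets it equal to `r10`.
#' @param relaxivity Contrast-agent longitudinal relaxivity r1, 1/(s mM).
#' @return A list of class `"qimnet_fxr_params"`.
#' @export
fxr_params <- function(ktrans, ve, tau_i, r10 = 1 / 1.4, r10e = r10,
                       r1i = r10, relaxivity = 3.7) {
  stopifnot(ktrans > 0, ve > 0, ve < 1, tau_i > 0, r10 > 0, relaxivity > 0)
  structure(list(ktrans = ktrans, ve = ve, tau_i = tau_i,
                 kep = ktrans / ve, kie = 1 / tau_i,
                 kei = (1 / tau_i) * (1 - ve) / ve,
                 r10 = r10, r10e = r10e, r1i = r1i,
                 relaxivity = relaxivity),
            class = "qimnet_fxr_params")
}

#' Tofts tissue concentration
#'
#' Standard Tofts model:
#' `Ct(t) = Ktrans int_0^t exp(-kep (t - u)) Cp(u) du`.
#' The convolution is evaluated by an exact recursion for a
#' piecewise-linear Cp; with `dt_fine` set, Cp is first resampled onto a
#' refined grid so that the piecewise-linear representation of a smooth AIF
#' is accurate at coarse frame spacings.
#'
#' @param ktrans Volume transfer constant, 1/min.
#' @param ve EES volume fraction (sets `kep = ktrans/ve`).
#' @param aif An AIF object ([aif_biexponential()] or [aif_measured()]).
#' @param times_s Output times, s, ascending.
#' @param dt_fine Internal resampling interval, s; `NULL` evaluates on
#'   `times_s` only (Cp treated as linear between those points).
#' @return Tissue concentration, mM, at `times_s`.
#' @examples
#' aif <- aif_biexponential(bolus_arrival_s = 0)
#' ct <- tofts_concentration(0.18, 0.32, aif, seq(0, 300, 4))
#' @export
tofts_concentration <- function(ktrans, ve, aif, times_s, dt_fine = 0.25) {
  stopifnot(ktrans >= 0, ve > 0, !is.unsorted(times_s))
  kep_s <- (ktrans / ve) / 60
  knots <- if (!is.null(aif$params$bolus_arrival_s))
    aif$params$bolus_arrival_s else numeric(0)
  if (is.null(dt_fine)) {
    g <- list(grid = times_s, idx = seq_along(times_s))
  } else {
    g <- refine_grid(times_s, dt_fine, knots)
  }
  cp <- aif$cp(g$grid)
  ct <- (ktrans / 60) * exp_conv_pwl(g$grid, cp, kep_s)
  pmax(ct[g$idx], 0)
}

#' FXR longitudinal relaxation rate
#'
#' Observable tissue relaxation rate of the two-site water-exchange model:
#' the smaller eigenvalue of the 2x2 Bloch-McConnell exchange matrix,
#' \deqn{R_{1t} = \tfrac12\left[(R_{1i}+k_{ie}+R_{1e}+k_{ei}) -
#'   \sqrt{(R_{1i}+k_{ie}-R_{1e}-k_{ei})^2 + 4 k_{ie} k_{ei}}\right],}
#' with the EES rate from the fast-exchange-limit relation
#' `R1e(t) = R10e + r1 Ce(t)` and `Ce = Ct / ve`.
#'
#' @param params A [fxr_params()] object.
#' @param ct Tissue contrast-agent concentration series, mM.
#' @return `R1t` series, 1/s.
#' @export
fxr_longitudinal_rate <- function(params, ct) {
  stopifnot(inherits(params, "qimnet_fxr_params"), all(ct >= 0))
  r1e <- params$r10e + params$relaxivity * ct / params$ve
  a <- params$r1i + params$kie
  b <- r1e + params$kei
  0.5 * ((a + b) - sqrt((a - b)^2 + 4 * params$kie * params$kei))
}

#' Spoiled gradient-echo signal
#'
#' Steady-state SPGR signal
#' `S = M0 sin(a) (1 - E1) / (1 - E1 cos(a))`, `E1 = exp(-TR R1)`.
#' Monotone increasing in R1 at fixed settings.
#'
#' @param r1 Longitudinal relaxation rate(s), 1/s.
#' @param m0 Equilibrium magnetization, signal units.
#' @param flip_deg Flip angle, degrees, in (0, 90).
#' @param tr Repetition time, ms.
#' @return Signal, same length as `r1`.
#' @export
spgr_signal <- function(r1, m0, flip_deg, tr) {
  stopifnot(flip_deg > 0, flip_deg < 90, tr > 0, all(r1 >= 0))
  a <- flip_deg * pi / 180
  e1 <- exp(-(tr / 1000) * r1)
  m0 * sin(a) * (1 - e1) / (1 - e1 * cos(a))
}

# invert SPGR at known R1 for the equilibrium magnetization
spgr_m0 <- function(signal, r1, flip_deg, tr) {
  a <- flip_deg * pi / 180
  e1 <- exp(-(tr / 1000) * r1)
  signal * (1 - e1 * cos(a)) / (sin(a) * (1 - e1))
}

#' Variable-flip-angle T1 estimation
#'
#' Estimates the pre-contrast T1 (and M0) from SPGR signals at multiple flip
#' angles: the linearized DESPOT1 regression of `S/sin(a)` on `S/tan(a)`
#' (slope `E1 = exp(-TR/T1)`) provides the starting point, refined by
#' nonlinear least squares on the SPGR equation.
#'
#' @param vfa_signals Signal at each flip angle.
#' @param tr Repetition time, ms.
#' @param flip_angles_deg Flip angles, degrees (>= 2 distinct).
#' @return List with `t10` (s), `m0`, `converged` flag.
#' @examples
#' s <- spgr_signal(1 / 1.4, 1000, c(5, 15, 30), 7)
#' estimate_t10(s, 7, c(5, 15, 30))$t10
#' @export
estimate_t10 <- function(vfa_signals, tr, flip_angles_deg) {
  stopifnot(length(vfa_signals) == length(flip_angles_deg),
            length(unique(flip_angles_deg)) >= 2)
  if (diff(range(vfa_signals)) <= 1e-10 * max(abs(vfa_signals), 1e-12))
    return(list(t10 = NA_real_, m0 = NA_real_, converged = FALSE))
  a <- flip_angles_deg * pi / 180
  y <- vfa_signals / sin(a)
  x <- vfa_signals / tan(a)
  fit <- lm(y ~ x)
  e1 <- coef(fit)[["x"]]
  if (!is.finite(e1) || e1 <= 0 || e1 >= 1)
    return(list(t10 = NA_real_, m0 = NA_real_, converged = FALSE))
  t10 <- -(tr / 1000) / log(e1)
  m0 <- coef(fit)[["(Intercept)"]] / (1 - e1)
  res <- minpack.lm::nls.lm(
    par = c(log(t10), log(m0)),
    fn = function(p) {
      spgr_signal(1 / exp(p[1]), exp(p[2]), flip_angles_deg, tr) - vfa_signals
    },
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                         ptol = 1e-14))
  list(t10 = exp(res$par[1]), m0 = exp(res$par[2]),
       converged = res$info %in% 1:4)
}

# forward FXR signal chain shared by the simulator and the fit
fxr_forward <- function(ktrans, ve, tau_i, aif, times_s, m0, t10,
                        flip_deg, tr, r10e = 1 / t10, relaxivity = 3.7,
                        dt_fine = 0.25) {
  ct <- tofts_concentration(ktrans, ve, aif, times_s, dt_fine = dt_fine)
  pars <- fxr_params(ktrans, ve, tau_i, r10 = 1 / t10, r10e = r10e,
                     relaxivity = relaxivity)
  r1t <- fxr_longitudinal_rate(pars, ct)
  spgr_signal(r1t, m0, flip_deg, tr)
}

#' Fit the FXR water-exchange model to a dynamic signal
#'
#' Voxelwise nonlinear least-squares fit of (Ktrans, ve, tau_i) to a dynamic
#' SPGR series. The intracellular relaxation rate is fixed at the
#' pre-contrast tissue rate (`R1i = R10 = 1/t10`), and M0 is calibrated from
#' the mean pre-contrast signal. Fitting is bounded
#' (`Ktrans` in `[1e-4, 2]` 1/min, `ve` in `[0.01, 0.99]`, `tau_i` in `[0.05, 3]` s)
#' and multi-started: a fast-exchange-limit two-parameter fit seeds the
#' three-parameter fit together with two perturbed restarts; the best
#' residual wins.
#'
#' @param signal Dynamic signal series at the protocol frame times.
#' @param aif AIF object covering the dynamic times.
#' @param t10 Pre-contrast T1, s.
#' @param protocol A [default_protocol()].
#' @param relaxivity Contrast relaxivity, 1/(s mM).
#' @param lower,upper Bounds on `(ktrans, ve, tau_i)`.
#' @return List with `ktrans`, `ve`, `tau_i`, `kep`, `m0`, `residual_norm`,
#'   `converged`, `flag` (`"ok"`, `"no_enhancement"` or `"max_iter"`).
#' @export
fit_fxr <- function(signal, aif, t10, protocol, relaxivity = 3.7,
                    lower = c(1e-4, 0.01, 0.05), upper = c(2, 0.99, 3)) {
  stopifnot(t10 > 0, protocol$n_baseline >= 1,
            length(signal) == protocol$n_dynamics)
  times <- dce_times(protocol)
  flip <- protocol$dynamic_flip_deg
  pre <- mean(signal[seq_len(protocol$n_baseline)])
  m0 <- spgr_m0(pre, 1 / t10, flip, protocol$tr)

  resid_fn <- function(p) {
    fxr_forward(p[1], p[2], p[3], aif, times, m0, t10, flip, protocol$tr,
                relaxivity = relaxivity) - signal
  }
  fxl_fit <- minpack.lm::nls.lm(
    par = c(0.2, 0.3),
    lower = lower[1:2], upper = upper[1:2],
    fn = function(p) {
      fxr_forward(p[1], p[2], lower[3], aif, times, m0, t10, flip,
                  protocol$tr, relaxivity = relaxivity) - signal
    },
    control = minpack.lm::nls.lm.control(maxiter = 150))
  seed <- c(fxl_fit$par, 0.7)
  starts <- list(seed,
                 pmin(pmax(seed * c(1.6, 0.7, 2.0), lower), upper),
                 pmin(pmax(seed * c(0.6, 1.3, 0.3), lower), upper))
  best <- NULL
  for (s in starts) {
    fit <- minpack.lm::nls.lm(
      par = s, lower = lower, upper = upper, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-13,
                                           ptol = 1e-13))
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  p <- best$par
  # no-enhancement degeneracy: if clamping Ktrans at its lower bound fits as
  # well as the optimum, the series carries no kinetic information
  dev_lb <- sum(resid_fn(c(lower[1], p[2], p[3]))^2)
  no_enh <- p[1] <= lower[1] * 1.01 ||
    dev_lb <= best$deviance * (1 + 1e-6) + 1e-12
  if (no_enh) p[1] <- lower[1]
  flag <- if (no_enh) "no_enhancement"
          else if (!(best$info %in% 1:4)) "max_iter" else "ok"
  list(ktrans = p[1], ve = p[2], tau_i = p[3], kep = p[1] / p[2],
       m0 = m0, residual_norm = sqrt(best$deviance),
       converged = best$info %in% 1:4, flag = flag)
}
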