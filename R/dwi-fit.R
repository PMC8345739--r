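#' Monoexponential ADC fit
#'
#' Fits `S(b) = S0 exp(-b ADC)` to a diffusion signal decay. Non-positive
#' signals are excluded; a weighted log-linear regression (weights `S^2`,
#' the first-order variance correction for log-transformed data) provides
#' the start, refined by nonlinear least squares on the signal scale.
#'
#' @param signal Signal at each b-value.
#' @param b_values Diffusion weightings, s/mm2.
#' @param b_subset Optional subset of b-values to use (default: all).
#' @return List with `adc` (mm2/s), `s0`, `residual_norm`, `flag`
#'   (`"ok"`, `"boundary"` for adc pinned at 0, `"insufficient_data"`).
#' @examples
#' b <- c(0, 20, 50, 80, 200, 300, 500, 800, 1500, 2000)
#' fit_adc(100 * exp(-b * 0.93e-3), b)$adc
#' @export
fit_adc <- function(signal, b_values, b_subset = NULL) {
  stopifnot(length(signal) == length(b_values))
  if (!is.null(b_subset)) {
    keep <- b_values %in% b_subset
    signal <- signal[keep]; b_values <- b_values[keep]
  }
  ok <- is.finite(signal) & signal > 0
  if (sum(ok) < 2 || length(unique(b_values[ok])) < 2)
    return(list(adc = NA_real_, s0 = NA_real_, residual_norm = NA_real_,
                flag = "insufficient_data"))
  s <- signal[ok]; b <- b_values[ok]
  w <- s^2
  fit0 <- lm(log(s) ~ b, weights = w)
  adc0 <- max(-coef(fit0)[["b"]], 0)
  s00 <- exp(coef(fit0)[["(Intercept)"]])
  res <- minpack.lm::nls.lm(
    par = c(s00, adc0), lower = c(1e-12, 0), upper = c(Inf, 0.1),
    fn = function(p) p[1] * exp(-b * p[2]) - s,
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                         ptol = 1e-15))
  adc <- res$par[2]
  list(adc = adc, s0 = res$par[1], residual_norm = sqrt(res$deviance),
       flag = if (adc < 1e-9) "boundary" else "ok")
}

#' IVIM biexponential fit
#'
#' Fits the intravoxel-incoherent-motion model
#' `S(b) = S0 [ f exp(-b D*) + (1 - f) exp(-b D) ]`
#' by segmented initialization followed by a full bounded four-parameter
#' nonlinear least squares. The high-b segment (`b >= b_split`) gives D and
#' the perfusion fraction from the intercept gap; D* starts at a typical
#' pseudo-diffusion value. A monoexponential-collapse start (`f = 0`) is
#' also tried so the IVIM residual can never exceed the monoexponential one.
#'
#' Bounds: D in `[1e-5, 4e-3]`, D* in `[3e-3, 0.1]` mm2/s, f in `[0, 1]`; the
#' disjoint D/D* boxes prevent compartment swap.
#'
#' @param signal Signal at each b-value.
#' @param b_values Diffusion weightings, s/mm2 (>= 5, spanning `b_split`).
#' @param b_split Segmentation threshold, s/mm2.
#' @return List with `d_true`, `d_star`, `f`, `s0`, `residual_norm`,
#'   `converged`, `flag`.
#' @export
fit_ivim <- function(signal, b_values, b_split = 200) {
  stopifnot(length(signal) == length(b_values), length(b_values) >= 5,
            any(b_values >= b_split), any(b_values < b_split))
  lower <- c(1e-12, 0, 1e-5, 3e-3)
  upper <- c(Inf, 1, 4e-3, 0.1)
  hi <- b_values >= b_split & signal > 0
  seg <- fit_adc(signal[hi], b_values[hi])
  s0_obs <- max(signal[b_values == min(b_values)][1], 1e-12)
  if (seg$flag == "insufficient_data") {
    d0 <- 1e-3; f0 <- 0.1; s0_seg <- s0_obs
  } else {
    d0 <- min(max(seg$adc, lower[3]), upper[3])
    s0_seg <- seg$s0
    f0 <- min(max(1 - s0_seg / s0_obs, 0), 0.6)
  }
  model <- function(p, b) p[1] * (p[2] * exp(-b * p[4]) +
                                  (1 - p[2]) * exp(-b * p[3]))
  run <- function(start) {
    minpack.lm::nls.lm(
      par = pmin(pmax(start, lower), upper), lower = lower, upper = upper,
      fn = function(p) model(p, b_values) - signal,
      control = minpack.lm::nls.lm.control(maxiter = 400, ftol = 1e-15,
                                           ptol = 1e-15))
  }
  mono <- fit_adc(signal, b_values)
  starts <- list(c(s0_obs, f0, d0, 0.01),
                 c(s0_obs, max(f0, 0.05), d0, 0.03))
  if (mono$flag == "ok")
    starts <- c(starts, list(c(mono$s0, 0, min(max(mono$adc, lower[3]),
                                               upper[3]), 0.01)))
  best <- NULL
  for (s in starts) {
    fit <- run(s)
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  p <- best$par
  converged <- best$info %in% 1:4
  list(d_true = p[3], d_star = p[4], f = p[2], s0 = p[1],
       residual_norm = sqrt(best$deviance), converged = converged,
       flag = if (converged) "ok" else "segmented_fallback")
}
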