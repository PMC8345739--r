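#' Arterial input function models
#'
#' Plasma contrast-agent concentration Cp(t) used by the Tofts/FXR forward
#' model and fits. Two forms are provided: a biexponential decay of the
#' Tofts-Kermode type (zero before bolus arrival, then
#' `dose * (a1 exp(-m1 t) + a2 exp(-m2 t))` with t counted from arrival), and
#' a "measured" form interpolating a sampled Cp series piecewise-linearly.
#'
#' @param dose Injected contrast dose, mmol/kg body weight.
#' @param a1,a2 Amplitudes, kg/L (so that `dose * a` is in mM).
#' @param m1,m2 Decay rates, 1/min.
#' @param bolus_arrival_s Bolus arrival time, s.
#' @return An object of class `"qimnet_aif"`: a list with `form`, `params`
#'   and a vectorized evaluator `cp(t_s)` returning mM at times in seconds.
#' @examples
#' aif <- aif_biexponential(bolus_arrival_s = 48)
#' aif$cp(c(0, 60, 120))
#' @export
aif_biexponential <- function(dose = 0.1, a1 = 3.99, a2 = 4.78,
                              m1 = 0.144, m2 = 0.0111,
                              bolus_arrival_s = 48) {
  stopifnot(dose > 0, a1 >= 0, a2 >= 0, m1 > 0, m2 > 0, bolus_arrival_s >= 0)
  params <- list(dose = dose, a1 = a1, a2 = a2, m1 = m1, m2 = m2,
                 bolus_arrival_s = bolus_arrival_s)
  cp <- function(t_s) {
    u <- pmax(0, (t_s - bolus_arrival_s) / 60)  # min since arrival
    ifelse(t_s < bolus_arrival_s, 0,
           dose * (a1 * exp(-m1 * u) + a2 * exp(-m2 * u)))
  }
  structure(list(form = "biexponential", params = params, cp = cp),
            class = "qimnet_aif")
}

#' @rdname aif_biexponential
#' @param times_s Sample times, s, ascending.
#' @param cp_mM Sampled plasma concentrations, mM, nonnegative.
#' @export
aif_measured <- function(times_s, cp_mM) {
  stopifnot(length(times_s) == length(cp_mM), !is.unsorted(times_s),
            all(cp_mM >= 0))
  ts <- times_s; cs <- cp_mM
  cp <- function(t_s) {
    if (any(t_s < ts[1] - 1e-9) || any(t_s > ts[length(ts)] + 1e-9))
      stop("AIF/timebase mismatch: requested times outside the sampled AIF support")
    approx(ts, cs, xout = t_s, rule = 2)$y
  }
  structure(list(form = "measured",
                 params = list(times_s = ts, cp_mM = cs), cp = cp),
            class = "qimnet_aif")
}

#' Triphasic-exponential PET input function
#'
#' Image-based whole-blood input function model for dynamic FMISO PET: zero
#' before bolus arrival, a linear rise to the peak, then a sum of three
#' decaying exponentials, continuous at the peak (peak value equals the sum
#' of the three amplitudes).
#'
#' @param bolus_arrival_s,peak_time_s Bolus arrival and peak time, s
#'   (`peak_time_s > bolus_arrival_s`).
#' @param amplitudes Three exponential amplitudes, kBq/mL, positive.
#' @param rates Three decay rates, 1/s, positive (any order).
#' @return An object of class `"qimnet_if"` with fields `bolus_arrival_s`,
#'   `peak_time_s`, `amplitudes`, `rates`, `peak` and an evaluator
#'   `cb(t_s)` in kBq/mL.
#' @examples
#' ifm <- input_function_triphasic()
#' ifm$cb(c(30, 60, 600))
#' @export
input_function_triphasic <- function(bolus_arrival_s = 30, peak_time_s = 60,
                                     amplitudes = c(40, 15, 12),
                                     rates = c(0.05, 0.004, 2e-5)) {
  stopifnot(peak_time_s > bolus_arrival_s, length(amplitudes) == 3,
            length(rates) == 3, all(amplitudes > 0), all(rates > 0))
  o <- order(rates, decreasing = TRUE)
  amplitudes <- unname(amplitudes[o]); rates <- unname(rates[o])
  peak <- sum(amplitudes)
  cb <- function(t_s) {
    out <- numeric(length(t_s))
    rising <- t_s >= bolus_arrival_s & t_s < peak_time_s
    out[rising] <- peak * (t_s[rising] - bolus_arrival_s) /
      (peak_time_s - bolus_arrival_s)
    late <- t_s >= peak_time_s
    if (any(late)) {
      u <- t_s[late] - peak_time_s
      out[late] <- amplitudes[1] * exp(-rates[1] * u) +
        amplitudes[2] * exp(-rates[2] * u) +
        amplitudes[3] * exp(-rates[3] * u)
    }
    out
  }
  structure(list(form = "triphasic-exponential",
                 bolus_arrival_s = bolus_arrival_s, peak_time_s = peak_time_s,
                 amplitudes = amplitudes, rates = rates, peak = peak,
                 cb = cb),
            class = "qimnet_if")
}

#' @rdname input_function_triphasic
#' @param times_s,activity Sampled input-function series (s, kBq/mL).
#' @export
input_function_sampled <- function(times_s, activity) {
  stopifnot(length(times_s) == length(activity), !is.unsorted(times_s),
            all(activity >= 0))
  ts <- times_s; a <- activity
  cb <- function(t_s) {
    if (any(t_s > ts[length(ts)] + 1e-9))
      stop("frame schedule extends beyond input-function support")
    approx(ts, a, xout = t_s, rule = 2)$y
  }
  structure(list(form = "sampled", times_s = ts, activity = a,
                 peak = max(a), cb = cb),
            class = "qimnet_if")
}
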