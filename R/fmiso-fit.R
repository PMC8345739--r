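#' Irreversible two-tissue compartment model
#'
#' Instantaneous tissue activity of the irreversible one-plasma two-tissue
#' compartment model with a blood volume component:
#' \deqn{dC_1/dt = K_1 C_p - (k_2 + k_3) C_1,\quad dC_2/dt = k_3 C_1,}
#' \deqn{C_T(t) = (1 - v_b)(C_1 + C_2) + v_b C_{wb}(t).}
#' With `beta = k2 + k3` the free+trapped sum has the exponential-kernel
#' form `C1 + C2 = K1/beta int [k3 + k2 exp(-beta (t-u))] Cp(u) du`, which
#' is evaluated exactly for a piecewise-linear input. The whole-blood curve
#' `Cwb` is taken equal to the input function (image-based venous input).
#'
#' @param k1 Delivery rate, 1/min.
#' @param k2 Washout rate, 1/min.
#' @param k3 Irreversible trapping rate, 1/min.
#' @param vb Blood volume fraction, in `[0, 0.2]`.
#' @param if_model Input function ([input_function_triphasic()] or
#'   [input_function_sampled()]).
#' @param times_s Evaluation times, s, ascending; the input function is
#'   treated as piecewise-linear between these points.
#' @return Tissue activity at `times_s`, kBq/mL.
#' @examples
#' ifm <- input_function_triphasic()
#' simulate_2tc(0.33, 0.33 / 0.89, 0.0087, 0.05, ifm, seq(0, 1800, 5))
#' @export
simulate_2tc <- function(k1, k2, k3, vb, if_model, times_s) {
  stopifnot(k1 >= 0, k2 > 0, k3 >= 0, vb >= 0, vb <= 0.2,
            !is.unsorted(times_s))
  cp <- if_model$cb(times_s)
  t_min <- times_s / 60
  beta <- k2 + k3
  conv_b <- exp_conv_pwl(t_min, cp, beta)
  conv_0 <- exp_conv_pwl(t_min, cp, 0)
  free_trapped <- (k1 / beta) * (k3 * conv_0 + k2 * conv_b)
  pmax((1 - vb) * free_trapped + vb * cp, 0)
}

# evaluation grid covering all frames plus input-function kinks
pet_eval_grid <- function(frames, if_model, dt_dyn = 0.5, dt_static = 2) {
  ends <- frames[, "start"] + frames[, "duration"]
  pieces <- lapply(seq_len(nrow(frames)), function(i) {
    dt <- if (frames[i, "duration"] <= 60) dt_dyn else dt_static
    seq(frames[i, "start"], ends[i], by = dt)
  })
  knots <- c(0, if_model$bolus_arrival_s, if_model$peak_time_s)
  sort(unique(c(0, unlist(pieces), ends,
                knots[!vapply(knots, is.null, TRUE)])))
}

# frame averages of a curve sampled on `grid`
frame_average <- function(grid, values, frames) {
  vapply(seq_len(nrow(frames)), function(i) {
    a <- frames[i, "start"]; b <- a + frames[i, "duration"]
    inside <- grid >= a - 1e-9 & grid <= b + 1e-9
    tt <- grid[inside]; vv <- values[inside]
    sum(diff(tt) * (vv[-1] + vv[-length(vv)]) / 2) / (tt[length(tt)] - tt[1])
  }, numeric(1))
}

# frame-averaged 2TC model, shared by the simulator and the fit
tac_frame_means <- function(k1, k2, k3, vb, if_model, frames) {
  grid <- pet_eval_grid(frames, if_model)
  ct <- simulate_2tc(k1, k2, k3, vb, if_model, grid)
  frame_average(grid, ct, frames)
}

#' Fit the irreversible 2TC model to a time-activity curve
#'
#' Weighted nonlinear least squares on frame-averaged model values, weights
#' proportional to the square root of frame duration (inverse-variance for
#' count-limited noise). Bounds: K1, k2 in `[1e-3, 2]` 1/min, k3 in
#' `[0, 0.05]` 1/min, vb in `[0, 0.2]`. The distribution volume is reported as
#' `DV = K1/k2`.
#'
#' @param tac Frame-averaged tissue activity, kBq/mL, one value per frame.
#' @param if_model Input function object.
#' @param frames Frame schedule matrix `(start, duration)`, s; defaults to
#'   the protocol schedule.
#' @return List with `k1`, `k2`, `k3`, `vb`, `dv`, `residual_norm`,
#'   `converged`, `flag` (`"ok"`, `"no_uptake"`, `"max_iter"`).
#' @export
fit_2tc <- function(tac, if_model, frames = pet_frame_schedule()) {
  frames <- as.matrix(frames)
  stopifnot(length(tac) == nrow(frames))
  lower <- c(1e-3, 1e-3, 0, 0)
  upper <- c(2, 2, 0.05, 0.2)
  w <- sqrt(frames[, "duration"] / max(frames[, "duration"]))
  resid_fn <- function(p)
    w * (tac_frame_means(p[1], p[2], p[3], p[4], if_model, frames) - tac)
  starts <- list(c(0.2, 0.25, 0.005, 0.05),
                 c(0.5, 0.5, 0.001, 0.02),
                 c(0.1, 0.1, 0.02, 0.1))
  best <- NULL
  for (s in starts) {
    fit <- minpack.lm::nls.lm(
      par = s, lower = lower, upper = upper, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-13,
                                           ptol = 1e-13))
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  p <- best$par
  flag <- if (p[1] <= lower[1] * 1.01) "no_uptake"
          else if (!(best$info %in% 1:4)) "max_iter" else "ok"
  list(k1 = p[1], k2 = p[2], k3 = p[3], vb = p[4], dv = p[1] / p[2],
       residual_norm = sqrt(best$deviance), converged = best$info %in% 1:4,
       flag = flag)
}

# frame-averaged triphasic input-function model
if_frame_means <- function(if_model, frames) {
  grid <- pet_eval_grid(frames, if_model)
  frame_average(grid, if_model$cb(grid), frames)
}

#' Fit a triphasic-exponential input function to a blood TAC
#'
#' Parametric fit of the image-based input-function model (linear rise from
#' bolus arrival to peak, then three decaying exponentials, continuous at
#' the peak) to a frame-averaged blood time-activity curve.
#'
#' @param blood_tac Frame-averaged blood activity, kBq/mL.
#' @param frames Frame schedule matrix `(start, duration)`, s.
#' @return List with `if_model` (a [input_function_triphasic()]),
#'   `residual_norm`, `converged`, `flag` (`"ok"`, `"degenerate"`).
#' @export
fit_input_function <- function(blood_tac, frames = pet_frame_schedule()) {
  frames <- as.matrix(frames)
  stopifnot(length(blood_tac) == nrow(frames))
  if (nrow(frames) < 6) stop("input-function fit needs at least 6 frames")
  if (max(blood_tac) <= 0)
    return(list(if_model = NULL, residual_norm = NA_real_,
                converged = FALSE, flag = "degenerate"))
  mids <- frame_mid(frames)
  ipk <- which.max(blood_tac)
  tp0 <- max(mids[ipk], 10)
  t00 <- if (ipk > 1) frames[ipk, "start"] / 2 else tp0 / 2
  peak0 <- max(blood_tac)
  # parameters: t0, log(tp - t0), log amplitudes (3), log rates (3)
  par0 <- c(t00, log(max(tp0 - t00, 5)),
            log(peak0 * c(0.55, 0.25, 0.20)),
            log(c(0.05, 0.004, 2e-5)))
  unpack <- function(p) {
    input_function_triphasic(bolus_arrival_s = p[1],
                             peak_time_s = p[1] + exp(p[2]),
                             amplitudes = exp(p[3:5]),
                             rates = exp(p[6:8]))
  }
  w <- sqrt(frames[, "duration"] / max(frames[, "duration"]))
  fit <- minpack.lm::nls.lm(
    par = par0,
    lower = c(0, log(1), rep(log(1e-6), 3), rep(log(1e-8), 3)),
    upper = c(max(mids), log(600), rep(log(10 * peak0), 3), rep(log(1), 3)),
    fn = function(p) w * (if_frame_means(unpack(p), frames) - blood_tac),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14))
  list(if_model = unpack(fit$par), residual_norm = sqrt(fit$deviance),
       converged = fit$info %in% 1:4,
       flag = if (fit$info %in% 1:4) "ok" else "max_iter")
}

#' Lean body mass (James formula)
#'
#' `1.10 W - 128 (W/H)^2` for males, `1.07 W - 148 (W/H)^2` for females,
#' with weight W in kg and height H in cm.
#'
#' @param weight_kg,height_cm Anthropometrics.
#' @param sex `"male"` or `"female"`.
#' @return Lean body mass, kg.
#' @export
lbm_james <- function(weight_kg, height_cm, sex = c("male", "female")) {
  sex <- match.arg(sex)
  stopifnot(weight_kg > 0, height_cm > 0)
  r <- weight_kg / height_cm
  if (sex == "male") 1.10 * weight_kg - 128 * r^2
  else 1.07 * weight_kg - 148 * r^2
}

#' Static uptake metrics: TBR and SUL
#'
#' Tumor-to-blood ratio at the late static time point and the standardized
#' uptake value normalized to lean body mass:
#' `TBR = Ct/Cb`, `SUL = Ct / (A0 / LBM)` with tissue activity in kBq/mL,
#' injected activity A0 in MBq and LBM from [lbm_james()] (1 MBq/kg of
#' normalization cancels the kBq/g scale, so SUL is dimensionless).
#'
#' @param tissue_late,blood_late Late static tissue and blood activity,
#'   kBq/mL (`blood_late > 0`).
#' @param injected_activity_mbq Injected activity, MBq.
#' @param weight_kg,height_cm,sex Anthropometrics for [lbm_james()].
#' @return List with `tbr` and `sul`.
#' @examples
#' static_uptake_metrics(5, 4, 370, 80, 180, "male")
#' @export
static_uptake_metrics <- function(tissue_late, blood_late,
                                  injected_activity_mbq,
                                  weight_kg, height_cm,
                                  sex = c("male", "female")) {
  if (blood_late <= 0) stop("blood activity must be positive for TBR")
  stopifnot(injected_activity_mbq > 0)
  lbm <- lbm_james(weight_kg, height_cm, match.arg(sex))
  list(tbr = tissue_late / blood_late,
       sul = tissue_late * lbm / injected_activity_mbq)
}
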