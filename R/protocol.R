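#' Acquisition protocols
#'
#' Constructors for the acquisition settings the simulators and fitters share:
#' the diffusion b-value ladder, the spoiled-gradient-echo (SPGR) settings for
#' variable-flip-angle T1 mapping and the dynamic contrast-enhanced series,
#' and the PET frame schedule (30 min dynamic acquisition plus two late
#' 10-minute static acquisitions).
#'
#' Defaults reproduce a typical 3 T head-and-neck protocol: ten b-values from
#' 0 to 2000 s/mm2; flip angles 5/15/30 degrees with TR/TE = 7/2.7 ms; a
#' 40-frame dynamic series at 8 s temporal resolution with 6 pre-contrast
#' frames and a 15-degree dynamic flip angle; and a dynamic PET binning of
#' 6x5 s, 3x10 s, 4x60 s, 2x150 s, 2x300 s and 1x600 s frames followed by
#' 600 s static acquisitions starting at 90 and 160 minutes post-injection.
#'
#' @param b_values Diffusion weightings, s/mm2, nonnegative ascending.
#' @param tr,te Repetition and echo time, ms.
#' @param flip_angles_deg Flip angles of the pre-contrast T1-mapping series,
#'   degrees.
#' @param dynamic_flip_deg Flip angle of the dynamic series, degrees.
#' @param n_dynamics Number of dynamic frames.
#' @param dt_dynamic Dynamic temporal resolution, s.
#' @param n_baseline Number of pre-contrast dynamic frames.
#' @param frames Two-column matrix or data.frame of PET frame
#'   `(start, duration)` in seconds, non-overlapping ascending.
#' @return A list with class `"qimnet_protocol"` holding all settings.
#' @examples
#' p <- default_protocol()
#' p$b_values
#' @export
default_protocol <- function(b_values = c(0, 20, 50, 80, 200, 300, 500, 800, 1500, 2000),
                             tr = 7, te = 2.7,
                             flip_angles_deg = c(5, 15, 30),
                             dynamic_flip_deg = 15,
                             n_dynamics = 40, dt_dynamic = 8,
                             n_baseline = 6,
                             frames = pet_frame_schedule()) {
  stopifnot(all(b_values >= 0), !is.unsorted(b_values, strictly = TRUE),
            tr > 0, te > 0, all(flip_angles_deg > 0 & flip_angles_deg < 90),
            n_dynamics >= 2, dt_dynamic > 0, n_baseline >= 1,
            n_baseline < n_dynamics)
  frames <- as.matrix(frames)
  colnames(frames) <- c("start", "duration")
  stopifnot(all(frames[, "duration"] > 0), !is.unsorted(frames[, "start"]))
  ends <- frames[, "start"] + frames[, "duration"]
  if (nrow(frames) > 1 && any(frames[-1, "start"] < ends[-nrow(frames)] - 1e-9))
    stop("PET frame schedule has overlapping frames")
  structure(list(
    b_values = b_values, tr = tr, te = te,
    flip_angles_deg = flip_angles_deg, dynamic_flip_deg = dynamic_flip_deg,
    n_dynamics = n_dynamics, dt_dynamic = dt_dynamic, n_baseline = n_baseline,
    frames = frames
  ), class = "qimnet_protocol")
}

#' @rdname default_protocol
#' @param static_starts_min Start times of the late static acquisitions, min.
#' @param static_duration_s Duration of each static acquisition, s.
#' @export
pet_frame_schedule <- function(static_starts_min = c(90, 160),
                               static_duration_s = 600) {
  dur <- c(rep(5, 6), rep(10, 3), rep(60, 4), rep(150, 2), rep(300, 2), 600)
  start <- cumsum(c(0, dur[-length(dur)]))
  frames <- cbind(start = start, duration = dur)
  statics <- cbind(start = static_starts_min * 60,
                   duration = rep(static_duration_s, length(static_starts_min)))
  rbind(frames, statics)
}

# frame midpoints in seconds
frame_mid <- function(frames) frames[, "start"] + frames[, "duration"] / 2

#' Dynamic-series frame times
#'
#' Mid-frame times (s) of the DCE dynamic series defined by a protocol.
#'
#' @param protocol A [default_protocol()] object.
#' @return Numeric vector of length `n_dynamics`, seconds.
#' @export
dce_times <- function(protocol) {
  (seq_len(protocol$n_dynamics) - 0.5) * protocol$dt_dynamic
}
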