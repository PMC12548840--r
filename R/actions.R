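#' Action template for a deadlift variant
#'
#' An action template holds the prescribed kinematic and kinetic shape of one
#' deadlift variant: the sagittal lumbar flexion range, the two-peak lumbar
#' torque profile (first/second peak magnitude and timing), the trial
#' duration, the barbell mass and the marker-noise level. The three shipped
#' variants are the conventional deadlift (`DL`, flexion 32--90 deg, first
#' peak 749 N.m), the stiff-legged deadlift (`SLDL`, 0--90 deg, 893 N.m,
#' earlier first peak) and the trap-bar deadlift (`TBDL`, 35--90 deg,
#' 640 N.m).
#'
#' @param action_id one of `"DL"`, `"SLDL"`, `"TBDL"`.
#' @param flexion_start_deg,flexion_end_deg flexion angle (degrees from
#'   vertical) at lockout and at the bottom position; the trial moves
#'   monotonically from `flexion_end_deg` to `flexion_start_deg`.
#' @param first_peak_torque_Nm,second_peak_torque_Nm the two interior torque
#'   maxima (N.m); the second must be smaller than the first.
#' @param peak_time_fractions length-2 increasing vector in (0, 1): times of
#'   the two torque peaks as fractions of the trial duration.
#' @param trial_duration_s trial duration in seconds (default 2, one
#'   metronome cycle).
#' @param barbell_mass_kg barbell mass (kg), default 120.
#' @param noise_sd_mm isotropic Gaussian marker noise SD in millimetres.
#' @param seed integer RNG seed used for the noise component.
#' @param baseline_torque_frac torque at `t = 0` as a fraction of the first
#'   peak (default 0.6 so that the first hard-pull phase is non-empty).
#' @param trough_torque_frac,end_torque_frac torque at the inter-peak trough
#'   and at the end of the trial, as fractions of the first peak.
#' @param trough_time_fraction time of the trough as a fraction of the trial;
#'   default midway between the two peaks.
#' @return an object of class `action_template`.
#' @export
action_template <- function(action_id,
                            flexion_start_deg,
                            flexion_end_deg,
                            first_peak_torque_Nm,
                            second_peak_torque_Nm,
                            peak_time_fractions,
                            trial_duration_s = 2,
                            barbell_mass_kg = 120,
                            noise_sd_mm = 0.5,
                            seed = 0L,
                            baseline_torque_frac = 0.6,
                            trough_torque_frac = 0.5,
                            end_torque_frac = 0.15,
                            trough_time_fraction = NULL) {
  action_id <- match.arg(action_id, c("DL", "SLDL", "TBDL"))
  if (flexion_end_deg < flexion_start_deg) {
    stop("flexion_end_deg must be >= flexion_start_deg", call. = FALSE)
  }
  if (second_peak_torque_Nm >= first_peak_torque_Nm) {
    stop("second peak torque must be smaller than the first peak",
         call. = FALSE)
  }
  if (length(peak_time_fractions) != 2L ||
      diff(peak_time_fractions) <= 0 ||
      any(peak_time_fractions <= 0) || any(peak_time_fractions >= 1)) {
    stop("peak_time_fractions must be strictly increasing within (0, 1)",
         call. = FALSE)
  }
  if (trial_duration_s <= 0) stop("trial_duration_s must be positive",
                                  call. = FALSE)
  if (is.null(trough_time_fraction)) {
    trough_time_fraction <- mean(peak_time_fractions)
  }
  if (trough_time_fraction <= peak_time_fractions[1] ||
      trough_time_fraction >= peak_time_fractions[2]) {
    stop("trough_time_fraction must lie strictly between the peak fractions",
         call. = FALSE)
  }
  structure(list(
    action_id = action_id,
    flexion_start_deg = flexion_start_deg,
    flexion_end_deg = flexion_end_deg,
    first_peak_torque_Nm = first_peak_torque_Nm,
    second_peak_torque_Nm = second_peak_torque_Nm,
    peak_time_fractions = as.numeric(peak_time_fractions),
    trough_time_fraction = trough_time_fraction,
    trial_duration_s = trial_duration_s,
    barbell_mass_kg = barbell_mass_kg,
    noise_sd_mm = noise_sd_mm,
    seed = as.integer(seed),
    baseline_torque_frac = baseline_torque_frac,
    trough_torque_frac = trough_torque_frac,
    end_torque_frac = end_torque_frac
  ), class = "action_template")
}

#' Default action template for a shipped deadlift variant
#'
#' Reads the packaged per-action configuration file
#' (`extdata/actions/<id>.yaml`) and builds the template; `...` overrides any
#' field (e.g. `noise_sd_mm = 0`, `seed = 1`).
#'
#' @param action_id `"DL"`, `"SLDL"` or `"TBDL"` (case-insensitive).
#' @param ... overrides passed to [action_template()].
#' @export
default_action_template <- function(action_id, ...) {
  action_id <- toupper(action_id)
  path <- system.file("extdata", "actions",
                      paste0(tolower(action_id), ".yaml"),
                      package = "lumbarlift")
  if (!nzchar(path)) {
    stop("no packaged template for action '", action_id, "'", call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  over <- list(...)
  cfg[names(over)] <- over
  do.call(action_template, cfg)
}

## Knot set of the two-peak torque profile. The curve is a monotone piecewise
## cubic Hermite interpolant through (baseline, peak1, trough, peak2, end);
## monotonicity between knots guarantees that the only interior extrema are
## the knots themselves, so the profile has exactly two interior maxima.
torque_knots <- function(template) {
  p1 <- template$first_peak_torque_Nm
  Tt <- template$trial_duration_s
  list(
    t = c(0,
          template$peak_time_fractions[1] * Tt,
          template$trough_time_fraction * Tt,
          template$peak_time_fractions[2] * Tt,
          Tt),
    y = c(template$baseline_torque_frac * p1,
          p1,
          template$trough_torque_frac * p1,
          template$second_peak_torque_Nm,
          template$end_torque_frac * p1)
  )
}

#' Prescribed lumbar torque profile of an action template
#'
#' Evaluates the template's double-peak sagittal lumbar torque curve: a C1
#' monotone cubic Hermite spline through the baseline, first peak, trough,
#' second peak and end knots. The curve attains exactly the configured peak
#' torques at the configured peak time fractions and has exactly two interior
#' local maxima separated by one interior minimum.
#'
#' @param template an [action_template()].
#' @param t time(s) in seconds, within `[0, trial_duration_s]`.
#' @return torque in N.m (extensor positive), same length as `t`.
#' @export
torque_template <- function(template, t) {
  stopifnot(inherits(template, "action_template"))
  if (any(t < 0 | t > template$trial_duration_s)) {
    stop("t outside the trial duration [0, ",
         template$trial_duration_s, "] s", call. = FALSE)
  }
  k <- torque_knots(template)
  f <- stats::splinefun(k$t, k$y, method = "monoH.FC")
  f(t)
}

## Quintic smoothstep: C2 ramp with zero first and second derivative at both
## ends, used so that angular velocity and acceleration vanish at the start
## and end of the lift.
smoothstep5 <- function(x) x^3 * (10 - 15 * x + 6 * x^2)
smoothstep5_d1 <- function(x) 30 * x^2 - 60 * x^3 + 30 * x^4
smoothstep5_d2 <- function(x) 60 * x - 180 * x^2 + 120 * x^3

#' Prescribed lumbar flexion profile of an action template
#'
#' The flexion angle (trunk line versus vertical, degrees) decreases
#' monotonically from `flexion_end_deg` at the bottom position (`t = 0`) to
#' `flexion_start_deg` at lockout, following a quintic smoothstep so the
#' angular velocity and acceleration vanish at both ends.
#'
#' @inheritParams torque_template
#' @param deriv 0 (angle, degrees), 1 or 2 (time derivatives, deg/s and
#'   deg/s^2).
#' @export
flexion_template <- function(template, t, deriv = 0) {
  stopifnot(inherits(template, "action_template"))
  if (any(t < 0 | t > template$trial_duration_s)) {
    stop("t outside the trial duration [0, ",
         template$trial_duration_s, "] s", call. = FALSE)
  }
  Tt <- template$trial_duration_s
  x <- t / Tt
  rom <- template$flexion_end_deg - template$flexion_start_deg
  switch(as.character(deriv),
    "0" = template$flexion_end_deg - rom * smoothstep5(x),
    "1" = -rom * smoothstep5_d1(x) / Tt,
    "2" = -rom * smoothstep5_d2(x) / Tt^2,
    stop("deriv must be 0, 1 or 2", call. = FALSE)
  )
}
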