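#' Trial generation configuration
#'
#' Sampling rates, laboratory frame and marker layout used by
#' [generate_trial()]. The laboratory frame follows the motion-capture
#' convention: X is the sagittal (facing) direction, Y the coronal
#' (left-positive) direction and Z vertical (up). Trunk markers (L5, L3, L1,
#' T2, C7) sit on the trunk line at fixed arc distances from the lumbar
#' joint; pelvis markers (bilateral ASIS/PSIS) are static; the barbell
#' midpoint markers ride on the bar, which hangs at arm's length below the
#' shoulder with a fixed anterior offset from the lumbar joint.
#'
#' @param marker_hz marker sampling rate (Hz), default 100.
#' @param force_hz force-plate sampling rate (Hz), default 500.
#' @param anthropometry see [default_anthropometry()].
#' @param joint_height_m height of the lumbar joint centre above the floor.
#' @param bar_offset_x_m fixed anterior offset of the bar line from the
#'   lumbar joint (m); keeps the bar moment arm positive at full lockout.
#' @param arm_length_m vertical drop from the shoulder marker to the bar.
#' @param gravity_m_s2 gravitational acceleration magnitude, default 9.81.
#' @export
trial_config <- function(marker_hz = 100,
                         force_hz = 500,
                         anthropometry = default_anthropometry(),
                         joint_height_m = 1.0,
                         bar_offset_x_m = 0.12,
                         arm_length_m = 0.55,
                         gravity_m_s2 = 9.81) {
  if (marker_hz <= 0 || force_hz <= 0) {
    stop("sampling rates must be positive", call. = FALSE)
  }
  if (force_hz %% marker_hz != 0) {
    stop("force sampling rate must be an integer multiple of the marker rate",
         call. = FALSE)
  }
  list(marker_hz = marker_hz, force_hz = force_hz,
       anthropometry = anthropometry,
       joint_height_m = joint_height_m,
       bar_offset_x_m = bar_offset_x_m,
       arm_length_m = arm_length_m,
       gravity_m_s2 = gravity_m_s2,
       # arc distances (m) of trunk-line markers from the lumbar joint
       trunk_markers = c(L5 = 0.00, L3 = 0.07, L1 = 0.14,
                         T2 = 0.38, C7 = 0.43),
       shoulder_arc_m = 0.43,
       # static pelvis marker offsets from the joint (m), lab frame
       pelvis_markers = list(
         R_ASIS = c(0.09, -0.12, -0.05), L_ASIS = c(0.09, 0.12, -0.05),
         R_PSIS = c(-0.07, -0.05, -0.03), L_PSIS = c(-0.07, 0.05, -0.03)),
       bar_half_width_m = 0.25)
}

## Trunk-line unit vector in the sagittal plane for flexion angle theta
## (radians from vertical): upright theta = 0, horizontal theta = pi/2.
trunk_dir <- function(theta) cbind(sin(theta), 0, cos(theta))

## Exact kinematic state of the supra-lumbar segment at times t (seconds).
segment_states_at <- function(template, config, t) {
  inertia <- trunk_inertia(config$anthropometry)
  d <- inertia$com_distance_m
  th <- flexion_template(template, t, 0) * pi / 180
  th1 <- flexion_template(template, t, 1) * pi / 180
  th2 <- flexion_template(template, t, 2) * pi / 180
  u <- trunk_dir(th)
  up <- cbind(cos(th), 0, -sin(th))   # d u / d theta
  joint <- cbind(rep(0, length(t)), 0, config$joint_height_m)
  com <- joint + d * u
  acom <- d * (th2 * up - th1^2 * u)
  data.frame(
    time_s = t, theta_rad = th,
    omega_y = th1, alpha_y = th2,
    joint_x = joint[, 1], joint_y = joint[, 2], joint_z = joint[, 3],
    com_x = com[, 1], com_y = com[, 2], com_z = com[, 3],
    acom_x = acom[, 1], acom_y = acom[, 2], acom_z = acom[, 3]
  )
}

## Bar centre position (m, lab frame) at flexion angle theta.
bar_position <- function(config, theta) {
  sh <- config$joint_height_m + config$shoulder_arc_m * cos(theta)
  cbind(config$bar_offset_x_m + config$shoulder_arc_m * sin(theta),
        0,
        sh - config$arm_length_m)
}

## Magnitude of the (downward) bar force required so that the Newton-Euler
## balance about the lumbar joint reproduces the prescribed torque exactly.
bar_force_magnitude <- function(template, config, t) {
  inertia <- trunk_inertia(config$anthropometry)
  st <- segment_states_at(template, config, t)
  tau <- torque_template(template, t)
  g <- c(0, 0, -config$gravity_m_s2)
  iyy <- inertia$inertia_kg_m2[2, 2]
  rc <- cbind(st$com_x, st$com_y - 0, st$com_z - config$joint_height_m)
  acc <- cbind(st$acom_x - g[1], st$acom_y - g[2], st$acom_z - g[3])
  # y-component of I alpha + m rc x (a_c - g); omega x (I omega) vanishes
  # for planar rotation about a principal axis
  ig_y <- iyy * st$alpha_y +
    inertia$mass_kg * (rc[, 3] * acc[, 1] - rc[, 1] * acc[, 3])
  xb <- bar_position(config, st$theta_rad)[, 1]   # anterior moment arm (m)
  (tau + ig_y) / xb
}

#' Generate a synthetic deadlift trial
#'
#' Builds one complete trial for an action template: marker trajectories at
#' the marker rate (mm), a bar-load force series at the force-plate rate
#' (N / mm), the exact rigid-body states of the supra-lumbar trunk segment
#' and the prescribed ("ground truth") lumbar torque curve. The trial is
#' constructed to be exactly consistent with the Newton-Euler joint balance:
#' the bar force magnitude is solved per frame so that inverse dynamics on
#' the noise-free outputs recovers the prescribed torque to machine
#' precision. Marker noise (isotropic Gaussian, `noise_sd_mm`) is added
#' after the kinematic construction and is the only seeded random component.
#'
#' @param template an [action_template()].
#' @param config a [trial_config()].
#' @return an object of class `deadlift_trial` with elements `markers`,
#'   `grf`, `segment_states`, `truth_torque`, `template` and `config`.
#' @export
generate_trial <- function(template, config = trial_config()) {
  stopifnot(inherits(template, "action_template"))
  Tt <- template$trial_duration_s
  n_m <- round(Tt * config$marker_hz) + 1L
  n_f <- round(Tt * config$force_hz) + 1L
  if (abs(Tt * config$marker_hz - (n_m - 1L)) > 1e-9 ||
      abs(Tt * config$force_hz - (n_f - 1L)) > 1e-9) {
    stop("trial duration is not an integer number of sampling intervals",
         call. = FALSE)
  }
  t_m <- seq(0, Tt, length.out = n_m)
  t_f <- seq(0, Tt, length.out = n_f)

  states <- segment_states_at(template, config, t_m)
  th <- states$theta_rad
  u <- trunk_dir(th)
  joint <- cbind(states$joint_x, states$joint_y, states$joint_z)

  markers <- data.frame(frame = seq_len(n_m) - 1L, time_s = t_m)
  for (lab in names(config$trunk_markers)) {
    p <- joint + config$trunk_markers[[lab]] * u
    markers[[paste0(lab, "_X")]] <- p[, 1] * 1000
    markers[[paste0(lab, "_Y")]] <- p[, 2] * 1000
    markers[[paste0(lab, "_Z")]] <- p[, 3] * 1000
  }
  for (lab in names(config$pelvis_markers)) {
    off <- config$pelvis_markers[[lab]]
    markers[[paste0(lab, "_X")]] <- (joint[, 1] + off[1]) * 1000
    markers[[paste0(lab, "_Y")]] <- (joint[, 2] + off[2]) * 1000
    markers[[paste0(lab, "_Z")]] <- (joint[, 3] + off[3]) * 1000
  }
  bar <- bar_position(config, th)
  for (side in c("BAR_L", "BAR_R")) {
    sgn <- if (side == "BAR_L") 1 else -1
    markers[[paste0(side, "_X")]] <- bar[, 1] * 1000
    markers[[paste0(side, "_Y")]] <- (bar[, 2] + sgn * config$bar_half_width_m) * 1000
    markers[[paste0(side, "_Z")]] <- bar[, 3] * 1000
  }

  if (template$noise_sd_mm > 0) {
    coord_cols <- setdiff(names(markers), c("frame", "time_s"))
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(template$seed)
    for (cc in coord_cols) {
      markers[[cc]] <- markers[[cc]] + stats::rnorm(n_m, 0, template$noise_sd_mm)
    }
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }

  fmag <- bar_force_magnitude(template, config, t_f)
  bar_f <- bar_position(config, flexion_template(template, t_f) * pi / 180)
  grf <- data.frame(sample = seq_len(n_f) - 1L, time_s = t_f,
                    Fx = 0, Fy = 0, Fz = -fmag,
                    COPx = bar_f[, 1] * 1000, COPy = bar_f[, 2] * 1000)

  truth <- data.frame(time_s = t_m,
                      torque_Nm = torque_template(template, t_m))

  structure(list(markers = markers, grf = grf,
                 segment_states = states, truth_torque = truth,
                 template = template, config = config),
            class = "deadlift_trial")
}

#' @export
#' @method print deadlift_trial
print.deadlift_trial <- function(x, ...) {
  cat("Synthetic deadlift trial:", x$template$action_id, "\n")
  cat("  frames:", nrow(x$markers), "@", x$config$marker_hz, "Hz;",
      "force samples:", nrow(x$grf), "@", x$config$force_hz, "Hz\n")
  cat("  flexion", x$template$flexion_start_deg, "-",
      x$template$flexion_end_deg, "deg; first peak torque",
      x$template$first_peak_torque_Nm, "N.m; noise SD",
      x$template$noise_sd_mm, "mm\n")
  invisible(x)
}
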