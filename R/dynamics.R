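#' Newton-Euler joint moment of a single rigid segment
#'
#' Rigid-body balance of the supra-lumbar trunk segment, moments taken about
#' the lumbar joint centre:
#' \deqn{\tau = I\alpha + \omega \times (I\omega) + m\, r_c \times (a_c - a_g)
#'       - \sum r \times F_{ext}}
#' where `I` is the centroidal inertia tensor, `r_c` the joint-to-centroid
#' vector, `a_c` the centroid acceleration and `a_g` the gravity vector, so
#' the gravito-inertial term combines gravity and centroid acceleration.
#' The scalar lumbar torque is the sagittal component with extensor moments
#' positive, i.e. minus the Y component of `tau` in the lab frame (X facing,
#' Y left, Z up).
#'
#' @param state list with `omega`, `alpha` (3-vectors, rad/s and rad/s^2),
#'   `r_c` (joint-to-centroid vector, m) and `a_c` (centroid acceleration,
#'   m/s^2).
#' @param inertia list with `mass_kg` and `inertia_kg_m2` (3x3 centroidal
#'   tensor), e.g. from [trunk_inertia()].
#' @param loads list of external loads, each a list with `force` (N) and
#'   `point` (application point relative to the joint centre, m).
#' @param world list with `gravity` (m/s^2), default `c(0, 0, -9.81)`.
#' @return list with `moment_Nm` (3-vector joint moment) and
#'   `sagittal_torque_Nm` (scalar, extensor positive).
#' @export
newton_euler_torque <- function(state, inertia, loads = list(),
                                world = list(gravity = c(0, 0, -9.81))) {
  vals <- c(state$omega, state$alpha, state$r_c, state$a_c,
            unlist(lapply(loads, function(l) c(l$force, l$point))),
            world$gravity)
  if (!all(is.finite(vals))) {
    stop("non-finite value in segment state, load or world configuration",
         call. = FALSE)
  }
  I <- inertia$inertia_kg_m2
  m <- inertia$mass_kg
  tau <- as.numeric(I %*% state$alpha) +
    cross3(state$omega, as.numeric(I %*% state$omega)) +
    m * cross3(state$r_c, state$a_c - world$gravity)
  for (l in loads) tau <- tau - cross3(l$point, l$force)
  list(moment_Nm = tau, sagittal_torque_Nm = -tau[2])
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## Central differences with one-sided ends; x may be a vector or a matrix
## (column-wise differentiation).
central_diff <- function(x, dt) {
  x <- cbind(x)
  n <- nrow(x)
  d <- x
  d[2:(n - 1), ] <- (x[3:n, ] - x[1:(n - 2), ]) / (2 * dt)
  d[1, ] <- (x[2, ] - x[1, ]) / dt
  d[n, ] <- (x[n, ] - x[n - 1, ]) / dt
  if (ncol(d) == 1) as.numeric(d) else d
}

#' Lumbar sagittal torque series by inverse dynamics
#'
#' The full measurement-side pipeline: filters the marker trajectories at
#' the kinematic cutoff (10 Hz) and the force series at the dynamic cutoff
#' (100 Hz), decimates the forces to the marker frames, reconstructs the
#' trunk segment state (orientation from the joint-to-C7 marker line,
#' angular velocity/acceleration and centroid acceleration by second-order
#' central differences), and applies the Newton-Euler balance frame by
#' frame. Segment mass, inertia and centre-of-mass location come from the
#' same anthropometric configuration used by the generator, as in any
#' inverse-dynamics analysis.
#'
#' @param trial a `deadlift_trial` (or a list with `markers` and `grf`
#'   tables plus a `config`).
#' @param kin_cutoff_hz,force_cutoff_hz Butterworth cutoffs (default 10 and
#'   100 Hz, order 4, zero phase).
#' @param config trial/anthropometry configuration; defaults to the trial's
#'   own.
#' @return a data frame of class `torque_series` with `time_s` and
#'   `torque_Nm` (extensor positive).
#' @export
lumbar_torque_series <- function(trial, kin_cutoff_hz = 10,
                                 force_cutoff_hz = 100, config = NULL) {
  if (is.null(config)) config <- trial$config
  if (is.null(trial$grf)) stop("trial has no force series", call. = FALSE)
  markers <- trial$markers
  grf <- trial$grf
  mhz <- config$marker_hz
  fhz <- config$force_hz

  markers <- filter_marker_table(markers, filter_spec(4, kin_cutoff_hz, mhz))
  fspec <- filter_spec(4, force_cutoff_hz, fhz)
  fz <- butterworth_lowpass(grf$Fz, fspec)
  fx <- butterworth_lowpass(grf$Fx, fspec)
  fy <- butterworth_lowpass(grf$Fy, fspec)
  copx <- butterworth_lowpass(grf$COPx, fspec)
  copy <- butterworth_lowpass(grf$COPy, fspec)

  dec <- seq(1L, nrow(grf), by = as.integer(fhz / mhz))
  n <- nrow(markers)
  if (length(dec) != n) {
    stop("force and marker series cover different time spans", call. = FALSE)
  }
  dt <- 1 / mhz

  joint <- marker_xyz(markers, "L5") / 1000
  top <- marker_xyz(markers, "C7") / 1000
  dvec <- top - joint
  theta <- atan2(dvec[, 1], dvec[, 3])
  u <- dvec / sqrt(rowSums(dvec^2))

  inertia <- trunk_inertia(config$anthropometry)
  d <- inertia$com_distance_m
  com <- joint + d * u
  omega <- central_diff(theta, dt)
  alpha <- central_diff(omega, dt)
  vcom <- central_diff(com, dt)
  acom <- central_diff(vcom, dt)

  barz <- (marker_xyz(markers, "BAR_L")[, 3] +
           marker_xyz(markers, "BAR_R")[, 3]) / 2 / 1000
  app <- cbind(copx[dec] / 1000, copy[dec] / 1000, barz)
  frc <- cbind(fx[dec], fy[dec], fz[dec])

  world <- list(gravity = c(0, 0, -config$gravity_m_s2))
  tau <- vapply(seq_len(n), function(i) {
    st <- list(omega = c(0, omega[i], 0), alpha = c(0, alpha[i], 0),
               r_c = com[i, ] - joint[i, ], a_c = acom[i, ])
    ld <- list(list(force = frc[i, ], point = app[i, ] - joint[i, ]))
    newton_euler_torque(st, inertia, ld, world)$sagittal_torque_Nm
  }, numeric(1))

  structure(data.frame(time_s = markers$time_s, torque_Nm = tau),
            class = c("torque_series", "data.frame"))
}

## Strict local maxima of a series with prominence filtering. Prominence of
## a peak is its height above the higher of the two deepest valleys that
## separate it from higher ground (or from the series ends).
find_peaks <- function(x, prominence_frac = 0.05) {
  n <- length(x)
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
  if (length(cand) == 0) return(integer(0))
  rng <- diff(range(x))
  prom <- vapply(cand, function(i) {
    left <- x[1:i]
    higher_l <- which(left > x[i])
    base_l <- min(left[(if (length(higher_l)) max(higher_l) else 1):i])
    right <- x[i:n]
    higher_r <- which(right > x[i])
    base_r <- min(right[1:(if (length(higher_r)) min(higher_r) else n - i + 1)])
    x[i] - max(base_l, base_r)
  }, numeric(1))
  cand[prom >= prominence_frac * rng]
}

#' Four-phase segmentation of a lift from its torque curve
#'
#' The lift is divided into four phases delimited by the two torque peaks
#' and the intervening trough: first hard pull (start to first peak),
#' transition (first peak to trough), second hard pull (trough to second
#' peak) and standing (second peak to the end). Peaks are strict local
#' maxima with prominence at least 5% of the series range; if more than two
#' qualify, the two largest are used (earliest first on ties).
#'
#' @param torque a `torque_series` (or numeric vector).
#' @param prominence_frac minimum peak prominence as a fraction of the
#'   series range.
#' @return an object of class `phase_segmentation`: a data frame with
#'   `phase`, `start_frame`, `end_frame`, `peak_torque_Nm`, plus attributes
#'   `peaks` (frame indices of the two peaks) and `trough`.
#' @export
segment_phases <- function(torque, prominence_frac = 0.05) {
  x <- if (is.data.frame(torque)) torque$torque_Nm else as.numeric(torque)
  n <- length(x)
  pk <- find_peaks(x, prominence_frac)
  if (length(pk) < 2) {
    stop("phase segmentation needs two interior torque peaks; detected ",
         length(pk), call. = FALSE)
  }
  if (length(pk) > 2) {
    ord <- order(-x[pk], pk)
    pk <- sort(pk[ord[1:2]])
  }
  trough <- pk[1] - 1L + which.min(x[pk[1]:pk[2]])
  seg <- data.frame(
    phase = c("first_pull", "transition", "second_pull", "standing"),
    start_frame = c(1L, pk[1], trough, pk[2]),
    end_frame = c(pk[1], trough, pk[2], n),
    peak_torque_Nm = c(x[pk[1]], x[pk[1]], x[pk[2]], x[pk[2]])
  )
  structure(seg, class = c("phase_segmentation", "data.frame"),
            peaks = pk, trough = trough)
}

#' First-peak torque of a series
#'
#' Convenience accessor: the torque at the first of the two detected peaks.
#' @param torque a `torque_series`.
#' @export
first_peak_torque <- function(torque) {
  x <- if (is.data.frame(torque)) torque$torque_Nm else as.numeric(torque)
  seg <- segment_phases(torque)
  x[attr(seg, "peaks")[1]]
}
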