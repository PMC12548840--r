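## Extract the (x, y, z) columns (mm) of one marker label from a wide table.
marker_xyz <- function(markers, label) {
  cols <- paste0(label, c("_X", "_Y", "_Z"))
  if (!all(cols %in% names(markers))) {
    stop("marker label '", label, "' not present in the marker table",
         call. = FALSE)
  }
  as.matrix(markers[, cols])
}

#' Sagittal flexion angle of a trunk line
#'
#' Angle in the sagittal (X-Z) plane between the line from a lower to an
#' upper marker and the vertical axis: 0 deg for an upright trunk, 90 deg
#' for a horizontal trunk. The coronal (Y) component is ignored.
#'
#' @param p_lower,p_upper 3-vectors or n x 3 matrices of marker positions
#'   (any consistent length unit).
#' @return angle(s) in degrees, in `[0, 180]`.
#' @export
lumbar_flexion_angle <- function(p_lower, p_upper) {
  pl <- rbind(p_lower); pu <- rbind(p_upper)
  dx <- pu[, 1] - pl[, 1]
  dz <- pu[, 3] - pl[, 3]
  r <- sqrt(dx^2 + dz^2)
  if (any(r < .Machine$double.eps^0.5)) {
    stop("degenerate trunk line: upper and lower markers coincide in the ",
         "sagittal plane", call. = FALSE)
  }
  acos(pmin(1, pmax(-1, dz / r))) * 180 / pi
}

#' Lumbar flexion angle series from a marker table
#'
#' Low-pass filters the marker trajectories (zero-phase Butterworth, 10 Hz
#' by default) and computes the per-frame sagittal flexion angle of the
#' trunk line. The default convention uses the L5 -> L1 marker line; any
#' other pair (e.g. L5 -> T2) can be substituted.
#'
#' @param markers wide marker table as produced by [generate_trial()] /
#'   [read_marker_table()].
#' @param lower,upper marker labels defining the trunk line.
#' @param spec kinematic [filter_spec()]; `NULL` skips filtering.
#' @param sampling_hz sampling rate used to build the default filter spec
#'   when `spec` is missing.
#' @return a data frame of class `angle_series` with `time_s` and
#'   `flexion_deg`.
#' @export
lumbar_flexion_series <- function(markers, lower = "L5", upper = "L1",
                                  spec = NULL, sampling_hz = 100) {
  if (is.null(spec)) spec <- filter_spec(4, 10, sampling_hz)
  if (!is.null(spec)) markers <- filter_marker_table(markers, spec)
  ang <- lumbar_flexion_angle(marker_xyz(markers, lower),
                              marker_xyz(markers, upper))
  structure(data.frame(time_s = markers$time_s, flexion_deg = ang),
            class = c("angle_series", "data.frame"))
}

#' Range of motion of an angle series
#'
#' @param angles an `angle_series` (or any data frame with a `flexion_deg`
#'   column, or a bare numeric vector).
#' @return max minus min, degrees.
#' @export
range_of_motion <- function(angles) {
  x <- if (is.data.frame(angles)) angles$flexion_deg else as.numeric(angles)
  if (length(x) == 0) stop("empty angle series", call. = FALSE)
  max(x) - min(x)
}
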