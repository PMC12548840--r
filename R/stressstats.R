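#' Injury-threshold configuration
#'
#' Classification boundaries for the standardized regional contrast
#' (`beta = 0.8`, `gamma = 1.27`) and the damage/tolerance thresholds used
#' by the risk assessment: 1000 MPa for cortical bone damage, 3.0 MPa for
#' trabecular (cancellous) bone fatigue, 40 MPa for the physiological
#' tolerance of the intervertebral disc.
#'
#' @param beta,gamma quantitative-difference class boundaries.
#' @param cortical_damage_MPa,trabecular_fatigue_MPa,disc_tolerance_MPa
#'   damage thresholds by part class.
#' @export
threshold_config <- function(beta = 0.8, gamma = 1.27,
                             cortical_damage_MPa = 1000,
                             trabecular_fatigue_MPa = 3.0,
                             disc_tolerance_MPa = 40) {
  if (!(beta > 0 && beta < gamma)) {
    stop("need 0 < beta < gamma", call. = FALSE)
  }
  if (any(c(cortical_damage_MPa, trabecular_fatigue_MPa,
            disc_tolerance_MPa) <= 0)) {
    stop("damage thresholds must be positive", call. = FALSE)
  }
  structure(list(beta = beta, gamma = gamma,
                 cortical_damage_MPa = cortical_damage_MPa,
                 trabecular_fatigue_MPa = trabecular_fatigue_MPa,
                 disc_tolerance_MPa = disc_tolerance_MPa),
            class = "threshold_config")
}

#' Partition a disc's elements into the 3 x 3 regional grid
#'
#' Tiles the disc's element centroids by empirical terciles of the two
#' transverse coordinates into nine regions labeled row-major A..I:
#' A, B, C across the anterior row (anterior = "upper"), D, E, F across the
#' middle row (E is the central region containing the nucleus centroid),
#' G, H, I across the posterior row. Within a row, the first column is the
#' left side (positive Y in the lab frame).
#'
#' @param field an `fe_solution` or element stress table.
#' @param disc disc identifier, e.g. `"L4-L5"`.
#' @return an object of class `regional_grid`: data frame with `element`,
#'   `region`, `von_mises` and centroid columns.
#' @export
partition_disc <- function(field, disc) {
  stress <- if (inherits(field, "fe_solution")) field$stress else field
  sel <- disc_elements(stress, disc)
  if (!any(sel)) stop("no disc elements found for '", disc, "'",
                      call. = FALSE)
  d <- stress[sel, , drop = FALSE]
  tercile <- function(v) {
    r <- rank(v, ties.method = "first")
    as.integer(ceiling(3 * r / length(r)))
  }
  row_idx <- 4L - tercile(d$cx)   # row 1 = anterior (largest x)
  col_idx <- 4L - tercile(d$cy)   # col 1 = left (largest y)
  region <- LETTERS[3L * (row_idx - 1L) + col_idx]
  nuc <- d$class == "nucleus"
  out <- data.frame(element = d$element, region = region,
                    von_mises = d$von_mises,
                    cx = d$cx, cy = d$cy, cz = d$cz,
                    class = d$class)
  structure(out, class = c("regional_grid", "data.frame"),
            disc = disc,
            nucleus_centroid = if (any(nuc))
              c(mean(d$cx[nuc]), mean(d$cy[nuc])) else NULL)
}

#' Regional von Mises statistics with standardized contrasts
#'
#' Per-region mean, standard deviation and coefficient of variation
#' (SD/mean) of the element von Mises stresses, plus the quantitative
#' difference of each region versus the reference (central) region: the
#' pooled-SD standardized mean difference
#' `QD = |mean_r - mean_ref| / SD_pooled`. Classes: `QD <= beta` not
#' significant, `beta < QD < gamma` significant, `QD >= gamma` very
#' significant.
#'
#' @param grid a `regional_grid` from [partition_disc()].
#' @param reference reference region label (default `"E"`).
#' @param thresholds a [threshold_config()].
#' @return data frame with `region`, `n`, `mean_MPa`, `sd_MPa`, `cv`,
#'   `quantitative_difference`, `significance`.
#' @export
region_stats <- function(grid, reference = "E",
                         thresholds = threshold_config()) {
  stopifnot(inherits(grid, "regional_grid"))
  regs <- sort(unique(grid$region))
  if (!(reference %in% regs)) stop("reference region '", reference,
                                   "' is empty", call. = FALSE)
  by_reg <- split(grid$von_mises, grid$region)
  ref <- by_reg[[reference]]
  stats_one <- function(lab) {
    x <- by_reg[[lab]]
    m <- mean(x); s <- stats::sd(x)
    if (length(x) == 1) s <- 0
    cv <- if (m > 0) s / m else if (s == 0) 0 else NA_real_
    qd <- pooled_qd(x, ref)
    cls <- if (!is.finite(qd)) "very significant"
           else if (qd <= thresholds$beta) "not significant"
           else if (qd < thresholds$gamma) "significant"
           else "very significant"
    data.frame(region = lab, n = length(x), mean_MPa = m, sd_MPa = s,
               cv = cv, quantitative_difference = qd, significance = cls)
  }
  out <- do.call(rbind, lapply(regs, stats_one))
  rownames(out) <- NULL
  out
}

## Pooled-SD standardized mean difference between two element samples;
## symmetric in its arguments, zero iff the means are equal.
pooled_qd <- function(x, y) {
  dm <- abs(mean(x) - mean(y))
  n1 <- length(x); n2 <- length(y)
  if (n1 + n2 <= 2) return(if (dm == 0) 0 else Inf)
  sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
             (n1 + n2 - 2))
  if (sp == 0) {
    if (dm == 0) 0 else Inf
  } else {
    dm / sp
  }
}

#' Injury-threshold risk assessment
#'
#' For each monitored part, the exceedance of its peak von Mises stress
#' over the class damage threshold:
#' `exceedance_pct = (peak - threshold) / threshold * 100`, with a strict
#' exceedance flag (a peak exactly at the threshold is not an exceedance).
#'
#' @param peaks data frame with columns `part`, `class` (one of
#'   `"cortical"`, `"cancellous"`, `"disc"`) and `peak_MPa`; or a named
#'   numeric vector with `class` supplied separately.
#' @param thresholds a [threshold_config()].
#' @param class part classes when `peaks` is a named vector.
#' @return data frame with `part`, `class`, `peak_MPa`, `threshold_MPa`,
#'   `exceedance_pct`, `exceeded`.
#' @export
risk_assessment <- function(peaks, thresholds = threshold_config(),
                            class = NULL) {
  if (!is.data.frame(peaks)) {
    peaks <- data.frame(part = names(peaks), class = class,
                        peak_MPa = as.numeric(peaks))
  }
  if (any(peaks$peak_MPa < 0)) stop("peak stresses must be non-negative",
                                    call. = FALSE)
  thr_map <- c(cortical = thresholds$cortical_damage_MPa,
               cancellous = thresholds$trabecular_fatigue_MPa,
               trabecular = thresholds$trabecular_fatigue_MPa,
               disc = thresholds$disc_tolerance_MPa)
  unknown <- setdiff(peaks$class, names(thr_map))
  if (length(unknown)) {
    stop("unknown part class for risk thresholds: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  thr <- thr_map[peaks$class]
  data.frame(part = peaks$part, class = peaks$class,
             peak_MPa = peaks$peak_MPa, threshold_MPa = as.numeric(thr),
             exceedance_pct = (peaks$peak_MPa - thr) / thr * 100,
             exceeded = peaks$peak_MPa > thr)
}

#' Packaged literature reference values for model validation
#'
#' Benchmark indicators from published lumbar-spine finite-element studies
#' (mean and dispersion), together with the reported reference-model values
#' they were originally compared against.
#'
#' @return data frame with `indicator`, `reference_value`, `lit_mean`,
#'   `lit_sd`, `source`.
#' @export
literature_reference <- function() {
  path <- system.file("extdata", "literature_validation.csv",
                      package = "lumbarlift")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Validation against literature values
#'
#' Relative error of simulated indicator values against literature means,
#' reported to one decimal (percent), with a flag for whether the simulated
#' value falls within the literature mean +/- SD.
#'
#' @param simulated named numeric vector (names = indicators).
#' @param literature data frame with `indicator`, `lit_mean`, `lit_sd`
#'   (default the packaged [literature_reference()] table).
#' @return data frame with `indicator`, `simulated`, `lit_mean`, `lit_sd`,
#'   `relative_error_pct`, `within_range`.
#' @export
validation_report <- function(simulated, literature = literature_reference()) {
  idx <- match(names(simulated), literature$indicator)
  if (any(is.na(idx))) {
    stop("indicator(s) not in the literature table: ",
         paste(names(simulated)[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  lm_ <- literature$lit_mean[idx]
  ls_ <- literature$lit_sd[idx]
  if (any(lm_ == 0)) stop("literature mean of zero: relative error undefined",
                          call. = FALSE)
  sim <- as.numeric(simulated)
  data.frame(indicator = names(simulated), simulated = sim,
             lit_mean = lm_, lit_sd = ls_,
             relative_error_pct = round(abs(sim - lm_) / lm_ * 100, 1),
             within_range = sim >= lm_ - ls_ & sim <= lm_ + ls_)
}

#' Default sensitivity protocol
#'
#' Cortical modulus +/-10%, nucleus modulus +/-20%, vertical load +/-5%,
#' sagittal peak moment +/-5%.
#' @export
default_sensitivity_cases <- function() {
  data.frame(parameter = c("cortical_modulus", "nucleus_modulus",
                           "vertical_load", "peak_moment"),
             amplitude_pct = c(10, 20, 5, 5))
}

#' Material- and load-parameter sensitivity analysis
#'
#' Re-solves the model at both ends of each parameter fluctuation and
#' reports the change rate of the monitored response (by default the L5
#' cortical peak von Mises stress) relative to the base solution:
#' `(perturbed - base) / base * 100`. Sensitivity levels follow the
#' magnitude of the largest change: high >= 5%, medium 3-5%, low < 3%.
#'
#' @param mesh a material-bound `lumbar_mesh`.
#' @param base_case the unperturbed `load_case`.
#' @param cases data frame with `parameter` and `amplitude_pct`; see
#'   [default_sensitivity_cases()].
#' @param response_part part whose peak stress is monitored.
#' @return data frame with `parameter`, `amplitude_pct`,
#'   `change_low_pct`, `change_high_pct`, `max_abs_change_pct`, `level`.
#' @export
sensitivity_analysis <- function(mesh, base_case,
                                 cases = default_sensitivity_cases(),
                                 response_part = "L5 cortical") {
  solve_peak <- function(msh, lc) {
    sol <- solve_static(assemble_system(msh), lc)
    peak_stress_by_part(sol, response_part)
  }
  base_peak <- solve_peak(mesh, base_case)

  perturb <- function(parameter, scale) {
    msh <- mesh; lc <- base_case
    if (parameter == "cortical_modulus") {
      sel <- msh$tet_class == "cortical"
      msh$tet_E[sel] <- msh$tet_E[sel] * scale
      if (any(msh$tet_E <= 0)) stop("parameter error: non-positive modulus",
                                    call. = FALSE)
    } else if (parameter == "nucleus_modulus") {
      sel <- msh$tet_class == "nucleus"
      msh$tet_E[sel] <- msh$tet_E[sel] * scale
      if (any(msh$tet_E <= 0)) stop("parameter error: non-positive modulus",
                                    call. = FALSE)
    } else if (parameter == "vertical_load") {
      lc <- build_load_case(msh, lc$action_id, lc$sagittal_moment_Nm,
                            vertical_load_N = lc$vertical_load_N * scale)
    } else if (parameter == "peak_moment") {
      lc <- build_load_case(msh, lc$action_id,
                            lc$sagittal_moment_Nm * scale,
                            vertical_load_N = lc$vertical_load_N)
    } else {
      stop("unknown sensitivity parameter '", parameter, "'", call. = FALSE)
    }
    solve_peak(msh, lc)
  }

  res <- lapply(seq_len(nrow(cases)), function(k) {
    par <- cases$parameter[k]
    amp <- cases$amplitude_pct[k] / 100
    if (amp <= 0) stop("fluctuation amplitude must be positive",
                       call. = FALSE)
    lo <- (perturb(par, 1 - amp) - base_peak) / base_peak * 100
    hi <- (perturb(par, 1 + amp) - base_peak) / base_peak * 100
    mx <- max(abs(c(lo, hi)))
    data.frame(parameter = par, amplitude_pct = cases$amplitude_pct[k],
               change_low_pct = lo, change_high_pct = hi,
               max_abs_change_pct = mx,
               level = if (mx >= 5) "high" else if (mx >= 3) "medium"
                       else "low")
  })
  out <- do.call(rbind, res)
  attr(out, "base_peak_MPa") <- base_peak
  out
}
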