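#' Pipeline configuration
#'
#' Loads the packaged default configuration (actions, filter cutoffs,
#' anthropometrics, geometry, load constants, thresholds) and applies
#' overrides. All physical constants of the default analysis live in the
#' packaged `default_config.yaml`, not in code paths.
#'
#' @param ... named overrides of top-level config entries (lists are merged
#'   one level deep).
#' @param config_file alternative YAML configuration file.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(..., config_file = NULL) {
  if (is.null(config_file)) {
    config_file <- system.file("extdata", "default_config.yaml",
                               package = "lumbarlift")
  }
  cfg <- yaml::read_yaml(config_file)
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  validate_pipeline_config(cfg)
  structure(cfg, class = c("pipeline_config", "list"))
}

validate_pipeline_config <- function(cfg) {
  need <- c("actions", "filters", "anthropometry", "geometry", "loads",
            "thresholds", "seed")
  missing_keys <- setdiff(need, names(cfg))
  if (length(missing_keys)) {
    stop("invalid pipeline configuration: missing ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  if (!all(cfg$actions %in% c("DL", "SLDL", "TBDL"))) {
    stop("invalid pipeline configuration: unknown action id", call. = FALSE)
  }
  invisible(cfg)
}

pipeline_trial_config <- function(cfg) {
  a <- cfg$anthropometry
  trial_config(anthropometry = list(
    frustum_a1_m = a$frustum_a1_m, frustum_b1_m = a$frustum_b1_m,
    frustum_a2_m = a$frustum_a2_m, frustum_b2_m = a$frustum_b2_m,
    frustum_h_m = a$frustum_h_m, density_kg_m3 = a$density_kg_m3,
    trunk_length_m = a$trunk_length_m, com_fraction = a$com_fraction))
}

pipeline_geometry <- function(cfg) {
  g <- cfg$geometry
  lumbar_geometry_params(
    vertebra_width_mm = g$vertebra_width_mm,
    vertebra_depth_mm = g$vertebra_depth_mm,
    vertebra_height_mm = g$vertebra_height_mm,
    cortical_offset_mm = g$cortical_offset_mm,
    disc_height_mm = g$disc_height_mm,
    endplate_thickness_mm = g$endplate_thickness_mm,
    nucleus_radius_frac = g$nucleus_radius_frac,
    annulus_layer_fracs = as.numeric(g$annulus_layer_fracs),
    target_edge_mm = g$target_edge_mm,
    ligament_area_mm2 = g$ligament_area_mm2)
}

#' Run the full analysis pipeline (or a subset of stages)
#'
#' Orchestrates, per configured action: trial simulation, flexion
#' kinematics, inverse-dynamics torque and phase segmentation, the
#' finite-element solves, regional disc statistics, threshold risk
#' assessment, literature validation arithmetic and the parameter
#' sensitivity protocol. Every stage writes its artifacts under `out_dir`
#' and later stages re-read them, so stages can be run incrementally. The
#' run is fully deterministic for a given configuration and seed, and ends
#' by writing `summary.json` plus a manifest with the configuration hash.
#'
#' @param config a [pipeline_config()].
#' @param stages character vector among `simulate`, `kinematics`,
#'   `dynamics`, `fem`, `stats`, `risk`, `validate`, `sensitivity`, or
#'   `"all"`.
#' @param out_dir output directory (created if needed).
#' @return the summary list, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), stages = "all",
                         out_dir) {
  all_stages <- c("simulate", "kinematics", "dynamics", "fem", "stats",
                  "risk", "validate", "sensitivity")
  if (identical(stages, "all")) stages <- all_stages
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tcfg <- pipeline_trial_config(config)
  summary_path <- file.path(out_dir, "summary.json")
  summ <- if (file.exists(summary_path)) {
    jsonlite::read_json(summary_path, simplifyVector = TRUE)
  } else {
    list()
  }
  need_artifact <- function(path, stage) {
    if (!file.exists(path)) {
      stop("dependency error: stage '", stage, "' needs missing artifact ",
           basename(path), "; run the upstream stage first", call. = FALSE)
    }
    path
  }

  if ("simulate" %in% stages) {
    for (act in config$actions) {
      trial <- generate_trial(
        default_action_template(act,
                                noise_sd_mm = config$noise_sd_mm,
                                seed = config$seed),
        tcfg)
      write_marker_table(trial$markers,
                         file.path(out_dir, paste0("markers_", act, ".tsv")))
      write_force_table(trial$grf,
                        file.path(out_dir, paste0("forces_", act, ".tsv")))
      write_series(trial$truth_torque,
                   file.path(out_dir, paste0("truth_torque_", act, ".tsv")))
    }
  }

  if ("kinematics" %in% stages) {
    rom <- list()
    for (act in config$actions) {
      mk <- read_marker_table(need_artifact(
        file.path(out_dir, paste0("markers_", act, ".tsv")), "kinematics"))
      ang <- lumbar_flexion_series(
        mk, lower = config$filters$flexion_lower,
        upper = config$filters$flexion_upper,
        spec = filter_spec(config$filters$order,
                           config$filters$kinematic_cutoff_hz,
                           tcfg$marker_hz))
      write_series(ang, file.path(out_dir, paste0("flexion_", act, ".tsv")))
      rom[[act]] <- range_of_motion(ang)
    }
    summ$flexion_rom_deg <- rom
  }

  if ("dynamics" %in% stages) {
    peaks1 <- list(); peaks2 <- list(); phases <- list()
    for (act in config$actions) {
      mk <- read_marker_table(need_artifact(
        file.path(out_dir, paste0("markers_", act, ".tsv")), "dynamics"))
      fr <- read_force_table(need_artifact(
        file.path(out_dir, paste0("forces_", act, ".tsv")), "dynamics"))
      trial <- list(markers = mk, grf = fr, config = tcfg)
      tq <- lumbar_torque_series(
        trial, kin_cutoff_hz = config$filters$kinematic_cutoff_hz,
        force_cutoff_hz = config$filters$force_cutoff_hz, config = tcfg)
      write_series(tq, file.path(out_dir, paste0("torque_", act, ".tsv")))
      seg <- segment_phases(tq)
      write_phase_report(seg, file.path(out_dir,
                                        paste0("phases_", act, ".json")))
      pk <- attr(seg, "peaks")
      peaks1[[act]] <- tq$torque_Nm[pk[1]]
      peaks2[[act]] <- tq$torque_Nm[pk[2]]
      phases[[act]] <- nrow(seg)
    }
    summ$first_peak_torque_Nm <- peaks1
    summ$second_peak_torque_Nm <- peaks2
    summ$n_phases <- phases
  }

  if ("fem" %in% stages) {
    params <- pipeline_geometry(config)
    mesh <- assign_materials(mesh_geometry(build_geometry(params)))
    write_census_json(mesh, file.path(out_dir, "mesh_census.json"))
    sys <- assemble_system(mesh)
    peaks <- list()
    for (act in config$actions) {
      tq <- read_series(need_artifact(
        file.path(out_dir, paste0("torque_", act, ".tsv")), "fem"))
      lc <- build_load_case(mesh, act,
                            first_peak_torque(tq),
                            vertical_load_N = config$loads$vertical_load_N)
      sol <- solve_static(sys, lc)
      utils::write.csv(sol$stress,
                       file.path(out_dir, paste0("stress_", act, ".csv")),
                       row.names = FALSE)
      peaks[[act]] <- list(
        L5_cortical = peak_stress_by_part(sol, "L5 cortical"),
        L5_cancellous = peak_stress_by_part(sol, "L5 cancellous"),
        L45_disc = peak_stress_by_part(sol, "L4-L5"))
    }
    summ$fe_peak_MPa <- peaks
  }

  if ("stats" %in% stages) {
    regions <- list()
    for (act in config$actions) {
      st <- utils::read.csv(need_artifact(
        file.path(out_dir, paste0("stress_", act, ".csv")), "stats"))
      grid <- partition_disc(st, config$stats$disc)
      rs <- region_stats(grid, thresholds = pipeline_thresholds(config))
      utils::write.csv(rs, file.path(out_dir,
                                     paste0("regions_", act, ".csv")),
                       row.names = FALSE)
      regions[[act]] <- stats::setNames(rs$mean_MPa, rs$region)
    }
    summ$region_mean_MPa <- regions
  }

  if ("risk" %in% stages) {
    if (is.null(summ$fe_peak_MPa)) {
      stop("dependency error: stage 'risk' needs the fem stage summary",
           call. = FALSE)
    }
    risks <- list()
    for (act in names(summ$fe_peak_MPa)) {
      pk <- summ$fe_peak_MPa[[act]]
      rr <- risk_assessment(
        data.frame(part = c("L5 cortical", "L5 cancellous", "L4-L5 disc"),
                   class = c("cortical", "cancellous", "disc"),
                   peak_MPa = as.numeric(unlist(pk))),
        pipeline_thresholds(config))
      risks[[act]] <- rr
    }
    jsonlite::write_json(risks, file.path(out_dir, "risk.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    summ$risk_exceeded <- lapply(risks, function(r)
      stats::setNames(as.list(r$exceeded), r$part))
  }

  if ("validate" %in% stages) {
    lit <- literature_reference()
    vr <- validation_report(
      stats::setNames(lit$reference_value, lit$indicator), lit)
    utils::write.csv(vr, file.path(out_dir, "validation.csv"),
                     row.names = FALSE)
    summ$validation_relative_error_pct <-
      stats::setNames(as.list(vr$relative_error_pct), vr$indicator)
  }

  if ("sensitivity" %in% stages) {
    params <- pipeline_geometry(config)
    mesh <- assign_materials(mesh_geometry(build_geometry(params)))
    lc <- build_load_case(mesh, "DL", config$loads$reference_moment_Nm,
                          vertical_load_N = config$loads$vertical_load_N)
    sens <- sensitivity_analysis(mesh, lc)
    jsonlite::write_json(sens, file.path(out_dir, "sensitivity.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    summ$sensitivity_level <-
      stats::setNames(as.list(sens$level), sens$parameter)
  }

  cfg_path <- file.path(out_dir, "config_used.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest <- list(
    package = "lumbarlift",
    version = as.character(utils::packageVersion("lumbarlift")),
    config_hash = unname(tools::md5sum(cfg_path)),
    stages = stages,
    seed = config$seed)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(summ, summary_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(summ)
}

pipeline_thresholds <- function(config) {
  th <- config$thresholds
  threshold_config(beta = th$beta, gamma = th$gamma,
                   cortical_damage_MPa = th$cortical_damage_MPa,
                   trabecular_fatigue_MPa = th$trabecular_fatigue_MPa,
                   disc_tolerance_MPa = th$disc_tolerance_MPa)
}
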