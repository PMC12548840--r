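#' Parametric L1-L5 geometry parameters
#'
#' The subject-specific CT geometry is replaced by an idealised parametric
#' stack: five elliptical-prism vertebral bodies (cortical shell of fixed
#' normal thickness around a cancellous core), four intervertebral discs
#' (central nucleus pulposus surrounded by three concentric annulus
#' fibrosus layers), a thin cartilaginous endplate above and below each
#' disc, and six posterior/anterior ligament line groups. Posterior
#' elements (pedicles, processes) are omitted.
#'
#' @param vertebra_width_mm full coronal width of the vertebral body
#'   (Y axis).
#' @param vertebra_depth_mm full sagittal depth (X axis).
#' @param vertebra_height_mm height of each vertebral body.
#' @param cortical_offset_mm normal thickness of the cortical shell
#'   (default 1 mm inward offset).
#' @param disc_height_mm height of each intervertebral disc.
#' @param endplate_thickness_mm thickness of each cartilaginous endplate
#'   (default 0.5 mm).
#' @param nucleus_radius_frac nucleus boundary as a fraction of the
#'   cross-section radius.
#' @param annulus_layer_fracs radial fractions of the three annulus layers
#'   (innermost to outermost); must sum to `1 - nucleus_radius_frac`.
#' @param target_edge_mm target tetrahedron edge length (default 2 mm).
#' @param ligament_area_mm2 truss cross-section of each ligament line.
#' @export
lumbar_geometry_params <- function(vertebra_width_mm = 44,
                                   vertebra_depth_mm = 34,
                                   vertebra_height_mm = 27,
                                   cortical_offset_mm = 1,
                                   disc_height_mm = 10,
                                   endplate_thickness_mm = 0.5,
                                   nucleus_radius_frac = 0.4,
                                   annulus_layer_fracs = c(0.2, 0.2, 0.2),
                                   target_edge_mm = 2,
                                   ligament_area_mm2 = 30) {
  dims <- c(vertebra_width_mm, vertebra_depth_mm, vertebra_height_mm,
            cortical_offset_mm, disc_height_mm, endplate_thickness_mm,
            nucleus_radius_frac, target_edge_mm, ligament_area_mm2)
  if (any(dims <= 0)) stop("all geometry dimensions must be positive",
                           call. = FALSE)
  if (length(annulus_layer_fracs) != 3 || any(annulus_layer_fracs <= 0)) {
    stop("annulus_layer_fracs must be three positive fractions",
         call. = FALSE)
  }
  if (abs(sum(annulus_layer_fracs) + nucleus_radius_frac - 1) > 1e-9) {
    stop("annulus layer fractions must sum to the annulus band ",
         "(1 - nucleus_radius_frac)", call. = FALSE)
  }
  if (nucleus_radius_frac >= 1) stop("nucleus must be strictly interior",
                                     call. = FALSE)
  structure(list(vertebra_width_mm = vertebra_width_mm,
                 vertebra_depth_mm = vertebra_depth_mm,
                 vertebra_height_mm = vertebra_height_mm,
                 cortical_offset_mm = cortical_offset_mm,
                 disc_height_mm = disc_height_mm,
                 endplate_thickness_mm = endplate_thickness_mm,
                 nucleus_radius_frac = nucleus_radius_frac,
                 annulus_layer_fracs = annulus_layer_fracs,
                 target_edge_mm = target_edge_mm,
                 ligament_area_mm2 = ligament_area_mm2),
            class = "lumbar_geometry_params")
}

#' Build the labeled L1-L5 solid description
#'
#' Assembles the stacking plan (slab type, part names, z extents, bottom to
#' top: L5 first, L1 last) and the cross-section specification (semi-axes,
#' cortical offset, radial part boundaries) from the geometry parameters.
#' The result is a light-weight solid description consumed by
#' [mesh_geometry()].
#'
#' @param params a [lumbar_geometry_params()].
#' @return an object of class `lumbar_solids`.
#' @export
build_geometry <- function(params) {
  stopifnot(inherits(params, "lumbar_geometry_params"))
  a <- params$vertebra_depth_mm / 2    # sagittal semi-axis (X)
  b <- params$vertebra_width_mm / 2    # coronal semi-axis (Y)
  if (params$cortical_offset_mm >= min(a, b)) {
    stop("geometrically impossible parameters: cortical offset (",
         params$cortical_offset_mm, " mm) must be smaller than the ",
         "smallest cross-section semi-axis (", min(a, b), " mm)",
         call. = FALSE)
  }
  vertebrae <- c("L5", "L4", "L3", "L2", "L1")
  discs <- c("L4-L5", "L3-L4", "L2-L3", "L1-L2")
  slabs <- list()
  z <- 0
  add <- function(type, name, h) {
    slabs[[length(slabs) + 1]] <<- list(type = type, name = name,
                                        z0 = z, z1 = z + h)
    z <<- z + h
  }
  for (i in seq_along(vertebrae)) {
    add("vertebra", vertebrae[i], params$vertebra_height_mm)
    if (i < length(vertebrae)) {
      add("endplate", paste(discs[i], "inferior endplate"),
          params$endplate_thickness_mm)
      add("disc", discs[i], params$disc_height_mm)
      add("endplate", paste(discs[i], "superior endplate"),
          params$endplate_thickness_mm)
    }
  }
  structure(list(params = params, a = a, b = b,
                 slabs = slabs, total_height_mm = z,
                 vertebrae = vertebrae, discs = discs),
            class = "lumbar_solids")
}

#' @export
#' @method print lumbar_solids
print.lumbar_solids <- function(x, ...) {
  cat("Parametric lumbar solids: L1-L5,", length(x$slabs), "slabs,",
      "height", format(x$total_height_mm), "mm, cross-section",
      2 * x$a, "x", 2 * x$b, "mm\n")
  invisible(x)
}

#' Block control solid for benchmarks
#'
#' A rectangular homogeneous block used by the solver verification
#' benchmarks (patch test, composite column, convergence studies).
#'
#' @param lx,ly,lz block dimensions (mm).
#' @export
block_solid <- function(lx = 1, ly = 1, lz = 1) {
  if (any(c(lx, ly, lz) <= 0)) stop("block dimensions must be positive",
                                    call. = FALSE)
  structure(list(lx = lx, ly = ly, lz = lz), class = "block_solid")
}
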