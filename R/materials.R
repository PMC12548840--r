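#' Material property table of the lumbar model
#'
#' The thirteen materials of the model: cortical and cancellous bone, the
#' three annulus fibrosus layers, the cartilaginous endplate, six ligaments
#' and the nucleus pulposus, each with elastic modulus (MPa) and Poisson
#' ratio. All materials are solved as isotropic linear elastic; the
#' `constitutive_tag` column records the nominal constitutive family. The
#' nucleus is tabulated incompressible (nu = 0.5) and is clamped to 0.4999
#' at assignment (near-incompressibility).
#'
#' @return data frame with `name`, `elastic_modulus_MPa`, `poisson_ratio`,
#'   `constitutive_tag`.
#' @export
material_table <- function() {
  path <- system.file("extdata", "materials.csv", package = "lumbarlift")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

## Part class -> material-table row name.
material_class_map <- function() {
  c(cortical = "Cortical bone",
    cancellous = "Cancellous bone",
    nucleus = "Nucleus pulposus",
    annulus_outer = "Outer layer of fibrous ring",
    annulus_middle = "Fiber ring second layer",
    annulus_inner = "Fiber ring third layer",
    endplate = "Cartilaginous endplate",
    lig_anterior = "Anterior longitudinal",
    lig_posterior = "Posterior longitudinal ligament",
    lig_flavum = "Ligamentum flavum",
    lig_interspinous = "Interspinous ligament",
    lig_supraspinous = "Supraspinal ligament",
    lig_intertransverse = "Intertransvers ligament")
}

#' Bind material properties to a labeled mesh
#'
#' Resolves each element's part class (or, for custom benchmark meshes, the
#' part name itself) against the material table and attaches per-element
#' elastic modulus and Poisson ratio. Poisson ratios >= 0.5 are clamped to
#' 0.4999.
#'
#' @param mesh a `lumbar_mesh`.
#' @param table a material table; defaults to [material_table()].
#' @return the mesh with `tet_E`, `tet_nu`, `line_E`, `line_nu` and a
#'   `materials` lookup attached.
#' @export
assign_materials <- function(mesh, table = material_table()) {
  stopifnot(inherits(mesh, "lumbar_mesh"))
  cmap <- material_class_map()
  resolve <- function(part, class) {
    nm <- if (part %in% table$name) part
          else if (class %in% table$name) class
          else if (class %in% names(cmap)) cmap[[class]]
          else NA_character_
    if (is.na(nm) || !(nm %in% table$name)) {
      stop("material binding error: no table row for part '", part,
           "' (class '", class, "')", call. = FALSE)
    }
    nm
  }
  key <- paste(mesh$tet_part, mesh$tet_class, sep = "\r")
  uk <- which(!duplicated(key))
  umat <- mapply(resolve, mesh$tet_part[uk], mesh$tet_class[uk])
  tet_mat <- umat[match(key, key[uk])]
  row_of <- match(tet_mat, table$name)
  mesh$tet_E <- table$elastic_modulus_MPa[row_of]
  mesh$tet_nu <- pmin(table$poisson_ratio[row_of], 0.4999)
  if (nrow(mesh$lines) > 0) {
    line_mat <- mapply(resolve, mesh$line_part, mesh$line_class)
    lrow <- match(line_mat, table$name)
    mesh$line_E <- table$elastic_modulus_MPa[lrow]
    mesh$line_nu <- pmin(table$poisson_ratio[lrow], 0.4999)
  } else {
    mesh$line_E <- numeric(0)
    mesh$line_nu <- numeric(0)
  }
  mesh$materials <- table
  mesh
}
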