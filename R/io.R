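## Delimited-text writers/readers. All numeric columns are written with
## %.17g so that write -> read round-trips reproduce the doubles exactly.

write_table_g17 <- function(df, path) {
  fmt <- vapply(df, function(col) {
    if (is.double(col)) "%.17g" else "%s"
  }, character(1))
  lines <- c(paste(names(df), collapse = "\t"),
             do.call(paste, c(lapply(seq_along(df), function(k) {
               if (fmt[k] == "%s") as.character(df[[k]])
               else sprintf("%.17g", df[[k]])
             }), sep = "\t")))
  writeLines(lines, path)
}

read_table_checked <- function(path, required, what) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.delim(path, check.names = FALSE),
    error = function(e) stop("parse error reading ", what, " file '",
                             basename(path), "': ", conditionMessage(e),
                             call. = FALSE))
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("parse error in ", what, " file '", basename(path),
         "': missing column(s) ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad <- !vapply(df, is.numeric, logical(1))
  if (any(bad) || anyNA(df)) {
    stop("parse error in ", what, " file '", basename(path),
         "': non-numeric or missing data", call. = FALSE)
  }
  df
}

#' Write / read a wide marker table
#'
#' Format: tab-separated, columns `frame`, `time_s`, then `<LABEL>_X/_Y/_Z`
#' in millimetres; full double precision.
#'
#' @param markers marker data frame (e.g. `trial$markers`).
#' @param path file path.
#' @export
write_marker_table <- function(markers, path) write_table_g17(markers, path)

#' @rdname write_marker_table
#' @export
read_marker_table <- function(path) {
  read_table_checked(path, c("frame", "time_s"), "marker")
}

#' Write / read a force-plate table
#'
#' Format: tab-separated `sample`, `time_s`, `Fx`, `Fy`, `Fz` (N), `COPx`,
#' `COPy` (mm).
#'
#' @param grf force table (e.g. `trial$grf`).
#' @param path file path.
#' @export
write_force_table <- function(grf, path) write_table_g17(grf, path)

#' @rdname write_force_table
#' @export
read_force_table <- function(path) {
  read_table_checked(path,
                     c("sample", "time_s", "Fx", "Fy", "Fz", "COPx", "COPy"),
                     "force")
}

#' Write / read an angle or torque series
#'
#' Two-column tab-separated series (`time_s` plus `flexion_deg` or
#' `torque_Nm`).
#'
#' @param series an `angle_series` or `torque_series`.
#' @param path file path.
#' @export
write_series <- function(series, path) write_table_g17(series, path)

#' @rdname write_series
#' @export
read_series <- function(path) read_table_checked(path, "time_s", "series")

#' Write a phase-segmentation report as JSON
#'
#' @param seg a `phase_segmentation`.
#' @param path file path.
#' @export
write_phase_report <- function(seg, path) {
  jsonlite::write_json(
    list(phases = as.data.frame(seg),
         peak_frames = attr(seg, "peaks"),
         trough_frame = attr(seg, "trough")),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Export a mesh (and optional fields) as legacy ASCII VTK
#'
#' Writes an UNSTRUCTURED_GRID with tetrahedra (type 10) and ligament lines
#' (type 3), cell data `part_id` (with the part names in the header
#' comment) and optionally `von_mises`, and point data `displacement`.
#'
#' @param mesh a `lumbar_mesh`.
#' @param path output path.
#' @param von_mises optional per-tet scalar (ligament lines get 0).
#' @param displacement optional n x 3 matrix.
#' @export
write_mesh_vtk <- function(mesh, path, von_mises = NULL,
                           displacement = NULL) {
  n <- nrow(mesh$nodes)
  parts <- c(mesh$tet_part, mesh$line_part)
  plev <- unique(parts)
  pid <- match(parts, plev) - 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               paste("lumbarlift mesh; parts:",
                     paste(plev, collapse = "|")),
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               paste("POINTS", n, "double")), con)
  writeLines(apply(mesh$nodes, 1, function(r)
    paste(sprintf("%.17g", r), collapse = " ")), con)
  m4 <- nrow(mesh$tets); m2 <- nrow(mesh$lines)
  writeLines(paste("CELLS", m4 + m2, 5 * m4 + 3 * m2), con)
  if (m4) writeLines(paste(4, mesh$tets[, 1] - 1L, mesh$tets[, 2] - 1L,
                           mesh$tets[, 3] - 1L, mesh$tets[, 4] - 1L), con)
  if (m2) writeLines(paste(2, mesh$lines[, 1] - 1L, mesh$lines[, 2] - 1L),
                     con)
  writeLines(paste("CELL_TYPES", m4 + m2), con)
  writeLines(as.character(c(rep(10L, m4), rep(3L, m2))), con)
  writeLines(c(paste("CELL_DATA", m4 + m2),
               "SCALARS part_id int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(pid), con)
  if (!is.null(von_mises)) {
    writeLines(c("SCALARS von_mises double 1", "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.17g", c(von_mises, rep(0, m2))), con)
  }
  if (!is.null(displacement)) {
    writeLines(c(paste("POINT_DATA", n), "VECTORS displacement double"),
               con)
    writeLines(apply(displacement, 1, function(r)
      paste(sprintf("%.17g", r), collapse = " ")), con)
  }
  invisible(path)
}

#' @rdname write_mesh_vtk
#' @export
read_mesh_vtk <- function(path) {
  ln <- readLines(path)
  expect_at <- function(i, pat) {
    if (i > length(ln) || !grepl(pat, ln[i])) {
      stop("parse error in VTK file at line ", i, ": expected '", pat, "'",
           call. = FALSE)
    }
  }
  expect_at(4, "^DATASET UNSTRUCTURED_GRID")
  expect_at(5, "^POINTS")
  n <- as.integer(strsplit(ln[5], "\\s+")[[1]][2])
  pts <- matrix(as.numeric(unlist(strsplit(ln[6:(5 + n)], "\\s+"))),
                ncol = 3, byrow = TRUE)
  i <- 6 + n
  expect_at(i, "^CELLS")
  nc <- as.integer(strsplit(ln[i], "\\s+")[[1]][2])
  cell_lines <- strsplit(ln[(i + 1):(i + nc)], "\\s+")
  i <- i + nc + 1
  expect_at(i, "^CELL_TYPES")
  types <- as.integer(ln[(i + 1):(i + nc)])
  i <- i + nc + 1
  tets <- do.call(rbind, lapply(cell_lines[types == 10L], function(v)
    as.integer(v[2:5]) + 1L))
  lines2 <- do.call(rbind, lapply(cell_lines[types == 3L], function(v)
    as.integer(v[2:3]) + 1L))
  part_id <- NULL
  if (i <= length(ln) && grepl("^CELL_DATA", ln[i])) {
    expect_at(i + 1, "^SCALARS part_id")
    part_id <- as.integer(ln[(i + 3):(i + 2 + nc)])
  }
  plev <- sub("^.*parts: ", "", ln[2])
  plev <- strsplit(plev, "\\|")[[1]]
  parts <- if (!is.null(part_id)) plev[part_id + 1L] else NULL
  list(nodes = pts,
       tets = if (is.null(tets)) matrix(0L, 0, 4) else tets,
       lines = if (is.null(lines2)) matrix(0L, 0, 2) else lines2,
       parts = parts)
}

#' Export the boundary surface of a mesh as ASCII STL
#'
#' The boundary surface consists of the tetrahedron faces that belong to
#' exactly one element.
#'
#' @param mesh a `lumbar_mesh`.
#' @param path output path.
#' @export
write_mesh_stl <- function(mesh, path) {
  Tt <- mesh$tets
  faces <- rbind(Tt[, c(1, 3, 2)], Tt[, c(1, 2, 4)],
                 Tt[, c(2, 3, 4)], Tt[, c(1, 4, 3)])
  key <- apply(faces, 1, function(f) paste(sort(f), collapse = "-"))
  tab <- table(key)
  bnd <- faces[key %in% names(tab)[tab == 1L], , drop = FALSE]
  p1 <- mesh$nodes[bnd[, 1], , drop = FALSE]
  p2 <- mesh$nodes[bnd[, 2], , drop = FALSE]
  p3 <- mesh$nodes[bnd[, 3], , drop = FALSE]
  v1 <- p2 - p1; v2 <- p3 - p1
  nrm <- cbind(v1[, 2] * v2[, 3] - v1[, 3] * v2[, 2],
               v1[, 3] * v2[, 1] - v1[, 1] * v2[, 3],
               v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1])
  nrm <- nrm / pmax(sqrt(rowSums(nrm^2)), .Machine$double.xmin)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid lumbarlift", con)
  for (k in seq_len(nrow(bnd))) {
    writeLines(c(sprintf("  facet normal %.9g %.9g %.9g",
                         nrm[k, 1], nrm[k, 2], nrm[k, 3]),
                 "    outer loop",
                 sprintf("      vertex %.9g %.9g %.9g",
                         c(p1[k, 1], p2[k, 1], p3[k, 1]),
                         c(p1[k, 2], p2[k, 2], p3[k, 2]),
                         c(p1[k, 3], p2[k, 3], p3[k, 3])),
                 "    endloop", "  endfacet"), con)
  }
  writeLines("endsolid lumbarlift", con)
  invisible(path)
}

#' Write a mesh census report as JSON
#' @param mesh a `lumbar_mesh`.
#' @param path file path.
#' @export
write_census_json <- function(mesh, path) {
  jsonlite::write_json(mesh_census(mesh), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}
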