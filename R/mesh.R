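## ---- 2D elliptical cross-section ------------------------------------------
##
## The cross-section is meshed as a structured "polar" triangulation: a
## centre node, concentric rings that follow the elliptical outline, and a
## dedicated ring on the cortical inner boundary (the exact 1 mm normal
## offset of the outer ellipse, so the shell thickness is the offset
## everywhere). All rings share the same angular stations, which makes every
## z-plane identical and the extruded mesh conforming across parts.

ellipse_section <- function(a, b, offset_mm, nucleus_frac, annulus_fracs,
                            target_edge_mm) {
  circ <- pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
  n_ang <- max(12L, 4L * as.integer(round(circ / target_edge_mm / 4)))
  psi <- 2 * pi * (0:(n_ang - 1)) / n_ang
  p <- cbind(a * cos(psi), b * sin(psi))            # outer ellipse
  nrm <- cbind(cos(psi) / a, sin(psi) / b)
  nrm <- nrm / sqrt(rowSums(nrm^2))
  q <- p - offset_mm * nrm                          # cortical inner boundary
  f_cort <- mean(sqrt(rowSums(q^2)) / sqrt(rowSums(p^2)))

  ann_bounds <- nucleus_frac + cumsum(c(0, annulus_fracs))  # 0.4 0.6 0.8 1.0
  base <- ann_bounds[-length(ann_bounds)]
  base <- base[abs(base - f_cort) > 1e-6]
  base <- sort(c(base, f_cort, 1))
  bounds <- c(0, base)
  r_ref <- (a + b) / 2
  fr <- numeric(0)
  for (i in seq_len(length(bounds) - 1)) {
    lo <- bounds[i]; hi <- bounds[i + 1]
    nsub <- max(1L, round((hi - lo) * r_ref / target_edge_mm))
    fr <- c(fr, lo + (hi - lo) * seq_len(nsub) / nsub)
  }
  n_r <- length(fr)

  nodes <- matrix(0, 1 + n_r * n_ang, 2)
  for (j in seq_len(n_r)) {
    f <- fr[j]
    ring <- if (f <= f_cort + 1e-12) {
      (f / f_cort) * q
    } else {
      w <- (f - f_cort) / (1 - f_cort)
      (1 - w) * q + w * p
    }
    nodes[1 + (j - 1) * n_ang + seq_len(n_ang), ] <- ring
  }

  idx <- function(j, k)
    as.integer(1L + (j - 1L) * n_ang + (k - 1L) %% n_ang + 1L)
  tris <- matrix(0L, n_ang + (n_r - 1) * 2 * n_ang, 3)
  frac_mid <- numeric(nrow(tris))
  m <- 0L
  for (k in seq_len(n_ang)) {                       # centre fan
    m <- m + 1L
    tris[m, ] <- c(1L, idx(1, k), idx(1, k + 1))
    frac_mid[m] <- fr[1] / 2
  }
  for (j in seq_len(n_r - 1)) {                     # annular bands
    fm <- (fr[j] + fr[j + 1]) / 2
    for (k in seq_len(n_ang)) {
      A <- idx(j, k); B <- idx(j, k + 1)
      C <- idx(j + 1, k + 1); D <- idx(j + 1, k)
      m <- m + 1L; tris[m, ] <- c(A, B, C); frac_mid[m] <- fm
      m <- m + 1L; tris[m, ] <- c(A, C, D); frac_mid[m] <- fm
    }
  }
  list(nodes = nodes, tris = tris, frac_mid = frac_mid,
       n_ang = n_ang, fr = fr, f_cort = f_cort,
       outer = p, cortical_inner = q,
       outer_ring_ids = idx(n_r, seq_len(n_ang)))
}

## ---- prism-to-tetrahedra splitting ----------------------------------------
##
## Each extruded triangular prism (b1,b2,b3 | t1,t2,t3) is cut into three
## tetrahedra. The diagonal of every vertical quad face is the one through
## the face's smallest global node id; with plane-major numbering the
## bottom ids are always smaller, so the rule is quad-local and adjacent
## prisms always agree on shared faces, and the cyclic "undecomposable"
## diagonal patterns cannot occur.
split_prisms <- function(prisms) {
  stopifnot(ncol(prisms) == 6)
  bot <- prisms[, 1:3, drop = FALSE]
  m <- max.col(-bot, ties.method = "first")         # position of min bottom id
  rot <- rbind(c(1L, 2L, 3L, 4L, 5L, 6L),
               c(2L, 3L, 1L, 5L, 6L, 4L),
               c(3L, 1L, 2L, 6L, 4L, 5L))
  P <- prisms
  for (r in 2:3) {
    sel <- m == r
    if (any(sel)) P[sel, ] <- prisms[sel, rot[r, ], drop = FALSE]
  }
  cond <- P[, 2] < P[, 3]                           # Q23 diagonal choice
  n <- nrow(P)
  tets <- matrix(0L, 3L * n, 4)
  i3 <- 3L * (seq_len(n) - 1L)
  # diagonal 2-6
  tets[i3 + 1L, ] <- cbind(P[, 1], P[, 2], P[, 3], P[, 6])
  tets[i3 + 2L, ] <- cbind(P[, 1], P[, 2], P[, 6], P[, 5])
  tets[i3 + 3L, ] <- cbind(P[, 1], P[, 5], P[, 6], P[, 4])
  # diagonal 3-5 overrides rows where cond is FALSE
  alt <- !cond
  if (any(alt)) {
    tets[i3[alt] + 1L, ] <- cbind(P[alt, 1], P[alt, 2], P[alt, 3], P[alt, 5])
    tets[i3[alt] + 2L, ] <- cbind(P[alt, 1], P[alt, 3], P[alt, 6], P[alt, 5])
  }
  tets
}

tet_signed_volumes <- function(nodes, tets) {
  p1 <- nodes[tets[, 1], , drop = FALSE]
  v1 <- nodes[tets[, 2], , drop = FALSE] - p1
  v2 <- nodes[tets[, 3], , drop = FALSE] - p1
  v3 <- nodes[tets[, 4], , drop = FALSE] - p1
  (v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
   v1[, 2] * (v2[, 1] * v3[, 3] - v2[, 3] * v3[, 1]) +
   v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])) / 6
}

orient_tets <- function(nodes, tets) {
  v <- tet_signed_volumes(nodes, tets)
  neg <- v < 0
  if (any(neg)) tets[neg, 3:4] <- tets[neg, c(4, 3), drop = FALSE]
  if (any(tet_signed_volumes(nodes, tets) <= 0)) {
    stop("meshing error: degenerate (zero-volume) tetrahedra produced",
         call. = FALSE)
  }
  tets
}

extrude_section <- function(nodes2d, tris, z_planes) {
  npp <- nrow(nodes2d)
  nz <- length(z_planes)
  nodes <- cbind(nodes2d[rep(seq_len(npp), nz), , drop = FALSE],
                 rep(z_planes, each = npp))
  nt <- nrow(tris)
  layers <- nz - 1L
  prisms <- matrix(0L, nt * layers, 6)
  for (l in seq_len(layers)) {
    off_b <- (l - 1L) * npp
    rows <- (l - 1L) * nt + seq_len(nt)
    prisms[rows, ] <- cbind(tris + off_b, tris + off_b + npp)
  }
  list(nodes = nodes, prisms = prisms, npp = npp,
       layer_of_prism = rep(seq_len(layers), each = nt),
       tri_of_prism = rep(seq_len(nt), times = layers))
}

## Layer thicknesses for a slab adjacent to the fixed boundary: geometric
## grading from about a sixteenth of the target edge at the clamp, then
## uniform layers.
graded_layers <- function(h, e) {
  th <- e / 16 * c(1, 1, 2, 4, 8, 16 * 2^(0:4))
  th <- th[th < e & cumsum(th) < h / 2]
  rest <- h - sum(th)
  n <- max(1L, round(rest / e))
  c(th, rep(rest / n, n))
}

## ---- ligament line groups --------------------------------------------------

ligament_groups <- function() {
  list(
    list(part = "ALL", class = "lig_anterior", angles_deg = 0),
    list(part = "PLL", class = "lig_posterior", angles_deg = 180),
    list(part = "LF", class = "lig_flavum", angles_deg = c(165, 195)),
    list(part = "ISL", class = "lig_interspinous", angles_deg = c(150, 210)),
    list(part = "SSL", class = "lig_supraspinous", angles_deg = 180),
    list(part = "ITL", class = "lig_intertransverse", angles_deg = c(90, 270))
  )
}

## ---- meshing front-end -----------------------------------------------------

#' Mesh a labeled solid description
#'
#' Produces a conforming labeled tetrahedral mesh. Part interfaces share
#' nodes (tied "binding" contact); the construction is fully deterministic.
#' For the lumbar solids the element census per part class is
#' 5 cortical / 5 cancellous / 4 nucleus / 8 endplate / 12 annulus-layer /
#' 6 ligament groups.
#'
#' @param solids a `lumbar_solids` (from [build_geometry()]) or a
#'   [block_solid()].
#' @param target_edge_mm target edge length; defaults to the geometry
#'   parameters' value (lumbar) or 0.5 (block).
#' @return an object of class `lumbar_mesh` with node coordinates (mm),
#'   tetrahedra, ligament line elements, part and class labels.
#' @export
mesh_geometry <- function(solids, target_edge_mm = NULL) {
  UseMethod("mesh_geometry")
}

#' @export
mesh_geometry.lumbar_solids <- function(solids, target_edge_mm = NULL) {
  params <- solids$params
  if (is.null(target_edge_mm)) target_edge_mm <- params$target_edge_mm
  sec <- ellipse_section(solids$a, solids$b, params$cortical_offset_mm,
                         params$nucleus_radius_frac,
                         params$annulus_layer_fracs, target_edge_mm)

  z_planes <- 0
  slab_of_layer <- integer(0)
  slab_planes <- matrix(0L, length(solids$slabs), 2)  # first/last plane index
  for (s in seq_along(solids$slabs)) {
    sl <- solids$slabs[[s]]
    h <- sl$z1 - sl$z0
    ## the basal vertebra carries the fixed (lumbosacral) boundary, where
    ## the stress concentration of interest lives: grade its layers towards
    ## the clamp instead of meshing it uniformly
    offs <- if (s == 1L && sl$type == "vertebra") {
      cumsum(graded_layers(h, target_edge_mm))
    } else {
      n_l <- if (sl$type == "endplate") 1L
             else max(1L, round(h / target_edge_mm))
      h * seq_len(n_l) / n_l
    }
    slab_planes[s, 1] <- length(z_planes)
    z_planes <- c(z_planes, sl$z0 + offs)
    slab_planes[s, 2] <- length(z_planes)
    slab_of_layer <- c(slab_of_layer, rep(s, length(offs)))
  }

  ext <- extrude_section(sec$nodes, sec$tris, z_planes)
  tets <- split_prisms(ext$prisms)
  tets <- orient_tets(ext$nodes, tets)

  slab_of_tet <- rep(slab_of_layer[ext$layer_of_prism], each = 3L)
  frac_of_tet <- rep(sec$frac_mid[ext$tri_of_prism], each = 3L)
  tet_part <- character(nrow(tets))
  tet_class <- character(nrow(tets))
  f_c <- sec$f_cort
  nuc <- params$nucleus_radius_frac
  ab <- nuc + cumsum(params$annulus_layer_fracs)
  for (s in seq_along(solids$slabs)) {
    sl <- solids$slabs[[s]]
    sel <- slab_of_tet == s
    if (!any(sel)) next
    fm <- frac_of_tet[sel]
    if (sl$type == "vertebra") {
      cls <- ifelse(fm < f_c, "cancellous", "cortical")
      tet_class[sel] <- cls
      tet_part[sel] <- paste(sl$name, cls)
    } else if (sl$type == "disc") {
      cls <- ifelse(fm < nuc, "nucleus",
             ifelse(fm < ab[1], "annulus_inner",
             ifelse(fm < ab[2], "annulus_middle", "annulus_outer")))
      tet_class[sel] <- cls
      lab <- c(nucleus = "nucleus", annulus_inner = "annulus inner",
               annulus_middle = "annulus middle", annulus_outer = "annulus outer")
      tet_part[sel] <- paste(sl$name, lab[cls])
    } else {
      tet_class[sel] <- "endplate"
      tet_part[sel] <- sl$name
    }
  }

  ## ligament lines spanning each vertebra-to-vertebra junction posteriorly,
  ## anteriorly and laterally
  n_ang <- sec$n_ang
  outer_first <- 1L + (length(sec$fr) - 1L) * n_ang + 1L
  ang_idx <- function(deg)
    as.integer(outer_first + (round(deg / 360 * n_ang) %% n_ang))
  npp <- ext$npp
  slab_names <- vapply(solids$slabs, `[[`, "", "name")
  slab_types <- vapply(solids$slabs, `[[`, "", "type")
  vert_names <- unique(slab_names[slab_types == "vertebra"])
  top_plane_of <- function(nm)
    max(slab_planes[slab_types == "vertebra" & slab_names == nm, 2])
  bot_plane_of <- function(nm)
    min(slab_planes[slab_types == "vertebra" & slab_names == nm, 1])
  lines <- matrix(0L, 0, 2)
  line_part <- character(0)
  line_class <- character(0)
  for (i in seq_len(length(vert_names) - 1)) {
    p_top <- top_plane_of(vert_names[i])
    p_bot <- bot_plane_of(vert_names[i + 1])
    for (g in ligament_groups()) {
      for (ang in g$angles_deg) {
        k <- ang_idx(ang)
        lines <- rbind(lines, c((p_top - 1L) * npp + k,
                                (p_bot - 1L) * npp + k))
        line_part <- c(line_part, g$part)
        line_class <- c(line_class, g$class)
      }
    }
  }

  structure(list(nodes = ext$nodes, tets = tets,
                 tet_part = tet_part, tet_class = tet_class,
                 lines = lines, line_part = line_part,
                 line_class = line_class,
                 line_area_mm2 = params$ligament_area_mm2,
                 section = sec, z_planes = z_planes,
                 surface_tris = sec$tris, npp = npp,
                 solids = solids, target_edge_mm = target_edge_mm,
                 materials = NULL),
            class = "lumbar_mesh")
}

#' @export
mesh_geometry.block_solid <- function(solids, target_edge_mm = NULL) {
  if (is.null(target_edge_mm)) target_edge_mm <- 0.5
  nx <- max(1L, round(solids$lx / target_edge_mm))
  ny <- max(1L, round(solids$ly / target_edge_mm))
  nz <- max(1L, round(solids$lz / target_edge_mm))
  xs <- solids$lx * (0:nx) / nx
  ys <- solids$ly * (0:ny) / ny
  nodes2d <- cbind(rep(xs, times = ny + 1), rep(ys, each = nx + 1))
  id <- function(i, j) (j - 1L) * (nx + 1L) + i
  tris <- matrix(0L, 2L * nx * ny, 3)
  m <- 0L
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      A <- id(i, j); B <- id(i + 1L, j)
      C <- id(i + 1L, j + 1L); D <- id(i, j + 1L)
      m <- m + 1L; tris[m, ] <- c(A, B, C)
      m <- m + 1L; tris[m, ] <- c(A, C, D)
    }
  }
  z_planes <- solids$lz * (0:nz) / nz
  ext <- extrude_section(nodes2d, tris, z_planes)
  tets <- split_prisms(ext$prisms)
  tets <- orient_tets(ext$nodes, tets)
  structure(list(nodes = ext$nodes, tets = tets,
                 tet_part = rep("block", nrow(tets)),
                 tet_class = rep("block", nrow(tets)),
                 lines = matrix(0L, 0, 2), line_part = character(0),
                 line_class = character(0), line_area_mm2 = 0,
                 section = NULL, z_planes = z_planes,
                 surface_tris = tris, npp = nrow(nodes2d),
                 solids = solids, target_edge_mm = target_edge_mm,
                 materials = NULL),
            class = "lumbar_mesh")
}

#' @export
#' @method print lumbar_mesh
print.lumbar_mesh <- function(x, ...) {
  cat("Labeled tetrahedral mesh:", nrow(x$nodes), "nodes,",
      nrow(x$tets), "tets,", nrow(x$lines), "line elements,",
      length(unique(x$tet_part)), "solid parts\n")
  invisible(x)
}

#' Part census of a labeled mesh
#'
#' Counts the distinct parts and elements per part class; for the default
#' lumbar geometry the solid-part census is (cortical 5, cancellous 5,
#' nucleus 4, endplate 8, annulus layers 12) plus 6 ligament groups.
#'
#' @param mesh a `lumbar_mesh`.
#' @return data frame with `class`, `n_parts`, `n_elements`.
#' @export
mesh_census <- function(mesh) {
  cls <- c(mesh$tet_class, mesh$line_class)
  prt <- c(mesh$tet_part, mesh$line_part)
  agg <- lapply(split(prt, cls), function(p)
    c(n_parts = length(unique(p)), n_elements = length(p)))
  out <- data.frame(class = names(agg),
                    n_parts = vapply(agg, `[[`, 0, "n_parts"),
                    n_elements = vapply(agg, `[[`, 0, "n_elements"),
                    row.names = NULL)
  out[order(out$class), ]
}

#' Per-part volumes of a mesh
#' @param mesh a `lumbar_mesh`.
#' @return named numeric vector of part volumes (mm^3).
#' @export
mesh_part_volumes <- function(mesh) {
  v <- tet_signed_volumes(mesh$nodes, mesh$tets)
  vapply(split(v, mesh$tet_part), sum, numeric(1))
}

#' Edge-length summary of a mesh
#' @param mesh a `lumbar_mesh`.
#' @return named vector with min, median, max tetrahedron edge length (mm).
#' @export
mesh_edge_lengths <- function(mesh) {
  Tt <- mesh$tets
  pairs <- rbind(Tt[, c(1, 2)], Tt[, c(1, 3)], Tt[, c(1, 4)],
                 Tt[, c(2, 3)], Tt[, c(2, 4)], Tt[, c(3, 4)])
  d <- sqrt(rowSums((mesh$nodes[pairs[, 1], ] - mesh$nodes[pairs[, 2], ])^2))
  c(min = min(d), median = stats::median(d), max = max(d))
}

tet_centroids <- function(mesh) {
  (mesh$nodes[mesh$tets[, 1], ] + mesh$nodes[mesh$tets[, 2], ] +
   mesh$nodes[mesh$tets[, 3], ] + mesh$nodes[mesh$tets[, 4], ]) / 4
}
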