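## Shape-function gradients and volumes of linear (constant-strain)
## tetrahedra, vectorised over elements. G[[a]] is the m x 3 matrix of
## grad(N_a); V the element volumes.
tet_gradients <- function(nodes, tets) {
  p1 <- nodes[tets[, 1], , drop = FALSE]
  v1 <- nodes[tets[, 2], , drop = FALSE] - p1
  v2 <- nodes[tets[, 3], , drop = FALSE] - p1
  v3 <- nodes[tets[, 4], , drop = FALSE] - p1
  crossm <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                 a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                 a[, 1] * b[, 2] - a[, 2] * b[, 1])
  c1 <- crossm(v2, v3); c2 <- crossm(v3, v1); c3 <- crossm(v1, v2)
  det <- rowSums(v1 * c1)
  G2 <- c1 / det
  G3 <- c2 / det
  G4 <- c3 / det
  G1 <- -(G2 + G3 + G4)
  list(G = list(G1, G2, G3, G4), V = det / 6)
}

## Sparse stiffness triplets of all tetrahedra (isotropic linear elasticity,
## lambda/mu form): K[ai,bj] = V (lambda Ga_i Gb_j + mu Ga_j Gb_i
##                                + mu delta_ij Ga.Gb).
assemble_tet_stiffness <- function(nodes, tets, E, nu) {
  gr <- tet_gradients(nodes, tets)
  G <- gr$G; V <- gr$V
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  m <- nrow(tets)
  ii <- integer(144 * m); jj <- integer(144 * m); xx <- numeric(144 * m)
  s <- 0L
  for (a in 1:4) {
    for (b in 1:4) {
      dab <- rowSums(G[[a]] * G[[b]])
      for (i in 1:3) {
        rows <- 3L * (tets[, a] - 1L) + i
        for (j in 1:3) {
          val <- V * (lam * G[[a]][, i] * G[[b]][, j] +
                      mu * G[[a]][, j] * G[[b]][, i] +
                      (if (i == j) mu * dab else 0))
          sel <- s + seq_len(m)
          ii[sel] <- rows
          jj[sel] <- 3L * (tets[, b] - 1L) + j
          xx[sel] <- val
          s <- s + m
        }
      }
    }
  }
  list(i = ii, j = jj, x = xx)
}

## Truss (2-node line) element triplets: k = E A / L along the axis.
assemble_truss_stiffness <- function(nodes, lines, E, area) {
  if (nrow(lines) == 0) return(list(i = integer(0), j = integer(0),
                                    x = numeric(0)))
  d <- nodes[lines[, 2], , drop = FALSE] - nodes[lines[, 1], , drop = FALSE]
  L <- sqrt(rowSums(d^2))
  d <- d / L
  k <- E * area / L
  m <- nrow(lines)
  ii <- integer(36 * m); jj <- integer(36 * m); xx <- numeric(36 * m)
  s <- 0L
  for (a in 1:2) {
    for (b in 1:2) {
      sgn <- if (a == b) 1 else -1
      for (i in 1:3) {
        for (j in 1:3) {
          sel <- s + seq_len(m)
          ii[sel] <- 3L * (lines[, a] - 1L) + i
          jj[sel] <- 3L * (lines[, b] - 1L) + j
          xx[sel] <- sgn * k * d[, i] * d[, j]
          s <- s + m
        }
      }
    }
  }
  list(i = ii, j = jj, x = xx)
}

#' Assemble the static linear-elastic system of a labeled mesh
#'
#' Builds the global sparse stiffness operator from linear constant-strain
#' tetrahedra and 2-node truss (ligament) elements. Units: lengths mm,
#' moduli MPa, so forces are N and displacements mm. The operator is
#' symmetric positive semi-definite; rigid-body modes are removed later by
#' the Dirichlet boundary in [solve_static()].
#'
#' @param mesh a `lumbar_mesh` with materials bound (see
#'   [assign_materials()]).
#' @return an object of class `fe_system` with the stiffness matrix `K`
#'   (N/mm), the mesh, and the number of degrees of freedom.
#' @export
assemble_system <- function(mesh) {
  stopifnot(inherits(mesh, "lumbar_mesh"))
  if (is.null(mesh$tet_E)) {
    stop("materials are not bound; call assign_materials() first",
         call. = FALSE)
  }
  n <- nrow(mesh$nodes)
  tt <- assemble_tet_stiffness(mesh$nodes, mesh$tets, mesh$tet_E, mesh$tet_nu)
  lt <- assemble_truss_stiffness(mesh$nodes, mesh$lines, mesh$line_E,
                                 mesh$line_area_mm2)
  K <- Matrix::sparseMatrix(i = c(tt$i, lt$i), j = c(tt$j, lt$j),
                            x = c(tt$x, lt$x), dims = c(3 * n, 3 * n))
  structure(list(K = K, mesh = mesh, ndof = 3L * n), class = "fe_system")
}

node_dofs <- function(nodes) as.vector(t(cbind(3 * (nodes - 1) + 1,
                                               3 * (nodes - 1) + 2,
                                               3 * (nodes - 1) + 3)))

#' Solve the static problem
#'
#' Direct sparse solve of `K u = f` with homogeneous (fixed) and optional
#' non-zero prescribed displacements, followed by element stress recovery.
#'
#' @param system an `fe_system`.
#' @param loadcase optionally a `load_case` built by [build_load_case()];
#'   supplies `f` and `fixed_nodes`.
#' @param f external nodal force vector (length `3n`, N).
#' @param fixed_nodes node indices fully fixed (all three DOFs zero).
#' @param prescribed optional list with `dofs` and `values` for non-zero
#'   Dirichlet conditions.
#' @param rel_tol admissible relative residual of the solve.
#' @return an object of class `fe_solution`: displacements `u` (n x 3, mm),
#'   the per-element [element_stresses()] table `stress`, ligament axial
#'   stresses `line_stress`, boundary `reactions`, and a `report` (DOF
#'   count, residual, peak displacement, per-part peak von Mises).
#' @export
solve_static <- function(system, loadcase = NULL, f = NULL,
                         fixed_nodes = NULL, prescribed = NULL,
                         rel_tol = 1e-8) {
  stopifnot(inherits(system, "fe_system"))
  mesh <- system$mesh
  if (!is.null(loadcase)) {
    f <- loadcase$f
    fixed_nodes <- loadcase$fixed_nodes
  }
  if (is.null(f)) f <- numeric(system$ndof)
  if (length(f) != system$ndof) stop("force vector has wrong length",
                                     call. = FALSE)
  dir_dofs <- integer(0); dir_vals <- numeric(0)
  if (!is.null(fixed_nodes) && length(fixed_nodes)) {
    dir_dofs <- node_dofs(fixed_nodes)
    dir_vals <- numeric(length(dir_dofs))
  }
  if (!is.null(prescribed)) {
    dir_dofs <- c(dir_dofs, prescribed$dofs)
    dir_vals <- c(dir_vals, prescribed$values)
  }
  if (!length(dir_dofs)) {
    stop("singular system: no Dirichlet boundary removes the rigid-body ",
         "modes", call. = FALSE)
  }
  keep <- !duplicated(dir_dofs)
  dir_dofs <- dir_dofs[keep]; dir_vals <- dir_vals[keep]
  free <- setdiff(seq_len(system$ndof), dir_dofs)

  K <- system$K
  rhs <- f[free]
  if (any(dir_vals != 0)) {
    rhs <- rhs - as.numeric(K[free, dir_dofs, drop = FALSE] %*% dir_vals)
  }
  Kff <- Matrix::forceSymmetric(K[free, free, drop = FALSE])
  u_free <- tryCatch(
    as.numeric(Matrix::solve(Kff, rhs)),
    error = function(e) {
      stop("solver error: the reduced stiffness could not be factorised ",
           "(disconnected or under-constrained parts?): ",
           conditionMessage(e), call. = FALSE)
    })
  if (any(!is.finite(u_free))) {
    stop("solver error: non-finite displacement solution (singular system)",
         call. = FALSE)
  }
  u <- numeric(system$ndof)
  u[free] <- u_free
  u[dir_dofs] <- dir_vals

  res <- as.numeric(Kff %*% u_free) - rhs
  scale <- max(sqrt(sum(rhs^2)), .Machine$double.eps)
  rel_res <- sqrt(sum(res^2)) / scale
  if (rel_res > rel_tol) {
    stop("solver error: relative residual ", format(rel_res),
         " exceeds tolerance ", rel_tol, call. = FALSE)
  }

  reac <- as.numeric(K[dir_dofs, , drop = FALSE] %*% u) - f[dir_dofs]
  umat <- matrix(u, ncol = 3, byrow = TRUE)
  stress <- element_stresses(mesh, umat)
  lstress <- line_stresses(mesh, umat)
  part_peak <- if (nrow(stress)) {
    vapply(split(stress$von_mises, stress$part), max, numeric(1))
  } else numeric(0)
  structure(list(u = umat, stress = stress, line_stress = lstress,
                 reactions = data.frame(dof = dir_dofs, force_N = reac),
                 loadcase = loadcase,
                 report = list(dof = system$ndof,
                               n_free = length(free),
                               relative_residual = rel_res,
                               peak_displacement_mm =
                                 max(sqrt(rowSums(umat^2))),
                               part_peak_MPa = part_peak)),
            class = "fe_solution")
}

#' Von Mises equivalent stress
#'
#' @param s matrix (or data frame) with columns `sxx, syy, szz, sxy, syz,
#'   szx` in MPa.
#' @return vector of von Mises stresses.
#' @export
von_mises_stress <- function(s) {
  s <- as.matrix(s)
  sqrt(0.5 * ((s[, 1] - s[, 2])^2 + (s[, 2] - s[, 3])^2 +
              (s[, 3] - s[, 1])^2) +
       3 * (s[, 4]^2 + s[, 5]^2 + s[, 6]^2))
}

#' Per-element Cauchy stresses from a displacement field
#'
#' Constant-strain recovery on each tetrahedron: the strain is the
#' symmetric displacement gradient, the stress follows the element's
#' isotropic Hooke law, and the scalar intensity is the von Mises
#' equivalent. Element (not nodal-averaged) values are reported.
#'
#' @param mesh a `lumbar_mesh` with materials bound.
#' @param u displacement matrix (n x 3, mm).
#' @return data frame with element index, part, class, centroid (mm),
#'   stress components and `von_mises` (MPa).
#' @export
element_stresses <- function(mesh, u) {
  m <- nrow(mesh$tets)
  if (m == 0) return(data.frame())
  gr <- tet_gradients(mesh$nodes, mesh$tets)
  G <- gr$G
  grad <- matrix(0, m, 9)  # du_i/dx_j, columns (11,12,13,21,...,33)
  for (a in 1:4) {
    ua <- u[mesh$tets[, a], , drop = FALSE]
    for (i in 1:3) {
      for (j in 1:3) {
        grad[, 3 * (i - 1) + j] <- grad[, 3 * (i - 1) + j] +
          ua[, i] * G[[a]][, j]
      }
    }
  }
  exx <- grad[, 1]; eyy <- grad[, 5]; ezz <- grad[, 9]
  exy <- (grad[, 2] + grad[, 4]) / 2
  eyz <- (grad[, 6] + grad[, 8]) / 2
  ezx <- (grad[, 3] + grad[, 7]) / 2
  lam <- mesh$tet_E * mesh$tet_nu /
    ((1 + mesh$tet_nu) * (1 - 2 * mesh$tet_nu))
  mu <- mesh$tet_E / (2 * (1 + mesh$tet_nu))
  tr <- exx + eyy + ezz
  s <- cbind(sxx = lam * tr + 2 * mu * exx,
             syy = lam * tr + 2 * mu * eyy,
             szz = lam * tr + 2 * mu * ezz,
             sxy = 2 * mu * exy,
             syz = 2 * mu * eyz,
             szx = 2 * mu * ezx)
  ctr <- tet_centroids(mesh)
  data.frame(element = seq_len(m), part = mesh$tet_part,
             class = mesh$tet_class,
             cx = ctr[, 1], cy = ctr[, 2], cz = ctr[, 3],
             s, von_mises = von_mises_stress(s))
}

## Axial stresses of the truss (ligament) elements.
line_stresses <- function(mesh, u) {
  if (nrow(mesh$lines) == 0) return(data.frame())
  d <- mesh$nodes[mesh$lines[, 2], , drop = FALSE] -
       mesh$nodes[mesh$lines[, 1], , drop = FALSE]
  L <- sqrt(rowSums(d^2))
  dhat <- d / L
  du <- u[mesh$lines[, 2], , drop = FALSE] - u[mesh$lines[, 1], , drop = FALSE]
  eps <- rowSums(du * dhat) / L
  data.frame(element = seq_len(nrow(mesh$lines)), part = mesh$line_part,
             class = mesh$line_class, axial_stress_MPa = mesh$line_E * eps)
}

#' Peak von Mises stress of a part or part class
#'
#' @param field an `fe_solution` or its `stress` data frame.
#' @param part exact part name (e.g. `"L5 cortical"`) or a part class
#'   (e.g. `"cancellous"`, `"nucleus"`); for discs, a disc id such as
#'   `"L4-L5"` selects the nucleus plus all annulus layers.
#' @return maximum element von Mises stress (MPa).
#' @export
peak_stress_by_part <- function(field, part) {
  stress <- if (inherits(field, "fe_solution")) field$stress else field
  sel <- stress$part == part
  if (!any(sel)) sel <- stress$class == part
  if (!any(sel)) sel <- disc_elements(stress, part)
  if (!any(sel)) stop("no elements in part or class '", part, "'",
                      call. = FALSE)
  max(stress$von_mises[sel])
}

## Logical selector of the solid disc elements (nucleus + annulus) of one
## intervertebral disc, e.g. "L4-L5".
disc_elements <- function(stress, disc) {
  startsWith(stress$part, paste0(disc, " ")) &
    stress$class %in% c("nucleus", "annulus_inner", "annulus_middle",
                        "annulus_outer")
}
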