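## Tributary-area weights of the mesh's top or bottom surface nodes: each
## surface triangle contributes a third of its area to each of its nodes,
## so equal nodal shares of a load reproduce a uniform traction.
surface_node_weights <- function(mesh, which = c("top", "bottom")) {
  which <- match.arg(which)
  npp <- mesh$npp
  nz <- length(mesh$z_planes)
  plane <- if (which == "top") nz else 1L
  off <- (plane - 1L) * npp
  tris <- mesh$surface_tris + off
  p1 <- mesh$nodes[tris[, 1], , drop = FALSE]
  p2 <- mesh$nodes[tris[, 2], , drop = FALSE]
  p3 <- mesh$nodes[tris[, 3], , drop = FALSE]
  v1 <- p2 - p1; v2 <- p3 - p1
  cr <- cbind(v1[, 2] * v2[, 3] - v1[, 3] * v2[, 2],
              v1[, 3] * v2[, 1] - v1[, 1] * v2[, 3],
              v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1])
  area <- sqrt(rowSums(cr^2)) / 2
  w <- numeric(npp)
  for (k in 1:3) {
    acc <- tapply(area / 3, tris[, k] - off, sum)
    w[as.integer(names(acc))] <- w[as.integer(names(acc))] + acc
  }
  list(nodes = off + seq_len(npp), weights = w)
}

#' Build a load case for the lumbar model
#'
#' The inferior endplate surface of L5 (the bottom node plane) is fully
#' fixed, simulating the lumbosacral junction; the superior endplate
#' surface of L1 (the top node plane) carries a vertical compressive load
#' distributed as a uniform traction plus a sagittal (forward-flexion)
#' moment applied as a linearly varying force couple over the same nodes.
#' The default vertical load is 1425 N (the 120 kg lift condition); the
#' moment defaults to the action's first-peak lumbar torque.
#'
#' @param mesh a `lumbar_mesh` of the lumbar solids.
#' @param action_id `"DL"`, `"SLDL"` or `"TBDL"` (or any tag).
#' @param torque_source sagittal moment in N.m (scalar), or a
#'   `torque_series` whose first-peak torque is used.
#' @param vertical_load_N vertical compressive load (default 1425 N).
#' @return an object of class `load_case` with the nodal force vector `f`
#'   (length 3n, N), `fixed_nodes`, `loaded_nodes`, `vertical_load_N` and
#'   `sagittal_moment_Nm`.
#' @export
build_load_case <- function(mesh, action_id, torque_source,
                            vertical_load_N = 1425) {
  stopifnot(inherits(mesh, "lumbar_mesh"))
  moment_Nm <- if (inherits(torque_source, "torque_series") ||
                   is.data.frame(torque_source)) {
    first_peak_torque(torque_source)
  } else {
    as.numeric(torque_source)
  }
  if (length(moment_Nm) != 1 || !is.finite(moment_Nm) || moment_Nm < 0) {
    stop("sagittal moment must be a single non-negative number",
         call. = FALSE)
  }
  if (vertical_load_N <= 0) stop("vertical load must be positive",
                                 call. = FALSE)
  top <- surface_node_weights(mesh, "top")
  bot <- surface_node_weights(mesh, "bottom")
  if (!length(top$nodes) || !length(bot$nodes)) {
    stop("model error: empty loaded or fixed node set", call. = FALSE)
  }
  if (length(intersect(top$nodes, bot$nodes))) {
    stop("model error: loaded and fixed node sets overlap", call. = FALSE)
  }
  n <- nrow(mesh$nodes)
  f <- numeric(3 * n)
  wz <- top$weights / sum(top$weights)
  zi <- 3 * (top$nodes - 1) + 3
  f[zi] <- f[zi] - vertical_load_N * wz
  if (moment_Nm > 0) {
    x <- mesh$nodes[top$nodes, 1]
    xbar <- sum(wz * x)
    denom <- sum(wz * (x - xbar)^2)
    cc <- moment_Nm * 1000 / denom      # N.mm
    f[zi] <- f[zi] - cc * wz * (x - xbar)
  }
  structure(list(action_id = action_id,
                 vertical_load_N = vertical_load_N,
                 sagittal_moment_Nm = moment_Nm,
                 fixed_nodes = bot$nodes, loaded_nodes = top$nodes,
                 f = f),
            class = "load_case")
}

#' Net force and moment checks of a load case
#'
#' @param mesh the mesh the case was built for.
#' @param loadcase a `load_case`.
#' @return list with `total_vertical_N` (sum of applied vertical forces)
#'   and `net_moment_Nm` (sagittal moment of the applied forces about the
#'   loaded-surface centroid).
#' @export
loadcase_totals <- function(mesh, loadcase) {
  zi <- 3 * (loadcase$loaded_nodes - 1) + 3
  fz <- loadcase$f[zi]
  top <- surface_node_weights(mesh, "top")
  wz <- top$weights / sum(top$weights)
  x <- mesh$nodes[loadcase$loaded_nodes, 1]
  xbar <- sum(wz * x)
  # about the traction-weighted centroid the uniform compression part has
  # zero sagittal moment, so this isolates the couple distribution
  list(total_vertical_N = sum(fz),
       net_moment_Nm = -sum((x - xbar) * fz) / 1000)
}
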