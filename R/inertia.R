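#' Mass of a regular elliptical frustum
#'
#' The torso above the lumbar joint is idealised as a regular elliptical
#' frustum: a solid whose cross-sections interpolate linearly between an
#' elliptical base with semi-axes `a1`, `b1` and an elliptical top with
#' semi-axes `a2`, `b2` over height `h`. Its volume is
#' `pi * h / 3 * (a1*b1 + a2*b2 + sqrt(a1*b1*a2*b2))`, the elliptical
#' analogue of the conical frustum formula; the mass is volume times
#' density.
#'
#' @param a1,b1 semi-axes of the base ellipse (m).
#' @param a2,b2 semi-axes of the top ellipse (m).
#' @param h frustum height (m).
#' @param density tissue density (kg/m^3).
#' @return mass in kg.
#' @export
elliptical_frustum_mass <- function(a1, b1, a2, b2, h, density) {
  if (any(c(a1, b1, a2, b2) < 0)) {
    stop("semi-axes must be non-negative", call. = FALSE)
  }
  if (h <= 0) stop("height must be positive", call. = FALSE)
  if (density <= 0) stop("density must be positive", call. = FALSE)
  if (a1 * b1 == 0 && a2 * b2 == 0) {
    stop("both end ellipses are degenerate", call. = FALSE)
  }
  s1 <- a1 * b1
  s2 <- a2 * b2
  density * pi * h / 3 * (s1 + s2 + sqrt(s1 * s2))
}

#' Rigid-body parameters of the supra-lumbar trunk segment
#'
#' Builds the mass, centroidal inertia tensor and centre-of-mass offset of
#' the single rigid trunk segment above the lumbar joint. The mass comes
#' from the elliptical-frustum torso model; the centroidal inertia about the
#' sagittal bending axis uses the slender-rod approximation
#' `I = m L^2 / 12` about the segment's transverse axes.
#'
#' @param anthropometry list with elements `frustum_a1_m`, `frustum_b1_m`,
#'   `frustum_a2_m`, `frustum_b2_m`, `frustum_h_m`, `density_kg_m3`,
#'   `trunk_length_m` (joint-to-C7 distance) and `com_fraction` (centroid
#'   position along the trunk line as a fraction of its length). Defaults
#'   from [default_anthropometry()].
#' @return list with `mass_kg`, `inertia_kg_m2` (3x3 diagonal matrix about
#'   the centroid) and `com_distance_m` (centroid distance from the joint
#'   along the trunk line).
#' @export
trunk_inertia <- function(anthropometry = default_anthropometry()) {
  a <- anthropometry
  m <- elliptical_frustum_mass(a$frustum_a1_m, a$frustum_b1_m,
                               a$frustum_a2_m, a$frustum_b2_m,
                               a$frustum_h_m, a$density_kg_m3)
  L <- a$trunk_length_m
  i_tr <- m * L^2 / 12
  i_ax <- m * (a$frustum_a1_m^2 + a$frustum_b1_m^2) / 4
  list(mass_kg = m,
       inertia_kg_m2 = diag(c(i_tr, i_tr, i_ax)),
       com_distance_m = a$com_fraction * L)
}

#' Default trunk anthropometry
#'
#' Torso frustum semi-axes taper from 0.16 x 0.11 m at the lumbar end to
#' 0.14 x 0.09 m at the shoulder end over 0.45 m at soft-tissue density
#' 1050 kg/m^3 (about 22 kg above the lumbar joint); the trunk line is
#' 0.45 m long with its centre of mass at 45% of the way up.
#'
#' @export
default_anthropometry <- function() {
  list(frustum_a1_m = 0.16, frustum_b1_m = 0.11,
       frustum_a2_m = 0.14, frustum_b2_m = 0.09,
       frustum_h_m = 0.45, density_kg_m3 = 1050,
       trunk_length_m = 0.45, com_fraction = 0.45)
}
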