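# Shared fixtures. Heavy objects (lumbar meshes, solved load cases) are
# built once per test run and cached in this environment.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# Noise-free trial for an action, cached.
trial_for <- function(action, noise = 0, seed = 0) {
  cached(paste0("trial_", action, "_", noise, "_", seed),
         generate_trial(default_action_template(action, noise_sd_mm = noise,
                                                seed = seed)))
}

# Coarse lumbar mesh used by the solver-level tests.
test_edge_mm <- 6

lumbar_mesh_coarse <- function() {
  cached("lumbar_mesh_coarse", {
    params <- lumbar_geometry_params(target_edge_mm = test_edge_mm)
    assign_materials(mesh_geometry(build_geometry(params)))
  })
}

lumbar_system_coarse <- function() {
  cached("lumbar_system", assemble_system(lumbar_mesh_coarse()))
}

# Solved load case (1425 N + first-peak moment) per action, cached.
lumbar_solution <- function(action) {
  moments <- c(DL = 749, SLDL = 893, TBDL = 640)
  cached(paste0("sol_", action), {
    mesh <- lumbar_mesh_coarse()
    lc <- build_load_case(mesh, action, moments[[action]])
    solve_static(lumbar_system_coarse(), lc)
  })
}

# Minimal mesh object built directly from arrays, for element-level and
# benchmark tests.
tiny_mesh <- function(nodes, tets, E, nu, part = "block", class = part) {
  m <- nrow(tets)
  structure(list(nodes = nodes, tets = tets,
                 tet_part = rep_len(part, m), tet_class = rep_len(class, m),
                 tet_E = rep_len(E, m), tet_nu = rep_len(nu, m),
                 lines = matrix(0L, 0, 2), line_part = character(0),
                 line_class = character(0), line_E = numeric(0),
                 line_nu = numeric(0), line_area_mm2 = 0,
                 z_planes = sort(unique(nodes[, 3])),
                 surface_tris = NULL, npp = NA_integer_,
                 materials = data.frame()),
            class = "lumbar_mesh")
}

# Homogeneous block mesh with materials bound.
block_mesh <- function(lx = 10, ly = 10, lz = 10, edge = 2.5,
                       E = 100, nu = 0) {
  mesh <- mesh_geometry(block_solid(lx, ly, lz), edge)
  assign_materials(mesh, data.frame(name = "block",
                                    elastic_modulus_MPa = E,
                                    poisson_ratio = nu,
                                    constitutive_tag = "test"))
}

# Two-material composite column (side-by-side bars sharing the top face),
# split by the x coordinate; materials named after the bone classes so the
# sensitivity machinery can address them.
composite_mesh <- function(lx = 10, ly = 10, lz = 20, edge = 2.5,
                           E1 = 12000, E2 = 100) {
  mesh <- mesh_geometry(block_solid(lx, ly, lz), edge)
  ctr <- (mesh$nodes[mesh$tets[, 1], 1] + mesh$nodes[mesh$tets[, 2], 1] +
          mesh$nodes[mesh$tets[, 3], 1] + mesh$nodes[mesh$tets[, 4], 1]) / 4
  left <- ctr < lx / 2
  mesh$tet_part <- ifelse(left, "stiff", "soft")
  mesh$tet_class <- ifelse(left, "cortical", "cancellous")
  assign_materials(mesh, data.frame(
    name = c("stiff", "soft"),
    elastic_modulus_MPa = c(E1, E2),
    poisson_ratio = c(0, 0),
    constitutive_tag = "test"))
}

# Uniform-compression solve of a composite column under a prescribed top
# displacement (rigid platen): returns per-material mean axial stress and
# the total platen reaction.
platen_compression <- function(mesh, delta = -0.01) {
  sys <- assemble_system(mesh)
  zmax <- max(mesh$nodes[, 3]); zmin <- min(mesh$nodes[, 3])
  top <- which(abs(mesh$nodes[, 3] - zmax) < 1e-9)
  bot <- which(abs(mesh$nodes[, 3] - zmin) < 1e-9)
  sol <- solve_static(sys, fixed_nodes = bot,
                      prescribed = list(dofs = 3 * (top - 1) + 3,
                                        values = rep(delta, length(top))))
  szz <- tapply(sol$stress$szz, sol$stress$part, mean)
  reac <- sol$reactions
  topd <- 3 * (top - 1) + 3
  list(szz = szz, total_force = sum(reac$force_N[reac$dof %in% topd]),
       sol = sol)
}
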