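# Independent constant-strain tetrahedron stiffness: shape-function
# gradients from a Vandermonde solve and K = V B' D B assembled explicitly.
cst_stiffness_oracle <- function(coords, E, nu) {
  A <- cbind(1, coords)
  C <- solve(A)            # row 2:4 of column a = grad of N_a
  grads <- t(C[2:4, ])
  V <- abs(det(A)) / 6
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  B <- matrix(0, 6, 12)
  for (a in 1:4) {
    g <- grads[a, ]
    cc <- 3 * (a - 1)
    B[1, cc + 1] <- g[1]; B[2, cc + 2] <- g[2]; B[3, cc + 3] <- g[3]
    B[4, cc + 1] <- g[2]; B[4, cc + 2] <- g[1]
    B[5, cc + 2] <- g[3]; B[5, cc + 3] <- g[2]
    B[6, cc + 1] <- g[3]; B[6, cc + 3] <- g[1]
  }
  V * t(B) %*% D %*% B
}

test_that("single-element stiffness matches the closed-form CST matrix", {
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  for (nu in c(0, 0.3)) {
    mesh <- tiny_mesh(coords, matrix(1:4, 1), E = 1, nu = nu)
    sys <- assemble_system(mesh)
    K <- as.matrix(sys$K)
    expect_equal(K, unname(cst_stiffness_oracle(coords, 1, nu)),
                 tolerance = 1e-12)
  }
  # a skewed element too
  coords2 <- rbind(c(0.1, 0.2, 0), c(1.3, 0.1, 0.2), c(0.2, 1.1, -0.1),
                   c(0.4, 0.3, 0.9))
  mesh2 <- tiny_mesh(coords2, matrix(1:4, 1), E = 7, nu = 0.25)
  expect_equal(as.matrix(assemble_system(mesh2)$K),
               unname(cst_stiffness_oracle(coords2, 7, 0.25)),
               tolerance = 1e-12)
})

test_that("assembled operators are exactly symmetric", {
  sys <- assemble_system(block_mesh(5, 5, 5, 2.5, E = 100, nu = 0.3))
  expect_lt(max(abs(sys$K - Matrix::t(sys$K))),
            1e-9 * max(abs(sys$K)))
})

test_that("disconnected parts with one fixed part are singular", {
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                  c(5, 5, 5), c(6, 5, 5), c(5, 6, 5), c(5, 5, 6))
  mesh <- tiny_mesh(coords, rbind(1:4, 5:8), E = 1, nu = 0)
  sys <- assemble_system(mesh)
  f <- numeric(24); f[24] <- 1
  suppressWarnings(
    expect_error(solve_static(sys, f = f, fixed_nodes = 1:4),
                 "solver error"))
  expect_error(solve_static(sys, f = f), "singular")
})

test_that("uniform pressure patch test yields the uniaxial state", {
  mesh <- block_mesh(10, 10, 10, 2.5, E = 100, nu = 0)
  sys <- assemble_system(mesh)
  bot <- which(abs(mesh$nodes[, 3]) < 1e-9)
  top <- lumbarlift:::surface_node_weights(mesh, "top")
  p <- 2
  f <- numeric(sys$ndof)
  f[3 * (top$nodes - 1) + 3] <- -p * top$weights
  sol <- solve_static(sys, f = f, fixed_nodes = bot)
  interior <- sol$stress$cz > 2 & sol$stress$cz < 8
  expect_equal(mean(sol$stress$von_mises[interior]), p, tolerance = 0.01)
  expect_lt(max(abs(sol$stress$von_mises[interior] - p)) / p, 0.01)
  expect_lt(sol$report$relative_residual, 1e-8)
  # equilibrium: boundary reactions balance the applied load
  rz <- sol$reactions$force_N[sol$reactions$dof %% 3 == 0]
  expect_equal(sum(rz), -sum(f), tolerance = 1e-6 * abs(sum(f)))
  # linearity: doubling the load exactly doubles every stress
  sol2 <- solve_static(sys, f = 2 * f, fixed_nodes = bot)
  expect_equal(sol2$stress$von_mises, 2 * sol$stress$von_mises,
               tolerance = 1e-10)
  # zero load, zero field
  sol0 <- solve_static(sys, f = numeric(sys$ndof), fixed_nodes = bot)
  expect_equal(max(sol0$stress$von_mises), 0, tolerance = 1e-12)
})

test_that("hydrostatic stress has zero von Mises intensity", {
  s <- cbind(sxx = -7, syy = -7, szz = -7, sxy = 0, syz = 0, szx = 0)
  expect_equal(unname(von_mises_stress(s)), 0)
  # and a uniaxial state returns its magnitude
  expect_equal(unname(von_mises_stress(cbind(3, 0, 0, 0, 0, 0))), 3)
})

test_that("composite column shares load in proportion to E_i A_i", {
  E1 <- 12000; E2 <- 100
  mesh <- composite_mesh(10, 10, 20, 2.5, E1, E2)
  out <- platen_compression(mesh)
  A <- 50  # mm^2 per material
  F <- out$total_force
  expect_equal(unname(out$szz["stiff"]), F * E1 / (E1 * A + E2 * A),
               tolerance = 0.02)
  expect_equal(unname(out$szz["soft"]), F * E2 / (E1 * A + E2 * A),
               tolerance = 0.02)
  # uniform field: the peak equals the mean within each material
  st <- out$sol$stress
  for (p in c("stiff", "soft")) {
    vm <- st$von_mises[st$part == p]
    expect_equal(max(vm), mean(vm), tolerance = 1e-9)
  }
})

test_that("strain energy converges monotonically on the bending benchmark", {
  # end couple on a square-section cantilever block; exact energy
  # M^2 L / (2 E I) for the beam solution
  E <- 100; lx <- 4; ly <- 4; lz <- 20; M <- 50
  energy <- function(edge) {
    mesh <- block_mesh(lx, ly, lz, edge, E = E, nu = 0)
    sys <- assemble_system(mesh)
    top <- lumbarlift:::surface_node_weights(mesh, "top")
    x <- mesh$nodes[top$nodes, 1]
    w <- top$weights / sum(top$weights)
    xbar <- sum(w * x)
    cc <- M / sum(w * (x - xbar)^2)
    f <- numeric(sys$ndof)
    f[3 * (top$nodes - 1) + 3] <- -cc * w * (x - xbar)
    bot <- which(abs(mesh$nodes[, 3]) < 1e-9)
    sol <- solve_static(sys, f = f, fixed_nodes = bot)
    sum(f * as.vector(t(sol$u))) / 2
  }
  I <- ly * lx^3 / 12
  exact <- M^2 * lz / (2 * E * I)
  errs <- abs(vapply(c(2, 1.4, 1), energy, numeric(1)) - exact)
  expect_true(all(diff(errs) < 0))
})

test_that("peak queries resolve parts, classes and discs", {
  sol <- lumbar_solution("DL")
  expect_gt(peak_stress_by_part(sol, "L5 cortical"), 0)
  expect_gte(peak_stress_by_part(sol, "cortical"),
             peak_stress_by_part(sol, "L5 cortical"))
  expect_gt(peak_stress_by_part(sol, "L4-L5"), 0)
  expect_error(peak_stress_by_part(sol, "T12 cortical"), "no elements")
})

test_that("bone load sharing follows the cortical-dominance ordering", {
  for (act in c("DL", "SLDL", "TBDL")) {
    sol <- lumbar_solution(act)
    # dense cortical bone carries far more stress than cancellous bone
    expect_gt(peak_stress_by_part(sol, "cortical"),
              peak_stress_by_part(sol, "cancellous"))
  }
  # L5 carries the largest cortical peak of all vertebrae
  sol <- lumbar_solution("DL")
  l5 <- peak_stress_by_part(sol, "L5 cortical")
  for (v in c("L1", "L2", "L3", "L4")) {
    expect_gte(l5, peak_stress_by_part(sol, paste(v, "cortical")))
  }
})

test_that("stress ordering across actions follows the injury-risk gradient", {
  for (part in c("L5 cortical", "L5 cancellous", "L4-L5")) {
    p <- vapply(c("SLDL", "DL", "TBDL"), function(a)
      peak_stress_by_part(lumbar_solution(a), part), numeric(1))
    expect_true(p[["SLDL"]] > p[["DL"]] && p[["DL"]] > p[["TBDL"]])
  }
})
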