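test_that("geometry parameters are validated", {
  expect_error(lumbar_geometry_params(vertebra_height_mm = -2), "positive")
  expect_error(lumbar_geometry_params(nucleus_radius_frac = 0.5),
               "annulus layer fractions")
  expect_error(lumbar_geometry_params(annulus_layer_fracs = c(0.3, 0.3)),
               "three positive fractions")
  # offset must stay below the smallest cross-section semi-axis
  expect_error(build_geometry(lumbar_geometry_params(cortical_offset_mm = 17)),
               "impossible")
})

test_that("the default geometry has the canonical part census", {
  mesh <- lumbar_mesh_coarse()
  cen <- mesh_census(mesh)
  counts <- stats::setNames(cen$n_parts, cen$class)
  expect_identical(unname(counts["cortical"]), 5)
  expect_identical(unname(counts["cancellous"]), 5)
  expect_identical(unname(counts["nucleus"]), 4)
  expect_identical(unname(counts["endplate"]), 8)
  # 12 annulus layer parts across the three concentric layers
  expect_identical(unname(counts["annulus_inner"] + counts["annulus_middle"] +
                          counts["annulus_outer"]), 12)
  # six ligament groups
  lig <- cen[startsWith(cen$class, "lig_"), ]
  expect_identical(nrow(lig), 6L)
  # every part label is populated even at coarse resolution
  expect_true(all(cen$n_elements > 0))
})

test_that("the cortical shell honours the normal offset everywhere", {
  mesh <- lumbar_mesh_coarse()
  sec <- mesh$section
  thick <- sqrt(rowSums((sec$outer - sec$cortical_inner)^2))
  expect_equal(thick, rep(1, nrow(sec$outer)), tolerance = 1e-9)
})

test_that("meshing is deterministic and produces a valid tessellation", {
  params <- lumbar_geometry_params(target_edge_mm = 9)
  m1 <- mesh_geometry(build_geometry(params))
  m2 <- mesh_geometry(build_geometry(params))
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$tets, m2$tets)
  v <- lumbarlift:::tet_signed_volumes(m1$nodes, m1$tets)
  expect_true(all(v > 0))
  # no orphan nodes
  expect_identical(sort(unique(as.vector(m1$tets))), seq_len(nrow(m1$nodes)))
})

test_that("block control mesh is watertight and covers the volume", {
  mesh <- mesh_geometry(block_solid(1, 1, 1), 0.5)
  v <- lumbarlift:::tet_signed_volumes(mesh$nodes, mesh$tets)
  expect_true(all(v > 0))
  expect_equal(sum(v), 1, tolerance = 1e-12)
  # every interior face is shared by exactly two tets, boundary by one;
  # boundary area must equal the cube surface
  Tt <- mesh$tets
  faces <- rbind(Tt[, c(1, 2, 3)], Tt[, c(1, 2, 4)],
                 Tt[, c(1, 3, 4)], Tt[, c(2, 3, 4)])
  key <- apply(t(apply(faces, 1, sort)), 1, paste, collapse = "-")
  counts <- table(key)
  expect_true(all(counts %in% c(1L, 2L)))
  bnd <- faces[key %in% names(counts)[counts == 1L], , drop = FALSE]
  tri_area <- function(f) {
    a <- mesh$nodes[f[2], ] - mesh$nodes[f[1], ]
    b <- mesh$nodes[f[3], ] - mesh$nodes[f[1], ]
    sqrt(sum(c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
               a[1] * b[2] - a[2] * b[1])^2)) / 2
  }
  expect_equal(sum(apply(bnd, 1, tri_area)), 6, tolerance = 1e-12)
})

test_that("median edge length tracks the target", {
  mesh <- lumbar_mesh_coarse()
  med <- mesh_edge_lengths(mesh)[["median"]]
  expect_gt(med, 0.7 * test_edge_mm)
  expect_lt(med, 1.3 * test_edge_mm)
})

test_that("part volumes are stable under re-meshing and scale cubically", {
  p1 <- lumbar_geometry_params(target_edge_mm = 8)
  v1 <- mesh_part_volumes(mesh_geometry(build_geometry(p1)))
  v2 <- mesh_part_volumes(mesh_geometry(build_geometry(p1), 6.5))
  expect_equal(v1[sort(names(v1))], v2[sort(names(v2))], tolerance = 0.02)
  # doubling all linear dimensions multiplies volumes by 8
  p2 <- lumbar_geometry_params(vertebra_width_mm = 88, vertebra_depth_mm = 68,
                               vertebra_height_mm = 54, cortical_offset_mm = 2,
                               disc_height_mm = 20, endplate_thickness_mm = 1,
                               target_edge_mm = 16)
  v8 <- mesh_part_volumes(mesh_geometry(build_geometry(p2)))
  expect_equal(v8[sort(names(v8))], 8 * v1[sort(names(v1))],
               tolerance = 1e-6)
})

test_that("materials bind by part class with the tabulated constants", {
  mesh <- lumbar_mesh_coarse()
  expect_equal(unique(mesh$tet_E[mesh$tet_class == "cortical"]), 12000)
  expect_equal(unique(mesh$tet_nu[mesh$tet_class == "cortical"]), 0.3)
  expect_equal(unique(mesh$tet_E[mesh$tet_class == "cancellous"]), 100)
  expect_equal(unique(mesh$tet_nu[mesh$tet_class == "cancellous"]), 0.2)
  # nucleus: incompressible in the table, clamped at binding
  expect_equal(unique(mesh$tet_E[mesh$tet_class == "nucleus"]), 1)
  expect_equal(unique(mesh$tet_nu[mesh$tet_class == "nucleus"]), 0.4999)
  expect_equal(unique(mesh$line_E[mesh$line_part == "ALL"]), 8)
  tab <- material_table()
  expect_identical(nrow(tab), 13L)
  expect_error(assign_materials(mesh_geometry(build_geometry(
    lumbar_geometry_params(target_edge_mm = 9))),
    tab[tab$name != "Cartilaginous endplate", ]),
    "binding error.*endplate")
})

test_that("load cases reproduce their nominal totals", {
  mesh <- lumbar_mesh_coarse()
  lc <- build_load_case(mesh, "DL", 749)
  expect_identical(lc$vertical_load_N, 1425)
  tot <- loadcase_totals(mesh, lc)
  expect_equal(tot$total_vertical_N, -1425, tolerance = 1e-9)
  expect_equal(tot$net_moment_Nm, 749, tolerance = 1e-6)
  # moment from a torque series: the first-peak torque
  tq <- cached("torque_SLDL", lumbar_torque_series(trial_for("SLDL")))
  lc2 <- build_load_case(mesh, "SLDL", tq)
  expect_equal(lc2$sagittal_moment_Nm, first_peak_torque(tq))
  # a zero-moment case is pure compression
  lc0 <- build_load_case(mesh, "DL", 0)
  xi <- setdiff(seq_along(lc0$f), 3 * (seq_len(nrow(mesh$nodes)) - 1) + 3)
  expect_true(all(lc0$f[xi] == 0))
  expect_equal(sum(lc0$f), -1425, tolerance = 1e-9)
  expect_error(build_load_case(mesh, "DL", -5), "non-negative")
})
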