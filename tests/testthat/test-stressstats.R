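# A synthetic "disc" stress table on a regular grid: 3k x 3k centroids.
grid_stress_table <- function(k = 6, vm = NULL) {
  xy <- seq_len(3 * k)
  d <- expand.grid(cx = xy, cy = xy)
  n <- nrow(d)
  data.frame(element = seq_len(n), part = "D1 nucleus", class = "nucleus",
             cx = d$cx, cy = d$cy, cz = 0,
             von_mises = if (is.null(vm)) rep(1, n) else vm)
}

test_that("a uniform 9n grid partitions into nine equal regions", {
  st <- grid_stress_table(6)
  grid <- partition_disc(st, "D1")
  tab <- table(grid$region)
  expect_identical(sort(names(tab)), LETTERS[1:9])
  expect_true(all(tab == nrow(st) / 9))
})

test_that("the solved disc grid is complete, disjoint and centred", {
  sol <- lumbar_solution("DL")
  grid <- partition_disc(sol, "L4-L5")
  disc_n <- sum(lumbarlift:::disc_elements(sol$stress, "L4-L5"))
  expect_identical(nrow(grid), disc_n)           # completeness
  expect_identical(anyDuplicated(grid$element), 0L)
  expect_identical(length(unique(grid$region)), 9L)
  expect_true(all(table(grid$region) > 0))
  # the nucleus centroid lies in the central region E
  nc <- attr(grid, "nucleus_centroid")
  e <- grid[grid$region == "E", ]
  expect_true(nc[1] >= min(e$cx) && nc[1] <= max(e$cx))
  expect_true(nc[2] >= min(e$cy) && nc[2] <= max(e$cy))
})

test_that("region statistics and quantitative-difference classes", {
  sol <- lumbar_solution("DL")
  grid <- partition_disc(sol, "L4-L5")
  rs <- region_stats(grid)
  expect_identical(rs$region, LETTERS[1:9])
  # the reference region contrasts to zero with itself
  expect_equal(rs$quantitative_difference[rs$region == "E"], 0)
  expect_identical(rs$significance[rs$region == "E"], "not significant")
  expect_equal(rs$cv, rs$sd_MPa / rs$mean_MPa)
  # peripheral stress pattern: the central region has the lowest mean
  expect_true(all(rs$mean_MPa[rs$region == "E"] <
                  rs$mean_MPa[rs$region != "E"]))
})

test_that("identical element multisets contrast to zero and QD is
           symmetric", {
  x <- c(1, 2, 3, 4); y <- c(2, 3, 5, 8)
  expect_equal(lumbarlift:::pooled_qd(x, x), 0)
  expect_equal(lumbarlift:::pooled_qd(x, y), lumbarlift:::pooled_qd(y, x))
  # zero iff means are equal
  expect_equal(lumbarlift:::pooled_qd(c(1, 3), c(2, 2)), 0)
  expect_gt(lumbarlift:::pooled_qd(c(1, 3), c(4, 6)), 0)
})

test_that("QD classification is monotone across the beta/gamma boundaries", {
  th <- threshold_config()
  classify <- function(qd) {
    if (qd <= th$beta) "not significant"
    else if (qd < th$gamma) "significant"
    else "very significant"
  }
  # 1.22 sits between beta = 0.8 and gamma = 1.27: significant but not very
  expect_identical(classify(1.22), "significant")
  expect_identical(classify(0.5), "not significant")
  expect_identical(classify(1.27), "very significant")
  qds <- c(0, 0.4, 0.8, 1.0, 1.22, 1.27, 2, 4)
  lev <- match(vapply(qds, classify, ""), c("not significant",
                                            "significant",
                                            "very significant"))
  expect_true(all(diff(lev) >= 0))
})

test_that("risk exceedance arithmetic matches the worked examples", {
  th <- threshold_config()
  rr <- risk_assessment(
    data.frame(part = c("L4-L5 disc", "L5 cortical", "boundary"),
               class = c("disc", "cortical", "disc"),
               peak_MPa = c(45.6, 997, 40)), th)
  expect_equal(rr$exceedance_pct[1], 14)
  expect_true(rr$exceeded[1])
  expect_equal(rr$exceedance_pct[2], -0.3)
  expect_false(rr$exceeded[2])
  # a peak exactly at the threshold: zero exceedance, not flagged
  expect_equal(rr$exceedance_pct[3], 0)
  expect_false(rr$exceeded[3])
  expect_error(risk_assessment(data.frame(part = "x", class = "tendon",
                                          peak_MPa = 1), th),
               "unknown part class")
})

test_that("risk exceedance is strictly increasing in the peak and is -100%
           at zero stress", {
  th <- threshold_config()
  peaks <- seq(0, 80, by = 5)
  rr <- risk_assessment(data.frame(part = paste0("p", peaks),
                                   class = "disc", peak_MPa = peaks), th)
  expect_true(all(diff(rr$exceedance_pct) > 0))
  expect_equal(rr$exceedance_pct[1], -100)
})

test_that("validation arithmetic reproduces the reference relative errors", {
  vr <- validation_report(c(
    "L5 cortical peak stress (MPa)" = 815,
    "L4-L5 disc peak stress (MPa)" = 36.9,
    "L5 trabecular peak stress (MPa)" = 2.6,
    "Lumbar compression stiffness (N/mm)" = 1250))
  expect_equal(vr$relative_error_pct,
               c(0.6, 1.6, 4.0, 1.6))
  expect_true(all(vr$within_range))
  # exact agreement gives a 0.0% error
  lit <- literature_reference()
  vr0 <- validation_report(stats::setNames(lit$lit_mean[1],
                                           lit$indicator[1]))
  expect_equal(vr0$relative_error_pct, 0)
  expect_error(validation_report(
    c(a = 1), data.frame(indicator = "a", lit_mean = 0, lit_sd = 1)),
    "zero")
})

test_that("pure vertical load perturbation scales the stress exactly", {
  mesh <- block_mesh(6, 6, 12, 3, E = 100, nu = 0.3)
  lc <- build_load_case(mesh, "bench", 0, vertical_load_N = 100)
  sens <- sensitivity_analysis(mesh, lc,
                               cases = data.frame(parameter = "vertical_load",
                                                  amplitude_pct = 5),
                               response_part = "block")
  expect_equal(sens$change_high_pct, 5, tolerance = 1e-9)
  expect_equal(sens$change_low_pct, -5, tolerance = 1e-9)
})

test_that("modulus perturbations on the composite stay below the parallel
           bound", {
  E1 <- 12000; E2 <- 100; A <- 50
  mesh <- composite_mesh(10, 10, 20, 2.5, E1, E2)
  base <- platen_compression(mesh)
  mesh_p <- mesh
  mesh_p$tet_E[mesh_p$tet_class == "cortical"] <- 1.1 * E1
  pert <- platen_compression(mesh_p)
  # normalise by the platen reaction: force-controlled change rate
  change <- (pert$szz["stiff"] / pert$total_force) /
            (base$szz["stiff"] / base$total_force) - 1
  closed <- (1.1 * E1 / (1.1 * E1 * A + E2 * A)) /
            (E1 / (E1 * A + E2 * A)) - 1
  expect_equal(unname(change), closed, tolerance = 1e-6)
  expect_lt(abs(change), 0.10)
})

test_that("the lumbar model is far less sensitive to the nucleus modulus
           than to the cortical modulus", {
  mesh <- lumbar_mesh_coarse()
  lc <- build_load_case(mesh, "DL", 749)
  sens <- cached("sens_coarse", sensitivity_analysis(
    mesh, lc, cases = data.frame(parameter = c("cortical_modulus",
                                               "nucleus_modulus"),
                                 amplitude_pct = c(10, 20))))
  cort <- sens$max_abs_change_pct[sens$parameter == "cortical_modulus"]
  nuc <- sens$max_abs_change_pct[sens$parameter == "nucleus_modulus"]
  expect_lt(nuc, cort)
  # the modulus change rate never exceeds the perturbation itself
  expect_lt(cort, 10)
  expect_error(sensitivity_analysis(
    mesh, lc, cases = data.frame(parameter = "cortical_modulus",
                                 amplitude_pct = 110)),
    "non-positive")
})
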