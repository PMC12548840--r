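world0 <- list(gravity = c(0, 0, -9.81))

test_that("static limit reduces to the closed-form gravity moment", {
  inertia <- list(mass_kg = 40, inertia_kg_m2 = diag(3))
  st <- list(omega = c(0, 0, 0), alpha = c(0, 0, 0),
             r_c = c(0.25, 0, 0), a_c = c(0, 0, 0))
  out <- newton_euler_torque(st, inertia, list(), world0)
  expect_equal(out$sagittal_torque_Nm, 40 * 9.81 * 0.25, tolerance = 1e-12)
  # upright trunk: no gravity moment
  st$r_c <- c(0, 0, 0.25)
  expect_equal(newton_euler_torque(st, inertia, list(),
                                   world0)$sagittal_torque_Nm, 0,
               tolerance = 1e-12)
})

test_that("pure angular acceleration about Y gives I_yy * alpha", {
  inertia <- list(mass_kg = 10, inertia_kg_m2 = diag(c(1, 2.5, 1)))
  st <- list(omega = c(0, 0, 0), alpha = c(0, 3, 0),
             r_c = c(0, 0, 0), a_c = c(0, 0, 0))
  out <- newton_euler_torque(st, inertia, list(),
                             list(gravity = c(0, 0, 0)))
  expect_equal(out$moment_Nm, c(0, 2.5 * 3, 0), tolerance = 1e-12)
})

test_that("non-finite states are rejected", {
  inertia <- list(mass_kg = 1, inertia_kg_m2 = diag(3))
  st <- list(omega = c(0, NA, 0), alpha = c(0, 0, 0),
             r_c = c(0, 0, 0), a_c = c(0, 0, 0))
  expect_error(newton_euler_torque(st, inertia, list(), world0),
               "non-finite")
})

test_that("full inverse-dynamics pipeline recovers the template peaks", {
  targets <- c(DL = 749, SLDL = 893, TBDL = 640)
  peak_times <- numeric(0)
  for (act in names(targets)) {
    tq <- cached(paste0("torque_", act),
                 lumbar_torque_series(trial_for(act)))
    pk <- first_peak_torque(tq)
    expect_lt(abs(pk - targets[[act]]) / targets[[act]], 0.02)
    seg <- segment_phases(tq)
    peak_times[act] <- tq$time_s[attr(seg, "peaks")[1]]
    # the second peak stays below the first for every template
    expect_lt(tq$torque_Nm[attr(seg, "peaks")[2]], pk)
  }
  # the stiff-legged first peak appears earlier than the conventional one
  expect_lt(peak_times["SLDL"], peak_times["DL"])
})

test_that("torque recovery stays within 2% at default marker noise", {
  trial <- trial_for("DL", noise = 0.5)
  pk <- first_peak_torque(lumbar_torque_series(trial))
  expect_lt(abs(pk - 749) / 749, 0.02)
})

test_that("zero-motion trial reduces to the constant static moment", {
  # trunk frozen mid-flexion, no external load: the torque series must be
  # the closed-form gravity moment at every frame
  trial <- trial_for("DL")
  mk <- trial$markers
  for (cc in setdiff(names(mk), c("frame", "time_s"))) {
    mk[[cc]] <- mk[[cc]][1]
  }
  grf <- trial$grf
  grf[c("Fx", "Fy", "Fz", "COPx", "COPy")] <- 0
  still <- list(markers = mk, grf = grf, config = trial$config)
  tq <- lumbar_torque_series(still)
  inertia <- trunk_inertia(trial$config$anthropometry)
  theta0 <- trial$segment_states$theta_rad[1]
  expected <- inertia$mass_kg * 9.81 * inertia$com_distance_m * sin(theta0)
  expect_equal(tq$torque_Nm, rep(expected, nrow(tq)), tolerance = 1e-6)
})

test_that("phase segmentation places boundaries at the peaks and trough", {
  # constructed curve: peaks at 25% and 75% of the frames, trough at 50%
  n <- 201L
  y <- stats::approx(x = c(1, 51, 101, 151, n),
                     y = c(0.5, 1, 0.2, 0.8, 0.3), xout = 1:n)$y
  seg <- segment_phases(y)
  expect_identical(attr(seg, "peaks"), c(51L, 151L))
  expect_identical(attr(seg, "trough"), 101L)
  expect_identical(nrow(seg), 4L)
  expect_identical(seg$phase,
                   c("first_pull", "transition", "second_pull", "standing"))
  # phases tile the series contiguously
  expect_identical(seg$start_frame[-1], seg$end_frame[-4])
  expect_identical(seg$start_frame[1], 1L)
  expect_identical(seg$end_frame[4], n)
})

test_that("default trials segment into exactly four phases with two peaks", {
  for (act in c("DL", "SLDL", "TBDL")) {
    tq <- cached(paste0("torque_", act),
                 lumbar_torque_series(trial_for(act)))
    seg <- segment_phases(tq)
    expect_identical(nrow(seg), 4L)
    expect_identical(length(attr(seg, "peaks")), 2L)
  }
})

test_that("monotone curves cannot be segmented", {
  expect_error(segment_phases(seq(0, 100, length.out = 50)),
               "two interior torque peaks")
})

test_that("appending idle frames does not move interior boundaries", {
  tq <- cached("torque_DL", lumbar_torque_series(trial_for("DL")))
  seg <- segment_phases(tq)
  padded <- c(tq$torque_Nm, rep(tq$torque_Nm[nrow(tq)], 40))
  seg2 <- segment_phases(padded)
  expect_identical(attr(seg2, "peaks"), attr(seg, "peaks"))
  expect_identical(attr(seg2, "trough"), attr(seg, "trough"))
})
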