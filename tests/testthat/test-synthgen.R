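# Exact inverse dynamics on a trial's own stored states and loads, no
# filtering or differencing: the generator's consistency contract.
exact_recovered_torque <- function(trial) {
  st <- trial$segment_states
  inertia <- trunk_inertia(trial$config$anthropometry)
  dec <- seq(1, nrow(trial$grf),
             by = trial$config$force_hz / trial$config$marker_hz)
  vapply(seq_len(nrow(st)), function(i) {
    g <- trial$grf[dec[i], ]
    barz <- (trial$markers$BAR_L_Z[i] + trial$markers$BAR_R_Z[i]) / 2 / 1000
    state <- list(omega = c(0, st$omega_y[i], 0),
                  alpha = c(0, st$alpha_y[i], 0),
                  r_c = c(st$com_x[i] - st$joint_x[i],
                          st$com_y[i] - st$joint_y[i],
                          st$com_z[i] - st$joint_z[i]),
                  a_c = c(st$acom_x[i], st$acom_y[i], st$acom_z[i]))
    loads <- list(list(force = c(g$Fx, g$Fy, g$Fz),
                       point = c(g$COPx / 1000 - st$joint_x[i],
                                 g$COPy / 1000 - st$joint_y[i],
                                 barz - st$joint_z[i])))
    newton_euler_torque(state, inertia, loads)$sagittal_torque_Nm
  }, numeric(1))
}

test_that("noise-free trials are exactly consistent with the prescribed
           torque at every frame", {
  for (act in c("DL", "SLDL", "TBDL")) {
    trial <- trial_for(act)
    rec <- exact_recovered_torque(trial)
    truth <- trial$truth_torque$torque_Nm
    expect_lt(max(abs(rec - truth) / max(abs(truth))), 1e-6)
  }
})

test_that("trials are deterministic given a seed, and seeds only change the
           noise", {
  a <- generate_trial(default_action_template("DL", seed = 0))
  b <- generate_trial(default_action_template("DL", seed = 0))
  expect_identical(a$markers, b$markers)
  expect_identical(a$grf, b$grf)
  c2 <- generate_trial(default_action_template("DL", seed = 1))
  expect_false(identical(a$markers, c2$markers))
  # force series and ground truth carry no noise
  expect_identical(a$grf, c2$grf)
  expect_identical(a$truth_torque, c2$truth_torque)
  # noise-free trials are seed-independent
  n0a <- generate_trial(default_action_template("DL", noise_sd_mm = 0,
                                                seed = 0))
  n0b <- generate_trial(default_action_template("DL", noise_sd_mm = 0,
                                                seed = 7))
  expect_identical(n0a$markers, n0b$markers)
})

test_that("stiff-legged start position has a horizontal trunk", {
  trial <- trial_for("SLDL")
  ang0 <- lumbar_flexion_angle(
    c(trial$markers$L5_X[1], trial$markers$L5_Y[1], trial$markers$L5_Z[1]),
    c(trial$markers$L1_X[1], trial$markers$L1_Y[1], trial$markers$L1_Z[1]))
  expect_equal(ang0, 90, tolerance = 1e-8)
})

test_that("sampling rates and layout follow the acquisition protocol", {
  trial <- trial_for("DL")
  expect_equal(nrow(trial$markers), 201)   # 2 s at 100 Hz
  expect_equal(nrow(trial$grf), 1001)      # 2 s at 500 Hz
  expect_true(all(c("L1_X", "L3_X", "L5_X", "T2_X", "C7_X",
                    "R_ASIS_X", "L_ASIS_X", "R_PSIS_X", "L_PSIS_X",
                    "BAR_L_X", "BAR_R_X") %in% names(trial$markers)))
  expect_false(anyNA(trial$markers))
  expect_error(trial_config(marker_hz = 100, force_hz = 433),
               "integer multiple")
})
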