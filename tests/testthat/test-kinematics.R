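test_that("pose series recovers a prescribed pure sagittal rotation", {
  # static trajectory: identity-relative poses throughout
  rom0 <- default_rom(); rom0$flexion_deg <- rom0$extension_deg <- 0
  g0 <- generate_trajectory(the_model, quick_scenario(rom = rom0))
  ps <- pose_series(g0$trajectory, the_model, "C1")
  expect_false(any(ps$missing))
  for (f in seq(1, n_frames(g0$trajectory), by = 40)) {
    expect_equal(ps$R[, , f], diag(3), tolerance = 1e-9)
  }

  # 10-degree flexion about the C1-C2 axis, recovered to machine precision
  rom10 <- default_rom(); rom10$flexion_deg <- c(0, 10, 0)
  rom10$extension_deg <- 0
  g <- generate_trajectory(the_model, quick_scenario(rom = rom10))
  up <- pose_series(g$trajectory, the_model, "C1")
  lo <- pose_series(g$trajectory, the_model, "C2")
  ang <- relative_angle(up, lo, the_model)
  expect_equal(max(ang$theta_deg), 10, tolerance = 1e-6)
})

test_that("relative angle is zero when upper and lower move together", {
  g <- generate_trajectory(the_model, quick_scenario("instability"))
  ps <- pose_series(g$trajectory, the_model, "C1")
  ang <- relative_angle(ps, ps, the_model, joint = "C1C1")
  expect_true(all(abs(ang$theta_deg) < 1e-12))
  lo <- pose_series(g$trajectory, the_model, "C2")
  short <- lo; short$missing <- short$missing[1:10]
  expect_error(relative_angle(ps, short), "frame count")
})

test_that("noise-free pipeline reproduces the prescribed atlanto-axial angles", {
  for (cond in c("physiological", "instability")) {
    g <- generate_trajectory(the_model, quick_scenario(cond))
    kin <- kinematics_pipeline(g$trajectory, the_model, condition = cond)
    ref <- default_rom(cond)
    for (j in c("C0C1", "C1C2")) {
      expect_equal(kin$rom$flexion_deg[kin$rom$joint == j],
                   ref$flexion_deg[ref$joint == j], tolerance = 0.01)
      expect_equal(kin$rom$extension_deg[kin$rom$joint == j],
                   ref$extension_deg[ref$joint == j], tolerance = 0.01)
    }
  }
})

test_that("rom summary follows the sign convention and ignores frame order", {
  s <- data.frame(frame = 1:5, time_s = (0:4) / 500, joint = "C1C2",
                  theta_deg = c(0, 3.2, 1, -11.16, -2),
                  ap_translation_mm = 0, missing = FALSE)
  class(s) <- c("joint_angle_series", "data.frame")
  r <- rom_summary(s)
  expect_equal(r$flexion_deg, 3.2)
  expect_equal(r$extension_deg, 11.16)
  rev_s <- s[5:1, ]
  expect_equal(rom_summary(rev_s)[, 1:4], r[, 1:4])

  ramp <- s; ramp$theta_deg <- seq(0, 5.51, length.out = 5)
  rr <- rom_summary(ramp)
  expect_equal(rr$flexion_deg, 5.51)
  expect_equal(rr$extension_deg, 0)

  zero <- s; zero$theta_deg <- 0
  rz <- rom_summary(zero)
  expect_equal(c(rz$flexion_deg, rz$extension_deg), c(0, 0))

  all_na <- s; all_na$missing <- TRUE
  expect_error(rom_summary(all_na), "all-missing")
})

test_that("sagittal angles are additive across joints for moderate rotations", {
  rom <- default_rom()
  rom$flexion_deg <- c(7, 12, 0); rom$extension_deg <- c(10, 15, 0)
  g <- generate_trajectory(the_model, quick_scenario(rom = rom))
  c0 <- pose_series(g$trajectory, the_model, "C0")
  c2 <- pose_series(g$trajectory, the_model, "C2")
  ang02 <- relative_angle(c0, c2, the_model, joint = "C0C2")
  expect_equal(max(ang02$theta_deg), 7 + 12, tolerance = 0.1)
  expect_equal(-min(ang02$theta_deg), 10 + 15, tolerance = 0.1)
})

test_that("occluded frames are flagged without disturbing their neighbours", {
  g <- generate_trajectory(the_model, quick_scenario())
  tr <- g$trajectory
  k <- 50L
  tr$missing[k, tr$labels$vertebra == "C1"] <- TRUE
  ps <- pose_series(tr, the_model, "C1")
  expect_true(ps$missing[k])
  expect_false(any(ps$missing[-k]))
  lo <- pose_series(tr, the_model, "C2")
  ang <- relative_angle(ps, lo, the_model)
  expect_true(ang$missing[k])
  expect_true(is.finite(max(ang$theta_deg[-k])))
  expect_error(pose_series(tr, the_model, "C9"), "not present")
})

test_that("instability predicate applies strict thresholds on both branches", {
  expect_true(classify_instability(13.70, 0))
  expect_false(classify_instability(11.0, 3.5))
  expect_true(classify_instability(0, 3.6))
  expect_false(classify_instability(10.99, 3.49))
  expect_true(classify_instability(11.01, 0))
  expect_error(classify_instability(NaN, 0))
})
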