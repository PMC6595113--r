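test_that("tension-only spring force matches the published cell arithmetic", {
  expect_equal(spring_force(3.9, 11.6), 45.24, tolerance = 1e-12)
  expect_equal(spring_force(0.915, 28.6), 26.169, tolerance = 1e-12)
  expect_equal(spring_force(-1.0, 25.32), 0)
  expect_equal(spring_force(0, 25.32), 0)
  expect_error(spring_force(1, 0), "positive")
  # user-supplied nonlinear curve hook, still tension-only
  f <- spring_force(c(-1, 2), 1, force_curve = function(dl) 3 * dl^2)
  expect_equal(f, c(0, 12))
})

test_that("pressure is engineering stress over the effective area", {
  expect_equal(ligament_pressure(45.24, 50.1), 0.902994012, tolerance = 1e-9)
  expect_equal(ligament_pressure(29.34588, 10.3), 2.849114563, tolerance = 1e-9)
  expect_equal(ligament_pressure(0, 13.1), 0)
  expect_error(ligament_pressure(1, 0), "positive")
})

test_that("ligament length responds to poses as a straight-line spring", {
  s <- the_ligaments[the_ligaments$name == "apical_odontoid", ]
  idp <- list(C0 = rigid_pose(diag(3), the_model$vertebrae$C0$origin),
              C2 = rigid_pose(diag(3), the_model$vertebrae$C2$origin))
  L0 <- ligament_length(idp$C2, idp$C0, s, the_model)
  expect_equal(L0, s$rest_length_L0)
  # translate the insertion vertebra 1 mm along the ligament line
  p0 <- ucspine:::attachment_world(the_model, s$origin_vertebra, s$origin_point)
  p1 <- ucspine:::attachment_world(the_model, s$insertion_vertebra, s$insertion_point)
  u <- (p1 - p0) / sqrt(sum((p1 - p0)^2))
  moved <- rigid_pose(diag(3), the_model$vertebrae$C0$origin + u)
  expect_equal(ligament_length(idp$C2, moved, s, the_model), L0 + 1)
})

test_that("flexion stretches posterior ligaments and slackens anterior ones", {
  flex <- ucspine:::chain_poses(the_model, c(C0C1 = 8, C1C2 = 8, C2C3 = 5))
  neut <- ucspine:::chain_poses(the_model, c(C0C1 = 0, C1C2 = 0, C2C3 = 0))
  dl_of <- function(nm, poses) {
    s <- the_ligaments[the_ligaments$name == nm, ]
    ligament_length(poses[[s$origin_vertebra]], poses[[s$insertion_vertebra]],
                    s, the_model) - s$rest_length_L0
  }
  for (nm in c("flavum_c1c2", "flavum_c2c3", "interspinal_c1c2",
               "supraspinous", "posterior_longitudinal_c2c3")) {
    expect_gt(dl_of(nm, flex), 0)
  }
  expect_lte(dl_of("anterior_longitudinal_c1c2", flex), 0)
  # the alar ligament engages in extension
  ext <- ucspine:::chain_poses(the_model, c(C0C1 = -8, C1C2 = -8, C2C3 = -5))
  expect_gt(dl_of("alar", ext), 0)
  expect_equal(dl_of("alar", neut), 0, tolerance = 1e-12)
})

test_that("published state tables 2-4 are reproduced cell-exactly", {
  for (case in list(c("physiological", "flexion"),
                    c("physiological", "extension"),
                    c("instability", "flexion"))) {
    ref <- published_state_inputs(case[1], case[2])
    st <- build_state_table(setNames(ref$length_change_mm, ref$ligament),
                            the_ligaments, case[1], case[2])
    expect_lt(max(abs(st$stress_N - ref$stress_N_ref) / ref$stress_N_ref), 1e-6)
    expect_lt(max(abs(st$pressure_MPa - ref$pressure_MPa_ref) /
                    ref$pressure_MPa_ref), 1e-6)
    expect_identical(st$rigidity_N_mm, ref$rigidity_N_mm)
  }
})

test_that("the instability-extension table reproduces except its inconsistent rows", {
  ref <- published_state_inputs("instability", "extension")
  st <- build_state_table(setNames(ref$length_change_mm, ref$ligament),
                          the_ligaments, "instability", "extension")
  consistent <- !(ref$ligament %in% c("alar", "posterior_longitudinal_c2c3"))
  rel_F <- abs(st$stress_N - ref$stress_N_ref) / ref$stress_N_ref
  rel_P <- abs(st$pressure_MPa - ref$pressure_MPa_ref) / ref$pressure_MPa_ref
  expect_lt(max(rel_F[consistent], rel_P[consistent]), 0.005)
  # the comparison report flags exactly those two rows, in that table only
  cmp <- state_table_comparison(the_ligaments)
  flagged <- cmp[cmp$flagged, ]
  expect_identical(flagged$condition, rep("instability", 2))
  expect_identical(flagged$direction, rep("extension", 2))
  expect_setequal(flagged$ligament, c("alar", "posterior_longitudinal_c2c3"))
})

test_that("state-table construction validates names and preserves structure", {
  expect_error(build_state_table(c(nonexistent = 1), the_ligaments), "unknown")
  dl0 <- setNames(rep(0, nrow(the_ligaments)), the_ligaments$name)
  st0 <- build_state_table(dl0, the_ligaments)
  expect_true(all(st0$stress_N == 0))
  expect_true(all(st0$pressure_MPa == 0))
})

test_that("force is monotone in elongation and invariant to dl-k rescaling", {
  k <- 25.32
  dls <- seq(0.01, 3, length.out = 40)
  F <- spring_force(dls, k)
  expect_true(all(diff(F) > 0))
  expect_true(all(diff(ligament_pressure(F, 10.3)) > 0))
  # homogeneity: dl -> c*dl with k -> k/c leaves the force unchanged
  c_ <- 3.7
  expect_equal(spring_force(dls * c_, k / c_), F, tolerance = 1e-12)
})
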