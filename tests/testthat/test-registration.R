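test_that("identical triangles register to the identity pose", {
  tri <- matrix(c(0, 0, 0, 30, 0, 0, 0, 40, 0), 3, 3, byrow = TRUE)
  p <- fit_rigid_triangle(tri, tri)
  expect_equal(p$R, diag(3), tolerance = 1e-12)
  expect_equal(p$t, c(0, 0, 0), tolerance = 1e-12)
  expect_lt(attr(p, "rms_mm"), 1e-9)
})

test_that("triangle method recovers random rigid transforms exactly", {
  set.seed(101)
  for (i in 1:200) {
    tri <- random_triangle()
    pose <- random_pose()
    tgt <- apply_pose(pose, tri)
    rec <- fit_rigid_triangle(tri, tgt)
    expect_lt(max(abs(apply_pose(rec, tri) - tgt)), 1e-9)
    expect_lt(max(abs(rec$R - pose$R)), 1e-9)
  }
})

test_that("triangle method agrees with the Procrustes oracle on congruent input", {
  set.seed(102)
  for (i in 1:200) {
    tri <- random_triangle()
    tgt <- apply_pose(random_pose(), tri)
    p1 <- fit_rigid_triangle(tri, tgt)
    p2 <- fit_rigid_procrustes(tri, tgt)
    expect_lt(sqrt(sum((p1$R - p2$R)^2)), 1e-6)
    expect_lt(max(abs(p1$t - p2$t)), 1e-6)
  }
})

test_that("degenerate triangles are rejected with the offending vertices named", {
  line <- matrix(c(0, 0, 0, 1, 1, 1, 2, 2, 2), 3, 3, byrow = TRUE)
  tri <- random_triangle()
  expect_error(fit_rigid_triangle(line, tri), "source")
  expect_error(fit_rigid_triangle(tri, line), "target")
  expect_error(fit_rigid_procrustes(line, line), "collinear")
})

test_that("similar but non-congruent triangles: rigid fit, vertex-3 residual surfaced", {
  tri <- matrix(c(0, 0, 0, 30, 0, 0, 0, 40, 0), 3, 3, byrow = TRUE)
  tgt <- apply_pose(random_pose(), tri * 1.2)
  p <- fit_rigid_triangle(tri, tgt)
  fitted <- apply_pose(p, tri)
  # vertex 1 and the 1-2 edge direction still match exactly
  expect_lt(max(abs(fitted[1, ] - tgt[1, ])), 1e-9)
  e_f <- fitted[2, ] - fitted[1, ]; e_t <- tgt[2, ] - tgt[1, ]
  expect_lt(max(abs(e_f / sqrt(sum(e_f^2)) - e_t / sqrt(sum(e_t^2)))), 1e-9)
  expect_gt(attr(p, "vertex3_residual_mm"), 1)
})

test_that("Procrustes is exact noise-free and degrades gracefully with noise", {
  set.seed(103)
  pts <- the_model$vertebrae$C0$markers
  pose <- random_pose()
  tgt <- apply_pose(pose, pts)
  rec <- fit_rigid_procrustes(pts, tgt)
  expect_lt(max(abs(rec$R - pose$R)), 1e-9)
  expect_lt(max(abs(rec$t - pose$t)), 1e-9)
  # Monte-Carlo noise propagation: for isotropic marker noise sigma, the
  # rotation error about a principal axis u has std ~ sigma / sqrt(sum of
  # squared perpendicular marker radii about u); the weakest axis of the
  # marker cluster dominates the total error
  sigma <- 0.1
  centered <- sweep(pts, 2, colMeans(pts))
  resist <- vapply(1:3, function(ax) {
    sum(centered[, -ax]^2)
  }, numeric(1))
  theory_rms_deg <- sqrt(sum(sigma^2 / resist)) * 180 / pi
  errs <- replicate(1000, {
    noisy <- tgt + matrix(rnorm(12, sd = sigma), 4, 3)
    r <- fit_rigid_procrustes(pts, noisy)
    rotation_angle_deg(t(r$R) %*% pose$R)
  })
  expect_lt(sqrt(mean(errs^2)), 1.5 * theory_rms_deg)
  expect_gt(sqrt(mean(errs^2)), 0.5 * theory_rms_deg)
})

test_that("registered poses preserve isometry and left-invariance", {
  set.seed(104)
  tri <- random_triangle()
  tgt <- apply_pose(random_pose(), tri)
  p <- fit_rigid_triangle(tri, tgt)
  fitted <- apply_pose(p, tri)
  expect_equal(as.numeric(dist(fitted)), as.numeric(dist(tri)),
               tolerance = 1e-12)
  # pre-transforming source and target together leaves the residual unchanged
  g <- random_pose()
  p2 <- fit_rigid_triangle(apply_pose(g, tri), apply_pose(g, tgt))
  expect_equal(attr(p2, "rms_mm"), attr(p, "rms_mm"), tolerance = 1e-9)
})

test_that("neutral-frame registration handles clean, noisy and occluded data", {
  g <- generate_trajectory(the_model, quick_scenario())
  reg <- register_model_to_neutral(the_model, g$trajectory)
  res <- attr(reg, "residuals")
  expect_true(all(res$rms_mm <= 1e-9))

  gn <- generate_trajectory(the_model,
                            scenario_config(duration_s = 0.2, seed = 5L,
                                            noise_sigma_mm = 0.1))
  regn <- register_model_to_neutral(the_model, gn$trajectory)
  expect_true(all(attr(regn, "residuals")$rms_mm <= 0.5))

  # one occluded marker on C1: the remaining triangle suffices
  tr <- g$trajectory
  tr$missing[1, which(tr$labels$vertebra == "C1")[1]] <- TRUE
  reg3 <- register_model_to_neutral(the_model, tr)
  expect_lt(attr(reg3, "residuals")$rms_mm[2], 1e-9)

  # two occluded markers: error names the vertebra
  tr$missing[1, which(tr$labels$vertebra == "C1")[2]] <- TRUE
  expect_error(register_model_to_neutral(the_model, tr), "C1")
})
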