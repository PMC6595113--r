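test_that("default ligament table contains the full 22-ligament enumeration", {
  counts <- table(the_ligaments$category)
  expect_identical(nrow(the_ligaments), 22L)
  expect_identical(sum(counts), 22L)
  expect_identical(as.integer(counts[c("apical_odontoid", "intertransverse",
                                       "interspinal", "supraspinous", "flavum",
                                       "atlantoaxial_collateral",
                                       "occipital_collateral", "capsular",
                                       "anterior_longitudinal",
                                       "posterior_longitudinal", "alar",
                                       "cruciate")]),
                   c(1L, 4L, 2L, 1L, 2L, 1L, 1L, 6L, 1L, 1L, 1L, 1L))
  expect_false(anyDuplicated(the_ligaments$name) > 0)
})

test_that("published material values are attached to the ligament specs", {
  row <- function(nm) the_ligaments[the_ligaments$name == nm, ]
  expect_equal(row("flavum_c1c2")$cross_section_A, 50.1)
  expect_equal(row("flavum_c1c2")$elastic_modulus_E, 50)
  expect_equal(row("flavum_c1c2")$rigidity_k, 11.6)
  expect_equal(row("alar")$cross_section_A, 3.4)
  expect_equal(row("alar")$rigidity_k, 25.32)
  expect_equal(row("posterior_longitudinal_c2c3")$poisson_nu, 0.45)
  expect_equal(row("anterior_longitudinal_c1c2")$rigidity_k, 24)
  mat <- material_properties()
  expect_equal(mat$elastic_modulus_E[mat$part == "Cortical bone"], 12000)
  expect_equal(mat$elastic_modulus_E[mat$part == "Intervertebral discs"], 20)
})

test_that("effective areas reconcile the material table with the state tables", {
  # derived from published stress/pressure ratios
  expect_equal(effective_area_from_row(1.792656, 0.174044272), 10.3,
               tolerance = 1e-6)
  expect_equal(effective_area_from_row(45.24, 0.902994012), 50.1,
               tolerance = 1e-6)
  expect_equal(effective_area_from_row(26.169, 10.4676), 2.5, tolerance = 1e-6)
  expect_equal(effective_area_from_row(1, 1), 1)
  expect_error(effective_area_from_row(1, 0), "positive")

  row <- function(nm) the_ligaments[the_ligaments$name == nm, ]
  expect_equal(row("alar")$effective_area_A_eff, 10.3)
  expect_equal(row("apical_odontoid")$effective_area_A_eff, 2.5)
  expect_equal(row("cruciate_longitudinal")$effective_area_A_eff, 6.8)
  # ligaments whose printed area already matches the state tables
  for (nm in c("flavum_c1c2", "anterior_longitudinal_c1c2",
               "posterior_longitudinal_c2c3")) {
    r <- row(nm)
    expect_lt(abs(r$effective_area_A_eff - r$cross_section_A) /
                r$cross_section_A, 0.001)
  }
})

test_that("spine model geometric invariants are enforced", {
  expect_silent(validate_spine_model(the_model))
  bad <- the_model
  rownames(bad$vertebrae$C1$markers) <- rep("m", 4)
  expect_error(validate_spine_model(bad), "duplicate")
  bad2 <- the_model
  bad2$vertebrae$C2$markers <- matrix(rep(c(0, 1, 2, 3), 3), 4, 3)
  expect_error(validate_spine_model(bad2), "collinear")
})

test_that("contact, load and criterion parameter objects hold their defaults", {
  cs <- contact_spec()
  expect_equal(cs$friction_mu, 0.10)
  expect_equal(cs$clearance_mm, 0.01)
  expect_identical(nrow(cs$pairs), 6L)
  expect_error(contact_spec(friction_mu = -0.1))

  lc <- load_case()
  expect_equal(lc$preload_F, 100)
  expect_equal(lc$moment_M, 1500)
  expect_error(load_case(preload_F = -1))

  cr <- instability_criterion()
  expect_equal(cr$angle_threshold_deg, 11)
  expect_equal(cr$displacement_threshold_mm, 3.5)
  expect_error(instability_criterion(angle_threshold_deg = 0))
})

test_that("rest lengths and rigidities are positive and geometry-consistent", {
  expect_true(all(the_ligaments$rest_length_L0 > 0))
  expect_true(all(the_ligaments$rigidity_k > 0))
  # rest length equals the neutral attachment distance
  s <- the_ligaments[the_ligaments$name == "apical_odontoid", ]
  p0 <- ucspine:::attachment_world(the_model, s$origin_vertebra, s$origin_point)
  p1 <- ucspine:::attachment_world(the_model, s$insertion_vertebra, s$insertion_point)
  expect_equal(s$rest_length_L0, sqrt(sum((p1 - p0)^2)))
})
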