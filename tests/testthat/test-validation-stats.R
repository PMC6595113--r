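test_that("regression recovers an exact line and rejects degenerate input", {
  x <- 1:5
  r <- linear_regression(x, 2 * x + 1)
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 1)
  expect_equal(r$r_squared, 1)
  expect_identical(r$n, 5L)
  expect_error(linear_regression(rep(1, 5), 1:5), "constant")
  expect_error(linear_regression(1:2, 1:2))
})

test_that("regression on independent noise has near-zero explanatory power", {
  set.seed(21)
  x <- rnorm(1000); y <- rnorm(1000)
  r <- linear_regression(x, y)
  expect_lte(r$r_squared, 0.01)
  expect_gte(r$r_squared, 0)
})

test_that("unit rescaling scales the slope and leaves R-squared unchanged", {
  set.seed(22)
  x <- rnorm(50); y <- 1.348 * x - 0.723 + rnorm(50, sd = 0.2)
  r_mm <- linear_regression(x, y)
  r_m <- linear_regression(x / 1000, y)   # predictor mm -> m
  expect_equal(r_m$slope, r_mm$slope * 1000, tolerance = 1e-9)
  expect_equal(r_m$r_squared, r_mm$r_squared, tolerance = 1e-12)
})

test_that("model angles sit inside the literature intervals, bounds inclusive", {
  rom <- data.frame(joint = c("C0C1", "C1C2"),
                    flexion_deg = c(3.49, 8.84),
                    extension_deg = c(11.16, 14.20))
  rc <- range_check(rom)
  expect_true(all(rc$within))
  expect_identical(nrow(rc), 4L)
  # inclusive boundary
  rom_b <- data.frame(joint = "C0C1", flexion_deg = 1.9, extension_deg = 10.8)
  expect_true(all(range_check(rom_b)$within))
  # widening an interval can never flip a containment to FALSE (monotone)
  wide <- literature_ranges()
  wide$low_deg <- wide$low_deg - 5; wide$high_deg <- wide$high_deg + 5
  expect_true(all(range_check(rom, wide)$within[rc$within]))
  # missing interval is an error
  rom_c3 <- data.frame(joint = "C2C3", flexion_deg = 1, extension_deg = 1)
  expect_error(range_check(rom_c3), "C2C3")
})

test_that("paired agreement testing follows its conventions and symmetry", {
  a <- c(3.49, 8.84, 11.16, 14.20, 5.51, 13.70, 12.96, 17.20)
  b <- c(3.82, 8.01, 10.4, 14.89, 4.91, 14.08, 12.55, 16.41)
  res <- paired_agreement_test(a, b)
  expect_true(res$agree)
  expect_gt(res$p_value, 0.05)
  # identical sets agree with p = 1
  same <- paired_agreement_test(a, a)
  expect_equal(same$p_value, 1)
  expect_true(same$agree)
  # constant nonzero shift with zero variance: p -> 0
  shift <- paired_agreement_test(a, a + 100)
  expect_equal(shift$p_value, 0)
  expect_false(shift$agree)
  # symmetry: swapping flips the statistic, preserves p
  swapped <- paired_agreement_test(b, a)
  expect_equal(swapped$statistic, -res$statistic, tolerance = 1e-12)
  expect_equal(swapped$p_value, res$p_value, tolerance = 1e-12)
  # Wilcoxon variant available behind the method flag
  w <- paired_agreement_test(a, b, method = "wilcoxon")
  expect_true(w$p_value > 0 && w$p_value <= 1)
})

test_that("synthetic strain pairs recover the generating regression line", {
  set.seed(23)
  x <- runif(200, 0, 3)
  y <- 1.348 * x - 0.723 + rnorm(200, sd = 0.35)
  r <- linear_regression(x, y)
  fit <- lm(y ~ x)
  ci <- confint(fit)
  expect_gte(1.348, ci[2, 1]); expect_lte(1.348, ci[2, 2])
  expect_gte(-0.723, ci[1, 1]); expect_lte(-0.723, ci[1, 2])
  expect_equal(r$slope, unname(coef(fit)[2]), tolerance = 1e-12)
})

test_that("validation report bundles the three blocks into JSON and markdown", {
  rom <- data.frame(joint = c("C0C1", "C1C2"),
                    flexion_deg = c(3.49, 8.84),
                    extension_deg = c(11.16, 14.20))
  jd <- tempfile(fileext = ".json"); md <- tempfile(fileext = ".md")
  rep <- validation_report(
    regression = linear_regression(1:5, 2 * (1:5) + 1),
    containment = range_check(rom),
    agreement = paired_agreement_test(c(1, 2, 3), c(1, 2, 3)),
    path = jd, md_path = md)
  back <- jsonlite::read_json(jd, simplifyVector = TRUE)
  expect_equal(back$regression$slope, 2)
  expect_true(all(back$containment$within))
  expect_true(back$agreement$agree)
  expect_true(any(grepl("Validation report", readLines(md))))
})
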