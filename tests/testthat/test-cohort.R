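test_that("BMI computation and unit logic are exact", {
  expect_equal(round(compute_bmi(70, 1.80), 1), 21.6)
  h <- c(0.5, 23, 97.3)
  expect_equal(compute_bmi(h, 1.0), h)  # identity at unit height
  expect_error(compute_bmi(-70, 1.8), "positive")
  expect_error(compute_bmi(70, 0), "positive")
})

test_that("extract-to-dry-mass conversion reproduces the LOQ and is (inverse-)linear", {
  expect_equal(extract_to_dry_mass(7.8, 1.0, 0.3), 26)
  expect_equal(extract_to_dry_mass(5, 1.0, 1.0), 5)
  expect_equal(extract_to_dry_mass(2.0, 3.0, 0.5), 12.0)
  # linear in concentration and volume, inverse-linear in mass
  base <- extract_to_dry_mass(3.1, 1.7, 0.4)
  expect_equal(extract_to_dry_mass(2 * 3.1, 1.7, 0.4), 2 * base)
  expect_equal(extract_to_dry_mass(3.1, 3 * 1.7, 0.4), 3 * base)
  expect_equal(extract_to_dry_mass(3.1, 1.7, 2 * 0.4), base / 2)
  expect_error(extract_to_dry_mass(0, 1, 1), "positive")
})

test_that("BMI categories partition the positive axis with closed normal range", {
  expect_equal(as.character(categorize_bmi(13.8)), "underweight")
  expect_equal(as.character(categorize_bmi(18.5)), "normal")
  expect_equal(as.character(categorize_bmi(24.99)), "normal")
  expect_equal(as.character(categorize_bmi(37.1)), "excessive")
  set.seed(1)
  bmi <- exp(runif(500, log(5), log(60)))
  cat3 <- categorize_bmi(bmi)
  expect_false(any(is.na(cat3)))  # every positive value maps somewhere
  # preimages are contiguous and ordered
  expect_true(max(bmi[cat3 == "underweight"]) <
              min(bmi[cat3 == "normal"]))
  expect_true(max(bmi[cat3 == "normal"]) <
              min(bmi[cat3 == "excessive"]))
  expect_error(categorize_bmi(c(20, -1)), "positive")
})

test_that("weight-change categories use the 5% rule and are antisymmetric", {
  expect_equal(as.character(categorize_weight_change(-6)), "loss")
  expect_equal(as.character(categorize_weight_change(0)), "stable")
  expect_equal(as.character(categorize_weight_change(5)), "stable")
  expect_equal(as.character(categorize_weight_change(-5)), "stable")
  set.seed(2)
  x <- runif(100, 5.001, 40)
  expect_true(all(categorize_weight_change(x) == "gain"))
  expect_true(all(categorize_weight_change(-x) == "loss"))
})

test_that("fiber category follows diet type with numeric g/day override", {
  expect_equal(as.character(categorize_fiber(
    c("low_fiber", "easily_digestible", "standard", "high_fiber"))),
    c("low", "low", "normal", "high"))
  expect_equal(as.character(categorize_fiber("standard", 24.9)), "low")
  expect_equal(as.character(categorize_fiber("standard", 30.5)), "high")
  expect_equal(as.character(categorize_fiber("low_fiber", 27)), "normal")
  expect_error(categorize_fiber("keto"), "unknown diet type")
})

test_that("detection limits enforce LOD = LOQ/3", {
  dl <- detection_limits(loq = 26)
  expect_equal(dl$lod, 26 / 3)
  expect_equal(detection_limits(loq = 9, lod = 3)$lod, 3)
  expect_error(detection_limits(loq = 26, lod = 5), "loq")
  expect_error(detection_limits(max_rsd = 1.5), "max_rsd")
})

test_that("censoring retains sub-LOQ values and substitutes half-LOD below LOD", {
  dl <- detection_limits(loq = 26)
  out <- censor_concentration(c(100, 10, 5), dl)
  expect_equal(as.numeric(out), c(100, 10, 26 / 6))
  expect_equal(as.character(attr(out, "censoring")),
               c("none", "below_loq", "below_lod"))
  expect_error(censor_concentration(-1, dl), "non-negative")
})

test_that("cohort CSV round trip is exact", {
  rec <- generate_cohort(cohort_spec(), seed = 11)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(rec, path)
  expect_equal(length(readLines(path)), nrow(rec) + 1L)  # header + rows
  back <- read_cohort(path)
  expect_equal(back, rec)
  # empty cohort gives a header-only file
  write_cohort(rec[0, ], path)
  expect_equal(length(readLines(path)), 1L)
})
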