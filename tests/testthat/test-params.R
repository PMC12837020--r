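test_that("bundled national configuration loads, validates, and carries the transcribed values", {
  p <- ksa_parameters()
  expect_s3_class(p, "coi_parameters")
  expect_identical(nrow(validate_parameters(p)), 0L)

  expect_equal(p$population$adult_population, 12830572)
  expect_equal(p$unit_costs$anti_vegf_lucentis$cost_sar, 2942.40)
  expect_equal(p$unit_costs$optical_devices$cost_sar, 3000)
  expect_equal(p$economy$nurse_annual_salary_sar, 37000)
  expect_equal(p$productivity$absenteeism_days[["R3"]], 28)
  expect_equal(p$productivity$absenteeism_days[["R4"]], 261)
  expect_equal(p$productivity$employment_rate, 0.8)
  expect_equal(p$productivity$working_days_per_month, 22)

  endo <- Filter(
    function(ae) ae$name == "endophthalmitis",
    p$adverse_events$R1
  )[[1]]
  expect_equal(endo$probability, 0.00035)
  cat_surg <- Filter(
    function(ae) ae$name == "cataract_after_vitrectomy",
    p$adverse_events$R2
  )[[1]]
  expect_equal(cat_surg$probability, 0.4804)
})

test_that("serialization round-trips are value-identical for YAML and JSON", {
  p <- ksa_parameters()
  for (ext in c(".yaml", ".json")) {
    f <- tempfile(fileext = ext)
    write_parameters(p, f)
    expect_identical(load_parameters(f), p, label = ext)
  }
})

test_that("validation rejects out-of-range fractions, bad references, and overlap violations", {
  p <- ksa_parameters()

  bad <- unclass(p)
  bad$population$diabetic_prevalence <- 1.5
  rep1 <- validate_parameters(as_coi_parameters(bad))
  expect_true(any(grepl("fraction out of \\[0,1\\]", rep1$message)))
  f <- tempfile(fileext = ".yaml")
  write_parameters(as_coi_parameters(bad), f)
  expect_error(load_parameters(f), "fraction out of")

  bad <- unclass(p)
  bad$protocols$R1[[1]]$item <- "XYZ"
  rep2 <- validate_parameters(as_coi_parameters(bad))
  expect_true(any(grepl("'XYZ'", rep2$message)))

  bad <- unclass(p)
  bad$unit_costs$oct$cost_sar <- -1
  rep3 <- validate_parameters(as_coi_parameters(bad))
  expect_identical(nrow(rep3), 1L)
  expect_match(rep3$field, "unit_costs.oct")

  bad <- unclass(p)
  bad$population$combined_prevalence <- 0.6 # > 0.345 + 0.203
  rep4 <- validate_parameters(as_coi_parameters(bad))
  expect_true(any(grepl("correction factor > 1", rep4$message)))
})

test_that("loader reports parse failures and missing files by name", {
  expect_error(load_parameters(tempfile()), "not found")
  f <- tempfile(fileext = ".yaml")
  writeLines(c("coi_schema: 1", "population: {", "  bad"), f)
  expect_error(load_parameters(f), "parse failure")
  f2 <- tempfile(fileext = ".yaml")
  writeLines("population: {}", f2)
  expect_error(load_parameters(f2), "coi_schema")
})

test_that("supportive-care flags default to the severity eligibility rule", {
  p <- unclass(ksa_parameters())
  p$supportive_care <- NULL
  p <- as_coi_parameters(p)
  expect_true(p$supportive_care$R1$visual_aids)
  expect_false(p$supportive_care$R1$pension)
  for (g in c("R4", "M2", "BLIND")) {
    expect_false(p$supportive_care[[g]]$visual_aids)
    expect_true(p$supportive_care[[g]]$psychological)
    expect_true(p$supportive_care[[g]]$home_nurse)
    expect_true(p$supportive_care[[g]]$pension)
  }
})

test_that("severity grade mapping is fixed", {
  expect_identical(
    severity_class(c("R1", "R2", "M1", "R3", "R4", "M2", "BLIND")),
    c(
      "mild", "moderate", "moderate", "severe", "sight_threatening",
      "sight_threatening", "blind"
    )
  )
  expect_error(severity_class("R9"), "unknown severity grade")
})
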