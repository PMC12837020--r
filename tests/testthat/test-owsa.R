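test_that("parameter enumeration is deterministic, sorted, and covers numeric leaves only", {
  p <- ksa_parameters()
  paths <- enumerate_parameters(p)
  expect_identical(paths, enumerate_parameters(p))
  expect_identical(paths, sort(paths))
  expect_true("population.retinopathy_prevalence" %in% paths)
  expect_true("unit_costs.oct.cost_sar" %in% paths)
  expect_true("protocols.M1.1.frequency.n" %in% paths)
  expect_false(any(grepl("annotations", paths)))
  expect_false(any(grepl("coi_schema", paths)))

  # population scalars survive even with no protocols at all
  q <- unclass(p)
  q$protocols <- list()
  q$adverse_events <- list()
  paths2 <- enumerate_parameters(as_coi_parameters(q))
  expect_true("population.diabetic_prevalence" %in% paths2)
})

test_that("perturbation is multiplicative, clamped for fractions, and non-destructive", {
  p <- ksa_parameters()
  same <- perturb(p, "population.diabetic_prevalence", 1)
  attr(same, "clamped") <- NULL
  expect_identical(same, p)

  up <- perturb(p, "unit_costs.oct.cost_sar", 0.8)
  expect_equal(up$unit_costs$oct$cost_sar, 0.8 * 380)
  expect_false(attr(up, "clamped"))
  expect_equal(p$unit_costs$oct$cost_sar, 380) # original untouched

  q <- unclass(p)
  q$population$diabetic_prevalence <- 0.9
  clamped <- perturb(as_coi_parameters(q), "population.diabetic_prevalence", 1.2)
  expect_identical(clamped$population$diabetic_prevalence, 1)
  expect_true(attr(clamped, "clamped"))

  expect_error(perturb(p, "population.nonexistent", 1.2), "path")
  expect_error(perturb(p, "unit_costs.oct.cost_sar", 0), "> 0")
})

test_that("a purely linear toy model has span 0.4 x baseline and unused costs rank last", {
  p <- unclass(toy_params(count_per_year = 2, cost = 50))
  p$unit_costs$unused <- list(cost_sar = 999, category = "procedure")
  # keep the overlap constraint strictly interior so +/-20% on any
  # prevalence stays a valid cascade
  p$population$maculopathy_prevalence <- 0.1
  p$population$combined_prevalence <- 0.15
  p <- as_coi_parameters(p)
  tor <- one_way_sensitivity(p, fraction = 0.2)
  baseline <- attr(tor, "baseline")

  cost_row <- tor[tor$parameter == "unit_costs.widget.cost_sar", ]
  expect_equal(cost_row$span, 0.4 * baseline, tolerance = 1e-12)
  expect_equal(cost_row$high_output - baseline, baseline - cost_row$low_output,
    tolerance = 1e-12
  )

  unused_row <- tor[tor$parameter == "unit_costs.unused.cost_sar", ]
  expect_identical(unused_row$span, 0)
  # zero-span parameters all rank below every influential one
  expect_lt(max(which(tor$span > 0)), min(which(tor$span == 0)))
})

test_that("fraction 0 collapses every entry onto the baseline", {
  tor <- one_way_sensitivity(toy_params(), fraction = 0)
  expect_true(all(tor$span == 0))
  expect_true(all(tor$low_output == attr(tor, "baseline")))
  expect_true(all(tor$high_output == attr(tor, "baseline")))
})

test_that("linearly entering national parameters perturb symmetrically about the baseline", {
  p <- ksa_parameters()
  linear_paths <- c(
    "unit_costs.anti_vegf_lucentis.cost_sar",
    "economy.pension_annual_sar",
    "productivity.daily_wage_general_sar",
    "population.adult_population"
  )
  tor <- one_way_sensitivity(p, fraction = 0.2, paths = linear_paths)
  for (i in seq_len(nrow(tor))) {
    expect_equal(
      tor$high_output[i] - tor$baseline_output[i],
      tor$baseline_output[i] - tor$low_output[i],
      tolerance = 1e-9
    )
  }
})

test_that("spans do not depend on the enumeration order", {
  p <- ksa_parameters()
  paths <- c(
    "population.retinopathy_prevalence", "unit_costs.oct.cost_sar",
    "economy.pension_annual_sar"
  )
  fwd <- one_way_sensitivity(p, paths = paths)
  rev_ <- one_way_sensitivity(p, paths = rev(paths))
  expect_identical(
    fwd$span[order(fwd$parameter)], rev_$span[order(rev_$parameter)]
  )
  expect_identical(fwd$parameter, rev_$parameter) # same final ranking
})

test_that("the owsa config block restricts the analysed scope", {
  q <- unclass(ksa_parameters())
  q$owsa <- list(include = list(
    "population.retinopathy_prevalence", "unit_costs.oct.cost_sar"
  ))
  tor <- one_way_sensitivity(as_coi_parameters(q))
  expect_identical(nrow(tor), 2L)
  q$owsa <- list(exclude = list("population.adult_population"))
  tor2 <- one_way_sensitivity(as_coi_parameters(q))
  expect_false("population.adult_population" %in% tor2$parameter)
})
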