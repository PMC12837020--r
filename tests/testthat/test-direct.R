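test_that("frequency annualization follows the stated conventions", {
  expect_identical(annualize(list(kind = "every_n_weeks", n = 4)), 13)
  expect_identical(annualize(list(kind = "every_n_months", n = 6)), 2)
  expect_identical(annualize(list(kind = "once_at_diagnosis")), 1)
  expect_identical(annualize(list(kind = "per_year", count = 7)), 7)
  expect_error(annualize(list(kind = "every_n_weeks", n = 0)), "> 0")
  expect_error(annualize(list(kind = "per_year", count = -1)), ">= 0")
  expect_error(annualize(list(kind = "fortnightly")), "unknown frequency")
})

test_that("protocol costing multiplies frequency, multiplicity and unit cost into category buckets", {
  costs <- list(
    anti_vegf = list(cost_sar = 2942.40, category = "medication"),
    oct = list(cost_sar = 380, category = "monitoring")
  )
  line <- function(item, kind, n = NULL, mult = 1) {
    fr <- list(kind = kind)
    if (!is.null(n)) fr$n <- n
    list(item = item, frequency = fr, multiplicity = mult)
  }

  one <- protocol_cost_per_patient(
    list(line("anti_vegf", "every_n_weeks", 4)), costs
  )
  expect_equal(one[["medication"]], 38251.20)
  expect_identical(one[["surgery_resources"]], 0)

  expect_identical(
    protocol_cost_per_patient(list(), costs),
    c(medication = 0, surgery_resources = 0)
  )

  # two identical lines == one line at doubled multiplicity
  twice <- protocol_cost_per_patient(
    list(line("oct", "every_n_months", 3), line("oct", "every_n_months", 3)),
    costs
  )
  doubled <- protocol_cost_per_patient(
    list(line("oct", "every_n_months", 3, mult = 2)), costs
  )
  expect_equal(twice, doubled)
  expect_equal(twice[["surgery_resources"]], 2 * 4 * 380)

  expect_error(
    protocol_cost_per_patient(list(line("absent", "once_at_diagnosis")), costs),
    "'absent'"
  )
})

test_that("adverse events are costed as probability times bundle cost", {
  costs <- list(
    phaco = list(cost_sar = 4400, category = "procedure"),
    iol = list(cost_sar = 2800, category = "procedure")
  )
  once <- function(item) {
    list(
      item = item, frequency = list(kind = "once_at_diagnosis"),
      multiplicity = 1
    )
  }
  bundle <- list(once("phaco"), once("iol"))
  ae <- function(p) list(name = "cataract", probability = p, cost_bundle = bundle)

  expect_equal(
    expected_adverse_event_cost(list(ae(0.4804)), costs),
    0.4804 * 7200
  )
  expect_identical(expected_adverse_event_cost(list(ae(0)), costs), 0)
  expect_equal(expected_adverse_event_cost(list(ae(1)), costs), 7200)
  expect_identical(expected_adverse_event_cost(list(), costs), 0)
  expect_error(expected_adverse_event_cost(list(ae(1.2)), costs), "probability")
})

test_that("supportive care applies the eligibility flags", {
  p <- ksa_parameters()
  r1 <- supportive_care_cost("R1", p)
  expect_equal(r1[["visual_aids"]], 3000)
  expect_identical(r1[["psychological"]], 0)
  expect_identical(r1[["home_nurse"]], 0)

  m2 <- supportive_care_cost("M2", p)
  expect_equal(m2[["home_nurse"]], 37000)
  expect_equal(m2[["psychological"]], 12 * 345)
  expect_identical(m2[["visual_aids"]], 0)

  q <- unclass(p)
  q$supportive_care$M2 <- list(
    visual_aids = FALSE, psychological = FALSE, home_nurse = FALSE,
    pension = FALSE
  )
  expect_identical(
    unname(supportive_care_cost("M2", as_coi_parameters(q))), rep(0, 3)
  )
})

test_that("direct costs are linear in counts and unit costs, and the partition identity holds", {
  p <- ksa_parameters()
  cas <- build_cascade(p)
  d <- direct_costs(cas, p)

  # same money partitioned by component and by grade
  expect_equal(sum(d$per_component), sum(d$per_grade_total), tolerance = 1e-12)
  expect_equal(d$total_sar, sum(d$per_component), tolerance = 1e-12)
  expect_true(all(d$by_grade_component >= 0))

  cas2 <- cas
  cas2$grade_counts <- cas$grade_counts * 2
  d2 <- direct_costs(cas2, p)
  expect_equal(d2$per_component, d$per_component * 2, tolerance = 1e-12)

  q <- unclass(p)
  for (item in names(q$unit_costs)) {
    q$unit_costs[[item]]$cost_sar <- q$unit_costs[[item]]$cost_sar * 3
  }
  q$economy$nurse_annual_salary_sar <- q$economy$nurse_annual_salary_sar * 3
  d3 <- direct_costs(cas, as_coi_parameters(q))
  expect_equal(d3$per_component, d$per_component * 3, tolerance = 1e-12)

  q0 <- unclass(p)
  for (item in names(q0$unit_costs)) q0$unit_costs[[item]]$cost_sar <- 0
  q0$economy$nurse_annual_salary_sar <- 1e-9 # economy must stay positive
  d0 <- direct_costs(cas, as_coi_parameters(q0))
  expect_lt(d0$total_sar, 1)
})
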