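# Minimal hand-built parameter sets used across tests.

# one active grade (R1), one item, trivially auditable by hand
toy_params <- function(count_per_year = 1, cost = 5, prevalence = 0.1,
                       adult = 100, diabetic = 1) {
  as_coi_parameters(list(
    coi_schema = 1,
    population = list(
      adult_population = adult,
      diabetic_prevalence = diabetic,
      blindness_prevalence = 0,
      retinopathy_prevalence = prevalence,
      maculopathy_prevalence = 0,
      combined_prevalence = prevalence,
      grade_prevalence = list(R1 = prevalence, R2 = 0, R3 = 0, R4 = 0, M1 = 0, M2 = 0)
    ),
    unit_costs = list(
      widget = list(cost_sar = cost, category = "medication")
    ),
    protocols = list(
      R1 = list(list(
        item = "widget",
        frequency = list(kind = "per_year", count = count_per_year),
        multiplicity = 1
      ))
    ),
    adverse_events = list(),
    supportive_care = setNames(
      rep(list(list(
        visual_aids = FALSE, psychological = FALSE,
        home_nurse = FALSE, pension = FALSE
      )), 7),
      c("R1", "R2", "R3", "R4", "M1", "M2", "BLIND")
    ),
    productivity = list(
      employment_rate = 0,
      absenteeism_days = list(R1 = 0, R2 = 0, R3 = 0, R4 = 0, M1 = 0, M2 = 0, BLIND = 0),
      caregiver_days = list(R1 = 0, R2 = 0, R3 = 0, R4 = 0, M1 = 0, M2 = 0, BLIND = 0),
      monthly_salary_sar = 0,
      daily_wage_general_sar = 0,
      working_days_per_month = 22,
      working_days_per_week = 5
    ),
    economy = list(
      ppp_rate_sar_per_intl_dollar = 2,
      gdp_sar = 1e6,
      pension_annual_sar = 1,
      nurse_annual_salary_sar = 1
    )
  ))
}

# printed national figures used in several comparisons
ksa_table_counts <- c(
  diabetic = 2271011.24, blind = 74943.37, retinopathy = 783498.88,
  maculopathy = 461015.28, combined = 835732.14,
  R1 = 337037.96, R2 = 76252.93, R3 = 59477.29, R4 = 53377.05,
  M1 = 67102.58, M2 = 242484.32
)

ksa_direct_components <- c(
  medication = 70610172590, surgery_resources = 11319029616,
  adverse_events = 2323124452, psychological = 1535131658,
  visual_aids = 1619612282, home_nurse = 13719775687
)

ksa_indirect_components <- c(
  pension = 17798627918, patient = 30314412406, caregiver = 1085025576
)
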