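# run expr with a private, seeded RNG stream; the caller's global
# .Random.seed is left untouched
with_local_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(expr)
}

#' Generate a random but structurally valid parameter set
#'
#' Emits a seeded `coi_parameters` instance that always passes
#' [validate_parameters()]: grade prevalences are drawn so their sum stays
#' below 1 and defines the any-retinopathy / any-maculopathy prevalences,
#' the combined prevalence is drawn inside
#' `[max(ret, mac), ret + mac]` so the overlap correction factor is valid,
#' unit costs are log-uniform around `cost_scale`, protocols mix all four
#' frequency kinds, adverse-event probabilities lie in \[0, 0.5\] and
#' productivity day counts in \[0, 300\]. Scenarios exist to exercise the
#' cost engines against [oracle_total()]; they make no attempt to be
#' epidemiologically realistic.
#'
#' @param seed integer seed; the same seed reproduces the identical
#'   scenario. The global RNG state is not disturbed.
#' @param n_grades number of active disease grades (1--6, taken in order
#'   R1, R2, R3, R4, M1, M2; the rest get zero prevalence).
#' @param n_items number of unit-cost items available to protocols; 0
#'   yields a scenario with empty protocols.
#' @param population_scale magnitude of the adult population.
#' @param cost_scale central magnitude of unit costs (SAR).
#' @param zero_prevalence if TRUE, every disease and blindness prevalence
#'   is zero (degenerate cascade).
#' @return a validated `coi_parameters` object.
#' @examples
#' s <- generate_scenario(seed = 1)
#' nrow(validate_parameters(s)) # 0
#' @export
generate_scenario <- function(seed, n_grades = 6, n_items = 8,
                              population_scale = 1e6, cost_scale = 1000,
                              zero_prevalence = FALSE) {
  stopifnot(
    n_grades >= 1, n_grades <= 6, n_items >= 0,
    population_scale > 0, cost_scale > 0
  )
  with_local_rng(seed, {
    all_grades <- prevalence_grades()
    active <- all_grades[seq_len(n_grades)]

    gp <- stats::setNames(rep(0, 6), all_grades)
    if (!zero_prevalence) {
      raw <- stats::runif(n_grades)
      gp[active] <- raw / sum(raw) * stats::runif(1, 0.1, 0.6)
    }
    ret <- sum(gp[c("R1", "R2", "R3", "R4")])
    mac <- sum(gp[c("M1", "M2")])
    combined <- if (ret + mac > 0) {
      stats::runif(1, max(ret, mac), min(ret + mac, 1))
    } else {
      0
    }

    items <- if (n_items > 0) sprintf("item_%02d", seq_len(n_items)) else character(0)
    categories <- c("medication", "procedure", "monitoring")
    unit_costs <- stats::setNames(lapply(items, function(i) {
      list(
        cost_sar = cost_scale * exp(stats::runif(1, -1, 1)),
        category = sample(categories, 1)
      )
    }), items)
    has_items <- n_items > 0
    if (has_items) {
      unit_costs$optical_devices <-
        list(cost_sar = cost_scale * exp(stats::runif(1, -1, 1)), category = "visual_aid")
      unit_costs$psychologist_visit <-
        list(cost_sar = cost_scale * exp(stats::runif(1, -1, 1)), category = "psychological")
    }

    rand_freq <- function() {
      kind <- sample(
        c("per_year", "every_n_weeks", "every_n_months", "once_at_diagnosis"), 1
      )
      switch(kind,
        per_year = list(kind = kind, count = sample(0:12, 1)),
        every_n_weeks = list(kind = kind, n = sample(c(2, 4, 6, 8, 13, 26), 1)),
        every_n_months = list(kind = kind, n = sample(c(1, 2, 3, 6, 12), 1)),
        once_at_diagnosis = list(kind = kind)
      )
    }
    rand_line <- function() {
      list(
        item = sample(items, 1), frequency = rand_freq(),
        multiplicity = sample(c(1, 2), 1)
      )
    }
    protocols <- stats::setNames(lapply(active, function(g) {
      if (!has_items) {
        return(list())
      }
      lapply(seq_len(sample(1:6, 1)), function(i) rand_line())
    }), active)
    adverse_events <- stats::setNames(lapply(active, function(g) {
      if (!has_items) {
        return(list())
      }
      lapply(seq_len(sample(0:2, 1)), function(i) {
        list(
          name = paste0("ae_", i),
          probability = stats::runif(1, 0, 0.5),
          cost_bundle = lapply(seq_len(sample(1:2, 1)), function(j) rand_line())
        )
      })
    }), active)

    supportive_care <- stats::setNames(lapply(coi_grades(), function(g) {
      list(
        visual_aids = has_items && stats::runif(1) < 0.5,
        psychological = has_items && stats::runif(1) < 0.5,
        home_nurse = stats::runif(1) < 0.5,
        pension = stats::runif(1) < 0.5
      )
    }), coi_grades())

    days <- function(hi) {
      stats::setNames(stats::runif(7, 0, hi), coi_grades())
    }
    params <- list(
      coi_schema = 1,
      population = list(
        adult_population = population_scale * exp(stats::runif(1, -0.5, 0.5)),
        diabetic_prevalence = if (zero_prevalence) 0 else stats::runif(1, 0.05, 0.3),
        blindness_prevalence = if (zero_prevalence) 0 else stats::runif(1, 0, 0.1),
        retinopathy_prevalence = ret,
        maculopathy_prevalence = mac,
        combined_prevalence = combined,
        grade_prevalence = as.list(gp)
      ),
      unit_costs = unit_costs,
      protocols = protocols,
      adverse_events = adverse_events,
      supportive_care = supportive_care,
      supportive_settings = list(
        psychologist_visits_per_year = sample(0:24, 1),
        visual_aid_item = "optical_devices",
        psychologist_item = "psychologist_visit"
      ),
      productivity = list(
        employment_rate = stats::runif(1),
        absenteeism_days = as.list(days(300)),
        caregiver_days = as.list(days(100)),
        monthly_salary_sar = stats::runif(1, 2000, 8000),
        daily_wage_general_sar = stats::runif(1, 100, 600),
        working_days_per_month = 22,
        working_days_per_week = 5
      ),
      economy = list(
        ppp_rate_sar_per_intl_dollar = stats::runif(1, 1, 4),
        gdp_sar = 1e12,
        pension_annual_sar = stats::runif(1, 1e4, 6e4),
        nurse_annual_salary_sar = stats::runif(1, 2e4, 5e4)
      )
    )
    if (!has_items) {
      # without items there is nothing to buy; keep referential integrity
      for (g in coi_grades()) {
        params$supportive_care[[g]]$visual_aids <- FALSE
        params$supportive_care[[g]]$psychological <- FALSE
      }
    }
    as_coi_parameters(params)
  })
}

#' Independent total-burden oracle
#'
#' Recomputes the total annual burden of a parameter set by a deliberately
#' naive enumeration -- nested loops over grades, protocol lines,
#' adverse-event bundles and indirect components, with all arithmetic
#' written out inline and no code shared with the cost engines. Used to
#' verify that the pipeline's aggregate equals an independent accounting
#' of the same model.
#'
#' @param params a `coi_parameters` object.
#' @return total annual burden in SAR.
#' @examples
#' s <- generate_scenario(seed = 7)
#' oracle_total(s)
#' @export
oracle_total <- function(params) {
  params <- as_coi_parameters(params)
  pop <- params$population
  pr <- params$productivity
  ec <- params$economy
  ss <- params$supportive_settings

  diabetic <- pop$adult_population * pop$diabetic_prevalence
  rp <- pop$retinopathy_prevalence
  mp <- pop$maculopathy_prevalence
  cf <- if (rp + mp > 0) pop$combined_prevalence / (rp + mp) else 1

  per_year <- function(fr) {
    if (fr$kind == "per_year") {
      fr$count
    } else if (fr$kind == "every_n_weeks") {
      52 / fr$n
    } else if (fr$kind == "every_n_months") {
      12 / fr$n
    } else {
      1
    }
  }
  price <- function(item) params$unit_costs[[item]]$cost_sar

  total <- 0
  for (g in c("R1", "R2", "R3", "R4", "M1", "M2", "BLIND")) {
    count <- if (g == "BLIND") {
      diabetic * pop$blindness_prevalence
    } else {
      diabetic * (pop$grade_prevalence[[g]]) * cf
    }

    per_patient <- 0
    for (line in params$protocols[[g]]) {
      per_patient <- per_patient +
        per_year(line$frequency) * line$multiplicity * price(line$item)
    }
    for (ae in params$adverse_events[[g]]) {
      bundle <- 0
      for (line in ae$cost_bundle) {
        bundle <- bundle +
          per_year(line$frequency) * line$multiplicity * price(line$item)
      }
      per_patient <- per_patient + ae$probability * bundle
    }
    flags <- params$supportive_care[[g]]
    if (isTRUE(flags$visual_aids)) {
      per_patient <- per_patient + price(ss$visual_aid_item)
    }
    if (isTRUE(flags$psychological)) {
      per_patient <- per_patient +
        ss$psychologist_visits_per_year * price(ss$psychologist_item)
    }
    if (isTRUE(flags$home_nurse)) {
      per_patient <- per_patient + ec$nurse_annual_salary_sar
    }

    severe_tier <- g %in% c("R3", "R4", "M2", "BLIND")
    wage <- if (severe_tier) {
      pr$monthly_salary_sar / pr$working_days_per_month
    } else {
      pr$daily_wage_general_sar
    }
    absent <- if (g %in% names(pr$absenteeism_days)) pr$absenteeism_days[[g]] else 0
    cgdays <- if (g %in% names(pr$caregiver_days)) pr$caregiver_days[[g]] else 0
    indirect <- pr$employment_rate * absent * wage +
      cgdays * pr$daily_wage_general_sar +
      if (isTRUE(flags$pension)) ec$pension_annual_sar else 0

    total <- total + count * (per_patient + indirect)
  }
  total
}
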