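#' Model parameter files
#'
#' The entire cost-of-illness model is declarative: a single YAML (or JSON)
#' file carries the population and prevalence inputs, the unit-cost
#' registry, per-grade treatment protocols and adverse-event bundles,
#' supportive-care eligibility flags, productivity assumptions and economy
#' scalars (PPP rate, GDP, pension, nurse salary). `load_parameters()`
#' reads and fully validates such a file; `write_parameters()` serializes a
#' parameter object back so that a load/write cycle is value-identical.
#'
#' Files must carry the schema marker `coi_schema: 1`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` parameter file.
#' @return `load_parameters()` returns a validated object of class
#'   `coi_parameters`.
#' @seealso [ksa_parameters()] for the bundled Saudi Arabia configuration,
#'   [validate_parameters()] for the violation report.
#' @examples
#' params <- ksa_parameters()
#' f <- tempfile(fileext = ".yaml")
#' write_parameters(params, f)
#' identical(load_parameters(f), params)
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) {
    stop("parameter file not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    tryCatch(
      jsonlite::read_json(path, simplifyVector = FALSE),
      error = function(e) {
        stop("JSON parse failure in '", path, "': ", conditionMessage(e),
          call. = FALSE
        )
      }
    )
  } else {
    tryCatch(
      yaml::read_yaml(path),
      error = function(e) {
        stop("YAML parse failure in '", path, "': ", conditionMessage(e),
          call. = FALSE
        )
      }
    )
  }
  params <- as_coi_parameters(raw)
  report <- validate_parameters(params)
  if (nrow(report) > 0L) {
    stop(
      "invalid parameter file '", path, "':\n",
      paste0("  - [", report$field, "] ", report$message, collapse = "\n"),
      call. = FALSE
    )
  }
  params
}

#' @rdname load_parameters
#' @param params a `coi_parameters` object.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "coi_parameters"))
  # named atomic vectors serialize as YAML/JSON maps only as named lists
  listify <- function(x) {
    if (is.list(x)) {
      lapply(x, listify)
    } else if (is.atomic(x) && !is.null(names(x))) {
      as.list(x)
    } else {
      x
    }
  }
  x <- listify(unclass(params))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    # precision 15 keeps doubles exact through a write/read cycle
    yaml::write_yaml(x, path, precision = 15)
  }
  invisible(path)
}

#' Coerce a plain nested list into a `coi_parameters` object
#'
#' Normalizes a parsed configuration: numeric maps become named numeric
#' vectors, protocol-line multiplicities default to 1, missing
#' supportive-care flags take the model's eligibility rule (visual aids for
#' R1, R2, M1, R3; psychological support, home nursing and pension for R4,
#' M2 and the blind), and supportive-care settings receive their defaults.
#' No validation is performed here; see [validate_parameters()].
#'
#' @param x a nested list following the parameter schema.
#' @return an object of class `coi_parameters`.
#' @export
as_coi_parameters <- function(x) {
  if (inherits(x, "coi_parameters")) {
    return(x)
  }
  stopifnot(is.list(x))
  if (is.null(x$coi_schema) || !identical(as.numeric(x$coi_schema), 1)) {
    stop("parameter set lacks schema marker 'coi_schema: 1'", call. = FALSE)
  }
  x$coi_schema <- 1

  num_map <- function(m) {
    if (is.null(m)) {
      return(stats::setNames(numeric(0), character(0)))
    }
    v <- vapply(m, function(e) as.numeric(e)[1], numeric(1))
    stats::setNames(v, names(m))
  }
  x$population$grade_prevalence <- num_map(x$population$grade_prevalence)
  x$productivity$absenteeism_days <- num_map(x$productivity$absenteeism_days)
  x$productivity$caregiver_days <- num_map(x$productivity$caregiver_days)

  x$unit_costs <- lapply(x$unit_costs, function(e) {
    list(cost_sar = as.numeric(e$cost_sar), category = as.character(e$category))
  })

  scalar_or_null <- function(v) {
    if (is.null(v) || length(v) == 0L) NULL else as.numeric(v[[1]])
  }
  norm_line <- function(line) {
    freq <- line$frequency
    # YAML 1.1 resolves an unquoted key `n` to boolean FALSE; accept it
    n <- scalar_or_null(freq$n %||% freq[["FALSE"]])
    count <- scalar_or_null(freq$count)
    fr <- list(kind = as.character(freq$kind))
    if (!is.null(n)) fr$n <- n
    if (!is.null(count)) fr$count <- count
    list(
      item = as.character(line$item),
      frequency = fr,
      multiplicity = as.numeric(line$multiplicity %||% 1)
    )
  }
  x$protocols <- lapply(x$protocols %||% list(), function(lines) {
    lapply(lines, norm_line)
  })
  x$adverse_events <- lapply(x$adverse_events %||% list(), function(aes) {
    lapply(aes, function(ae) {
      list(
        name = as.character(ae$name),
        probability = as.numeric(ae$probability),
        cost_bundle = lapply(ae$cost_bundle %||% list(), norm_line)
      )
    })
  })

  default_flags <- function(g) {
    st <- severity_class(g) %in% c("sight_threatening", "blind")
    list(
      visual_aids = !st && g %in% c("R1", "R2", "M1", "R3"),
      psychological = st, home_nurse = st, pension = st
    )
  }
  sc <- x$supportive_care %||% list()
  x$supportive_care <- stats::setNames(lapply(coi_grades(), function(g) {
    flags <- sc[[g]] %||% default_flags(g)
    lapply(flags[c("visual_aids", "psychological", "home_nurse", "pension")],
      isTRUE
    )
  }), coi_grades())

  ss <- x$supportive_settings %||% list()
  x$supportive_settings <- list(
    psychologist_visits_per_year =
      as.numeric(ss$psychologist_visits_per_year %||% 12),
    visual_aid_item = as.character(ss$visual_aid_item %||% "optical_devices"),
    psychologist_item =
      as.character(ss$psychologist_item %||% "psychologist_visit")
  )

  for (f in c(
    "employment_rate", "monthly_salary_sar", "daily_wage_general_sar",
    "working_days_per_month", "working_days_per_week"
  )) {
    if (!is.null(x$productivity[[f]])) {
      x$productivity[[f]] <- as.numeric(x$productivity[[f]])
    }
  }
  x$economy <- lapply(x$economy, as.numeric)

  structure(x, class = "coi_parameters")
}

#' Bundled Saudi Arabia parameterization
#'
#' Returns the packaged national configuration: adult population and
#' prevalence cascade, severity-grade prevalences, the unit-cost registry,
#' per-grade treatment protocols and adverse-event bundles, productivity
#' assumptions and economy scalars for fiscal year 2024. The file lives at
#' `system.file("extdata", "ksa_2024.yaml", package = "coivis")`.
#'
#' @return a validated `coi_parameters` object.
#' @examples
#' p <- ksa_parameters()
#' p$population$adult_population
#' p$unit_costs$anti_vegf_lucentis$cost_sar
#' @export
ksa_parameters <- function() {
  load_parameters(
    system.file("extdata", "ksa_2024.yaml", package = "coivis", mustWork = TRUE)
  )
}

#' Validate a parameter set
#'
#' Checks every schema invariant and returns the violations as data rather
#' than raising: fractions within \[0, 1\], non-negative costs and day
#' counts, strictly positive economy scalars, valid frequency
#' specifications, referential integrity of every protocol and
#' adverse-event item against the unit-cost registry, and the overlap
#' consistency `combined <= retinopathy + maculopathy` without which the
#' correction factor would exceed 1.
#'
#' @param params a `coi_parameters` object (or coercible list).
#' @return a data frame of class `coi_validation` with columns `field`,
#'   `rule`, `message`; zero rows means the parameter set is valid.
#' @examples
#' nrow(validate_parameters(ksa_parameters())) # 0
#' @export
validate_parameters <- function(params) {
  params <- as_coi_parameters(params)
  rows <- list()
  flag <- function(field, rule, message) {
    rows[[length(rows) + 1L]] <<- data.frame(
      field = field, rule = rule, message = message,
      stringsAsFactors = FALSE
    )
  }

  pop <- params$population
  if (!is_scalar_number(pop$adult_population) || pop$adult_population < 0) {
    flag("population.adult_population", "nonnegative", "must be >= 0")
  }
  fracs <- c(
    "diabetic_prevalence", "blindness_prevalence", "retinopathy_prevalence",
    "maculopathy_prevalence", "combined_prevalence"
  )
  for (f in fracs) {
    if (!is_fraction(pop[[f]])) {
      flag(paste0("population.", f), "fraction", "fraction out of [0,1]")
    }
  }
  for (g in names(pop$grade_prevalence)) {
    if (!is_fraction(pop$grade_prevalence[[g]])) {
      flag(
        paste0("population.grade_prevalence.", g), "fraction",
        "fraction out of [0,1]"
      )
    }
  }
  missing_g <- setdiff(prevalence_grades(), names(pop$grade_prevalence))
  if (length(missing_g)) {
    flag(
      "population.grade_prevalence", "coverage",
      paste("missing grade(s):", paste(missing_g, collapse = ", "))
    )
  }
  if (is_fraction(pop$combined_prevalence) &&
    is_fraction(pop$retinopathy_prevalence) &&
    is_fraction(pop$maculopathy_prevalence) &&
    pop$combined_prevalence >
      pop$retinopathy_prevalence + pop$maculopathy_prevalence + 1e-12) {
    flag(
      "population.combined_prevalence", "overlap",
      "combined prevalence exceeds retinopathy + maculopathy (correction factor > 1)"
    )
  }

  costs <- params$unit_costs
  if (anyDuplicated(names(costs))) {
    flag("unit_costs", "unique", "duplicate item identifiers")
  }
  categories <- c(
    "medication", "procedure", "monitoring", "visual_aid",
    "psychological", "nursing"
  )
  for (item in names(costs)) {
    e <- costs[[item]]
    if (!is_scalar_number(e$cost_sar) || e$cost_sar < 0) {
      flag(
        paste0("unit_costs.", item), "nonnegative",
        paste0("negative or missing cost for item '", item, "'")
      )
    }
    if (!e$category %in% categories) {
      flag(
        paste0("unit_costs.", item), "category",
        paste0("unknown category '", e$category, "'")
      )
    }
  }

  check_line <- function(line, where) {
    if (!line$item %in% names(costs)) {
      flag(
        where, "referential",
        paste0("item '", line$item, "' not in unit-cost registry")
      )
    }
    fk <- line$frequency$kind
    kinds <- c("per_year", "every_n_weeks", "every_n_months", "once_at_diagnosis")
    if (!fk %in% kinds) {
      flag(where, "frequency", paste0("unknown frequency kind '", fk, "'"))
    } else if (fk %in% c("every_n_weeks", "every_n_months")) {
      if (!is_scalar_number(line$frequency$n) || line$frequency$n <= 0) {
        flag(where, "frequency", "interval n must be > 0")
      }
    } else if (fk == "per_year") {
      cnt <- line$frequency$count
      if (!is_scalar_number(cnt) || cnt < 0) {
        flag(where, "frequency", "per_year count must be >= 0 and finite")
      }
    }
    if (!is_scalar_number(line$multiplicity) || line$multiplicity <= 0) {
      flag(where, "multiplicity", "multiplicity must be > 0")
    }
  }
  for (g in names(params$protocols)) {
    lines <- params$protocols[[g]]
    for (i in seq_along(lines)) {
      check_line(lines[[i]], paste0("protocols.", g, ".", i))
    }
  }
  for (g in names(params$adverse_events)) {
    aes <- params$adverse_events[[g]]
    for (i in seq_along(aes)) {
      ae <- aes[[i]]
      where <- paste0("adverse_events.", g, ".", i)
      if (!is_fraction(ae$probability)) {
        flag(where, "fraction", "probability out of [0,1]")
      }
      for (j in seq_along(ae$cost_bundle)) {
        check_line(ae$cost_bundle[[j]], paste0(where, ".cost_bundle.", j))
      }
    }
  }

  ss <- params$supportive_settings
  needs <- function(flagname, item) {
    used <- any(vapply(
      params$supportive_care, function(f) isTRUE(f[[flagname]]), logical(1)
    ))
    if (used && !item %in% names(costs)) {
      flag(
        paste0("supportive_settings.", flagname), "referential",
        paste0("item '", item, "' not in unit-cost registry")
      )
    }
  }
  needs("visual_aids", ss$visual_aid_item)
  needs("psychological", ss$psychologist_item)
  if (!is_scalar_number(ss$psychologist_visits_per_year) ||
    ss$psychologist_visits_per_year < 0) {
    flag(
      "supportive_settings.psychologist_visits_per_year", "nonnegative",
      "must be >= 0"
    )
  }

  pr <- params$productivity
  if (!is_fraction(pr$employment_rate)) {
    flag("productivity.employment_rate", "fraction", "fraction out of [0,1]")
  }
  for (m in c("absenteeism_days", "caregiver_days")) {
    for (g in names(pr[[m]])) {
      if (!is_scalar_number(pr[[m]][[g]]) || pr[[m]][[g]] < 0) {
        flag(paste0("productivity.", m, ".", g), "nonnegative", "days must be >= 0")
      }
    }
  }
  for (f in c("monthly_salary_sar", "daily_wage_general_sar")) {
    if (!is_scalar_number(pr[[f]]) || pr[[f]] < 0) {
      flag(paste0("productivity.", f), "nonnegative", "must be >= 0")
    }
  }
  if (!is_scalar_number(pr$working_days_per_month) ||
    pr$working_days_per_month <= 0) {
    flag("productivity.working_days_per_month", "positive", "must be > 0")
  }

  ec <- params$economy
  for (f in c(
    "ppp_rate_sar_per_intl_dollar", "gdp_sar", "pension_annual_sar",
    "nurse_annual_salary_sar"
  )) {
    if (!is_scalar_number(ec[[f]]) || ec[[f]] <= 0) {
      flag(paste0("economy.", f), "positive", "must be strictly positive")
    }
  }

  report <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    data.frame(
      field = character(0), rule = character(0), message = character(0),
      stringsAsFactors = FALSE
    )
  }
  class(report) <- c("coi_validation", "data.frame")
  report
}

#' @export
print.coi_validation <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("Parameter set valid: no violations.\n")
  } else {
    cat(nrow(x), "violation(s):\n")
    for (i in seq_len(nrow(x))) {
      cat("  - [", x$field[i], "] ", x$message[i], "\n", sep = "")
    }
  }
  invisible(x)
}

#' @export
print.coi_parameters <- function(x, ...) {
  cat("Cost-of-illness model parameters (coi_schema ", x$coi_schema, ")\n",
    sep = ""
  )
  cat(
    "  adult population: ", format(x$population$adult_population, big.mark = ","),
    "; diabetic prevalence: ", x$population$diabetic_prevalence * 100, "%\n",
    sep = ""
  )
  cat(
    "  unit costs: ", length(x$unit_costs), " items; protocols for ",
    length(x$protocols), " grade(s)\n",
    sep = ""
  )
  invisible(x)
}
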