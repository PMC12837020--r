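direct_components <- function() {
  c(
    "medication", "surgery_resources", "adverse_events",
    "psychological", "visual_aids", "home_nurse"
  )
}

#' Annualize a frequency specification
#'
#' Converts the protocol frequency forms to events per year: an event every
#' n weeks occurs 52/n times a year (a 4-weekly anti-VEGF injection is 13
#' injections, not 12), every n months 12/n times, a one-off at diagnosis
#' once within the one-year horizon, and `per_year` carries its count
#' directly.
#'
#' @param freq a frequency spec: list with `kind` in `per_year`,
#'   `every_n_weeks`, `every_n_months`, `once_at_diagnosis`, and `n` or
#'   `count` as the kind requires.
#' @return events per year.
#' @examples
#' annualize(list(kind = "every_n_weeks", n = 4)) # 13
#' annualize(list(kind = "every_n_months", n = 6)) # 2
#' @export
annualize <- function(freq) {
  kind <- freq$kind
  if (kind %in% c("every_n_weeks", "every_n_months")) {
    n <- freq$n
    if (!is_scalar_number(n) || n <= 0) {
      stop("frequency interval n must be > 0", call. = FALSE)
    }
    return(if (kind == "every_n_weeks") 52 / n else 12 / n)
  }
  if (kind == "once_at_diagnosis") {
    return(1)
  }
  if (kind == "per_year") {
    cnt <- freq$count
    if (!is_scalar_number(cnt) || cnt < 0) {
      stop("per_year count must be >= 0 and finite", call. = FALSE)
    }
    return(cnt)
  }
  stop("unknown frequency kind '", kind, "'", call. = FALSE)
}

# annual cost of a list of protocol lines for one patient, split into the
# medication vs surgery/resources buckets by the item's registry category
line_cost <- function(line, costs) {
  entry <- costs[[line$item]]
  if (is.null(entry)) {
    stop("item '", line$item, "' not in unit-cost registry", call. = FALSE)
  }
  annualize(line$frequency) * line$multiplicity * entry$cost_sar
}

#' Annual protocol cost per patient
#'
#' Sums `events/year x multiplicity x unit cost` over the protocol lines,
#' accumulating drug acquisition (registry category `medication`) into the
#' medication bucket and everything else (procedures, monitoring,
#' diagnostics) into the surgery-and-resources bucket.
#'
#' @param lines list of protocol lines (`item`, `frequency`,
#'   `multiplicity`).
#' @param costs the unit-cost registry (named list with `cost_sar`,
#'   `category`).
#' @return named numeric vector `c(medication =, surgery_resources =)`, SAR
#'   per patient-year.
#' @examples
#' costs <- list(anti_vegf = list(cost_sar = 2942.4, category = "medication"))
#' protocol_cost_per_patient(
#'   list(list(
#'     item = "anti_vegf",
#'     frequency = list(kind = "every_n_weeks", n = 4), multiplicity = 1
#'   )),
#'   costs
#' )
#' @export
protocol_cost_per_patient <- function(lines, costs) {
  out <- c(medication = 0, surgery_resources = 0)
  for (line in lines) {
    cost <- line_cost(line, costs) # also checks the item resolves
    bucket <- if (costs[[line$item]]$category == "medication") {
      "medication"
    } else {
      "surgery_resources"
    }
    out[[bucket]] <- out[[bucket]] + cost
  }
  out
}

#' Expected annual adverse-event cost per treated patient
#'
#' Deterministic expected-value costing: each adverse event contributes
#' `probability x annual cost of its management bundle`; no stochastic
#' draws are made.
#'
#' @param aes list of adverse-event specs (`name`, `probability`,
#'   `cost_bundle`).
#' @param costs unit-cost registry.
#' @return SAR per patient-year.
#' @export
expected_adverse_event_cost <- function(aes, costs) {
  total <- 0
  for (ae in aes) {
    if (!is_fraction(ae$probability)) {
      stop("adverse-event probability out of [0,1]", call. = FALSE)
    }
    bundle <- sum(vapply(ae$cost_bundle, line_cost, numeric(1), costs = costs))
    total <- total + ae$probability * bundle
  }
  total
}

#' Annual supportive-care cost per patient
#'
#' Applies the grade's eligibility flags: visual aids charge the annual
#' optical-device cost; psychological support charges the configured
#' number of psychologist visits per year; home nursing charges the annual
#' home-nurse salary. Pension is a transfer, not a direct medical cost,
#' and is handled by the indirect engine.
#'
#' @param grade a severity-grade code.
#' @param params a `coi_parameters` object.
#' @return named numeric vector `c(psychological =, visual_aids =,
#'   home_nurse =)`, SAR per patient-year.
#' @examples
#' supportive_care_cost("R1", ksa_parameters()) # visual aids only
#' @export
supportive_care_cost <- function(grade, params) {
  flags <- params$supportive_care[[grade]]
  if (is.null(flags)) {
    stop("no supportive-care flags for grade '", grade, "'", call. = FALSE)
  }
  ss <- params$supportive_settings
  costs <- params$unit_costs
  out <- c(psychological = 0, visual_aids = 0, home_nurse = 0)
  if (isTRUE(flags$visual_aids)) {
    out[["visual_aids"]] <- costs[[ss$visual_aid_item]]$cost_sar
  }
  if (isTRUE(flags$psychological)) {
    out[["psychological"]] <-
      ss$psychologist_visits_per_year * costs[[ss$psychologist_item]]$cost_sar
  }
  if (isTRUE(flags$home_nurse)) {
    out[["home_nurse"]] <- params$economy$nurse_annual_salary_sar
  }
  out
}

#' Direct medical costs across the cascade
#'
#' Per grade, the per-patient annual direct cost is the sum of its
#' treatment-protocol cost, the expected adverse-event cost, and
#' supportive care; grade totals multiply by the cascade's patient counts
#' and component totals sum across grades. The same money is partitioned
#' two ways: by grade and by the six components (medication,
#' surgery/resources, adverse events, psychological, visual aids, home
#' nurse).
#'
#' @param cascade a `coi_cascade` from [build_cascade()].
#' @param params a `coi_parameters` object.
#' @return an object of class `coi_direct`: list with matrix
#'   `by_grade_component` (grades x components, SAR/year), vectors
#'   `per_component`, `per_grade_total` (SAR/year) and
#'   `per_grade_per_patient` (SAR/patient-year), and scalar `total_sar`.
#' @examples
#' p <- ksa_parameters()
#' d <- direct_costs(build_cascade(p), p)
#' d$per_component
#' @export
direct_costs <- function(cascade, params) {
  grades <- names(cascade$grade_counts)
  comps <- direct_components()
  per_patient <- matrix(0,
    nrow = length(grades), ncol = length(comps),
    dimnames = list(grades, comps)
  )
  for (g in grades) {
    pc <- protocol_cost_per_patient(
      params$protocols[[g]] %||% list(), params$unit_costs
    )
    per_patient[g, "medication"] <- pc[["medication"]]
    per_patient[g, "surgery_resources"] <- pc[["surgery_resources"]]
    per_patient[g, "adverse_events"] <- expected_adverse_event_cost(
      params$adverse_events[[g]] %||% list(), params$unit_costs
    )
    sc <- supportive_care_cost(g, params)
    per_patient[g, names(sc)] <- sc
  }
  totals <- per_patient * cascade$grade_counts[grades]
  structure(
    list(
      by_grade_component = totals,
      per_component = colSums(totals),
      per_grade_total = rowSums(totals),
      per_grade_per_patient = rowSums(per_patient),
      total_sar = sum(totals)
    ),
    class = "coi_direct"
  )
}

#' @export
print.coi_direct <- function(x, ...) {
  cat("Direct medical costs (SAR/year)\n")
  for (cmp in names(x$per_component)) {
    cat(sprintf("  %-18s %s\n", cmp, fmt_sar(x$per_component[[cmp]])))
  }
  cat("  total:", fmt_sar(x$total_sar), "\n")
  invisible(x)
}

#' @export
#' @method as.data.frame coi_direct
as.data.frame.coi_direct <- function(x, ...) {
  df <- as.data.frame(x$by_grade_component)
  df <- cbind(grade = rownames(df), df, total = unname(x$per_grade_total))
  rownames(df) <- NULL
  df
}
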