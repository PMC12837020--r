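#' Daily wage from a monthly salary
#'
#' @param monthly_salary SAR per month.
#' @param working_days_per_month working days in a month (> 0).
#' @return SAR per working day.
#' @examples
#' daily_wage(4000, 22)
#' @export
daily_wage <- function(monthly_salary, working_days_per_month) {
  if (!is_scalar_number(working_days_per_month) || working_days_per_month <= 0) {
    stop("working days per month must be > 0", call. = FALSE)
  }
  monthly_salary / working_days_per_month
}

#' Human-capital productivity losses and pension transfers
#'
#' The model values lost production by the human capital method: days of
#' absenteeism times the daily wage, over the employed share of each
#' grade's population. Caregivers of moderate and severe patients lose
#' work days too, valued at the general wage with no employment-rate
#' attenuation. Government disability pensions are transfers counted per
#' eligible (pension-flagged) patient.
#'
#' @param grade_count persons in the grade.
#' @param employment_rate employed fraction in \[0, 1\].
#' @param absent_days work days lost per patient per year.
#' @param wage SAR per working day.
#' @return SAR per year.
#' @examples
#' patient_productivity_loss(100, 0.8, 28, daily_wage(4000, 22))
#' @export
patient_productivity_loss <- function(grade_count, employment_rate,
                                      absent_days, wage) {
  stopifnot(
    grade_count >= 0, absent_days >= 0, wage >= 0,
    employment_rate >= 0, employment_rate <= 1
  )
  grade_count * employment_rate * absent_days * wage
}

#' @rdname patient_productivity_loss
#' @param caregiver_days caregiver work days lost per patient per year.
#' @export
caregiver_productivity_loss <- function(grade_count, caregiver_days, wage) {
  stopifnot(grade_count >= 0, caregiver_days >= 0, wage >= 0)
  grade_count * caregiver_days * wage
}

#' @rdname patient_productivity_loss
#' @param eligible_count persons eligible for the disability pension.
#' @param pension_annual SAR per eligible person per year.
#' @export
pension_cost <- function(eligible_count, pension_annual) {
  stopifnot(eligible_count >= 0, pension_annual >= 0)
  eligible_count * pension_annual
}

# wage tier: severe, sight-threatening and blind patients use the printed
# monthly salary for severely vision-impaired individuals; mild/moderate
# patients (and all caregivers) use the GDP-derived general daily wage
patient_wage <- function(grade, productivity) {
  if (severity_class(grade) %in% c("severe", "sight_threatening", "blind")) {
    daily_wage(
      productivity$monthly_salary_sar,
      productivity$working_days_per_month
    )
  } else {
    productivity$daily_wage_general_sar
  }
}

#' Indirect costs across the cascade
#'
#' Applies [patient_productivity_loss()], [caregiver_productivity_loss()]
#' and [pension_cost()] per grade. Absenteeism days come from the
#' productivity assumptions (14/21/28 days for mild/moderate/severe, 261
#' days for sight-threatening grades); the employment rate attenuates all
#' patient losses, including the sight-threatening ones. Pension
#' eligibility follows the supportive-care `pension` flags.
#'
#' @param cascade a `coi_cascade`.
#' @param params a `coi_parameters` object.
#' @return an object of class `coi_indirect`: list with scalars
#'   `patient_productivity`, `caregiver_productivity`, `pension`,
#'   `total_sar`, and matrix `by_grade` (grades x the three components).
#' @examples
#' p <- ksa_parameters()
#' indirect_costs(build_cascade(p), p)$pension
#' @export
indirect_costs <- function(cascade, params) {
  pr <- params$productivity
  ec <- params$economy
  grades <- names(cascade$grade_counts)
  out <- matrix(0,
    nrow = length(grades), ncol = 3,
    dimnames = list(grades, c("patient", "caregiver", "pension"))
  )
  cg_wage <- pr$daily_wage_general_sar
  for (g in grades) {
    n <- cascade$grade_counts[[g]]
    out[g, "patient"] <- patient_productivity_loss(
      n, pr$employment_rate, pr$absenteeism_days[[g]] %||% 0,
      patient_wage(g, pr)
    )
    out[g, "caregiver"] <- caregiver_productivity_loss(
      n, pr$caregiver_days[[g]] %||% 0, cg_wage
    )
    if (isTRUE(params$supportive_care[[g]]$pension)) {
      out[g, "pension"] <- pension_cost(n, ec$pension_annual_sar)
    }
  }
  structure(
    list(
      by_grade = out,
      patient_productivity = sum(out[, "patient"]),
      caregiver_productivity = sum(out[, "caregiver"]),
      pension = sum(out[, "pension"]),
      total_sar = sum(out)
    ),
    class = "coi_indirect"
  )
}

#' @export
print.coi_indirect <- function(x, ...) {
  cat("Indirect costs (SAR/year)\n")
  cat("  patient productivity:  ", fmt_sar(x$patient_productivity), "\n")
  cat("  caregiver productivity:", fmt_sar(x$caregiver_productivity), "\n")
  cat("  government pension:    ", fmt_sar(x$pension), "\n")
  cat("  total:                 ", fmt_sar(x$total_sar), "\n")
  invisible(x)
}

#' @export
#' @method as.data.frame coi_indirect
as.data.frame.coi_indirect <- function(x, ...) {
  df <- as.data.frame(x$by_grade)
  df <- cbind(grade = rownames(df), df, total = rowSums(x$by_grade))
  rownames(df) <- NULL
  df
}
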