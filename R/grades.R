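#' Severity grades of diabetes-related visual impairment
#'
#' The model stratifies the diabetic population into six disease grades on
#' the Scottish grading system -- four diabetic retinopathy grades (R1--R4)
#' and two maculopathy grades (M1, M2) -- plus a separately counted blind
#' population (`BLIND`). Each grade carries a severity class used for
#' supportive-care eligibility and the productivity wage tier:
#'
#' * `R1` -- mild
#' * `R2`, `M1` -- moderate
#' * `R3` -- severe
#' * `R4`, `M2` -- sight-threatening
#' * `BLIND` -- blind
#'
#' @return `coi_grades()` returns the character vector of the seven grade
#'   codes in canonical order; `severity_class()` maps grade codes to their
#'   severity class.
#' @examples
#' coi_grades()
#' severity_class("M2")
#' @export
coi_grades <- function() {
  c("R1", "R2", "R3", "R4", "M1", "M2", "BLIND")
}

#' @rdname coi_grades
#' @param grade character vector of grade codes.
#' @export
severity_class <- function(grade) {
  map <- c(
    R1 = "mild", R2 = "moderate", M1 = "moderate", R3 = "severe",
    R4 = "sight_threatening", M2 = "sight_threatening", BLIND = "blind"
  )
  bad <- setdiff(grade, names(map))
  if (length(bad)) {
    stop("unknown severity grade(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  unname(map[grade])
}

# grades carrying a prevalence row in the population inputs (BLIND is
# counted through its own prevalence and is not overlap-corrected)
prevalence_grades <- function() c("R1", "R2", "R3", "R4", "M1", "M2")
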