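#' Apply a prevalence to a base population
#'
#' Counts are carried as continuous (fractional) persons throughout the
#' model; no rounding to whole persons is performed.
#'
#' @param base base population (persons, >= 0).
#' @param prevalence fraction in \[0, 1\].
#' @return `base * prevalence`, in persons.
#' @examples
#' scale_population(12830572, 0.177) # diabetic adults
#' @export
scale_population <- function(base, prevalence) {
  if (!is_scalar_number(base) || base < 0) {
    stop("base population must be a nonnegative number", call. = FALSE)
  }
  if (!is_fraction(prevalence)) {
    stop("prevalence out of [0,1]", call. = FALSE)
  }
  base * prevalence
}

#' Overlap correction factor
#'
#' Patients can have both retinopathy and maculopathy; summing the two
#' prevalence groups would double-count them. The model corrects with
#'
#' \deqn{CF = \frac{\mathrm{combined}}{\mathrm{retinopathy} + \mathrm{maculopathy}}}
#'
#' where `combined` counts patients with retinopathy and/or maculopathy.
#' The factor lies in (0, 1] and multiplies every severity-grade count.
#'
#' @param retinopathy persons with any retinopathy.
#' @param maculopathy persons with any maculopathy.
#' @param combined persons with retinopathy and/or maculopathy; must not
#'   exceed `retinopathy + maculopathy`.
#' @return the correction factor, a fraction in (0, 1].
#' @examples
#' correction_factor(783498.88, 461015.28, 835732.14)
#' @export
correction_factor <- function(retinopathy, maculopathy, combined) {
  stopifnot(
    is_scalar_number(retinopathy), is_scalar_number(maculopathy),
    is_scalar_number(combined)
  )
  denom <- retinopathy + maculopathy
  if (denom <= 0) {
    stop("retinopathy + maculopathy must be > 0", call. = FALSE)
  }
  if (combined < 0 || combined > denom + 1e-9 * denom) {
    stop("combined count must lie in [0, retinopathy + maculopathy]",
      call. = FALSE
    )
  }
  combined / denom
}

#' Build the population cascade
#'
#' Derives all model populations from the prevalence inputs: diabetic,
#' blind, any-retinopathy, any-maculopathy and combined counts via
#' [scale_population()], the overlap [correction_factor()] from the three
#' derived counts, and per-grade counts as
#' `grade prevalence x diabetic count x correction factor` for the six
#' R/M grades. The blind count is not overlap-corrected.
#'
#' @param params a `coi_parameters` object, or a bare `population` input
#'   list with the same fields.
#' @return an object of class `coi_cascade`: list with `diabetic_count`,
#'   `blind_count`, `retinopathy_count`, `maculopathy_count`,
#'   `combined_count`, `correction_factor` and named vector `grade_counts`
#'   (six R/M grades plus `BLIND`).
#' @examples
#' cas <- build_cascade(ksa_parameters())
#' cas$grade_counts[["R1"]]
#' @export
build_cascade <- function(params) {
  pop <- if (inherits(params, "coi_parameters")) params$population else params
  diabetic <- scale_population(pop$adult_population, pop$diabetic_prevalence)
  blind <- scale_population(diabetic, pop$blindness_prevalence)
  retino <- scale_population(diabetic, pop$retinopathy_prevalence)
  maculo <- scale_population(diabetic, pop$maculopathy_prevalence)
  combined <- scale_population(diabetic, pop$combined_prevalence)
  cf <- if (retino + maculo > 0) {
    correction_factor(retino, maculo, combined)
  } else {
    1 # degenerate cascade with no disease: nothing to correct
  }
  gp <- pop$grade_prevalence
  grades <- prevalence_grades()
  counts <- vapply(
    grades,
    function(g) scale_population(diabetic, gp[[g]]) * cf,
    numeric(1)
  )
  counts <- c(counts, BLIND = blind)
  structure(
    list(
      diabetic_count = diabetic, blind_count = blind,
      retinopathy_count = retino, maculopathy_count = maculo,
      combined_count = combined, correction_factor = cf,
      grade_counts = counts
    ),
    class = "coi_cascade"
  )
}

#' @export
print.coi_cascade <- function(x, ...) {
  cat("Population cascade\n")
  cat("  diabetic:    ", fmt_sar(x$diabetic_count), "\n")
  cat("  blind:       ", fmt_sar(x$blind_count), "\n")
  cat("  retinopathy: ", fmt_sar(x$retinopathy_count), "\n")
  cat("  maculopathy: ", fmt_sar(x$maculopathy_count), "\n")
  cat("  combined:    ", fmt_sar(x$combined_count), "\n")
  cat("  correction factor:", format(x$correction_factor, digits = 7), "\n")
  cat("  grade counts:\n")
  for (g in names(x$grade_counts)) {
    cat(sprintf("    %-6s %s\n", g, fmt_sar(x$grade_counts[[g]])))
  }
  invisible(x)
}

#' @export
#' @method as.data.frame coi_cascade
as.data.frame.coi_cascade <- function(x, ...) {
  data.frame(
    grade = names(x$grade_counts),
    count = unname(x$grade_counts),
    stringsAsFactors = FALSE
  )
}
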