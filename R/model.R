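#' Run the full cost-of-illness model
#'
#' The single entry point tying the pipeline together: builds the
#' population cascade from the prevalence inputs, costs each severity
#' grade's treatment protocol, expected adverse events and supportive
#' care, values productivity losses and pensions, and aggregates to the
#' headline burden with currency conversion and GDP share.
#'
#' @param params a `coi_parameters` object (e.g. [ksa_parameters()] or
#'   [load_parameters()]), or a path to a parameter file.
#' @return an object of class `coi_model`: list with `params`, `cascade`
#'   (`coi_cascade`), `direct` (`coi_direct`), `indirect`
#'   (`coi_indirect`) and `result` (`coi_result`).
#' @examples
#' fit <- coi_model(ksa_parameters())
#' fit
#' coef(fit)
#' @export
coi_model <- function(params) {
  if (is.character(params)) params <- load_parameters(params)
  params <- as_coi_parameters(params)
  report <- validate_parameters(params)
  if (nrow(report) > 0L) {
    stop(
      "invalid parameters:\n",
      paste0("  - [", report$field, "] ", report$message, collapse = "\n"),
      call. = FALSE
    )
  }
  cascade <- build_cascade(params)
  direct <- direct_costs(cascade, params)
  indirect <- indirect_costs(cascade, params)
  result <- aggregate_costs(direct, indirect, params$economy)
  structure(
    list(
      params = params, cascade = cascade, direct = direct,
      indirect = indirect, result = result
    ),
    class = "coi_model"
  )
}

#' @export
print.coi_model <- function(x, ...) {
  cat("Prevalence-based cost-of-illness model (one-year horizon)\n\n")
  print(x$result)
  invisible(x)
}

#' @export
summary.coi_model <- function(object, ...) {
  structure(object, class = c("summary.coi_model", class(object)))
}

#' @export
print.summary.coi_model <- function(x, ...) {
  print.coi_model(x)
  cat("\n")
  print(x$cascade)
  cat("\n")
  print(x$direct)
  cat("\n")
  print(x$indirect)
  invisible(x)
}

#' @export
coef.coi_model <- function(object, ...) {
  r <- object$result
  c(
    direct_sar = r$direct_sar, indirect_sar = r$indirect_sar,
    total_sar = r$total_sar, total_intl = r$total_intl,
    direct_share = r$direct_share, indirect_share = r$indirect_share,
    gdp_share = r$gdp_share
  )
}

#' Component bar chart of the modelled burden
#'
#' @param x a `coi_model` object.
#' @param ... further arguments passed to [graphics::barplot()].
#' @return `x`, invisibly.
#' @export
plot.coi_model <- function(x, ...) {
  comp <- c(x$result$components$direct, x$result$components$indirect)
  old <- graphics::par(mar = c(9, 5, 2, 1))
  on.exit(graphics::par(old))
  graphics::barplot(comp / 1e9,
    las = 2, ylab = "SAR (billions)/year",
    main = "Annual burden by component",
    col = c(
      rep("steelblue", length(x$result$components$direct)),
      rep("indianred", length(x$result$components$indirect))
    ), ...
  )
  invisible(x)
}
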