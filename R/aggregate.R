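#' Convert SAR to international dollars
#'
#' @param amount_sar money in SAR.
#' @param ppp purchasing-power-parity exchange rate, SAR per international
#'   dollar (> 0).
#' @return money in international dollars.
#' @examples
#' convert_currency(37000, 1.85) # 20000
#' @export
convert_currency <- function(amount_sar, ppp) {
  if (!is_scalar_number(ppp) || ppp <= 0) {
    stop("PPP rate must be strictly positive", call. = FALSE)
  }
  amount_sar / ppp
}

#' Derive the PPP rate from printed currency pairs
#'
#' The unit-cost table prints each cost in SAR and international dollars;
#' the implied exchange rate is recovered as the median of the SAR/I$
#' ratios, which is robust to rounding noise in individual pairs.
#'
#' @param pairs a two-column data frame or matrix: SAR amounts and the
#'   corresponding international-dollar amounts.
#' @return the SAR-per-international-dollar rate.
#' @examples
#' derive_ppp_rate(data.frame(sar = c(37000, 2942.4), intl = c(20000, 1590.49)))
#' @export
derive_ppp_rate <- function(pairs) {
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) == 0L) {
    stop("need at least one SAR/I$ pair", call. = FALSE)
  }
  sar <- pairs[[1]]
  intl <- pairs[[2]]
  keep <- intl != 0
  if (!any(keep)) {
    stop("need at least one pair with a nonzero I$ value", call. = FALSE)
  }
  stats::median(sar[keep] / intl[keep])
}

#' Aggregate direct and indirect costs into the headline result
#'
#' Sums the component breakdowns to the total annual burden, splits it
#' into direct/indirect shares, converts every figure to international
#' dollars at the PPP rate, and relates the total to GDP.
#'
#' @param direct a `coi_direct` object, or a named numeric vector of
#'   direct component totals (SAR/year).
#' @param indirect a `coi_indirect` object, or a named numeric vector with
#'   elements `pension`, `patient`, `caregiver` (SAR/year).
#' @param economy the `economy` block of a `coi_parameters` object
#'   (`ppp_rate_sar_per_intl_dollar`, `gdp_sar`, ...).
#' @return an object of class `coi_result` with fields `direct_sar`,
#'   `indirect_sar`, `total_sar`, their international-dollar counterparts
#'   `*_intl`, `direct_share`, `indirect_share`, `gdp_share`,
#'   `degenerate` (TRUE when the total is zero and shares are reported as
#'   0), and the two component breakdowns under `components`.
#' @examples
#' p <- ksa_parameters()
#' cas <- build_cascade(p)
#' aggregate_costs(direct_costs(cas, p), indirect_costs(cas, p), p$economy)
#' @export
aggregate_costs <- function(direct, indirect, economy) {
  direct_comp <- if (inherits(direct, "coi_direct")) {
    direct$per_component
  } else {
    unlist(direct)
  }
  indirect_comp <- if (inherits(indirect, "coi_indirect")) {
    c(
      pension = indirect$pension,
      patient = indirect$patient_productivity,
      caregiver = indirect$caregiver_productivity
    )
  } else {
    unlist(indirect)
  }
  stopifnot(all(direct_comp >= 0), all(indirect_comp >= 0))
  ppp <- economy$ppp_rate_sar_per_intl_dollar
  if (!is_scalar_number(ppp) || ppp <= 0) {
    stop("PPP rate must be strictly positive", call. = FALSE)
  }

  direct_sar <- sum(direct_comp)
  indirect_sar <- sum(indirect_comp)
  total_sar <- direct_sar + indirect_sar
  degenerate <- total_sar == 0
  structure(
    list(
      direct_sar = direct_sar,
      indirect_sar = indirect_sar,
      total_sar = total_sar,
      direct_intl = convert_currency(direct_sar, ppp),
      indirect_intl = convert_currency(indirect_sar, ppp),
      total_intl = convert_currency(total_sar, ppp),
      direct_share = if (degenerate) 0 else direct_sar / total_sar,
      indirect_share = if (degenerate) 0 else indirect_sar / total_sar,
      gdp_share = total_sar / economy$gdp_sar,
      degenerate = degenerate,
      components = list(direct = direct_comp, indirect = indirect_comp)
    ),
    class = "coi_result"
  )
}

#' @export
print.coi_result <- function(x, ...) {
  ppct <- function(s) sprintf("%.0f%%", 100 * s)
  cat("Annual economic burden\n")
  cat(
    "  direct:   SAR ", fmt_sar(x$direct_sar), "  (I$ ",
    fmt_sar(x$direct_intl), "; ", ppct(x$direct_share), ")\n",
    sep = ""
  )
  cat(
    "  indirect: SAR ", fmt_sar(x$indirect_sar), "  (I$ ",
    fmt_sar(x$indirect_intl), "; ", ppct(x$indirect_share), ")\n",
    sep = ""
  )
  cat(
    "  total:    SAR ", fmt_sar(x$total_sar), "  (I$ ",
    fmt_sar(x$total_intl), ")\n",
    sep = ""
  )
  cat(sprintf("  share of GDP: %.1f%%\n", 100 * x$gdp_share))
  if (x$degenerate) cat("  (zero total; shares reported as 0)\n")
  invisible(x)
}
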