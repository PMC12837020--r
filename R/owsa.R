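# dotted paths of every numeric scalar leaf eligible for perturbation;
# schema marker, annotations and the owsa scope block itself are not
# model inputs and are excluded
owsa_excluded_keys <- c("coi_schema", "annotations", "owsa")

#' Enumerate perturbable parameters
#'
#' Walks the parameter tree and returns the sorted, deterministic list of
#' dotted paths to every numeric scalar leaf (prevalences, unit costs,
#' probabilities, frequencies, day counts, wages, rates). Booleans, labels
#' and annotations are excluded. Unnamed list positions (protocol lines,
#' adverse events) appear as 1-based indices, e.g.
#' `"protocols.M1.2.frequency.n"`.
#'
#' @param params a `coi_parameters` object.
#' @return character vector of parameter paths, sorted.
#' @examples
#' head(enumerate_parameters(ksa_parameters()))
#' @export
enumerate_parameters <- function(params) {
  params <- as_coi_parameters(params)
  walk <- function(x, prefix) {
    if (is.list(x)) {
      keys <- names(x) %||% rep("", length(x))
      out <- character(0)
      for (i in seq_along(x)) {
        key <- if (nzchar(keys[i])) keys[i] else as.character(i)
        if (prefix == "" && key %in% owsa_excluded_keys) next
        if (key == "annotations") next
        out <- c(out, walk(x[[i]], paste0(
          if (nzchar(prefix)) paste0(prefix, ".") else "", key
        )))
      }
      return(out)
    }
    if (is.numeric(x)) {
      if (length(x) == 1L && is.null(names(x))) {
        return(prefix)
      }
      if (!is.null(names(x))) {
        return(paste0(prefix, ".", names(x)))
      }
    }
    character(0)
  }
  sort(walk(unclass(params), ""))
}

# leaves that are probabilities or fractions clamp at 1 under perturbation
is_fraction_path <- function(path) {
  grepl("prevalence|probability|employment_rate", path)
}

#' Multiplicatively perturb one parameter
#'
#' Returns a copy of the parameter set with the addressed leaf multiplied
#' by `multiplier`; the original is untouched. Leaves that are fractions
#' (prevalences, probabilities, employment rate) are clamped at 1, and the
#' clamp is recorded in the `"clamped"` attribute of the result.
#'
#' @param params a `coi_parameters` object.
#' @param path dotted parameter path (see [enumerate_parameters()]).
#' @param multiplier positive factor.
#' @return the perturbed `coi_parameters`, with attribute `clamped`.
#' @examples
#' p2 <- perturb(ksa_parameters(), "population.diabetic_prevalence", 1.2)
#' p2$population$diabetic_prevalence
#' @export
perturb <- function(params, path, multiplier) {
  params <- as_coi_parameters(params)
  if (!is_scalar_number(multiplier) || multiplier <= 0) {
    stop("multiplier must be > 0", call. = FALSE)
  }
  value <- path_get(unclass(params), path)
  if (!is_scalar_number(value)) {
    stop("path '", path, "' does not address a numeric scalar", call. = FALSE)
  }
  new <- value * multiplier
  clamped <- FALSE
  if (is_fraction_path(path) && new > 1) {
    new <- 1
    clamped <- TRUE
  }
  out <- as_coi_parameters(path_set(unclass(params), path, new))
  attr(out, "clamped") <- clamped
  out
}

# total annual burden for a parameter set; every intermediate (cascade
# included) is recomputed, nothing is cached across perturbations
coi_total_sar <- function(params) {
  cascade <- build_cascade(params)
  aggregate_costs(
    direct_costs(cascade, params),
    indirect_costs(cascade, params),
    params$economy
  )$total_sar
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Varies each eligible parameter one at a time by `+/- fraction`
#' (multiplicatively), recomputes the total annual burden from scratch,
#' and ranks parameters by the span `|high - low|` for a tornado diagram.
#' The parameter scope defaults to every path from
#' [enumerate_parameters()], optionally restricted by the `owsa:` block of
#' the configuration (`include` / `exclude` path lists) or by the `paths`
#' argument.
#'
#' @param params a `coi_parameters` object.
#' @param fraction perturbation fraction (default 0.2, i.e. +/-20%).
#' @param paths optional character vector restricting the analysed
#'   parameters.
#' @return a data frame of class `coi_owsa`, sorted by decreasing span
#'   (ties broken by path name): columns `parameter`, `baseline_output`,
#'   `low_output`, `high_output`, `span`, `clamped`; the shared baseline
#'   and fraction are carried as attributes.
#' @examples
#' tor <- one_way_sensitivity(ksa_parameters(), fraction = 0.2)
#' head(tor, 3)
#' @export
one_way_sensitivity <- function(params, fraction = 0.2, paths = NULL) {
  params <- as_coi_parameters(params)
  if (!is_scalar_number(fraction) || fraction < 0 || fraction >= 1) {
    stop("fraction must lie in [0, 1)", call. = FALSE)
  }
  if (is.null(paths)) {
    paths <- enumerate_parameters(params)
    scope <- params$owsa
    if (!is.null(scope$include)) {
      paths <- intersect(paths, unlist(scope$include))
    }
    if (!is.null(scope$exclude)) {
      paths <- setdiff(paths, unlist(scope$exclude))
    }
  }
  baseline <- coi_total_sar(params)
  eval_at <- function(path, mult) {
    if (mult == 1) {
      return(list(value = baseline, clamped = FALSE))
    }
    p <- perturb(params, path, mult)
    list(value = coi_total_sar(p), clamped = attr(p, "clamped"))
  }
  rows <- lapply(paths, function(path) {
    lo <- eval_at(path, 1 - fraction)
    hi <- eval_at(path, 1 + fraction)
    data.frame(
      parameter = path,
      baseline_output = baseline,
      low_output = lo$value,
      high_output = hi$value,
      span = abs(hi$value - lo$value),
      clamped = lo$clamped || hi$clamped,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$span, out$parameter), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("coi_owsa", "data.frame")
  attr(out, "baseline") <- baseline
  attr(out, "fraction") <- fraction
  out
}

#' @export
print.coi_owsa <- function(x, n = 10, ...) {
  cat(
    "One-way sensitivity analysis (+/-",
    100 * attr(x, "fraction"), "%), baseline SAR ",
    fmt_sar(attr(x, "baseline")), "\n",
    sep = ""
  )
  top <- utils::head(x, n)
  for (i in seq_len(nrow(top))) {
    cat(sprintf(
      "  %2d. %-45s span SAR %s%s\n", i, top$parameter[i],
      fmt_sar(top$span[i]), if (top$clamped[i]) " [clamped]" else ""
    ))
  }
  if (nrow(x) > n) cat("  ... and", nrow(x) - n, "more parameters\n")
  invisible(x)
}

#' Tornado diagram
#'
#' Horizontal bars for the top-ranked parameters, from the low-output to
#' the high-output total, centered on the shared baseline.
#'
#' @param x a `coi_owsa` object.
#' @param n number of top parameters to draw.
#' @param ... further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.coi_owsa <- function(x, n = 12, ...) {
  top <- utils::head(x, n)
  top <- top[rev(seq_len(nrow(top))), ]
  baseline <- attr(x, "baseline")
  xlim <- range(c(top$low_output, top$high_output, baseline))
  old <- graphics::par(mar = c(4.5, 16, 2, 1))
  on.exit(graphics::par(old))
  graphics::plot(NA,
    xlim = xlim, ylim = c(0.5, nrow(top) + 0.5),
    yaxt = "n", xlab = "total annual burden (SAR)", ylab = "",
    main = "One-way sensitivity (tornado)", ...
  )
  for (i in seq_len(nrow(top))) {
    graphics::segments(top$low_output[i], i, top$high_output[i], i,
      lwd = 8, col = "steelblue"
    )
  }
  graphics::abline(v = baseline, lty = 2)
  graphics::axis(2, at = seq_len(nrow(top)), labels = top$parameter, las = 1, cex.axis = 0.7)
  invisible(x)
}
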