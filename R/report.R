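# File-producing commands behind the `coi` command-line tool. Each
# returns a status code instead of raising for bad user input, mirroring
# shell exit conventions: 0 success, 1 I/O failure, 2 invalid input.

write_money_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.2f", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

write_manifest <- function(outdir, config, params, command, options, files) {
  manifest <- list(
    command = command,
    config = if (is.null(config)) NA else normalizePath(config),
    coi_schema = if (is.null(params)) NA else params$coi_schema,
    tool = "coivis",
    tool_version = as.character(utils::packageVersion("coivis")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    options = options,
    outputs = basename(files)
  )
  path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

load_or_status <- function(config) {
  if (!is.character(config) || !file.exists(config)) {
    return(list(status = 2L, message = paste0("config not found: ", config)))
  }
  tryCatch(
    list(status = 0L, params = load_parameters(config)),
    error = function(e) list(status = 2L, message = conditionMessage(e))
  )
}

#' Run the model from a configuration file and write its reports
#'
#' Produces, under `outdir`: `summary.json` (the headline result),
#' `cascade.csv`, `direct_costs.csv` and `indirect_costs.csv` (per-grade
#' breakdowns, money to 2 decimals), and `manifest.json` describing the
#' run. Re-running with the same configuration and options reproduces
#' identical result files (the manifest timestamp aside).
#'
#' @param config path to a parameter file.
#' @param outdir output directory (created if absent).
#' @return invisibly, a list with `status` (0 ok, 1 I/O failure, 2
#'   invalid input), `files`, and `message` on failure.
#' @examples
#' out <- coi_run(
#'   system.file("extdata", "ksa_2024.yaml", package = "coivis"),
#'   tempfile("run")
#' )
#' out$status
#' @export
coi_run <- function(config, outdir) {
  loaded <- load_or_status(config)
  if (loaded$status != 0L) {
    return(invisible(loaded))
  }
  params <- loaded$params
  res <- tryCatch(
    {
      dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
      fit <- coi_model(params)
      r <- fit$result
      summary_path <- file.path(outdir, "summary.json")
      jsonlite::write_json(
        list(
          total_sar = r$total_sar, direct_sar = r$direct_sar,
          indirect_sar = r$indirect_sar, total_intl = r$total_intl,
          direct_intl = r$direct_intl, indirect_intl = r$indirect_intl,
          direct_share = r$direct_share, indirect_share = r$indirect_share,
          gdp_share = r$gdp_share
        ),
        summary_path,
        auto_unbox = TRUE, digits = NA, pretty = TRUE
      )
      files <- c(
        summary_path,
        write_money_csv(
          as.data.frame(fit$cascade), file.path(outdir, "cascade.csv")
        ),
        write_money_csv(
          as.data.frame(fit$direct), file.path(outdir, "direct_costs.csv")
        ),
        write_money_csv(
          as.data.frame(fit$indirect), file.path(outdir, "indirect_costs.csv")
        )
      )
      files <- c(files, write_manifest(
        outdir, config, params, "run", list(), files
      ))
      list(status = 0L, files = files)
    },
    error = function(e) list(status = 1L, message = conditionMessage(e))
  )
  invisible(res)
}

#' One-way sensitivity analysis from a configuration file
#'
#' Writes `tornado.tsv` (parameter, low/high outputs, span, clamp flag,
#' ranked by span) and `tornado.json` (ranked bar data for plotting),
#' plus a manifest.
#'
#' @inheritParams coi_run
#' @param fraction perturbation fraction in \[0, 1).
#' @return invisibly, a status list as in [coi_run()].
#' @export
coi_owsa_run <- function(config, outdir, fraction = 0.2) {
  if (!is_scalar_number(fraction) || fraction < 0 || fraction >= 1) {
    return(invisible(list(
      status = 2L,
      message = paste0("invalid fraction: ", fraction)
    )))
  }
  loaded <- load_or_status(config)
  if (loaded$status != 0L) {
    return(invisible(loaded))
  }
  res <- tryCatch(
    {
      dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
      tor <- one_way_sensitivity(loaded$params, fraction = fraction)
      tsv <- file.path(outdir, "tornado.tsv")
      utils::write.table(tor, tsv,
        sep = "\t", row.names = FALSE, quote = FALSE
      )
      js <- file.path(outdir, "tornado.json")
      jsonlite::write_json(
        list(
          baseline = attr(tor, "baseline"), fraction = fraction,
          bars = tor
        ),
        js,
        auto_unbox = TRUE, digits = NA, pretty = TRUE
      )
      files <- c(tsv, js)
      files <- c(files, write_manifest(
        outdir, config, loaded$params, "owsa",
        list(fraction = fraction), files
      ))
      list(status = 0L, files = files)
    },
    error = function(e) list(status = 1L, message = conditionMessage(e))
  )
  invisible(res)
}

#' Generate a synthetic scenario and its oracle report
#'
#' Writes the generated scenario as `scenario.yaml` (same schema as real
#' configurations) and `oracle_report.json` comparing the pipeline total
#' with the independent [oracle_total()] enumeration.
#'
#' @param seed integer seed for [generate_scenario()].
#' @param outdir output directory.
#' @param ... further arguments passed to [generate_scenario()].
#' @return invisibly, a status list as in [coi_run()].
#' @export
coi_synth_run <- function(seed, outdir, ...) {
  res <- tryCatch(
    {
      dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
      params <- generate_scenario(seed = seed, ...)
      scenario_path <- file.path(outdir, "scenario.yaml")
      write_parameters(params, scenario_path)
      pipeline <- coi_model(params)$result$total_sar
      oracle <- oracle_total(params)
      rel <- if (oracle != 0) abs(pipeline - oracle) / abs(oracle) else 0
      report_path <- file.path(outdir, "oracle_report.json")
      jsonlite::write_json(
        list(
          seed = seed, pipeline_total_sar = pipeline,
          oracle_total_sar = oracle, relative_difference = rel
        ),
        report_path,
        auto_unbox = TRUE, digits = NA, pretty = TRUE
      )
      files <- c(scenario_path, report_path)
      files <- c(files, write_manifest(
        outdir, NULL, params, "synth", list(seed = seed), files
      ))
      list(status = 0L, files = files)
    },
    error = function(e) list(status = 1L, message = conditionMessage(e))
  )
  invisible(res)
}

#' Validate a configuration file
#'
#' @param config path to a parameter file.
#' @return invisibly, a list with `status` (0 valid, 2 invalid or
#'   unreadable) and `message`.
#' @export
coi_validate_run <- function(config) {
  loaded <- load_or_status(config)
  if (loaded$status != 0L) {
    return(invisible(loaded))
  }
  invisible(list(status = 0L, message = "valid"))
}
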