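ksa_config <- function() {
  system.file("extdata", "ksa_2024.yaml", package = "coivis", mustWork = TRUE)
}

test_that("a model run writes the summary, breakdown files and manifest", {
  outdir <- tempfile("run")
  res <- coi_run(ksa_config(), outdir)
  expect_identical(res$status, 0L)
  for (f in c(
    "summary.json", "cascade.csv", "direct_costs.csv",
    "indirect_costs.csv", "manifest.json"
  )) {
    expect_true(file.exists(file.path(outdir, f)), label = f)
  }

  summary <- jsonlite::read_json(file.path(outdir, "summary.json"))
  expect_equal(
    summary$total_sar, summary$direct_sar + summary$indirect_sar,
    tolerance = 1e-12
  )
  expect_equal(summary$gdp_share, summary$total_sar / 1e13)

  manifest <- jsonlite::read_json(file.path(outdir, "manifest.json"))
  expect_identical(manifest$coi_schema, 1L)
  expect_identical(manifest$command, "run")
  expect_true("summary.json" %in% unlist(manifest$outputs))

  cascade <- utils::read.csv(file.path(outdir, "cascade.csv"))
  expect_identical(nrow(cascade), 7L)
  expect_lt(abs(cascade$count[cascade$grade == "R1"] - 337037.96), 1)
})

test_that("re-running with identical inputs reproduces byte-identical result files", {
  out1 <- tempfile("rerun1")
  out2 <- tempfile("rerun2")
  coi_run(ksa_config(), out1)
  coi_run(ksa_config(), out2)
  for (f in c("summary.json", "cascade.csv", "direct_costs.csv", "indirect_costs.csv")) {
    expect_identical(
      readLines(file.path(out1, f)), readLines(file.path(out2, f)),
      label = f
    )
  }
})

test_that("invalid inputs exit with status 2, I/O problems with 1", {
  expect_identical(coi_run(tempfile("nope"), tempfile())$status, 2L)

  bad <- tempfile(fileext = ".yaml")
  p <- unclass(ksa_parameters())
  p$population$diabetic_prevalence <- 2
  write_parameters(as_coi_parameters(p), bad)
  expect_identical(coi_run(bad, tempfile())$status, 2L)
  expect_identical(coi_validate_run(bad)$status, 2L)
  expect_identical(coi_validate_run(ksa_config())$status, 0L)

  expect_identical(coi_owsa_run(ksa_config(), tempfile(), fraction = -0.1)$status, 2L)
})

test_that("the sensitivity command writes a span-ranked tornado table", {
  outdir <- tempfile("owsa")
  res <- coi_owsa_run(ksa_config(), outdir, fraction = 0.2)
  expect_identical(res$status, 0L)
  tor <- utils::read.delim(file.path(outdir, "tornado.tsv"))
  expect_true(all(diff(tor$span) <= 1e-9 * max(tor$span)))
  expect_true(all(c(
    "parameter", "low_output", "high_output", "span", "clamped"
  ) %in% names(tor)))
  js <- jsonlite::read_json(file.path(outdir, "tornado.json"))
  expect_equal(js$baseline, tor$baseline_output[1], tolerance = 1e-12)
})

test_that("the synth command writes a reloadable scenario and a tight oracle report", {
  out1 <- tempfile("synth1")
  out2 <- tempfile("synth2")
  expect_identical(coi_synth_run(8, out1)$status, 0L)
  expect_identical(coi_synth_run(8, out2)$status, 0L)
  expect_identical(
    readLines(file.path(out1, "scenario.yaml")),
    readLines(file.path(out2, "scenario.yaml"))
  )
  report <- jsonlite::read_json(file.path(out1, "oracle_report.json"))
  expect_lt(report$relative_difference, 1e-9)
  expect_true(is.numeric(report$pipeline_total_sar))
  expect_true(is.numeric(report$oracle_total_sar))
  reloaded <- load_parameters(file.path(out1, "scenario.yaml"))
  expect_identical(nrow(validate_parameters(reloaded)), 0L)
})

test_that("model object methods expose the headline figures", {
  fit <- coi_model(ksa_config())
  co <- coef(fit)
  expect_identical(
    co[["total_sar"]], co[["direct_sar"]] + co[["indirect_sar"]]
  )
  expect_output(print(fit), "share of GDP")
  expect_output(print(summary(fit)), "correction factor")

  f <- tempfile(fileext = ".png")
  grDevices::png(f)
  plot(fit)
  plot(one_way_sensitivity(fit$params, paths = c(
    "population.diabetic_prevalence", "unit_costs.oct.cost_sar"
  )))
  grDevices::dev.off()
  expect_true(file.exists(f))
})
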