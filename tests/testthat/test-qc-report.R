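test_that("a clean cohort produces an all-clear summary", {
  sim <- simulate_dataset(simulation_config(n_samples = 30,
                                            replicate_pairs = 3, seed = 101))
  out <- tempfile("qc")
  res <- qc_run(sim$dataset, out_dir = out, seed = 1)
  expect_equal(res$summary$n_control_flagged, 0L)
  expect_equal(res$summary$n_sex_mismatch, 0L)
  expect_equal(res$summary$n_conflicts, 0L)
  expect_equal(res$summary$n_detection_flagged, 0L)
  expect_equal(res$summary$n_snp_outlier_flagged, 0L)
  expect_false(res$any_failure)
  expect_true(all(file.exists(file.path(out, c(
    "qc_report.tsv", "conflicts.tsv", "sex_report.tsv", "summary.json")))))
  js <- jsonlite::read_json(file.path(out, "summary.json"))
  expect_equal(js$n_samples, 30L)
  expect_equal(js$n_pairwise_comparisons, choose(30, 2))
})

test_that("per-check counts equal the injected truth end to end", {
  cfg <- simulation_config(
    n_samples = 50, sex_swaps = 3, replicate_pairs = 4, donor_swaps = 2,
    control_failures = list("Bisulfite conversion II" = c(2L, 8L)),
    failed_samples = 20L, seed = 103)
  sim <- simulate_dataset(cfg)
  res <- qc_run(sim$dataset, seed = 2)
  expect_equal(res$summary$n_sex_mismatch, 3L)
  # each donor-id swap yields one unexpected agreement (the broken
  # replicate pair) and one unexpected disagreement (the false pair)
  expect_equal(res$summary$n_conflicts, 4L)
  expect_equal(sort(table(res$conflicts$conflict_type)),
               sort(c(unexpected_agreement = 2L, unexpected_disagreement = 2L)),
               ignore_attr = TRUE)
  # the signal-collapsed sample trips detection, control metrics may also fire
  expect_equal(res$summary$n_detection_flagged, 1L)
  expect_gte(res$summary$n_control_flagged, 2L)
  flagged <- res$report$sample_id[res$report$control_flagged]
  expect_true(all(sprintf("sample_%03d", c(2L, 8L)) %in% flagged))
  expect_true(res$any_failure)
})

test_that("reruns with the same seed and config are identical", {
  sim <- simulate_dataset(simulation_config(n_samples = 25, seed = 107))
  r1 <- qc_run(sim$dataset, seed = 5)
  r2 <- qc_run(sim$dataset, seed = 5)
  expect_identical(r1$report, r2$report)
  expect_identical(r1$summary, r2$summary)
})

test_that("qc_simulate writes files that read_dataset can parse back", {
  out <- tempfile("sim")
  res <- qc_simulate(list(n_samples = 8, seed = 4), out)
  ds <- read_dataset(file.path(out, "intensities.tsv"),
                     file.path(out, "manifest.tsv"),
                     controls_path = file.path(out, "controls.tsv"),
                     samples_path = file.path(out, "samples.tsv"))
  expect_equal(dim(ds$U), dim(res$dataset$U))
  expect_equal(ds$U, res$dataset$U, tolerance = 1e-6)
  truth <- data.table::fread(file.path(out, "truth.tsv"), data.table = FALSE)
  expect_equal(nrow(truth), 8L)
})

test_that("the command-line wrapper runs, reports, and sets exit codes", {
  skip_if(Sys.which("Rscript") == "", "Rscript not on PATH")
  cli <- system.file("cli", "qc.R", package = "methylscreen")
  skip_if(cli == "", "installed CLI script not found")
  simdir <- tempfile("cli_sim"); outdir <- tempfile("cli_out")
  code <- system2("Rscript", c(cli, "simulate", "--out", simdir, "--seed", "4"))
  expect_equal(code, 0L)
  code <- system2("Rscript", c(
    cli, "run", "--intensities", file.path(simdir, "intensities.tsv"),
    "--manifest", file.path(simdir, "manifest.tsv"),
    "--controls", file.path(simdir, "controls.tsv"),
    "--samples", file.path(simdir, "samples.tsv"),
    "--out", outdir, "--seed", "2"), stderr = FALSE)
  expect_equal(code, 0L)  # clean cohort -> success exit
  expect_true(file.exists(file.path(outdir, "summary.json")))
  # missing required option -> usage error
  code <- system2("Rscript", c(cli, "run", "--manifest", "x.tsv"),
                  stderr = FALSE)
  expect_equal(code, 2L)
})
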