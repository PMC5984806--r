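# End-to-end QC run: chain the individual checks over one dataset and
# emit machine-readable reports. The command-line wrapper in
# inst/cli/qc.R is a thin shell over qc_run()/qc_simulate().

#' Default QC run configuration
#'
#' @return named list of tunables: `dye_bias_correction` (logical),
#'   `detection_p_cutoff`, `max_undetected_fraction`,
#'   `conflict_threshold` (fingerprint agreement), `outlier_cutoff`
#'   (log2-odds above which a sample is considered contaminated/poor;
#'   the conventional choice is -4), `contamination` (logical: run the
#'   MCMC contamination fit), `mcmc_iter`, `mcmc_burn_in`.
#' @export
default_qc_config <- function() {
  list(
    dye_bias_correction = TRUE,
    detection_p_cutoff = 0.01,
    max_undetected_fraction = 0.01,
    conflict_threshold = 0.90,
    outlier_cutoff = -4,
    contamination = FALSE,
    mcmc_iter = 10000L,
    mcmc_burn_in = 5000L
  )
}

merge_config <- function(defaults, override) {
  for (nm in names(override)) defaults[[nm]] <- override[[nm]]
  defaults
}

write_report_tsv <- function(df, path)
  data.table::fwrite(df, path, sep = "\t", na = "", quote = FALSE)

#' Run the full QC battery on a dataset
#'
#' Chains dye-bias correction, detection p-values, the 17 control
#' metrics, the sex check, SNP fingerprinting (mixture fit, outlier
#' score, pairwise agreement/conflicts) and optionally the MCMC
#' contamination fit, then writes per-sample reports and a JSON summary.
#'
#' @param dataset a `MethylationDataset`.
#' @param out_dir directory for report files (created if needed);
#'   `NULL` skips writing.
#' @param config list of tunables, see [default_qc_config()]; partial
#'   lists are merged over the defaults.
#' @param seed integer seed for the stochastic components.
#' @return invisibly, a list with `report` (per-sample data.frame),
#'   `conflicts`, `sex`, `contamination` (or `NULL`), `summary` (named
#'   list as written to `summary.json`), and `any_failure`.
#' @export
qc_run <- function(dataset, out_dir = NULL, config = list(), seed = 1L) {
  cfg <- merge_config(default_qc_config(), config)
  set.seed(seed)

  if (isTRUE(cfg$dye_bias_correction))
    dataset <- suppressWarnings(correct_dye_bias(dataset))

  # detection p-values; Y probes are excluded from the flagging fraction
  # since they are expected to sit at background in female donors
  pvals <- detection_pvalues(dataset)
  not_y <- !rownames(pvals) %in% probe_subset(dataset$manifest, "chrY")
  det <- undetected_fraction(pvals[not_y, , drop = FALSE],
                             cfg$detection_p_cutoff,
                             cfg$max_undetected_fraction)

  # control metrics
  metrics <- control_metrics(dataset)
  metric_flags <- flag_samples(metrics)

  # sex check
  sex <- check_sex(dataset)

  # SNP fingerprinting
  beta <- compute_beta(dataset)
  snp_ids <- intersect(probe_subset(dataset$manifest, "snp"), rownames(beta))
  beta_snp <- beta[snp_ids, , drop = FALSE]
  model <- fit_snp_mixture(beta_snp)
  posts <- call_genotypes(model, beta_snp)
  outliers <- snp_outliers(posts)
  agreement <- check_snp_agreement(posts, dataset$samples$donor_id,
                                   cfg$conflict_threshold)

  contamination <- NULL
  if (isTRUE(cfg$contamination)) {
    fit <- fit_contamination(beta_snp, init = posts,
                             n_iter = as.integer(cfg$mcmc_iter),
                             burn_in = as.integer(cfg$mcmc_burn_in),
                             seed = seed)
    contamination <- contamination_report(fit)
  }

  sample_ids <- dataset$samples$sample_id
  in_conflict <- sample_ids %in% c(agreement$conflicts$sample_a,
                                   agreement$conflicts$sample_b)
  report <- data.frame(
    sample_id = sample_ids,
    control_flagged = metric_flags$flagged[match(sample_ids,
                                                 metric_flags$sample_id)],
    fraction_undetected = det$fraction_undetected[match(sample_ids,
                                                        det$sample_id)],
    detection_flagged = det$flagged[match(sample_ids, det$sample_id)],
    tX_norm = sex$tX_norm[match(sample_ids, sex$sample_id)],
    tY_norm = sex$tY_norm[match(sample_ids, sex$sample_id)],
    predicted_sex = sex$predicted_sex[match(sample_ids, sex$sample_id)],
    sex_status = sex$status[match(sample_ids, sex$sample_id)],
    snp_outlier_score = unname(outliers[sample_ids]),
    snp_outlier_flagged = unname(outliers[sample_ids]) > cfg$outlier_cutoff,
    in_conflict = in_conflict,
    stringsAsFactors = FALSE
  )
  if (!is.null(contamination))
    report$gamma_hat <- contamination$gamma_hat[match(sample_ids,
                                                      contamination$sample_id)]

  summary <- list(
    n_samples = length(sample_ids),
    n_control_flagged = sum(report$control_flagged, na.rm = TRUE),
    n_detection_flagged = sum(report$detection_flagged, na.rm = TRUE),
    n_sex_mismatch = sum(sex$status == "mismatch"),
    n_sex_unclear = sum(sex$status == "unclear"),
    n_snp_outlier_flagged = sum(report$snp_outlier_flagged, na.rm = TRUE),
    n_conflicts = nrow(agreement$conflicts),
    n_pairwise_comparisons = nrow(agreement$pairs),
    thresholds = cfg[c("detection_p_cutoff", "max_undetected_fraction",
                       "conflict_threshold", "outlier_cutoff")],
    seed = seed
  )
  any_failure <- isTRUE(summary$n_control_flagged > 0L) ||
    isTRUE(summary$n_detection_flagged > 0L) ||
    isTRUE(summary$n_sex_mismatch > 0L) ||
    isTRUE(summary$n_snp_outlier_flagged > 0L) ||
    isTRUE(summary$n_conflicts > 0L)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report_tsv(report, file.path(out_dir, "qc_report.tsv"))
    write_report_tsv(metrics, file.path(out_dir, "control_metrics.tsv"))
    conflicts <- agreement$conflicts
    write_report_tsv(conflicts, file.path(out_dir, "conflicts.tsv"))
    write_report_tsv(as.data.frame(sex), file.path(out_dir, "sex_report.tsv"))
    if (!is.null(contamination))
      write_report_tsv(contamination, file.path(out_dir, "contamination.tsv"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  invisible(list(report = report, metrics = metrics,
                 conflicts = agreement$conflicts, sex = sex,
                 outliers = outliers, mixture = model,
                 contamination = contamination,
                 summary = summary, any_failure = any_failure))
}

#' Simulate a dataset and write it in the TSV interchange dialect
#'
#' Thin wrapper over [simulate_dataset()] + [write_dataset()]; the truth
#' table is written alongside as `truth.tsv`.
#'
#' @param config a `SimulationConfig`, or a named list of
#'   [simulation_config()] arguments (e.g. parsed from YAML).
#' @param out_dir output directory.
#' @return invisibly, the simulation result list.
#' @export
qc_simulate <- function(config = list(), out_dir) {
  if (!inherits(config, "SimulationConfig")) {
    if (!is.list(config))
      stop("config must be a SimulationConfig or a named list", call. = FALSE)
    if ("control_failures" %in% names(config))
      config$control_failures <- lapply(config$control_failures, as.integer)
    config <- do.call(simulation_config, config)
  }
  sim <- simulate_dataset(config)
  write_dataset(sim$dataset, out_dir)
  write_report_tsv(sim$truth$samples, file.path(out_dir, "truth.tsv"))
  invisible(sim)
}
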