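# The 17 BeadArray control metrics. Each metric is the ratio of the mean
# signal of a designated foreground control group over the mean signal of
# a designated background group, in a designated channel. Group
# membership is configuration data (a policy table) so users can swap in
# the exact groupings of their platform's control reporter.

CONTROL_METRIC_NAMES <- c(
  "Restoration",
  "Staining green", "Staining red",
  "Extension green", "Extension red",
  "Hybridization high/medium", "Hybridization medium/low",
  "Target removal 1", "Target removal 2",
  "Bisulfite conversion I green", "Bisulfite conversion I red",
  "Bisulfite conversion II",
  "Specificity I green", "Specificity I red",
  "Specificity II",
  "Non-polymorphic green", "Non-polymorphic red"
)

#' Default control-metric policy
#'
#' One row per metric: the control category, probe-id pattern and color
#' channel of the numerator (foreground) and denominator (background)
#' groups, plus the flagging threshold. Thresholds follow the
#' manufacturer's control reporter defaults: 5 for staining, extension
#' and non-polymorphic, 0 for restoration, 1 otherwise. The probe-id
#' patterns match the naming convention of manifests produced by
#' [simulate_dataset()]; replace the policy (see
#' [read_control_policy()]) to match other manifests.
#'
#' @return data.frame with columns `metric`, `num_category`,
#'   `num_pattern`, `num_channel`, `den_category`, `den_pattern`,
#'   `den_channel`, `threshold`.
#' @export
default_control_policy <- function() {
  row <- function(metric, nc, np, nch, dc, dp, dch, thr)
    data.frame(metric = metric, num_category = nc, num_pattern = np,
               num_channel = nch, den_category = dc, den_pattern = dp,
               den_channel = dch, threshold = thr, stringsAsFactors = FALSE)
  rbind(
    row("Restoration", "restoration", "", "grn", "negative", "", "grn", 0),
    row("Staining green", "staining", "biotin_high", "grn",
        "staining", "biotin_bkg", "grn", 5),
    row("Staining red", "staining", "dnp_high", "red",
        "staining", "dnp_bkg", "red", 5),
    row("Extension green", "extension", "ext_[cg]$", "grn",
        "extension", "ext_[at]$", "grn", 5),
    row("Extension red", "extension", "ext_[at]$", "red",
        "extension", "ext_[cg]$", "red", 5),
    row("Hybridization high/medium", "hybridization", "hyb_high", "grn",
        "hybridization", "hyb_med$", "grn", 1),
    row("Hybridization medium/low", "hybridization", "hyb_med$", "grn",
        "hybridization", "hyb_low", "grn", 1),
    row("Target removal 1", "negative", "", "grn",
        "target_removal", "tr_1$", "grn", 1),
    row("Target removal 2", "negative", "", "grn",
        "target_removal", "tr_2$", "grn", 1),
    row("Bisulfite conversion I green", "bisulfite_conversion_I",
        "bs1_c[1-3]$", "grn", "bisulfite_conversion_I", "bs1_u[1-3]$", "grn", 1),
    row("Bisulfite conversion I red", "bisulfite_conversion_I",
        "bs1_c[4-6]$", "red", "bisulfite_conversion_I", "bs1_u[4-6]$", "red", 1),
    row("Bisulfite conversion II", "bisulfite_conversion_II", "", "red",
        "bisulfite_conversion_II", "", "grn", 1),
    row("Specificity I green", "specificity_I", "spec1_pm_[1-3]$", "grn",
        "specificity_I", "spec1_mm_[1-3]$", "grn", 1),
    row("Specificity I red", "specificity_I", "spec1_pm_[4-6]$", "red",
        "specificity_I", "spec1_mm_[4-6]$", "red", 1),
    row("Specificity II", "specificity_II", "", "red",
        "specificity_II", "", "grn", 1),
    row("Non-polymorphic green", "non_polymorphic", "np_[cg]$", "grn",
        "non_polymorphic", "np_[at]$", "grn", 5),
    row("Non-polymorphic red", "non_polymorphic", "np_[at]$", "red",
        "non_polymorphic", "np_[cg]$", "red", 5)
  )
}

#' Read/write a control-metric policy table
#'
#' @param path TSV with the columns of [default_control_policy()].
#' @return the policy data.frame.
#' @export
read_control_policy <- function(path) {
  pol <- read_tsv_strict(path, c("metric", "num_category", "num_pattern",
                                 "num_channel", "den_category", "den_pattern",
                                 "den_channel", "threshold"),
                         "control policy")
  pol$num_pattern[is.na(pol$num_pattern)] <- ""
  pol$den_pattern[is.na(pol$den_pattern)] <- ""
  validate_policy(pol)
  pol
}

validate_policy <- function(policy) {
  unknown <- setdiff(policy$metric, CONTROL_METRIC_NAMES)
  if (length(unknown) > 0L)
    stop("unknown metric name(s) in policy: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  invisible(policy)
}

policy_group_mean <- function(dataset, category, pattern, channel) {
  mf <- dataset$manifest
  ids <- mf$probe_id[mf$probe_class == "control" &
                     mf$control_category == category &
                     !is.na(mf$control_category)]
  if (nzchar(pattern)) ids <- ids[grepl(pattern, ids)]
  mat <- if (channel == "grn") dataset$controls_grn else dataset$controls_red
  ids <- intersect(ids, rownames(mat))
  if (length(ids) == 0L) return(rep(NA_real_, ncol(mat)))
  colMeans(mat[ids, , drop = FALSE], na.rm = TRUE)
}

#' Compute the 17 control metrics per sample
#'
#' Each value is the ratio of mean foreground to mean background control
#' intensity as laid out in the policy table; the ratio is dimensionless,
#' hence invariant to any per-sample rescaling of intensities. A sample
#' is flagged on a metric when its value falls strictly below the
#' metric's threshold (a value exactly at threshold passes). Groups with
#' no usable measurements yield a missing value (`n.a.`), which never
#' flags.
#'
#' @param dataset a `MethylationDataset`.
#' @param policy policy table, defaults to [default_control_policy()].
#' @return data.frame with one row per sample x metric: `sample_id`,
#'   `metric`, `value`, `threshold`, `flagged` (`NA` where the value is
#'   missing).
#' @export
control_metrics <- function(dataset, policy = default_control_policy()) {
  validate_policy(policy)
  sample_ids <- colnames(dataset$controls_grn)
  out <- vector("list", nrow(policy))
  for (i in seq_len(nrow(policy))) {
    num <- policy_group_mean(dataset, policy$num_category[i],
                             policy$num_pattern[i], policy$num_channel[i])
    den <- policy_group_mean(dataset, policy$den_category[i],
                             policy$den_pattern[i], policy$den_channel[i])
    value <- num / den
    value[!is.na(den) & den == 0] <- NA_real_
    out[[i]] <- data.frame(
      sample_id = sample_ids,
      metric = policy$metric[i],
      value = unname(value),
      threshold = policy$threshold[i],
      flagged = ifelse(is.na(value), NA, value < policy$threshold[i]),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Aggregate control-metric flags per sample
#'
#' A sample is flagged when any of its metrics falls strictly below its
#' threshold; missing (`n.a.`) metrics never flag. Supplying a policy
#' re-applies its thresholds to the stored metric values.
#'
#' @param results data.frame from [control_metrics()].
#' @param policy optional policy table overriding the thresholds used.
#' @return data.frame with `sample_id` and logical `flagged`.
#' @export
flag_samples <- function(results, policy = NULL) {
  if (!is.null(policy)) {
    validate_policy(policy)
    idx <- match(results$metric, policy$metric)
    if (anyNA(idx))
      stop("policy lacks threshold(s) for metric(s): ",
           paste(unique(results$metric[is.na(idx)]), collapse = ", "),
           call. = FALSE)
    results$threshold <- policy$threshold[idx]
    results$flagged <- ifelse(is.na(results$value), NA,
                              results$value < results$threshold)
  }
  agg <- tapply(results$flagged, results$sample_id,
                function(f) any(f, na.rm = TRUE))
  samples <- unique(results$sample_id)
  data.frame(sample_id = samples,
             flagged = as.logical(agg[samples]),
             stringsAsFactors = FALSE)
}
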