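# Sex inference from allosomal total intensities.
#
# Total intensity T = U + M tracks copy number, so probes on the X and Y
# chromosomes separate male (one X, one Y) from female (two X, no Y)
# donors. Per-sample averages over X and Y probes are normalized by the
# autosomal average to cancel differences in post-amplification DNA
# concentration, and sex-specific cutoffs are learned robustly from the
# (possibly partly mislabeled) recorded sex via the Hodges-Lehmann
# estimator.

#' Normalized X/Y total intensities per sample
#'
#' `tX` is the mean total intensity over X-chromosome probes divided by
#' the mean over autosomal probes (`tY` analogously); missing intensities
#' are skipped. Both are dimensionless and invariant to any per-sample
#' global intensity rescaling.
#'
#' @param dataset a `MethylationDataset`.
#' @return data.frame with `sample_id`, `tX_norm`, `tY_norm`.
#' @export
normalized_chr_intensities <- function(dataset) {
  total <- dataset$U + dataset$M
  idx <- function(ids) rownames(total) %in% ids
  auto <- idx(probe_subset(dataset$manifest, "autosomal"))
  xpro <- idx(probe_subset(dataset$manifest, "chrX"))
  ypro <- idx(probe_subset(dataset$manifest, "chrY"))
  if (!any(auto) || !any(xpro) || !any(ypro))
    stop("manifest must label autosomal, X and Y probes", call. = FALSE)
  auto_mean <- colMeans(total[auto, , drop = FALSE], na.rm = TRUE)
  if (any(!is.na(auto_mean) & auto_mean == 0))
    stop("zero autosomal mean intensity", call. = FALSE)
  data.frame(
    sample_id = colnames(total),
    tX_norm = unname(colMeans(total[xpro, , drop = FALSE], na.rm = TRUE) / auto_mean),
    tY_norm = unname(colMeans(total[ypro, , drop = FALSE], na.rm = TRUE) / auto_mean),
    stringsAsFactors = FALSE
  )
}

#' Hodges-Lehmann cutoff between recorded sexes
#'
#' The median of all pairwise male/female averages
#' `(value_male + value_female) / 2`. Being a median over cross-pairs, it
#' tolerates a sizable fraction of mislabeled sexes --- the reason it is
#' preferred here over cluster means. For an even number of pairs the
#' midpoint of the two central values is returned.
#'
#' @param values numeric vector, one per sample.
#' @param recorded_sex character vector (`"male"`/`"female"`; other
#'   values are ignored).
#' @return the scalar threshold.
#' @export
hodges_lehmann_cutoff <- function(values, recorded_sex) {
  m <- values[recorded_sex == "male" & !is.na(values)]
  f <- values[recorded_sex == "female" & !is.na(values)]
  if (length(m) == 0L || length(f) == 0L)
    stop("need at least one recorded male and one recorded female; ",
         "supply cutoffs manually otherwise", call. = FALSE)
  stats::median(outer(m, f, `+`) / 2)
}

#' Predict donor sex and flag metadata mismatches
#'
#' A sample is called male when `tX < cutoff_X` and `tY > cutoff_Y`
#' (one X, Y present), female when `tX > cutoff_X` and `tY < cutoff_Y`.
#' Samples in the remaining quadrants --- including ties exactly on a
#' cutoff --- are `unclear`; the upper-right quadrant is where an XXY
#' karyotype would fall. A mismatch is a clear prediction that
#' contradicts the recorded sex.
#'
#' @param intensities data.frame from [normalized_chr_intensities()].
#' @param cutoff_X,cutoff_Y thresholds on `tX_norm`/`tY_norm`.
#' @param recorded_sex character vector per sample.
#' @return A `SexCheckResult` data.frame: `sample_id`, `tX_norm`,
#'   `tY_norm`, `cutoff_X`, `cutoff_Y`, `predicted_sex`, `recorded_sex`,
#'   `mismatch`, `status`.
#' @export
predict_sex <- function(intensities, cutoff_X, cutoff_Y, recorded_sex) {
  tX <- intensities$tX_norm; tY <- intensities$tY_norm
  predicted <- rep("unclear", length(tX))
  predicted[tX < cutoff_X & tY > cutoff_Y] <- "male"
  predicted[tX > cutoff_X & tY < cutoff_Y] <- "female"
  predicted[is.na(tX) | is.na(tY)] <- "unclear"
  mismatch <- predicted != "unclear" & recorded_sex %in% c("male", "female") &
    predicted != recorded_sex
  out <- data.frame(
    sample_id = intensities$sample_id,
    tX_norm = tX, tY_norm = tY,
    cutoff_X = cutoff_X, cutoff_Y = cutoff_Y,
    predicted_sex = predicted,
    recorded_sex = recorded_sex,
    mismatch = mismatch,
    status = ifelse(predicted == "unclear", "unclear",
                    ifelse(mismatch, "mismatch", "ok")),
    stringsAsFactors = FALSE
  )
  class(out) <- c("SexCheckResult", "data.frame")
  out
}

#' Full sex check on a dataset
#'
#' Convenience wrapper: computes normalized X/Y intensities, learns both
#' Hodges-Lehmann cutoffs from the recorded sex, and predicts sex.
#'
#' @param dataset a `MethylationDataset` whose `samples` metadata carries
#'   `recorded_sex`.
#' @return A `SexCheckResult` data.frame.
#' @export
check_sex <- function(dataset) {
  ints <- normalized_chr_intensities(dataset)
  sex <- dataset$samples$recorded_sex
  cutoff_X <- hodges_lehmann_cutoff(ints$tX_norm, sex)
  cutoff_Y <- hodges_lehmann_cutoff(ints$tY_norm, sex)
  predict_sex(ints, cutoff_X, cutoff_Y, sex)
}
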