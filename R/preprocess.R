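# Methylation quantification and low-level signal preprocessing.

#' Compute beta-values
#'
#' The methylation level of probe i in sample n is estimated as
#' `M / (M + U)`, the proportion of methylated signal, without any offset
#' constant. Entries where the denominator is zero or either intensity is
#' missing become `NA`. Beta is invariant under any common positive
#' rescaling of `(U, M)`.
#'
#' @param dataset a `MethylationDataset`.
#' @return numeric matrix (probe x sample) of values in `[0, 1]` or `NA`.
#' @export
compute_beta <- function(dataset) {
  total <- dataset$M + dataset$U
  beta <- dataset$M / total
  beta[!is.na(total) & total == 0] <- NA_real_
  beta
}

# Control-probe pairs used for dye-bias regression: within categories
# that carry duplicate designs in both channels, the k-th green-designed
# control (sorted by probe_id) is paired with the k-th red-designed
# control of the same category. Probe naming in shipped manifests aligns
# equal design levels (e.g. biotin_bkg <-> dnp_bkg, bs1_c1 <-> bs1_c4).
DYE_BIAS_CATEGORIES <- c("staining", "extension",
                         "bisulfite_conversion_I", "specificity_I")

dye_bias_pairs <- function(manifest) {
  ctl <- manifest[manifest$probe_class == "control" &
                  manifest$control_category %in% DYE_BIAS_CATEGORIES, ,
                  drop = FALSE]
  out <- list(grn = character(0), red = character(0))
  for (cat in unique(ctl$control_category)) {
    g <- sort(ctl$probe_id[ctl$control_category == cat &
                           ctl$channel_design == "typeI_green"])
    r <- sort(ctl$probe_id[ctl$control_category == cat &
                           ctl$channel_design == "typeI_red"])
    k <- min(length(g), length(r))
    if (k > 0L) {
      out$grn <- c(out$grn, g[seq_len(k)])
      out$red <- c(out$red, r[seq_len(k)])
    }
  }
  out
}

#' Correct dye bias between color channels
#'
#' Rescales the red channel of each sample via a regression of
#' log green-channel on log red-channel intensities over paired internal
#' control probes (duplicate green/red designs in the staining,
#' extension, bisulfite-conversion-I and specificity-I categories,
#' matched by rank within category), leaving the green
#' channel unchanged. The fitted log-linear map is applied to every
#' red-channel measurement of the sample: type I red probes (U and M),
#' the unmethylated (red) half of type II probes, and the red control
#' intensities. The correction is monotone, so within-channel intensity
#' ranks are preserved.
#'
#' @param dataset a `MethylationDataset`.
#' @return the corrected `MethylationDataset`; samples for which fewer
#'   than 3 usable control pairs were available are left uncorrected,
#'   flagged in the `dye_bias_skipped` attribute, and reported via a
#'   warning.
#' @export
correct_dye_bias <- function(dataset) {
  pairs <- dye_bias_pairs(dataset$manifest)
  mf <- dataset$manifest
  red_probe_rows <- rownames(dataset$U) %in%
    mf$probe_id[mf$channel_design == "typeI_red"]
  t2_rows <- rownames(dataset$U) %in% mf$probe_id[mf$channel_design == "typeII"]

  skipped <- character(0)
  for (n in seq_len(ncol(dataset$U))) {
    g <- dataset$controls_grn[pairs$grn, n]
    r <- dataset$controls_red[pairs$red, n]
    ok <- !is.na(g) & !is.na(r) & g > 0 & r > 0
    if (sum(ok) < 3L) {
      skipped <- c(skipped, colnames(dataset$U)[n])
      next
    }
    fit <- stats::lm.fit(cbind(1, log(r[ok])), log(g[ok]))
    a <- fit$coefficients[1L]; b <- fit$coefficients[2L]
    map <- function(x) {
      pos <- !is.na(x) & x > 0
      x[pos] <- exp(a + b * log(x[pos]))
      x
    }
    dataset$U[red_probe_rows, n] <- map(dataset$U[red_probe_rows, n])
    dataset$M[red_probe_rows, n] <- map(dataset$M[red_probe_rows, n])
    dataset$U[t2_rows, n] <- map(dataset$U[t2_rows, n])
    dataset$controls_red[, n] <- map(dataset$controls_red[, n])
  }
  if (length(skipped) > 0L)
    warning("dye-bias correction skipped for sample(s) with < 3 control pairs: ",
            paste(skipped, collapse = ", "))
  attr(dataset, "dye_bias_skipped") <- skipped
  dataset
}

#' Detection p-values against negative-control background
#'
#' For each probe and sample, the upper-tail probability of the total
#' intensity `U + M` under a normal background model estimated from the
#' negative-control probes of the matching channel(s): type I probes use
#' twice the mean (and `sqrt(2)` times the sd) of their design channel's
#' negative controls, type II probes the sum of the green and red
#' negative-control means (variances added). Small p-values indicate
#' signal reliably above background; p-values are non-increasing in
#' total intensity.
#'
#' @param dataset a `MethylationDataset`.
#' @return matrix of p-values (probe x sample) in `[0, 1]`, `NA` where
#'   the total intensity is missing.
#' @export
detection_pvalues <- function(dataset) {
  neg <- probe_subset(dataset$manifest, "control", "negative")
  neg <- intersect(neg, rownames(dataset$controls_grn))
  if (length(neg) == 0L)
    stop("no negative-control probes available", call. = FALSE)
  mf <- dataset$manifest
  design <- mf$channel_design[match(rownames(dataset$U), mf$probe_id)]
  total <- dataset$U + dataset$M

  p <- matrix(NA_real_, nrow(total), ncol(total), dimnames = dimnames(total))
  for (n in seq_len(ncol(total))) {
    ng <- dataset$controls_grn[neg, n]; ng <- ng[!is.na(ng)]
    nr <- dataset$controls_red[neg, n]; nr <- nr[!is.na(nr)]
    if (length(ng) < 2L || length(nr) < 2L)
      stop("too few negative-control measurements for sample ",
           colnames(total)[n], call. = FALSE)
    mu <- c(typeI_green = 2 * mean(ng),
            typeI_red   = 2 * mean(nr),
            typeII      = mean(ng) + mean(nr))
    sd <- c(typeI_green = sqrt(2) * stats::sd(ng),
            typeI_red   = sqrt(2) * stats::sd(nr),
            typeII      = sqrt(stats::var(ng) + stats::var(nr)))
    p[, n] <- stats::pnorm(total[, n], mean = mu[design], sd = sd[design],
                           lower.tail = FALSE)
  }
  p
}

#' Fraction of undetected probes per sample
#'
#' The conventional screening criterion: the share of probes whose
#' detection p-value exceeds `p_cutoff` (default 0.01). Samples with more
#' than `max_fraction` (default 1%) undetected probes are flagged.
#'
#' @param pvals matrix from [detection_pvalues()].
#' @param p_cutoff detection p-value cutoff.
#' @param max_fraction maximum tolerated fraction of undetected probes.
#' @return data.frame with `sample_id`, `fraction_undetected`, `flagged`.
#' @export
undetected_fraction <- function(pvals, p_cutoff = 0.01, max_fraction = 0.01) {
  frac <- colMeans(pvals > p_cutoff, na.rm = TRUE)
  data.frame(sample_id = colnames(pvals),
             fraction_undetected = unname(frac),
             flagged = unname(frac > max_fraction),
             stringsAsFactors = FALSE)
}
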