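# Synthetic Infinium-style datasets with known ground truth.
#
# The generator emulates the structures the QC checks exploit: trimodal
# SNP-probe beta distributions under Hardy-Weinberg genotypes, sex-
# dependent X/Y intensity doses, control-probe signal/background pairs
# with injectable failures, dye bias, whole-sample signal collapse, and
# single-source DNA contamination mixing. Every latent variable is
# recorded in a truth table, and the output is fully determined by the
# seed.

#' Simulation configuration
#'
#' @param n_samples number of samples.
#' @param n_autosomal_probes,n_x_probes,n_y_probes CpG probe counts per
#'   compartment (scaled-down chip).
#' @param n_snp_probes number of SNP fingerprint probes (65 as on the
#'   450K chip; 59 emulates the EPIC chip).
#' @param allele_freq B-allele frequency per SNP (scalar recycled;
#'   default 0.5, the maximum-entropy choice mimicking high-frequency
#'   SNPs).
#' @param female_prop proportion of female donors.
#' @param genotype_means,genotype_sds cluster centers and noise sds of
#'   SNP beta-values per genotype AA/AB/BB (truncated-normal noise).
#' @param intensity_scale expected on-target fluorescence intensity
#'   (arbitrary units).
#' @param background expected off-target/background intensity.
#' @param intensity_cv lognormal coefficient of variation of intensities.
#' @param x_dose,y_dose named numeric `c(female=, male=)`: X/Y total
#'   intensity relative to the autosomal mean. Defaults reflect two vs
#'   one X dose and Y present/absent over a background floor.
#' @param replicate_pairs number of donors contributing two samples
#'   (samples `1..2*replicate_pairs` form the pairs).
#' @param sex_swaps number of samples whose recorded sex is flipped
#'   relative to truth (applied to samples outside replicate pairs).
#' @param donor_swaps number of donor-id mislabelings: for each, the
#'   recorded donor id of the second member of a replicate pair is
#'   exchanged with that of a singleton sample, producing one
#'   unexpected-agreement and one unexpected-disagreement conflict.
#'   Requires at least that many replicate pairs and singletons.
#' @param gamma per-sample contamination degree in `[0, 1)` (scalar
#'   recycled; default 0). Contamination mixes SNP beta-values toward a
#'   single foreign source's allele dosage and, through the source's
#'   sex, shifts allosomal intensity doses.
#' @param source_sex sex of the contaminating DNA source.
#' @param control_failures named list: metric name -> indices of samples
#'   whose corresponding control group is degraded below threshold.
#' @param failed_samples indices of samples whose probe signal collapses
#'   to background (undetectable probes).
#' @param red_bias per-sample multiplicative red-channel dye bias
#'   (scalar recycled; default 1 = unbiased).
#' @param n_negative_controls number of negative control probes.
#' @param seed integer seed.
#' @return A validated `SimulationConfig` list.
#' @export
simulation_config <- function(n_samples = 100L,
                              n_autosomal_probes = 200L,
                              n_x_probes = 60L,
                              n_y_probes = 20L,
                              n_snp_probes = 65L,
                              allele_freq = 0.5,
                              female_prop = 0.5,
                              genotype_means = c(0.05, 0.5, 0.95),
                              genotype_sds = c(0.05, 0.05, 0.05),
                              intensity_scale = 3000,
                              background = 300,
                              intensity_cv = 0.1,
                              x_dose = c(female = 1.0, male = 0.55),
                              y_dose = c(female = 0.12, male = 0.9),
                              replicate_pairs = 0L,
                              sex_swaps = 0L,
                              donor_swaps = 0L,
                              gamma = 0,
                              source_sex = "male",
                              control_failures = list(),
                              failed_samples = integer(0),
                              red_bias = 1,
                              n_negative_controls = 30L,
                              seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_samples >= 1L, n_autosomal_probes >= 1L, n_x_probes >= 1L,
            n_y_probes >= 1L, n_snp_probes >= 1L,
            all(allele_freq >= 0 & allele_freq <= 1),
            female_prop >= 0, female_prop <= 1,
            length(genotype_means) == 3L, length(genotype_sds) == 3L,
            all(genotype_means >= 0 & genotype_means <= 1),
            all(genotype_sds > 0),
            intensity_scale > 0, background > 0, intensity_cv > 0,
            all(gamma >= 0 & gamma < 1),
            source_sex %in% c("male", "female"),
            all(c("female", "male") %in% names(x_dose)),
            all(c("female", "male") %in% names(y_dose)),
            replicate_pairs >= 0L, 2L * replicate_pairs <= n_samples,
            sex_swaps >= 0L, donor_swaps >= 0L,
            donor_swaps <= replicate_pairs,
            2L * replicate_pairs + donor_swaps <= n_samples)
  cfg$allele_freq <- rep_len(allele_freq, n_snp_probes)
  cfg$gamma <- rep_len(gamma, n_samples)
  cfg$red_bias <- rep_len(red_bias, n_samples)
  if (length(failed_samples) > 0L)
    stopifnot(all(failed_samples >= 1L & failed_samples <= n_samples))
  for (nm in names(control_failures)) {
    if (!nm %in% CONTROL_METRIC_NAMES)
      stop("control_failures names must be control metric names; got: ", nm,
           call. = FALSE)
    stopifnot(all(control_failures[[nm]] >= 1L &
                  control_failures[[nm]] <= n_samples))
  }
  if (sex_swaps > n_samples)
    stop("more sex swaps than samples", call. = FALSE)
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Right-skewed per-sample contamination design
#'
#' Deterministic gamma spread emulating a cohort in which most samples
#' are at most mildly contaminated while a subset carries substantial
#' foreign DNA: the `ppoints(n)` quantiles of a `Beta(1, shape)`
#' distribution scaled to `[0, max_gamma]`. All values are distinct,
#' which keeps rank-based comparisons against downstream estimates
#' meaningful.
#'
#' @param n number of samples.
#' @param max_gamma largest contamination degree (default 0.5).
#' @param shape Beta skew parameter; larger means more samples near 0.
#' @return numeric vector of length `n`, increasing.
#' @export
skewed_gamma_design <- function(n, max_gamma = 0.5, shape = 2) {
  max_gamma * stats::qbeta(stats::ppoints(n), 1, shape)
}

rbeta_moment <- function(n, mean, sd) {
  # Beta draws moment-matched to (mean, sd), clipped to the open interval
  mean <- pmin(pmax(mean, 0.005), 0.995)
  v <- pmin(sd^2, mean * (1 - mean) * 0.95)
  nu <- mean * (1 - mean) / v - 1
  stats::rbeta(n, mean * nu, (1 - mean) * nu)
}

lognoise <- function(n, cv) exp(stats::rnorm(n, -0.5 * log(1 + cv^2),
                                             sqrt(log(1 + cv^2))))

# control probe layout: id, category, design channel (the channel the
# probe is designed to light up in), expected grn/red level as multiples
# of signal (s) or background (b)
control_layout <- function(n_negative) {
  row <- function(id, cat, design, grn, red)
    data.frame(probe_id = id, category = cat, design = design,
               grn = grn, red = red, stringsAsFactors = FALSE)
  rbind(
    row("ctl_restore_1", "restoration", "typeI_green", "s", "b"),
    row("ctl_stain_biotin_high", "staining", "typeI_green", "s", "b"),
    row("ctl_stain_biotin_bkg", "staining", "typeI_green", "b", "b"),
    row("ctl_stain_dnp_high", "staining", "typeI_red", "b", "s"),
    row("ctl_stain_dnp_bkg", "staining", "typeI_red", "b", "b"),
    row("ctl_ext_c", "extension", "typeI_green", "s", "b"),
    row("ctl_ext_g", "extension", "typeI_green", "s", "b"),
    row("ctl_ext_a", "extension", "typeI_red", "b", "s"),
    row("ctl_ext_t", "extension", "typeI_red", "b", "s"),
    row("ctl_hyb_low", "hybridization", "typeI_green", "s25", "b"),
    row("ctl_hyb_med", "hybridization", "typeI_green", "s50", "b"),
    row("ctl_hyb_high", "hybridization", "typeI_green", "s", "b"),
    row("ctl_tr_1", "target_removal", "typeI_green", "b50", "b"),
    row("ctl_tr_2", "target_removal", "typeI_green", "b50", "b"),
    row(paste0("ctl_bs1_c", 1:3), "bisulfite_conversion_I", "typeI_green", "s", "b"),
    row(paste0("ctl_bs1_u", 1:3), "bisulfite_conversion_I", "typeI_green", "b", "b"),
    row(paste0("ctl_bs1_c", 4:6), "bisulfite_conversion_I", "typeI_red", "b", "s"),
    row(paste0("ctl_bs1_u", 4:6), "bisulfite_conversion_I", "typeI_red", "b", "b"),
    row(paste0("ctl_bs2_", 1:4), "bisulfite_conversion_II", "typeI_red", "b", "s"),
    row(paste0("ctl_spec1_pm_", 1:3), "specificity_I", "typeI_green", "s", "b"),
    row(paste0("ctl_spec1_mm_", 1:3), "specificity_I", "typeI_green", "b", "b"),
    row(paste0("ctl_spec1_pm_", 4:6), "specificity_I", "typeI_red", "b", "s"),
    row(paste0("ctl_spec1_mm_", 4:6), "specificity_I", "typeI_red", "b", "b"),
    row(paste0("ctl_spec2_", 1:3), "specificity_II", "typeI_red", "b", "s"),
    row("ctl_np_c", "non_polymorphic", "typeI_green", "s", "b"),
    row("ctl_np_g", "non_polymorphic", "typeI_green", "s", "b"),
    row("ctl_np_a", "non_polymorphic", "typeI_red", "b", "s"),
    row("ctl_np_t", "non_polymorphic", "typeI_red", "b", "s"),
    row(sprintf("ctl_neg_%02d", seq_len(n_negative)), "negative", "typeII",
        "b", "b")
  )
}

#' Simulate a methylation QC dataset with known ground truth
#'
#' See [simulation_config()] for the knobs. Genotypes are drawn per
#' donor under Hardy-Weinberg equilibrium (replicate samples share their
#' donor's genotype); SNP beta-values get genotype-specific truncated-
#' normal noise and, for contaminated samples, are mixed toward the single foreign
#' source's expected beta by `gamma`; X/Y probe intensities are scaled
#' by sex-specific doses (blended with the source's doses under
#' contamination); control probes emit signal/background structure,
#' degraded for injected failures.
#'
#' @param config a `SimulationConfig`.
#' @return list with elements `dataset` (a `MethylationDataset`),
#'   `manifest` (its `Manifest`) and `truth` (list: `samples` truth
#'   table, `genotypes` sample x SNP allele dosages, `source_genotypes`,
#'   `config`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  N <- config$n_samples
  sample_ids <- sprintf("sample_%03d", seq_len(N))

  # donors: leading samples form replicate pairs, the rest are singletons
  donor <- integer(N)
  if (config$replicate_pairs > 0L)
    donor[seq_len(2L * config$replicate_pairs)] <-
      rep(seq_len(config$replicate_pairs), each = 2L)
  rest <- which(donor == 0L)
  donor[rest] <- config$replicate_pairs + seq_along(rest)
  donor_ids <- sprintf("donor_%03d", donor)
  n_donors <- max(donor)

  true_sex_donor <- ifelse(stats::runif(n_donors) < config$female_prop,
                           "female", "male")
  true_sex <- true_sex_donor[donor]
  recorded_sex <- true_sex
  if (config$sex_swaps > 0L) {
    eligible <- setdiff(seq_len(N), seq_len(2L * config$replicate_pairs))
    if (length(eligible) < config$sex_swaps)
      eligible <- seq_len(N)
    swap_idx <- sort(sample(eligible, config$sex_swaps))
    recorded_sex[swap_idx] <- ifelse(true_sex[swap_idx] == "male",
                                     "female", "male")
  } else swap_idx <- integer(0)

  # donor-id mislabeling: exchange the recorded donor of a replicate-pair
  # member with a singleton's; genotypes keep following the true donor
  recorded_donor <- donor_ids
  if (config$donor_swaps > 0L) {
    for (i in seq_len(config$donor_swaps)) {
      a <- 2L * i                 # second member of replicate pair i
      b <- N - i + 1L             # singleton from the end
      tmp <- recorded_donor[a]
      recorded_donor[a] <- recorded_donor[b]
      recorded_donor[b] <- tmp
    }
  }

  # --- manifest ---
  J <- config$n_snp_probes
  cpg_ids <- sprintf("cg%06d", seq_len(config$n_autosomal_probes +
                                       config$n_x_probes + config$n_y_probes))
  cpg_chrom <- c(as.character(sample(1:22, config$n_autosomal_probes,
                                     replace = TRUE)),
                 rep("X", config$n_x_probes), rep("Y", config$n_y_probes))
  cpg_design <- sample(c("typeII", "typeI_green", "typeI_red"),
                       length(cpg_ids), replace = TRUE,
                       prob = c(0.5, 0.25, 0.25))
  snp_ids <- sprintf("rs%04d", seq_len(J))
  ctl <- control_layout(config$n_negative_controls)
  manifest <- data.frame(
    probe_id = c(cpg_ids, snp_ids, ctl$probe_id),
    chromosome = c(cpg_chrom, as.character(sample(1:22, J, replace = TRUE)),
                   rep(NA_character_, nrow(ctl))),
    probe_class = c(rep("cpg", length(cpg_ids)), rep("snp", J),
                    rep("control", nrow(ctl))),
    control_category = c(rep(NA_character_, length(cpg_ids) + J),
                         ctl$category),
    channel_design = c(cpg_design, rep("typeII", J), ctl$design),
    stringsAsFactors = FALSE
  )
  manifest$address_a <- seq_len(nrow(manifest)) * 10L
  manifest$address_b <- ifelse(manifest$channel_design == "typeII" &
                               manifest$probe_class != "control",
                               NA_integer_, seq_len(nrow(manifest)) * 10L + 1L)
  manifest <- as_manifest(manifest)

  # --- genotypes under Hardy-Weinberg, per donor ---
  geno_donor <- matrix(0L, n_donors, J)
  for (j in seq_len(J)) {
    p <- config$allele_freq[j]
    geno_donor[, j] <- sample(0:2, n_donors, replace = TRUE,
                              prob = c((1 - p)^2, 2 * p * (1 - p), p^2))
  }
  genotypes <- geno_donor[donor, , drop = FALSE]          # sample x SNP
  source_geno <- vapply(seq_len(J), function(j) {
    p <- config$allele_freq[j]
    sample(0:2, 1L, prob = c((1 - p)^2, 2 * p * (1 - p), p^2))
  }, 0L)
  c_j <- config$genotype_means[source_geno + 1L]

  gamma <- config$gamma
  # --- SNP beta-values: convex mix of host genotype mean and source ---
  mu_host <- matrix(config$genotype_means[genotypes + 1L], N, J)
  sd_host <- matrix(config$genotype_sds[genotypes + 1L], N, J)
  mix_mean <- (1 - gamma) * mu_host + gamma * matrix(c_j, N, J, byrow = TRUE)
  mix_sd <- (1 - gamma) * sd_host
  # truncated-normal cluster noise: light tails keep the genotype modes
  # cleanly separated, matching the normal noise the contamination model
  # itself assumes
  beta_snp <- matrix(pmin(pmax(stats::rnorm(N * J, as.vector(mix_mean),
                                            as.vector(mix_sd)),
                               1e-3), 1 - 1e-3), N, J)

  # --- probe intensities ---
  scale <- config$intensity_scale
  bkg <- config$background
  cv <- config$intensity_cv
  n_cpg <- length(cpg_ids)
  is_failed <- seq_len(N) %in% config$failed_samples

  dose_for <- function(sex, tbl) unname(tbl[sex])
  x_eff <- dose_for(true_sex, config$x_dose)
  y_eff <- dose_for(true_sex, config$y_dose)
  if (any(gamma > 0)) {
    x_eff <- (1 - gamma) * x_eff + gamma * config$x_dose[config$source_sex]
    y_eff <- (1 - gamma) * y_eff + gamma * config$y_dose[config$source_sex]
  }
  dose <- matrix(1, n_cpg, N)
  dose[cpg_chrom == "X", ] <- matrix(x_eff, sum(cpg_chrom == "X"), N,
                                     byrow = TRUE)
  dose[cpg_chrom == "Y", ] <- matrix(y_eff, sum(cpg_chrom == "Y"), N,
                                     byrow = TRUE)

  total_cpg <- scale * dose * matrix(lognoise(n_cpg * N, cv), n_cpg, N)
  total_cpg[, is_failed] <- bkg * matrix(lognoise(n_cpg * sum(is_failed), cv),
                                         n_cpg, sum(is_failed))
  beta_probe <- stats::rbeta(n_cpg, 0.4, 0.4)  # bimodal methylation landscape
  beta_cpg <- matrix(rbeta_moment(n_cpg * N, rep(beta_probe, N), 0.03),
                     n_cpg, N)
  M_cpg <- total_cpg * beta_cpg
  U_cpg <- total_cpg * (1 - beta_cpg)

  total_snp <- scale * matrix(lognoise(J * N, cv), J, N)
  total_snp[, is_failed] <- bkg * matrix(lognoise(J * sum(is_failed), cv),
                                         J, sum(is_failed))
  M_snp <- total_snp * t(beta_snp)
  U_snp <- total_snp * (1 - t(beta_snp))

  U <- rbind(U_cpg, U_snp)
  M <- rbind(M_cpg, M_snp)
  dimnames(U) <- dimnames(M) <- list(c(cpg_ids, snp_ids), sample_ids)

  # --- control intensities ---
  level <- function(code) switch(code, s = scale, s50 = 0.5 * scale,
                                 s25 = 0.25 * scale, b = bkg, b50 = 0.5 * bkg)
  n_ctl <- nrow(ctl)
  grn_level <- vapply(ctl$grn, level, 0)
  red_level <- vapply(ctl$red, level, 0)
  controls_grn <- matrix(grn_level, n_ctl, N) * matrix(lognoise(n_ctl * N, cv),
                                                       n_ctl, N)
  controls_red <- matrix(red_level, n_ctl, N) * matrix(lognoise(n_ctl * N, cv),
                                                       n_ctl, N)
  dimnames(controls_grn) <- dimnames(controls_red) <-
    list(ctl$probe_id, sample_ids)

  # --- control failure injection ---
  policy <- default_control_policy()
  ctl_ids_of <- function(category, pattern) {
    ids <- ctl$probe_id[ctl$category == category]
    if (nzchar(pattern)) ids <- ids[grepl(pattern, ids)]
    ids
  }
  failed_metrics <- rep("", N)
  for (metric in names(config$control_failures)) {
    rows <- config$control_failures[[metric]]
    pol <- policy[policy$metric == metric, ]
    if (startsWith(metric, "Target removal")) {
      # failure mode: target not removed, denominator probe stays hot
      ids <- ctl_ids_of(pol$den_category, pol$den_pattern)
      mat <- if (pol$den_channel == "grn") "controls_grn" else "controls_red"
      vals <- get(mat)
      vals[ids, rows] <- 3 * bkg * lognoise(length(ids) * length(rows), cv)
      assign(mat, vals)
    } else {
      # failure mode: foreground group collapses below background
      ids <- ctl_ids_of(pol$num_category, pol$num_pattern)
      mat <- if (pol$num_channel == "grn") "controls_grn" else "controls_red"
      vals <- get(mat)
      vals[ids, rows] <- 0.5 * bkg * lognoise(length(ids) * length(rows), cv)
      assign(mat, vals)
    }
    failed_metrics[rows] <- ifelse(nzchar(failed_metrics[rows]),
                                   paste0(failed_metrics[rows], ";", metric),
                                   metric)
  }

  # --- dye bias ---
  red_rows <- manifest$probe_id[manifest$channel_design == "typeI_red" &
                                manifest$probe_class != "control"]
  t2_rows <- manifest$probe_id[manifest$channel_design == "typeII" &
                               manifest$probe_class != "control"]
  bias <- config$red_bias
  if (any(bias != 1)) {
    U[rownames(U) %in% red_rows, ] <-
      sweep(U[rownames(U) %in% red_rows, , drop = FALSE], 2, bias, `*`)
    M[rownames(M) %in% red_rows, ] <-
      sweep(M[rownames(M) %in% red_rows, , drop = FALSE], 2, bias, `*`)
    U[rownames(U) %in% t2_rows, ] <-
      sweep(U[rownames(U) %in% t2_rows, , drop = FALSE], 2, bias, `*`)
    controls_red <- sweep(controls_red, 2, bias, `*`)
  }

  samples <- data.frame(sample_id = sample_ids, donor_id = recorded_donor,
                        recorded_sex = recorded_sex, stringsAsFactors = FALSE)
  dataset <- methylation_dataset(U, M, controls_grn, controls_red,
                                 samples, manifest)

  truth_samples <- data.frame(
    sample_id = sample_ids,
    donor_id = recorded_donor,
    true_donor_id = donor_ids,
    donor_mislabeled = recorded_donor != donor_ids,
    true_sex = true_sex,
    recorded_sex = recorded_sex,
    sex_mismatch = seq_len(N) %in% swap_idx,
    gamma = gamma,
    signal_failed = is_failed,
    failed_metrics = failed_metrics,
    red_bias = bias,
    stringsAsFactors = FALSE
  )
  dimnames(genotypes) <- list(sample_ids, snp_ids)

  list(dataset = dataset,
       manifest = manifest,
       truth = list(samples = truth_samples,
                    genotypes = genotypes,
                    source_genotypes = stats::setNames(source_geno, snp_ids),
                    source_beta = stats::setNames(c_j, snp_ids),
                    config = config))
}
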