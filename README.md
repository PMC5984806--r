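# methylscreen

Extended quality control for Illumina Infinium DNA methylation
microarrays (450K/EPIC-style designs): screening of manufacturer control
metrics, sample-identity fingerprinting from SNP probes, sex inference
from allosomal intensities, and two complementary measures of DNA
contamination. The package targets analysts running epigenome-wide
association studies who need to catch failed experiments, mislabeled
samples and contaminated DNA *before* downstream modeling, where such
samples present as outliers and can create or mask associations.

Every check is exercisable entirely on synthetic data with known ground
truth: a first-class generator emulates trimodal SNP-probe β
distributions under Hardy-Weinberg genotypes, sex-dependent X/Y
intensity doses, control-probe signal/background structure with
injectable failures, dye bias, and single-source contamination mixing.

## The checks

**Quantification.** For each locus *i*, methylated and unmethylated
fluorescence intensities *M*ᵢ and *U*ᵢ give the methylation level
β = *M*ᵢ/(*M*ᵢ+*U*ᵢ) ∈ [0,1]. Red-channel intensities are first
rescaled by a per-sample log-log regression of green on red over
duplicate internal control probes (dye-bias correction); detection
p-values compare each probe's total intensity *T*ᵢ = *U*ᵢ+*M*ᵢ against
a normal background model estimated from negative controls of the
matching channel(s).

**Control metrics.** The 17 BeadArray control metrics (restoration,
staining, extension, hybridization, target removal, bisulfite
conversion I/II, specificity I/II, non-polymorphic; per channel where
applicable) are foreground/background intensity ratios over dedicated
control-probe groups. A sample is flagged when any metric falls
strictly below its threshold; group membership and thresholds are an
editable policy table (`default_control_policy()`).

**Identity fingerprinting.** β-values of the SNP ("rs") probes are
pooled across samples and probes and fitted with a four-component
mixture — three Beta densities for the genotypes AA/AB/BB and a uniform
outlier component — by EM (`fit_snp_mixture()`). Posterior genotype
probabilities give a *soft* pairwise agreement between samples a and b:

    agreement(a, b) = Σ_j Σ_k q[a,j,k]·q[b,j,k] / Σ_j w[a,j]·w[b,j],   w = 1 − p(outlier)

so probes partially classified as outliers are partially excluded.
Conflicts are pairs whose agreement contradicts the donor metadata
(`check_snp_agreement()`). The per-sample outlier score
*O*ₙ — the average log₂ odds of the outlier component across a sample's
SNP probes (`snp_outliers()`) — summarizes deviation from the ideal
trimodal pattern; above −4 is conventionally suspect.

**Sex check.** Average total intensities over X and Y probes, each
normalized by the autosomal average (`normalized_chr_intensities()`),
separate male (one X, one Y) from female (two X, no Y) donors. Cutoffs
are learned robustly from recorded sex via the Hodges-Lehmann estimator
(median of all male/female pairwise averages), predictions come from
the quadrant rule, and clear predictions contradicting the metadata are
mismatches (`check_sex()`).

**Contamination.** Single-source contamination is modeled generatively:

    β[n,j] ~ Normal((1 − γ_n)·μ_k(n,j) + γ_n·c_j,  (1 − γ_n)·σ_k(n,j))

with γₙ the contamination degree of sample *n*, c<sub>j</sub> the
foreign-DNA methylation level at SNP *j* and k(n,j) the latent genotype.
Parameters are estimated jointly over the cohort by
Metropolis-within-Gibbs sampling (`fit_contamination()`), fully
reproducible from one seed.

## Worked example

```r
library(methylscreen)

cfg <- simulation_config(
  n_samples = 60, replicate_pairs = 5, sex_swaps = 2, donor_swaps = 1,
  control_failures = list("Bisulfite conversion II" = c(12L, 40L)),
  seed = 42)
sim <- simulate_dataset(cfg)
res <- qc_run(sim$dataset, out_dir = "qc_out", seed = 1)
str(res$summary, give.attr = FALSE)
#> List of 10
#>  $ n_samples             : int 60
#>  $ n_control_flagged     : int 2
#>  $ n_detection_flagged   : int 0
#>  $ n_sex_mismatch        : int 2
#>  $ n_sex_unclear         : int 0
#>  $ n_snp_outlier_flagged : int 0
#>  $ n_conflicts           : int 2
#>  $ n_pairwise_comparisons: int 1770
#>  ...
res$conflicts[, c("sample_a", "sample_b", "agreement", "conflict_type")]
#>     sample_a   sample_b agreement           conflict_type
#> 1 sample_001 sample_002 0.9990081    unexpected_agreement
#> 2 sample_001 sample_060 0.3846444 unexpected_disagreement
```

Both injected bisulfite-conversion failures are flagged by the control
metrics, both cross-sex label swaps surface as mismatches, and the one
donor-id swap produces its two expected fingerprint conflicts: the
broken replicate pair still agrees (0.999) despite different recorded
donors, while the falsely co-labeled pair agrees only at the unrelated
baseline (0.385 ≈ Σₖ HWE(k)² for allele frequency ½). Reports land in
`qc_out/` (`qc_report.tsv`, `conflicts.tsv`, `sex_report.tsv`,
`summary.json`).

The same run is available from a shell:

```sh
QC=$(Rscript -e 'cat(system.file("cli", "qc.R", package = "methylscreen"))')
Rscript $QC simulate --out simdir --seed 42
Rscript $QC run --intensities simdir/intensities.tsv \
    --manifest simdir/manifest.tsv --controls simdir/controls.tsv \
    --samples simdir/samples.tsv --out qc_out --seed 1
```

Exit codes: 0 all clear, 2 usage/format error, 3 at least one sample
failed a check.

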