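---
title: "Quality-control models and design choices in methylscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality-control models and design choices in methylscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylscreen)
```

methylscreen screens Infinium-style methylation microarray data for
three families of problems that routine detection-p-value filtering
misses: technically failed experiments, mislabeled samples (wrong sex
or wrong donor), and contamination with foreign DNA. This vignette
explains the statistical models behind each check, the tunable
parameters and their defaults, what the synthetic-data generator does
and does not emulate, and the numerical choices made where the design
was genuinely open.

## Signal model and preprocessing

Each locus is measured by a pair of fluorescence intensities, $U_i$
(unmethylated) and $M_i$ (methylated), either within one color channel
(type I probes) or across the green/red channels (type II). The
methylation level is estimated as
$$\beta_i = \frac{M_i}{M_i + U_i},$$
with no offset constant; a $0/0$ ratio is a *missing* value, never 0,
so that missingness propagates into downstream averages instead of
masquerading as an unmethylated call.

**Dye-bias correction.** The two channels have systematically different
gains. `correct_dye_bias()` regresses log green on log red intensities
over internal control probes that exist as duplicate designs in both
channels (staining, extension, bisulfite-conversion-I and
specificity-I categories, paired by rank within category) and applies
the fitted log-linear map to every red-channel measurement of the
sample. The map is monotone, so within-channel ranks are preserved; a
sample with fewer than 3 usable pairs is left uncorrected and flagged.
We deliberately use *all* duplicate control pairs rather than only
staining/extension: with 4 pairs the per-sample fit recovers an
injected 2x red bias to only ~5–6% (median), with 16 pairs to ~2–3%,
at the generator's default intensity noise (CV 0.1).

**Detection p-values.** `detection_pvalues()` compares the total
intensity $T_i = U_i + M_i$ against a normal background estimated from
the negative controls of the contributing channel(s): type I probes use
mean $2\hat\mu_{ch}$ and sd $\sqrt2\,\hat\sigma_{ch}$ of their design
channel, type II probes $\hat\mu_{grn}+\hat\mu_{red}$ with variances
added. This is a conventional formulation — the method stack only
consumes the standard "more than 1% of probes with p > 0.01" screening
rule, so any monotone background model would serve; the choice is
documented rather than load-bearing. In `qc_run()` the flagging
fraction excludes Y-chromosome probes, which legitimately sit at
background in female donors; on a full-size chip (413 Y probes out of
~485k) this makes no numeric difference, but on scaled-down synthetic
chips it prevents spurious flags.

## The 17 control metrics

Each metric is the ratio of mean foreground to mean background control
intensity in a designated channel (e.g. *Bisulfite conversion II* =
converted-template signal in red over the same probes' green
background). Ratios are dimensionless, hence invariant to per-sample
intensity scaling. Flagging is strict `value < threshold` — a sample
exactly at threshold passes. Thresholds default to the manufacturer's
control-reporter values (5 for staining/extension/non-polymorphic, 0
for restoration, 1 otherwise). Because the exact probe groupings are
platform configuration rather than method, they ship as an editable
policy table (`default_control_policy()`, replaceable via
`read_control_policy()`); the default patterns match the manifests the
generator emits. Metrics whose control category is absent yield `n.a.`
and never flag.

## Genotype mixture and identity fingerprinting

SNP ("rs") probes query common polymorphisms, so their $\beta$-values
fall into three clusters near 0, 0.5 and 1 (genotypes AA/AB/BB).
`fit_snp_mixture()` pools $\beta$ across all SNP probes and samples and
fits, by EM,
$$p(\beta) = \sum_{k \in \{AA,AB,BB\}} w_k\,
  \mathrm{Beta}(\beta; a_k, b_k) + w_{out}\cdot 1,$$
a three-Beta mixture plus a uniform outlier component on $[0,1]$ whose
density is fixed at 1 (only $w_{out}$ is learned — the simplest model
in which "outlier" mass is weight, not shape). Numerical choices:

* $\beta$ is clamped to $[10^{-6}, 1-10^{-6}]$ before density
  evaluation, bounding Beta densities at the boundaries.
* The M-step maximizes each component's weighted Beta likelihood
  through its sufficient statistics ($\sum w\log x$,
  $\sum w\log(1-x)$, $\sum w$) with Nelder-Mead started at the current
  shapes, so every iteration is a generalized M-step and the
  log-likelihood trace is non-decreasing (asserted in the tests).
* EM runs from **two starts** — (i) moment-matched components on the
  $\beta$ ranges $[0,.25]$, $(.25,.75]$, $(.75,1]$ with
  $w_{out}=0.01$, and (ii) canonical clusters at $0.05/0.5/0.95$ (sd
  $0.05$) with $w_{out}=0.2$ — keeping the higher final
  log-likelihood. On heavily contaminated cohorts the data-driven
  start alone converges to a visibly inferior optimum in which the
  genotype components inflate to absorb between-cluster values.
* Components are relabeled by ascending mean after fitting; stopping
  at log-likelihood gain $<10^{-6}$ or 500 iterations.

`call_genotypes()` converts the fit into per-(sample, probe)
posteriors over {AA, AB, BB, outlier} by Bayes' rule.

**Pairwise agreement.** For samples $a, b$ with genotype posteriors
$q$ and non-outlier mass $w = 1 - p_{out}$,
$$\mathrm{agreement}(a,b) =
  \frac{\sum_j \sum_{k} q_{ajk}\, q_{bjk}}{\sum_j w_{aj}\, w_{bj}}.$$
The numerator is the expected number of probes at which both samples
carry the same genotype; the denominator softly excludes probes
classified (possibly partially) as outliers. Among the defensible
denominators (min, mean or product of the two samples' non-outlier
masses) we ship the **product**, which is the exact normalizer of the
numerator's expectation under independent posteriors; it is pinned by
a unit test. Under Hardy-Weinberg equilibrium with allele frequency
$p$, unrelated pairs agree at about $\sum_k \mathrm{HWE}_k(p)^2$
($=0.375$ at $p=0.5$) while same-donor pairs approach 1, so the
default conflict threshold of **0.90** sits far from both
distributions. Conflicts are pairs contradicting donor metadata in
either direction.

**Outlier score.** $O_n$ is the average over a sample's non-missing
SNP probes of $\log_2 \frac{p_{out}}{1-p_{out}}$ (base 2, posteriors
clipped at $10^{-8}$). It summarizes how far the sample deviates from
the trimodal ideal; the shipped flagging cutoff is $-4$ log2-odds,
overridable in the QC config. No universal cutoff exists — the score
depends on both the mixing fraction and how many SNPs differ between
host and contaminant — so the flag is a screening aid, not a verdict.

## Sex inference

Total intensity $T_i = U_i + M_i$ tracks copy number. With
$\bar T^X_n$, $\bar T^Y_n$ the means over X/Y probes normalized by the
autosomal mean (canceling DNA-input differences), males (one X, one Y)
and females (two X, no Y) form two clusters. Cutoffs on each axis are
the **Hodges-Lehmann estimator** — the median of all male/female
cross-pair averages — computed from the *recorded* sex: being a median
over cross-pairs, it tolerates a substantial fraction of wrong labels,
which is precisely the situation the check exists for (a robustness
test swaps 40% of one class's labels and moves the cutoff by less than
a tenth of the cluster separation). For an even pair count the median
is the midpoint of the central pair. Predictions follow the quadrant
rule (male: low X *and* high Y; female: high X *and* low Y); the other
two quadrants — and samples exactly on a cutoff, a conservative
tie-break — are `unclear`. The upper-right quadrant is where an XXY
karyotype would fall, so `unclear` is deliberately not treated as a
mismatch.

## Contamination model and sampler

Mixing DNA from two individuals pulls SNP $\beta$-values toward the
contaminant's allele dosage, the same way heterozygotes sit midway
between homozygotes. For a single foreign source:
$$\beta_{nj} \sim \mathcal N\!\big((1-\gamma_n)\,\mu_{k_{nj}} +
  \gamma_n\, c_j,\; (1-\gamma_n)\,\sigma_{k_{nj}}\big)$$
with $\gamma_n \in [0, 0.99]$ the contamination degree, $c_j \in
[0,1]$ the foreign methylation level at SNP $j$ (shared across
samples — the single-source assumption), and $k_{nj}$ latent
genotypes. The $(1-\gamma_n)$ factor appears in **both** the mean and
the sd: as the foreign fraction grows the host cluster contributes
less variance. No extra measurement-noise floor is added to the sd;
the genotype-level $\sigma_k$ absorbs it.

`fit_contamination()` samples the posterior by Metropolis-within-Gibbs:

* random-walk proposals, reflected at the bounds, for $\gamma_n$ (all
  samples in parallel — they are conditionally independent), $c_j$
  (likewise per probe), and each $\mu_k$, $\sigma_k$;
* discrete Gibbs draws of $k_{nj}$ proportional to the three component
  likelihoods (via the Gumbel-max trick, vectorized over the matrix);
* priors: uniform on $[0, 0.99]$ for $\gamma_n$ (the upper bound keeps
  the sd positive), uniform on $[0,1]$ for $c_j$, flat order-constrained
  on $\mu$, half-normal(0.1) on $\sigma_k$;
* proposal scales adapt every 100 burn-in iterations toward ~30%
  acceptance; defaults are 10,000 iterations with 5,000 burn-in,
  estimates are posterior means, intervals are 2.5/97.5 posterior
  percentiles, and the whole chain is reproducible from one integer
  seed.

Genotypes are initialized from the mixture model's hard calls when
posteriors are supplied; probes with high outlier posterior still
participate, because the contamination model itself is the explanation
for their displacement. The cohort is fitted jointly, matching how the
check is meant to be run on one suspect dataset.

## What the generator emulates — and what it does not

`simulate_dataset()` produces a full dataset plus a truth table
recording every latent variable: donor genotypes drawn per
Hardy-Weinberg (allele frequency defaults to 0.5, the
maximum-entropy/high-frequency-SNP choice; replicate samples share
their donor's genotypes), SNP cluster centers $0.05/0.5/0.95$ with sd
$0.05$, intensities lognormal around a scale of 3000 against a
background of 300 (CV 0.1), X/Y doses of 1.0/0.12 (female) and
0.55/0.9 (male) relative to autosomes, control probes with the
signal/background structure the default policy expects, and injectable
anomalies: per-metric control failures, whole-sample signal collapse,
cross-sex label swaps, donor-id swaps, per-sample red-channel bias,
and single-source contamination that shifts both SNP $\beta$ and (for
cross-sex mixes) allosomal doses.

Two generator choices deserve justification:

* **Cluster noise is truncated-normal, not Beta.** A Beta distribution
  moment-matched to mean 0.05 and sd 0.05 has shape $<1$: a J-shaped
  density with a heavy right tail that fills the valleys between
  genotype clusters and can never produce the cleanly trimodal
  histograms real SNP probes show. Light-tailed truncated-normal noise
  matches both the observed trimodality and the normal likelihood the
  contamination model assumes.
* **The contamination design is right-skewed.**
  `skewed_gamma_design(n)` spreads $\gamma$ over $[0, 0.5]$ as scaled
  Beta(1,2) quantiles, so most samples are mildly contaminated and a
  subset heavily — the pattern of a single contaminated plate or
  adjacent chip positions. This matters for method validity, not
  merely realism: the pooled genotype mixture that calibrates $O_n$
  assumes most mass still sits in the trimodal clusters. If half the
  cohort is heavily contaminated (e.g. $\gamma$ uniform on
  $[0, 0.5]$), no four-component fit can hold the clusters in place
  and the outlier score flattens — a genuine limitation of
  mixture-calibrated outlier scoring itself.

Not emulated: probe cross-reactivity, batch/plate effects, copy-number
aberrations beyond allosome dosage, multi-source contamination, and
tissue heterogeneity. Passing tests therefore demonstrate correctness
of the algorithms under the stated generative assumptions, not
robustness to every artifact of real cohorts.

## Problem sizes and verification

The test suite validates each operation against independent oracles:
brute-force enumeration for the Hodges-Lehmann cutoff and the
Hardy-Weinberg agreement baseline, hand-computed densities for Bayes
posteriors and the contamination likelihood, write-then-read oracles
for the TSV and IDAT readers, and parameter-recovery simulations for
EM (5,000 pooled observations; component means recovered within 0.02)
and the MCMC sampler (100-sample cohorts, 10,000 iterations; Pearson
correlation between estimated and true $\gamma$ above 0.99 in our
runs). Identity fingerprinting is exercised on 310-sample and
2,000-sample cohorts (1,000 duplicate pairs); duplicate and unrelated
agreement distributions separate with no overlap. These sizes keep the
full suite in the minutes range on a single CPU while leaving each
statistical conclusion comfortably away from its tolerance.

## Known limitations

* The detection-p-value background model is a documented convention;
  platforms with strongly non-normal negative-control distributions
  would need a replacement.
* `check_snp_agreement()` cannot tell *which* member of a conflicting
  pair is mislabeled, and is uninformative for cohorts with one sample
  per donor.
* The contamination model assumes one foreign source; mixtures of
  several DNAs violate the shared-$c_j$ structure and bias $\gamma$
  downward. $O_n$ remains usable as a generic irregularity score.
* Sex inference requires at least one recorded male and one recorded
  female; single-sex cohorts need manually supplied cutoffs.
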