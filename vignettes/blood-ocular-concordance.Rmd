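---
title: "Methods: blood as a surrogate tissue for ocular DNA methylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: blood as a surrogate tissue for ocular DNA methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oculoconcord)
```

## The scientific question

Epigenome-wide association studies of eye disease almost always measure DNA
methylation in peripheral blood, because retina, RPE/choroid and optic nerve
cannot be sampled in living people. Whether blood methylation is a usable
proxy depends on two separable phenomena: *tissue-driven* variation (CpGs
whose methylation is set by cell type, identical across donors) and
*individual-driven* variation (CpGs that co-vary across all of a donor's
tissues, typically because of underlying genetics, i.e. mQTLs). Only the
second kind is informative when blood stands in for eye tissue.

This package implements the analysis pipeline for matched-donor
multi-tissue HM450K-style beta-value matrices that separates these two
sources: probe-level QC, three-class methylation categorisation with
disjoint cross-tissue overlap counts, sample-level Spearman concordance,
blood-variable probe selection with per-probe matched blood--eye
correlation tested against a permutation null of unmatched donor pairings,
paired-t similarity screening, PCA with trait association, a moderated-F
test for tissue-specific probes, and genomic-context enrichment. A
synthetic-data generator with known ground truth makes every stage testable
without any external download.

## The generative model behind the simulator

`simulate_dataset()` draws, for each probe, a baseline methylation class
(hypo / intermediate / hyper, default weights 0.4 / 0.2 / 0.4, giving the
bimodal beta landscape characteristic of methylation arrays) and a baseline
beta value (Beta(2, 40), Beta(2, 2) rescaled into (0.2, 0.8), and
Beta(40, 2) respectively). All effects act on the logit scale, which keeps
beta in [0, 1] without truncation artefacts:

* **Tissue effects.** An exact `round(f_tissue * n_probes)` subset of
  probes receives per-tissue offsets. Tissues are embedded in a
  low-dimensional space by classical MDS of the configured
  `tissue_distance` matrix; each tissue-effect probe picks a random
  direction and magnitude through that embedding, so expected pairwise
  offset separations scale with the configured distances. The default
  distances encode the structure reported for matched blood/eye data:
  blood is the most distinct tissue and resembles RPE/choroid most, then
  optic nerve, then retina, while RPE/choroid and optic nerve are the most
  similar pair (blood--retina 4.0,
  blood--optic nerve 3.2, blood--RPE/choroid 2.6, retina--optic nerve 1.8,
  retina--RPE/choroid 1.4, RPE/choroid--optic nerve 0.7, logit units).
* **Donor-shared (individual) effects.** A disjoint, exact
  `round(f_individual * n_probes)` subset receives one offset per donor,
  identical in every tissue of that donor — the cleanest recoverable
  model of mQTL-like inter-individual variation. Effects are Gaussian with
  sd `individual_effect_sd` (default 1.5) by default; with
  `trimodal_genotype = TRUE` they take mQTL-like levels
  $\{-\delta, 0, +\delta\}$ with Hardy--Weinberg-like weights
  (0.25, 0.5, 0.25), $\delta$ scaled to preserve the marginal sd.
* **Technical noise.** Independent Gaussian logit-scale noise per cell
  (default sd 0.3).

The design emulates an 8-donor, 4-tissue post-mortem study: donors are
assigned to chips round-robin (default 3 chips), ages are drawn around a
mean of 60.6 (sd 11.3) years clipped to 37--76, preservation intervals are
uniform within 12 hours, and QC flags mark exact fractions of probes as
cross-reactive (default 0.057) or SNP-affected (default 0.017) — the
removal proportions such blacklists produce on the ~485k-probe array.
`f_tissue = 0.10` and `f_individual = 0.05` are calibration choices, not
measured values: the source study reports only variance-explained
percentages on its own data, and these fractions reproduce its qualitative
structure (tissue dominates, individual variation is a small PC) at desk
scale. Everything is deterministic given `seed`.

What the simulator does **not** emulate: Infinium type-I/II probe
chemistry, color-channel and background effects, cell-composition
heterogeneity within tissues, correlated (neighbouring-CpG) structure, and
partial sharing of donor effects across tissues (donor effects are either
fully shared or absent). Tests passing on simulated data therefore
demonstrate correctness of the statistical machinery under the stated
model, not robustness to those real-data artefacts.

## Thresholds and conventions

All tunable thresholds live in `analysis_config()`:

| parameter | default | meaning |
|---|---|---|
| `hypo_max` | 0.2 | hypomethylated iff mean beta <= 0.2 (closed boundary) |
| `hyper_min` | 0.8 | hypermethylated iff mean beta >= 0.8 (closed boundary) |
| `variability_range_min` | 0.05 | blood-variable iff q90 - q10 > 0.05 (strict) |
| `variability_quantiles` | 0.10, 0.90 | quantile pair defining the range |
| `corr_r_min`, `corr_p_max` | 0.5, 0.05 | matched-correlation selection |
| `detection_p_max` | 0.01 | failure iff detection p > 0.01 (strict) |
| `fdr_q` | 0.05 | Benjamini-Hochberg cutoff |
| `equivalence_delta` | 0.05 | beta-equivalence bound for `paired_similarity()` |
| `n_null_permutations` | 100 | non-identity donor permutations pooled |

Conventions that the source description leaves open were fixed as follows
and are deliberate design decisions, not inferences:

* **Quantiles** use linear interpolation between order statistics with
  $h = (n-1)p$ (`quantile(type = 7)`), the default of mainstream
  statistical environments; a range of exactly 0.05 is *excluded* (the
  rule is strictly "greater than 5%").
* **Detection failures** remove a probe when *any* sample exceeds the
  cutoff — the strictest reading; per-fraction rules can be emulated by
  pre-masking the detection matrix.
* **Multi-annotation probes** collapse to one genomic feature by the fixed
  priority TSS200 > TSS1500 > UTR5 > FirstExon > Body > UTR3 > Intergenic
  (`collapse_feature_classes()`).
* **Missing values** are the `NA` token on disk and propagate
  pairwise-complete through means, quantiles and correlations; probes with
  missing values are dropped (with a warning) before PCA and the
  moderated-F fit, and excluded from permutation-null pooling.
* **Clustering** uses distance $1 - \rho$ with average linkage, the common
  choice for methylation sample dendrograms; samples are pre-sorted
  lexicographically so merge order is deterministic. Results are labelled
  with these parameters since other choices are equally defensible.
* **Median** is the midpoint of the two central order statistics.
* **M-values** are $\log_2(\beta/(1-\beta))$ after clipping beta to
  `[0.001, 0.999]`; clipping perturbs only boundary values while keeping
  every M-value finite.

## The matched-correlation procedure and its null

For each blood-variable probe and eye tissue, Spearman's rho is computed
between the donor-ordered blood vector and the same donors' eye vector
(n = number of matched donors, 8 by default). Two p-values are available:

* the **t approximation** $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$
  degrees of freedom (default), and
* the **exact rank-permutation p** (`exact_p = TRUE`), enumerating all
  $n!$ orderings for $n \le 8$; it assumes untied ranks, which holds
  almost surely for continuous beta values.

At $n = 8$ the t approximation is slightly anti-conservative for this
discrete statistic: under the exact null it selects 5.76% of probes at
nominal p < 0.05 (the exact option selects 4.58%). The calibration tests
use exactly this band ($\pm 0.01$ around the enumerated value).

The **permutation null** re-pairs eye samples with the wrong donors:
`n_null_permutations` random non-identity donor permutations are drawn,
per-probe correlations recomputed for each, and all values pooled into one
empirical null distribution — pooling is what turns per-probe nulls into
the single distribution the matched distribution is compared against with
a two-sided Mann--Whitney rank-sum test (normal approximation with tie
correction, no continuity correction). Partial matches (permutations
fixing some donors) are allowed; only the full identity is excluded.

A probe "tracks blood" in an eye tissue when $|\rho| >$ `corr_r_min` and
p < `corr_p_max`; the pipeline's final surrogate set is the intersection
of these selections across all three eye tissues
(`common_correlated_probes()`). Recovery statements about donor-shared
probes refer to this common set: a single-tissue selection at a ~5%
type-I rate over a background of ~19 null probes per true probe would be
dominated by false positives no matter how sensitive the test, whereas
requiring selection in all three tissues drives the null contamination
toward zero while keeping sensitivity high (the per-tissue tests are
strongly dependent through the shared donor effects).

"Most similarly methylated" probes (`paired_similarity()`) are
operationalised as the conjunction of a non-significant paired t-test
(BH-adjusted p >= `fdr_q`) and an equivalence bound
(|mean difference| < `equivalence_delta`): absence of significance alone
is not evidence of similarity at n = 8, so both ingredients are emitted
separately and either definition can be reproduced from the output.

## PCA, trait association and the exclusivity screen

PCA runs on M-values with probes centered across samples (samples are the
observations); the sign of each component is fixed so its
largest-magnitude loading is positive. Components are tested against
traits by one-way ANOVA (categorical) or a simple-regression F test
(continuous). Components *exclusively* associated with individuals are
those with donor p < alpha and every other screened trait p >= alpha
(default alpha 0.05; 0.10 reproduces a more permissive screen).

The screen considers the genome-wide traits — donor, tissue, chip. With
only eight donors, donor-level phenotypes (age at death, cause of death,
preservation interval) are deterministic functions of donor identity, so
any donor-driven component resembles them by construction and including
them in the exclusivity criterion mostly measures chance; they are
computed in the association table as a follow-up check instead.

Probes "associated" with a component are selected by the Pearson
correlation of each probe's M-values with the component's score vector
(|r| > `corr_r_min`), matching the procedure's |r| phrasing; loading-based
selection would rank identically only for equal-variance probes.

## Tissue-specific probes: the moderated F

Per probe, a one-way model of M-values on tissue yields the between-tissue
mean square and a residual variance $s^2$ on $d$ degrees of freedom.
Residual variances are shrunk by empirical Bayes: assuming
$s^2 \sim s_0^2 F(d, d_0)$, the hyperparameters are estimated by moment
matching on $\log s^2$ (digamma/trigamma method, with a Newton inversion
of the trigamma function), the posterior variance is
$\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$, and the moderated
$F = \mathrm{MSB}/\tilde s^2$ is referred to $F(k-1,\ d_0+d)$ with BH
adjustment. The limits behave as expected — $d_0 = 0$ reproduces the
ordinary ANOVA F and $d_0 = \infty$ divides every probe by the prior
variance — and the estimates agree with limma's `eBayes` on the same
data, which the test suite uses as an independent cross-check.

## Enrichment

Probe subsets (all blood-variable probes, per-tissue correlated probes,
the common set, PC-associated probes) are compared against the post-QC
background per genomic feature class and CpG-island relation with the
two-sided Fisher exact test (exact at the small counts these panels can
produce; the cross-product odds ratio is reported, infinite for zero
cells) and BH adjustment within each scheme. The background defaults to
all retained probes, the probe-level analogue of using the whole array as
the reference list.

## Numerical and degenerate-input choices

* Spearman correlation needs >= 3 complete pairs and nonzero rank variance;
  otherwise the result is an error (scalar API) or `NA` (per-probe API,
  with the count reported).
* Zero-variance difference vectors in `paired_similarity()` leave t
  undefined; such probes are flagged and count as similar exactly when
  their mean difference is inside the equivalence bound.
* Matrix round-trips write 17 significant digits, so reading back
  reproduces doubles exactly; ties in `select_top_variable()` break by
  lexicographic probe id.
* Every output file records the configuration hash (md5 of the canonical
  YAML serialisation) and seed as `#` header comments; reruns with the
  same configuration are byte-identical.

## Problem sizes used by the automated checks

The test suite and `scripts/acceptance.R` exercise the pipeline at 20,000
probes x 32 samples for calibration and recovery runs and 300--5,000
probes for structural checks — sizes at which every Monte-Carlo band used
(e.g. $\pm 0.01$ on the null selection fraction, $\pm 0.02$ on the pooled
null mean over >= 100,000 values) is comfortably wider than the sampling
error, while a full run stays in the seconds-to-minutes range on one CPU.

## Known limitations

* The simulator's donor effects are fully shared across tissues; real
  mQTL effects are often tissue-dependent, so real-data recovery of the
  common correlated set will be lower than the simulated one.
* The t-approximation p at n = 8 is anti-conservative by design of the
  statistic; use `exact_p = TRUE` where calibration matters more than
  speed.
* The pipeline assumes normalised beta values as input; background
  correction, BMIQ-style normalisation and batch *adjustment* are out of
  scope (chip enters only as a trait in association tests).
* Sample-level QC, cell-composition deconvolution and genotype
  integration are not modelled.

## A minimal run

```{r example, eval = FALSE}
run <- run_pipeline(list(seed = 1,
                         simulate = list(n_probes = 2000),
                         analysis = list(n_null_permutations = 25)),
                    output_dir = "run1")
print(run)
```
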