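---
title: "Methods: simulating and inferring driver-mutation evolution in uveal melanoma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and inferring driver-mutation evolution in uveal melanoma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(umevol)
```

# Scope

`umevol` implements the analytic pipeline used in molecular-evolution
studies of uveal melanoma (UM): estimating tumor purity and cancer cell
fractions (CCF) from targeted sequencing read counts, calling chromosome-3p
loss of heterozygosity (LOH3p) from a B-allele/depth panel, rule-based
variant pathogenicity classification, the cohort statistics used in such
studies (test switching, Kaplan-Meier/log-rank, Cox, propensity matching,
power simulation), and evolutionary-state reports. Because real patient
cohorts of this kind are access-controlled, the package also ships a
synthetic cohort generator whose retained ground truth makes every
estimator testable end to end.

# The generative model

## Mutations

Every simulated tumor carries exactly one founder **Gq mutation** (GNAQ,
GNA11, PLCB4 or CYSLTR2; a second co-occurring Gq mutation is rare,
probability 6/1140), assumed clonal and heterozygous, so it is present at
50% VAF within tumor cells. Secondary **BSE mutations** (BAP1, SF3B1,
EIF1AX) are drawn conditional on the 15-gene expression profile (15-GEP)
class: BAP1 mutations concentrate in Class 2 (probability 0.80 vs 0.035 in
Class 1), SF3B1 and EIF1AX in Class 1. A second, distinct BSE mutation has
probability 26/1140. BSE mutations may be **sub-clonal**: SF3B1 and EIF1AX
CCFs are drawn from Beta(5, 2) (near-clonal-heavy), BAP1 from
Uniform(0.7, 1) in Class 2 and Uniform(0.2, 0.8) in Class 1.

## Size, class coupling, and purity

A tumor is "small" when thickness is at most 2.5 mm **and** largest basal
diameter is at most 12 mm (both boundaries inclusive); the default small
fraction is 131/1140. Size and class are coupled through an odds ratio
(default 3.7) so small tumors are enriched for Class 1, while the
cohort-wide Class 1 fraction stays exactly at its configured value (0.628):
the large-tumor Class-1 probability is solved from the mixture identity.
Tumor purity is truncated-normal, mean 0.586 (SD 0.15) in small and 0.819
(SD 0.10) in larger tumors, on [0.05, 0.99]. The SDs are not published
quantities; they were chosen so that the two strata overlap realistically
while keeping the means at the published values.

## 3p state and the discriminant score

LOH3p (copy loss or copy-neutral isodisomy, 25% of LOH being isodisomy) is
sampled conditional on class and BAP1 status (0.85 for Class 2 BAP1-mutant,
0.60 for Class 2 wild-type, 0.50 for Class 1 BAP1-mutant, 0 for Class 1
wild-type), reflecting its role in completing biallelic BAP1 inactivation.

The discriminant score emulates the conceptual model in which the 15-GEP
score inverts progressively after BAP1 loss. A latent score
`z = -1 + slope * deficit * m/(m + tau) + noise` increases with the BAP1
dosage deficit (`(mutation CCF + LOH)/2`, with a cryptic hit of 0.85 for
Class 2 tumors without a detected BAP1 mutation) and with months since BAP1
loss (`m`, linked to tumor diameter), saturating with time constant
`tau = 12` months. Class 2 corresponds to `z > 0`; noise is sign-constrained
by rejection so the class label and the latent score never contradict each
other, and the reported dscore is `min(|z|, 1)` — the absolute distance to
the SVM decision boundary. Low dscore therefore flags tumors near the
Class 1 to Class 2 transition.

## Read sampling

Alt counts are Binomial(depth, expected VAF) with log-normal depth noise
(sdlog 0.15). Two read models are provided:

* `paper_consistent` (default): expected VAF is `purity * CCF / 2` at
  heterozygous loci and `purity * CCF` at hemizygous (post-LOH, male-X)
  loci. This is the model the CCF estimator inverts exactly, so recovery
  tests validate the estimation arithmetic itself.
* `copy_aware`: full allele-pool mixing,
  `purity * CCF * copies_mut / (purity * copies_tumor + (1 - purity) * 2)`.
  At an LOH locus the normal diploid DNA dilutes the VAF, so the
  hemizygous estimator is biased: with clonal BAP1 and LOH at purity `p`
  the estimated CCF converges to `1/(2 - p) < 1`. The model exists to make
  this bias measurable rather than hidden.

The 74-locus 3p panel draws mirrored B-allele frequencies from the same
allele-pool arithmetic: expected mirrored BAF is 0.5 under retention,
`1/(2 - p)` under loss (with depth ratio `(2 - p)/2`), and `(1 + p)/2`
under isodisomy (depth ratio 1). A fraction of loci (default 0.2) is
germline-homozygous and uninformative.

# Estimators

* **Purity**: `TP = min(2 * VAF_Gq, 1)` from the maximum-VAF Gq mutation
  (ties broken GNAQ > GNA11 > PLCB4 > CYSLTR2); samples without a Gq
  mutation are excluded, not errored.
* **CCF**: corrected VAF `cv = VAF/TP` is kept uncapped and flagged when
  above 1. CCF is `min(2cv, 1)` for SF3B1, EIF1AX in females, and BAP1
  with 3p retention; `min(cv, 1)` for EIF1AX in males and BAP1 with a
  usable LOH3p call (loss or isodisomy, treated identically; LOH assumed at
  ~100% CCF). BAP1 with no usable LOH3p call (confidence below 2) has
  undefined CCF, matching the requirement that a confidence of 2 or 3 is
  needed for downstream use.
* **LOH3p**: per-locus mirrored BAF and depth log fold-change versus a
  panel of normals; a sample is called loss when the median mirrored BAF
  reaches the purity-aware threshold `1/(2 - TP) - 0.08` with median lfc
  below -0.15, isodisomy when the BAF threshold is met with |lfc| at most
  0.15, retention otherwise. The purity-aware threshold exists because
  normal-cell admixture bounds the observed BAF below 1. Confidence (0-3)
  is computed from the MADs of the per-locus summaries and the
  informative-locus count, replacing the study's manual adjudication with
  explicit dispersion bounds chosen so that added noise can never raise the
  score.
* **Pathogenicity**: truncating/length-changing types are pathogenic by
  type; splice-site calls require SpliceAI at least 0.5 **and** an
  acceptor/donor loss-or-gain effect; missense calls require a ClinVar
  pathogenic flag, SIFT at most 0.05, or PolyPhen-2 at least 0.5 (basis
  attributed in that precedence). Missense with all three annotations
  missing — and splice sites without a SpliceAI score — are *indeterminate*
  rather than benign.

# Statistical choices

Categorical association uses Fisher's exact test when at least 25% of
expected cell counts are below 5, chi-square (without continuity
correction) otherwise; continuous contrasts use the Wilcoxon rank-sum
test. Cox models use Efron tie handling, error on singular designs, and
warn below five events per covariate. Propensity matching is 3:1 greedy
nearest-neighbour on the logit propensity without replacement, caliper 0.2
SD of the logit, cases processed in decreasing propensity order. The
log-rank power simulation draws exponential event times matched to the
stated horizon survivals, censors administratively at the horizon, and
reports the rejection fraction with its Monte-Carlo standard error,
alongside the Schoenfeld events-based closed form as a cross-check; the
two can disagree materially when the expected event count is small and the
hazard ratio large, which is why the simulation, not the formula, is the
primary estimate.

# Default problem sizes

The defaults (1140 patients, 74 panel loci, variant depth 1000x, panel
depth 300x) are the package's own choices for a realistic desk-scale
cohort; tests use smaller cohorts where distributional checks allow it.

# Limitations

* Single-mutation CCFs only: no subclonal deconvolution, multi-region or
  phylogenetic reconstruction, and no whole-genome-doubling correction.
* The 15-GEP SVM and PRAME assay internals are out of scope; class,
  dscore and PRAME status are consumed (or simulated) as inputs.
* Annotation scores (SpliceAI, SIFT, PolyPhen-2, ClinVar) are input
  fields; the package never runs the annotators.
* The simulator is a statistical emulator, not a biophysical model: event
  times are exponential, the dscore process is a saturating deterministic
  trend plus noise, and mutation co-occurrence is near-exclusive by
  construction.

This vignette states no empirical result beyond what the package's test
suite and the bundled `scripts/acceptance.R` compute.
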