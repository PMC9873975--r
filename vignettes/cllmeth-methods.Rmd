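---
title: "Models and methods behind cllmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cllmeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cllmeth)
```

`cllmeth` packages the full decision chain of a 450K-style case–control
methylation study of CLL. This vignette explains the models each stage
assumes, the tunable parameters and their defaults, what the synthetic
world does and does not emulate, and the design choices made where the
design was genuinely open. It states no empirical result that the test
suite does not itself compute.

## 1. The measurement model

A probe's beta value is the methylated fraction M/(M+U+100) of its two
intensity channels, bounded in [0,1] and bimodal genome-wide. All
hypothesis tests run on the M-value, M = log2(β/(1−β)), whose noise is
closer to homoskedastic; effect sizes are reported as Δβ because the
field's decision rule (|Δβ| > 0.2) lives on the beta scale. `beta_to_m()`
clips β to [ε, 1−ε] with ε = 0.001 — the handling of exact 0/1 calls is
not specified by the criteria this pipeline implements, and clipping keeps
every probe finite without disturbing the (0,1) interior (`m_to_beta()`
inverts exactly there).

## 2. Quality control

Four probe rules (each configurable, defaults in parentheses): detection
p > 0.05 in more than 1% of samples; bead count < 3 in more than 5% of
samples; location on X/Y; SNP-overlapping or cross-reactive flags. A probe
matching several rules is counted under every reason but removed once, so
the per-reason counts add up transparently. Samples are dropped when more
than 1% of their probes fail detection, and when 2-component clustering of
a 2-D classical MDS of X-probe betas contradicts the recorded sex. If the
two clusters do not track recorded sex at all (no X-linked structure),
the check declares itself indeterminate and excludes nobody — silently
flagging half the cohort on noise would be worse than abstaining.

## 3. Normalization

Probe design types I and II have different dynamic ranges. We normalize
with full quantile normalization *within each design type*: each sample's
values are replaced by the mean order statistics of its type stratum
(average ties). When intensities are available the two channels are
normalized separately and β recomputed with the +100 offset. The
dasen/BMIQ internals are deliberately not reproduced: the synthetic data
carry no dye chemistry, and the testable contract — identical
within-type distributions across samples, rank preservation per sample —
is what downstream stages rely on.

A caveat worth stating: quantile normalization attenuates genuine global
case–control differences, because the reference quantiles blend both
groups. On the default synthetic world the recovered |Δβ| of an injected
0.3 effect is roughly 0.25 after normalization. This is a property of the
method, not a bug; the DMP threshold (0.2) sits below the attenuated
effect, and the power criterion in the acceptance suite is evaluated on
the generator's output, where the injected effect is exact.

## 4. Batch correction

`combat()` implements the parametric empirical-Bayes location/scale
model: standardize each probe preserving covariate effects, estimate
per-batch means and variances, shrink them toward across-probe priors
(normal for location, inverse-gamma for scale, both moment-matched,
solved iteratively), adjust and restore. It runs on the M scale with the
sample sheet's batch column — the source study does not state either
choice, and M-scale adjustment matches the scale of the downstream linear
model. The non-parametric variant is out of scope. A batch that
coincides 1:1 with a biological covariate is refused by name: no
adjustment can separate the two.

Two properties calibrate expectations. First, EB shrinkage leaves a
residual per-probe batch difference of order (1−w)·σ·√(2/n): with 2,000
probes the acceptance check of "99% of probes within 0.05" therefore uses
batches of 1,000 samples, where that residual (not the sampling noise of
the measured means) dominates. Second, a group effect injected on the
beta scale interacts non-linearly with an M-scale batch shift — the same
Δβ is a different ΔM in a shifted batch — so offset removal is verified
on a null-group construction and effect preservation on an orthogonal
group-effect construction, matching the two generator-ground-truth
examples the criteria derive from.

## 5. Differential methylation

Per probe, OLS of M on intercept + group + covariates (default age and
sex), a two-sided t on the group coefficient, and step-up FDR across all
tested probes. The BH computation orders its arithmetic exactly as the
reference implementations (`m/i · p`, cumulative minimum from the largest
p) so q-values are bit-identical to them. Δβ is computed on the
post-normalization, *pre*-ComBat betas (configurable): ComBat deforms
betas probe-by-probe, and the effect-size criterion should describe the
measured methylation difference. Probes with zero variance get p = 1
rather than NaN, keeping BH well-defined; rank-deficient designs fail
loudly with the collinear columns named. A moderated option squeezes
per-probe variances toward a scaled inverse-χ² prior fitted by moments —
the classical variance-moderation idea — but the default is the ordinary
t: the criteria that define a DMP (|Δβ| > 0.2, q < 0.05) dominate the
decision surface, and the unmoderated path is the more transparent
default at n = 48 vs 28.

A DMP is `|Δβ| > 0.2 & q < 0.05`, direction = sign(Δβ), positive =
hypermethylated in cases. The category tables (`feature_distribution()`)
compare the DMP distribution over CGI relations or genomic features
against the QC-passing background with a χ² goodness-of-fit test,
dropping empty background categories with a warning.

## 6. Regions

**DMRs.** The published criteria — more than seven DMPs ("≥ 8"), length
over 50 bp (span > 50), 1,000 bp minimum separation — are implemented as
fixed-gap chaining: sort DMPs per chromosome, break chains at gaps ≥ 1 kb,
keep chains meeting both thresholds. The variable-radius machinery of the
tool named in the source is intentionally replaced: the criteria, not the
algorithm internals, are the contract, and chaining is exhaustively
checked against a brute-force enumeration oracle in the tests.

**CNAs.** Per case sample: log2 total intensity over the per-probe
control median, median-centred per sample (making calls invariant to any
global rescaling of one sample's intensities), smoothed with a 50-probe
running median; maximal same-sign runs with |ratio| ≥ 0.2 become
segments, bridging sub-threshold gaps of ≤ 2 probes. Two additions
beyond the stated 0.2 threshold are ours: the running median (robust to
single-probe outliers) and a 10-probe minimum segment size, which
suppresses smoothing edge artifacts at chromosome ends. Segment means are
computed on the smoothed ratio so every emitted segment genuinely
satisfies the threshold. Both per-case segments and a cohort recurrence
summary (fraction of cases carrying an overlapping same-sign call) are
emitted, because the source leaves the per-case/cohort unit ambiguous.

## 7. Expression

The NB Wald path is a deliberate simplification of the full DESeq2
machinery: median-of-ratios size factors (geometric-mean-1 normalized,
upper-quartile fallback when no gene is all-nonzero), per-gene
method-of-moments dispersions floored at 1e−8 and shrunk halfway on the
log scale toward a fitted mean–dispersion trend, a log-link NB GLM with
offsets solved by IRLS, and a Wald z on the group coefficient. Cox–Reid
MAP dispersions, LFC shrinkage, outlier replacement and independent
filtering are all omitted — downstream, only the |log2FC| > 1 & q < 0.05
decision surface is consumed, and the simplified path is calibrated (null
type-I error checked in [0.03, 0.07]) and accurate (log2FC recovered
within ±0.5 in ≥ 90% of seeded replicates) by the acceptance suite.
Samples under 100,000 total reads are dropped first; the boundary is
strict "less than".

## 8. Integration

A replicated DMP is a probe that is a DMP in both cohorts with the same
Δβ sign; a `sign_only` flag relaxes the second cohort's DMP requirement
to sign agreement, since the source's wording leaves that open. A DMEG is
a DEG covered by ≥ 1 replicated DMP. Direction classes are anchored to
the concrete sign patterns reported for the two headline gene classes —
"83-type" (expression up, all promoter and body DMPs hypomethylated) and
"9-type" (expression down, promoter hyper, body hypo) — because the
source's prose about "same/inverse direction" is internally inconsistent
with its own examples; the decision table, not the labels, is the
contract. Mixed signs within a region render a gene unclassified rather
than guessing. Gene-set over-representation is a plain upper-tail
hypergeometric test on user-supplied GMT files, BH-adjusted; no GO DAG or
pathway topology.

## 9. Subtypes and B-cell differentiation

The subtype classifier is an RBF-kernel soft-margin SVM (C = 10,
γ = 0.01) over exactly five CpGs, trained one-vs-one with a deterministic
SMO solver (second working index by maximal |E_i − E_j|, no
randomization, so training is reproducible). The published reference
panel is controlled-access, so the module accepts any labelled 5-feature
matrix and the tests train on synthetic clusters; reproducing the
published 24/16/8 split is explicitly not a target. Features default to
the beta scale (an `--scale m` style switch exists) because the source
model's preprocessing is unspecified.

B-cell-differentiation CpGs come from four pairwise contrasts (each
sorted subtype vs the CD19+ mixture) with the standard DMP criteria and
no covariates — n = 3 per subtype makes covariate adjustment
rank-fragile. Their union is subtracted from the background and the
case–control screen re-run; the fraction of original DMPs lost to the
subtraction is reported.

## 10. The synthetic world

The generator emits what the analysis assumes, with every injection
recorded in a ledger:

* **Baselines**: a three-component Beta mixture per probe — low mode
  Beta(2,18), high mode Beta(18,2), intermediate Beta(4,4) at weight
  0.25 — with the low/high split driven by CGI context (islands 85% low,
  open sea 15%). The intermediate component exists because real arrays
  have substantial partially-methylated mass; without it the density
  valley is empty and quantile normalization misbehaves. Baseline means
  are bounded to [0.01, 0.99], as the +100 intensity offset bounds real
  betas.
* **Noise**: N(0, 0.5) per call on the M scale, plus additive M-scale
  batch offsets (default 0.5 between consecutive batches).
* **Case effects**: a fraction (default 5%) of clean autosomal probes,
  90% hypomethylation on well-methylated body/open-sea probes
  (β baseline ∈ [0.55, 0.97]), 10% hypermethylation on unmethylated
  island/promoter probes (∈ [0.03, 0.35]) — the canonical tumour
  patterns, and the headroom guarantees the ledger invariant that
  injected effects stay inside [0,1]. Effects are added on the beta
  scale after noise, so the ledgered Δβ is exactly the expected group
  difference. MBL samples receive the effect attenuated by 0.8 — the
  source describes MBL only as co-clustering with CLL, so intermediacy
  is a modelling choice.
* **Structure for each downstream stage**: island-dense probe spacing
  and ten injected ≥10-probe effect runs (DMRs); lognormal total
  intensities split by beta and scaled by segment dosages, 0.7 loss /
  1.3 gain (CNAs); a +0.25 female offset on X probes (sex check); five
  override probes with subtype-specific centres 0.15/0.5/0.85 (the SVM);
  200 subtype-differential probes at Δβ = 0.3 between n-CLL and m-CLL;
  300 per-subtype B-cell probes at |Δβ| = 0.5 (differentiation effects
  are large in reality), drawn 92% from a supplied pool so the pipeline
  reproduces the heavy overlap between B-cell and case–control CpGs;
  NB counts with lognormal baselines, lognormal size factors and
  ledger-coupled signs (83-type +2.5, 9-type −2.5 log2FC; default
  15 and 9 genes — the published class sizes do not scale to desk-sized
  data, so the 9 is kept and the 83 scaled down).
* **Replication cohorts** reuse a ledger's injections with fresh noise
  and baselines (`reuse_ledger=`), emulating independent cohorts sharing
  biology.

What it does **not** emulate: dye chemistry and probe-type intensity
bias, LD/SNP structure, cell-composition mixtures, count outliers,
library-preparation batch effects in RNA-seq, and any spatial
autocorrelation beyond the injected runs. A green test therefore
establishes that the *decision rules* behave as specified on data with
the assumed statistical structure — not that the pipeline would
reproduce any particular study's counts on real arrays.

## 11. Numerical choices and degenerate inputs

ε = 0.001 for the logit clip; BH arithmetic matched bit-for-bit to the
reference step-up; zero-variance probes p = 1; NB coefficients capped at
|β| ≤ 30 with fitted means floored at 1e−8 (genes with a zero group mean
get their log2FC from those offset-adjusted fitted means, never raw
ratios); SMO tolerance 1e−4 with margin-based tie-breaks in voting;
2-means in the sex check seeded at the extremes of the first MDS
coordinate (deterministic); empty DMP sets error in tabulation and
return empty data frames in region calling; configuration errors are
aggregated and reported together, with near-miss key suggestions.

## 12. Known limitations

Attenuation of global differences by quantile normalization (section 3);
parametric-only ComBat; no moderated-F or robust regression options; the
NB path's simplified dispersion estimation is slightly liberal at very
small n (its calibration window is [0.03, 0.07], not nominal); DMR
calling ignores probe density beyond the gap rule; CNA calling has no
purity or allele-specific model; the SVM has no probability calibration.
These are scope decisions, not oversights: each matches what the
implemented decision rules actually consume.
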