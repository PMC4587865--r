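---
title: "Methods: promoter hypermethylation biomarker discovery and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter hypermethylation biomarker discovery and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`methmark` implements the complete analysis chain behind a promoter
CpG-island hypermethylation biomarker study in cancer: a demethylating-drug
reactivation screen, promoter CpG-island screening, bisulfite
clone-sequencing quantification, array-cohort methylation scoring with a
diagnostic ROC, and a relapse-free-survival cutoff scan. Every stage is
driven either by user data in plain text formats or by the package's
synthetic-data generators, which emulate the statistical structure of each
input with known ground truth. This vignette documents the models, the
tunable parameters, the numerical choices, and what the synthetic data can
and cannot establish.

## 1. The reactivation screen

Genes silenced by promoter methylation in cancer cells are expected to
re-express after treatment with a demethylating agent such as
5-aza-2'-deoxycytidine (AZA), in cancer lines but not in non-tumorigenic
(NTB) lines whose promoters were never methylated. The screen consumes an
already-normalized log2 expression matrix (probes x samples) with
per-sample cell line / class / treatment / replicate annotations.

**Differential response.** Within each cell line, the log2 fold change is
`mean(drug) - mean(vehicle)` and significance comes from a
shrinkage-variance t: each probe's pooled variance \(s_g^2\) (df
\(d = n_1 + n_2 - 2\)) is moderated toward the across-probe mean variance
\(s_0^2\),

\[\tilde s_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d},\qquad
  t_g = \frac{\bar x_1 - \bar x_2}{\tilde s_g \sqrt{1/n_1 + 1/n_2}},\]

referred to a t distribution with \(d_0 + d\) df. This is a deliberate,
simple stand-in for the random-variance class-comparison models used by
microarray suites for very small replicate numbers; the prior df \(d_0\)
defaults to 10 and is configurable, and a plain Welch t is available
(`method = "welch"`). With three replicates per arm the moderated test is
mildly conservative under the null (about 3% of probes at p <= 0.05),
which we prefer to anti-conservative behaviour in a discovery screen. With
many replicates it converges to the Welch t (tested).

**Candidate selection.** A probe is a candidate when it passes
|fold| >= fold_min (default 1.5, linear scale) *and* p <= p_max (default
0.05) in **every** designated cancer line with a consistent direction, and
does **not** pass in the NTB line. Non-response in the NTB line is defined
as failing *either* criterion. The alternative — requiring the NTB line to
fail both — would discard probes weakly but non-significantly perturbed in
the control line, which is exactly the borderline class a discovery screen
wants to keep. Both thresholds are arguments, and selection is monotone:
relaxing either threshold never shrinks the cancer-side pass set.

**Cross-dataset validation.** Candidates are checked in an independent
panel of paired drug/vehicle cell lines with a per-probe paired t across
lines (>= 3 pairs required for the t to have degrees of freedom); the
summary is the fraction of candidates with p < 0.05 and a positive mean
difference.

## 2. Promoter CpG islands and the analysis region

Islands are detected with the classic sliding-window criteria (window 200,
step 1, GC >= 0.5, observed/expected CpG >= 0.6 with
\(\mathrm{Exp} = n_C n_G / L\), merged runs >= 200 bases). The vendor tool
used in the kind of study this package reproduces does not publish its
criteria, so the Gardiner-Garden–Frommer defaults are used and every
threshold is an argument.

**Coordinate convention.** TSS-relative positions are plain integers:
position 0 *is* the TSS base, negative positions are upstream, and
`extract_region(seq, tss, a, b)` returns the inclusive span `a..b` of
length `b - a + 1`. A region of −290..+117 therefore spans 408 bases. This
is stated prominently because promoter papers rarely define their
convention; all on-disk interval output (BED) is 0-based half-open.

## 3. Bisulfite clone quantification

Bisulfite treatment converts unmethylated cytosine to uracil (read as T)
while methylated CpG cytosines stay C. Each sequenced clone is one
molecule; the study design sequences five clones per sample.

**Alignment.** Clones are aligned globally against the *unconverted*
reference with bisulfite-aware scoring: reference C vs clone T scores as a
match (conversion) while the reverse orientation does not. Scoring is
match +1, mismatch −1, gap open −2, gap extend −0.5 per base. The aligner
is built on `Biostrings::pairwiseAlignment` with an asymmetric substitution
matrix; its scores are verified in the tests against an independent plain-R
Gotoh dynamic program. At each reference CpG the aligned clone base gives
the call — C methylated, T unmethylated, anything else (gap, substitution)
missing. The conversion rate is the fraction of aligned non-CpG reference
cytosines read as T; alignment identity below a hard floor of 0.6 flags the
clone as non-specific.

**QC.** Clones are excluded when conversion < 0.95 or identity < 0.9
(common clone-QC practice; both configurable). Filtering never alters the
calls of retained clones, and a sample with no surviving clone is flagged
invalid.

**Quantification.** Per-CpG fractions are computed over non-missing calls;
the per-sample percent pools *all* non-missing calls
(methylated / (methylated + unmethylated) x 100). When nothing is missing
this equals the mean of the per-clone percents — the conventional "average
of five clones" — and it degrades gracefully when calls are missing.

**Tests.** Group comparisons of per-sample percents use the Mann–Whitney
test; tumor/normal *pairs* are tested with the Wilcoxon signed-rank test
over their per-CpG fractions, because the CpGs are the only replicated unit
within a pair (per-clone percents would confound molecule sampling with the
pair effect). Zero differences are dropped; an all-zero pair is degenerate
and reported as p = 1 with a warning. Methylation–expression association
uses Spearman rank correlation.

The signed-rank test computes its exact null distribution by convolution
over (mid)ranks for n <= 25 — including tied absolute differences, where
the classic exact algorithm refuses — so a uniform shift across a 22-CpG
grid has the exact two-sided p \(2/2^{22}\). Mann–Whitney p-values are
exact for tie-free groups up to n = 20, and Spearman p-values exact for
n <= 9; all exact paths are tested against full-enumeration oracles.

## 4. Array-cohort scoring (NAMS)

Cohorts carry two methylation probes per gene on a 0–100 raw score scale.
The two probes are averaged per sample (their Spearman correlation is
reported as a concordance diagnostic), and averages are normalized to
**NAMS**: per dataset, the minimum maps to 0 and the maximum to 100.
"Fit into a sigmoidal curve" — the phrase normalizations of this kind are
described with — is under-specified, so two readings are implemented:

* `linear` (default): plain affine min–max rescale;
* `logistic`: scores are squashed through a logistic centred on the dataset
  mean with steepness `k` (default 1) in units of the score SD, then
  re-anchored so the endpoints hit exactly 0/100.

Both are strictly rank-preserving; the logistic mode compresses the
extremes relative to the middle. Multi-dataset tables are normalized per
dataset and then pooled, which is the correct behaviour when the datasets'
raw distributions are comparable but not identical.

**Calling.** The normal reference is the mean NAMS of the normal group. A
tumor is hypermethylated when its NAMS exceeds the reference by *strictly
more than* the margin (default 30 NAMS units), hypomethylated below
−margin, neutral otherwise; frequencies are reported overall and per grade.
The strict inequality matches the ">30 higher" phrasing such calls are
defined with, and boundary behaviour is tested at margin ± 1e-9.

**ROC.** The empirical ROC sweeps midpoint thresholds between consecutive
observed scores (tumor call: score >= threshold). AUC is the trapezoid
area, numerically identical to the tie-adjusted Mann–Whitney
\(U/(n_1 n_2)\) (tested against pair counting on random cohorts, and
cross-checked against pROC). The AUC CI is a stratified bootstrap (default
2000 replicates, seeded). The default operating point maximizes
sensitivity subject to 100% specificity — the natural rule for a rule-in
diagnostic marker, and the rule that reproduces a "100% specificity"
headline; Youden's J is available.

## 5. Survival and the cutoff scan

Kaplan–Meier curves come from `survival::survfit` (the package's wrapper
returns a plain data frame and is tested against hand product-limit
tables). The two-group test is the **Gehan–Breslow–Wilcoxon** statistic:
the log-rank observed-minus-expected at each event time weighted by the
total number at risk,

\[U = \sum_j n_j \left(d_{1j} - d_j \frac{n_{1j}}{n_j}\right),\qquad
 V = \sum_j \frac{d_j (n_j - d_j)\, n_{1j} n_{2j}}{n_j - 1},\]

with \(U^2/V \sim \chi^2_1\). This weighting emphasizes early differences.
It is written in the package because `survival::survdiff(rho = 1)` is the
Peto–Peto variant (weights \(\hat S(t)\)), not the at-risk-weighted Gehan
statistic. A seeded label-permutation p-value is available and agrees with
the asymptotic p at n = 100 within Monte-Carlo error (tested). Event-time
ties follow the standard Breslow convention of the formula above.

**Cutoff scan.** Follow-up is truncated at the horizon (default 10 years;
later events become censorings at the horizon). Each candidate cutoff `c`
in the grid (default 60, 65, 70, 75, 80, 85, 90) splits patients into
NAMS >= c vs < c; the best cutoff is the one with the smallest GBW p.
Because this is a minimum over several tests, the scan's output carries an
explicit multiplicity note — the selected p-value is optimistic and should
be labelled as such wherever it is reported. Cutoffs that make a group
empty are skipped with a warning.

## 6. What the synthetic data emulate — and what they do not

* `simulate_expression_screen`: per-probe Gaussian log2 baselines
  (mean 7, SD 1.5) with i.i.d. Gaussian noise (SD 0.3 by default); silenced
  probes sit `fold_induced` (default 2 log2 units) below baseline in cancer
  lines and regain exactly that amount under drug. Real arrays have
  correlated probes, heteroscedastic intensity-dependent noise and
  secondary (indirect) drug responses; none of these are modelled, so the
  screen's measured recovery (>= 90% at the default design of 1000 probes /
  50 silenced / 3 replicates) is an upper bound on real-data behaviour.
* `simulate_bisulfite_clones`: per-CpG Bernoulli methylation, uniform
  conversion failures restricted to non-CpG cytosines, uniform substitution
  errors. There is no co-methylation correlation along the molecule, no
  PCR/cloning bias, and no chromatogram-level noise.
* `simulate_cohort`: latent per-sample score from a truncated-normal
  mixture on the 0–100 scale — tumors bimodal (means 75/45, SDs 8, weights
  0.8/0.2), normals unimodal (mean 40, SD 8) — with two probe scores =
  latent + independent Gaussian noise (SD 10, giving inter-probe Spearman
  ≈ 0.7, the concordance regime such probe pairs show). Survival is
  exponential with a multiplicative hazard (default ratio 3) for the
  high-methylation group, exponential censoring calibrated to a target
  censoring fraction, and administrative censoring at 15 years. The hazard
  group is either the top tumor mixture component or, for cutoff-recovery
  experiments, a step planted exactly at NAMS 80. A real cohort's hazards
  are neither exponential nor single-step, so cutoff recovery measures the
  scan's statistical behaviour, not clinical truth.

All generators take a `seed` and are byte-reproducible.

## 7. Problem sizes and numerical choices

The test-suite and acceptance experiments run at the study's design scale:
1000-probe screens with 3 replicates (10 seeds), 408-base regions with
>= 22 CpGs and 5 clones per sample (hundreds of clones for binomial QC
checks), cohorts of 338 tumors / 33 normals, 2000 bootstrap and permutation
replicates, and 50-seed cutoff-scan recovery runs — chosen so the whole
suite completes in well under a minute of compute per stage while keeping
Monte-Carlo error far below the tested tolerances.

Numerical details worth knowing:

* ROC thresholds are midpoints, so the operating threshold on perfectly
  separated groups falls strictly between them.
* The exact signed-rank convolution doubles midranks to keep integer
  support; two-sided p is `2 * min(P(V <= v), P(V >= v))` capped at 1,
  matching the classic exact convention when ties are absent.
* `nams_normalize` refuses constant score vectors (the rescale is
  undefined) and `relative_expression` enforces primer efficiencies in
  (1, 2.2] and flags replicate Ct spreads above 0.5 cycles.
* Alignment identity counts bisulfite-aware matches over all alignment
  columns, so end gaps reduce identity — intentionally, since truncated
  clones deserve QC attention.

## 8. Known limitations

* The shrinkage t is a simple fixed-prior random-variance model; on real
  array data its p-values will differ in detail from those of
  empirical-Bayes microarray suites even though the ranking is very
  similar.
* The NAMS "sigmoidal" reading is ambiguous; results that depend on the
  distinction should be run in both modes (the linear mode is the default
  everywhere).
* The cutoff scan deliberately reproduces an uncorrected minimum-p
  selection and must be interpreted with its multiplicity note.
* `qPCR` quantification assumes efficiency-corrected quantities
  \(E^{-Ct}\); it does not estimate efficiencies from dilution series.
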