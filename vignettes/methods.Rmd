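---
title: "Methods: models, parameters and design choices in sensitizeR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in sensitizeR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`sensitizeR` analyzes two complementary experiments that together nominate
drug-sensitizer targets in BRAF-mutant melanoma: a pooled kinome shRNA
dropout screen under BRAF- and ERK-inhibitor treatment, and a triplex
isotope-label (phospho)proteomic time course of the drug response. This
vignette documents the statistical models, every tunable parameter that
matters, what the synthetic-data generators do and do not emulate, the
numerical choices, and known limitations.

## 1. Screen arm

### Read structure and quantification

Amplicon reads have a fixed layout chosen by this package (the wet-lab
primer design constrains but does not fully determine the sequenced read):
bases 1–6 carry the sample index, bases 7–27 the hairpin's 21-nt sense
target sequence, and the remainder a constant region. Demultiplexing is
exact on the 6-bp index by default — six bases give little room for error
correction — with an optional 1-mismatch mode; the synthetic generator
emits indices with pairwise Hamming distance ≥ 3 so that 1-mismatch
assignment can never be ambiguous. Hairpin counting compares the 21-mer at
the fixed offset against the library at 0 (default) or 1 substitution; a
read increments a hairpin only when that hairpin is the *unique* match,
and ambiguous or unmatched reads are discarded and tallied, never
arbitrarily assigned. A `scan` fallback searches all offsets for libraries
with shifted amplicon structure. Conservation (assigned + unassigned =
input; counted + discarded = assigned) is asserted in the tests.

### Normalization, dispersion, test

Counts are modeled negative-binomially with `Var = mu + alpha * mu^2`.

* **Size factors** use the median-of-ratios estimator restricted to
  hairpins observed in every sample; the median is taken on the linear
  ratio scale (a log-scale median interpolates geometrically for even
  counts and drifts from the definition by ~1e-4). A `pseudo_reference`
  fallback handles matrices where no hairpin is observed everywhere.
* **Dispersions** are method-of-moments per hairpin on normalized counts,
  `alpha_i = (v_i - mu_i)/mu_i^2` with `v_i` the pooled within-group
  variance, clamped at a floor of 1e-8. A parametric trend
  `alpha(mu) = a0 + a1/mu` is fit by ordinary least squares on the raw
  (unclamped) values — the parametric form avoids any smoothing-bandwidth
  choice and is fully deterministic — and the working dispersion is the
  conservative `max(raw, trend, floor)`. The sharing mode is configurable
  to `fit-only`; `max` is the default because the upstream method's
  conservative default is the safer choice for hit calling and the
  original analysis does not state its setting.
* **The exact test** conditions on the pooled count of the two groups.
  Group sums are modeled NB with mean `q * sum(s_j)` and variance
  `sum(q s_j + alpha q^2 s_j^2)` under the common-mean null, and the
  two-sided p-value sums the probabilities of all splits no more likely
  than the observed one. For `alpha -> 0` this converges to the
  conditioned binomial (Poisson limit), which the tests verify to 1e-3.
  All-zero hairpins are dropped from testing (never imputed); a
  symmetric-split hairpin gets `p = 1` exactly.

One property stated for this design had to be weakened: p-values of a test
that conditions on the pooled *raw* count cannot be exactly invariant to
rescaling one sample's column (the conditioned-on total changes). What is
exactly invariant — relative size factors and all fold changes — is
asserted at 1e-10.

### Filter cascade and gene hits

Per arm, a hairpin is selected iff day-7 fold change ≤ 0.66 (inclusive:
depletion by at least one third), day-7 raw p < 0.05, and day-4 fold
change < 1 (strict: any enrichment at day 4 disqualifies, suppressing
false positives from early stochastic drift). The p filter uses the raw
p-value — mirroring the published rule — while BH-adjusted values are
always reported alongside. Hairpins missing from the day-4 table fail the
cascade by default (conservative), overridable with
`allow_missing_day4 = TRUE`. A gene is a hit iff ≥ 2 of its hairpins are
selected in *both* arms. Pools are carried as QC metadata only; all pools
are analyzed jointly, matching the single merged hairpin list reported in
practice.

### Evidence integration

The published integration of screen hits with proteomics is narrative;
`integrate_evidence()` formalizes it as a transparent, configurable score:
every dual-screen gene hit starts at 2 (one point per supporting screen),
and each annotated regulator whose proteomic direction is consistent with
increased dependence on the target — an inhibitor of the target
significantly down, or an activator significantly up — adds one point.
The canonical example: Rnd3 (a negative regulator of ROCK1) significantly
down-regulated lifts ROCK1 to score 3.

## 2. Proteome arm

Input is a per-replicate log2-ratio table (M/L = 1 day/control,
H/L = 3 days/control, H/M = 3 days/1 day); a MaxQuant-proteinGroups-like
dialect with linear ratios is converted on load, and reverse/contaminant
rows are removed. One-sample t-tests against 0 (df = n−1) cover the two
against-control contrasts; an equal-variance two-sample t-test covers
3 d vs 1 d (Welch optional; the equal-variance default matches the simpler
published description). Zero-variance rows get p = 1 (mean 0) or p = 0
(mean ≠ 0) and are flagged. `min_replicates` defaults to 3 — the design
has three biological replicates and the published filter demands
consistency across them — with 2 allowed for real-world missingness.

Significance = raw p < 0.05 AND sign-preserving fold change ≥ 1.5 or
≤ −1.5 (`|mean log2| >= log2(1.5)`, inclusive). No multiple-testing
correction is applied in this filter (the published cutoff is on raw p);
BH values are reported alongside. Phosphosites additionally require
localization probability ≥ 0.75 (inclusive). Phospho ratios are *not*
normalized to protein-level changes — the upstream analysis does not do
so; a phosphosite change can therefore reflect protein abundance rather
than stoichiometry, a documented caveat.

## 3. Enrichment

Exact upper-tail hypergeometric over-representation per term against a
caller-supplied background, BH step-up across tested terms, flag at
adjusted p < 0.05. Term annotations are intersected with the background
first; target genes not annotated to any term still count in `n` and `N`
(the behavior of enrichment tools given an explicit background). Only
over-representation is tested; no GO DAG propagation — the term map is
taken as given.

## 4. Viability and dose-response

Readings are normalized linearly between the untreated control (100%) and
a kill control (0%); values outside [−20, 120]% are flagged but kept. The
4PL model `v(c) = bottom + (top−bottom)/(1+(c/ic50)^hill)` is fit by
least squares over a deterministic multi-start grid (hill ∈ {0.5, 1, 2} ×
ic50 at the 25/50/75% dose quantiles) refined by Nelder-Mead on
`(top, bottom, log ic50, log hill)`; the best-so-far objective is
monotone across starts by construction. ICx is defined on the viability
scale — IC20 is the dose giving 80% residual viability (20% inhibition) —
and solved analytically; it is NA when the requested level lies outside
the fitted asymptotes. Fits explaining < 30% of variance raise a
degenerate-fit error rather than returning meaningless ICx values.

A note on precision: with 3-percentage-point Gaussian noise on a 12-dose
triplicate plate, a truth-started reference optimizer places only ~70% of
ic50 estimates within 5% of the truth — that is the information limit of
the design, not a fitting deficiency. The tests therefore check that the
multi-start fit attains the reference optimizer's least-squares optimum
per dataset and meet that oracle-derived recovery rate, rather than an
optimistic nominal one.

## 5. Synthetic data: the stated world

`simulate_screen()` emulates the screen design: ~500 genes × 8 hairpins in
4 pools by default (the kinome library scale), three biological
replicates, a day-0 reference plus DMSO and treated samples at days 4 and
7 per arm. Counts are NB with `mu = depth * abundance * fold change *
size factor`; defaults: `depth_mean = 300`, `dispersion = 0.05` (typical
for pooled screens), per-hairpin abundance skew log-normal with
`sdlog = 0.5` (pool representation skew is not published; this is a
deliberate, flagged choice), per-sample depth multipliers log-uniform in
[0.5, 2]. Planted sensitizers apply a treated-vs-DMSO fold change to all
hairpins of a gene by default (`frac_hairpins_affected` exercises the
≥2-hairpin rule), in both arms; planted essentials deplete all day > 0
samples versus the reference. Where a planted day-4 fold change is needed
but unstated (recovery simulations), 0.7 is used: sensitizer depletion is
partial at day 4 and must be < 1 to clear the cascade.

`simulate_proteome()` draws per-replicate log2 ratios Normal around
planted per-protein effects; H/M has independent noise around the
difference of the 3 d and 1 d effects (measured, not derived — ratios in
real triplex data are quantified separately). Defaults: 3,800 proteins
(the quantified scale), 15% regulated (≈ the 588/3,800 unique-regulated
fraction), |log2 FC| in [log2 1.5, 2], `noise_sd = 0.2`. Localization
probabilities come from a Beta mixture (80% well-localized Beta(20, 1),
20% Beta(2, 2)) whose mass above 0.75 is ≈ 0.83, matching the reported
~80% of sites at ≥ 0.75; the closed-form mass is the oracle for
retention tests.

What the generators do **not** emulate — and hence what a green test does
not establish: PCR/sequencing biases beyond uniform substitution errors,
hairpin-specific knockdown efficacy differences, off-target effects,
missing values structured by protein abundance, ratio compression in
isotope labeling, and peptide-level quantification. Recovery results on
synthetic data bound what the pipeline can do when its model is correct;
they do not certify performance on real screens.

## 6. Determinism and budgets

Every generator takes an explicit seed and restores RNG state
(`withr::with_seed`); identical seeds give bit-identical outputs, and
pipeline reruns produce byte-identical TSVs (asserted in tests). Result
tables break ties deterministically (p, then id). Simulation-heavy checks
in the test suite are scaled to run in minutes on one CPU; where a check
is a scaled-down version of a larger stated simulation, the test says so
in a comment and keeps the threshold unchanged.

## 7. Known limitations

* The published 59-hairpin overlap and 5-gene hit list are not
  recomputable here: the raw screen reads were never deposited and the
  per-screen hairpin lists live in an external supplementary table.
  The package reproduces the published per-hairpin worked example (the
  ROCK1 rows) and substitutes property-based acceptance for the rest.
* The exact NB test enumerates up to the pooled count; for very deep
  screens (pooled counts ≫ 1e5 per hairpin) a normal approximation would
  be preferable. At the depths used here enumeration is fast and exact.
* The evidence score is a formalization of a narrative procedure; its
  weights (1 point per consistent regulator) are a convention, exposed as
  data rather than hard-coded biology.
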