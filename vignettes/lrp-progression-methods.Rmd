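---
title: "Classifying Lewy-related pathology progression patterns: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying Lewy-related pathology progression patterns: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrprog)
library(dplyr)
```

## The scientific setting

Lewy-related pathology (LRP) — α-synuclein-positive Lewy bodies and
neurites — is graded at autopsy on a semiquantitative 0–4 scale (none,
mild, moderate, severe, very severe) across CNS regions. `lrprog` works on a
fixed panel of twelve regions in caudo-rostral order: sacral and thoracic
spinal cord, medulla, pons, substantia nigra, amygdala, hippocampal CA2,
transentorhinal cortex, cingulate, temporal, frontal and parietal cortex.
The regions partition into three anatomical blocks — caudal (1–5), limbic
(6–9), neocortical (10–12) — and the package's central question is which
block dominates a subject's severity profile: dominance of the caudal block
marks the classical caudo-rostral progression, dominance of the limbic
block marks the AD-associated amygdala-based progression.

The spinal cord is originally scored at four sub-sites (sacral posterior
root entry, sacral anterior horn, central canal, thoracic intermediolateral
horn) but analysed as two regions. `aggregate_spinal_subsites()` takes the
maximum over the three sacral sub-sites and the thoracic sub-site as-is.
The maximum was chosen over the mean because downstream analyses of spinal
involvement are presence/severity oriented: any detectable sub-site
pathology should be visible in the regional score, and a mean over
differently vulnerable sub-sites would dilute it.

## The progression rule engine

For a profile $x = (x_1, \dots, x_{12})$, let $m_C$ and $m_L$ be the mean
scores of the caudal and limbic blocks over their non-missing regions.
`classify_progression()` is a total function:

1. all observed scores zero → `none`;
2. all observed scores equal 4 → `undetermined` (a saturated profile
   carries no directional information);
3. $m_L > m_C$ → `amygdala_based`; $m_C > m_L$ → `caudo_rostral`;
4. on an exact tie, `amygdala_based` iff the amygdala score strictly
   exceeds the medulla score, else `caudo_rostral`.

Block *means* rather than maxima drive the decision because the pattern
definitions concern the whole density/distribution profile, not a single
peak region; a mean over four or five regions is the simplest statistic that
uses every score. The tie-break falls back to the two index regions of the
two patterns (medulla and amygdala) and defaults to caudo-rostral, the
majority pattern in elderly populations and the generally accepted default
concept of LRP spread. Missing regions are skipped, never imputed — imputing
zeros would bias block means downward asymmetrically when block sizes
differ. A block with no observed region is excluded; if a comparator block
is entirely missing the decision degrades gracefully to the
medulla-versus-amygdala comparison. The cingulate cortex is counted in the
limbic block: the pattern definition for amygdala-based progression speaks
of "amygdala or limbic area", and limbic-system usage in the DLB literature
includes the cingulate; the choice is fixed in `lrp_regions()`.

## The DLB Consortium typing engine

The consensus typing is reconstructed as an explicit precedence list over
named thresholds (`lrp_rules()`; paucity ≤ 1, neocortical ≥ 2, substantia
nigra ≥ 1), evaluated in order:

1. `none` — no LRP anywhere;
2. `non_classifiable` — LRP confined to spinal cord, medulla and/or pons
   with no nigral, limbic or neocortical involvement. These profiles fall
   outside the consensus types; they plausibly represent the earliest stage
   of caudo-rostral progression, and the progression engine indeed labels
   every such profile `caudo_rostral`;
3. `amygdala_predominant` — amygdala positive and strictly above every
   other region, all other regions at most mild (score ≤ 1);
4. `diffuse_neocortical` — any neocortical region at moderate or worse;
5. `brainstem` — nigral involvement with at most mild limbic and no
   neocortical LRP. Requiring the substantia nigra here is deliberate:
   medulla/pons/spinal-only profiles must remain non-classifiable rather
   than satisfy the brainstem type;
6. `limbic` — everything else.

The exact consensus wording leaves threshold choices open; this rule table
is therefore a documented, config-overridable realization whose structural
behaviour is pinned by tests: on the exhaustive sub-grid of all $3^{12}$
profiles with scores in $\{0, 2, 4\}$, both engines are total, every
brainstem-type profile classifies caudo-rostral unless its amygdala
outscores its medulla, and every amygdala-predominant profile classifies
amygdala-based — the qualitative anatomy of the published
type-by-pattern cross-table.

## The synthetic cohort generator

The generator emulates a population-based 85+ autopsy series of 304
subjects. Its defaults are the study conditions, not free dials:

- **Pattern mixture**: none 0.60, caudo-rostral 0.27, amygdala-based 0.13
  (the published 59/27/13% composition, with the 1% mass of the single
  pattern-undetermined subject folded into the negative class; a saturated
  all-4 subject can be injected explicitly via `n_saturated`).
- **Archetype gradients**: per-region weights in [0, 1]
  (`archetype_weights()`), non-increasing along the axis for the
  caudo-rostral archetype (with the medulla at the joint maximum, matching
  its rank as the most frequently involved region) and unimodal with the
  amygdala peak for the amygdala-based archetype. The weights qualitatively
  reproduce the published per-region involvement ordering; per-region mean
  severities were not published, so the calibration is qualitative by
  design and the vectors are config-overridable.
- **Severity model**: a subject at latent extent $s \in (0,1]$ scores
  $\mathrm{clamp}(\mathrm{round}(4sw_r + \varepsilon), 0, 4)$ in region
  $r$, $\varepsilon \sim N(0, \sigma)$ with $\sigma = 0.3$ by default.
  Rounding is half-away-from-zero, avoiding the platform-dependent
  treatment of exact .5 offsets under banker's rounding. $s$ is uniform on
  (0.2, 1]: the paper gives no staging distribution, a uniform spread
  exercises every severity stage, and below $s \approx 0.2$ every weighted
  score rounds to zero, which would silently convert pattern subjects into
  LRP-negative ones.
- **Covariates**: per-pattern multinomials taken from the published
  group-wise tables (e.g. dementia in 92.5% of amygdala-based vs 63% of
  caudo-rostral subjects; APOE ε4 carriage 63% vs 31%; Braak V–VI 63% vs
  16%), age at death Normal(92.4, 3.7) truncated at 85, dementia onset
  Normal around 85.3 (amygdala-based), 88.5 (caudo-rostral) or 87.2
  (no LRP) years with SD 4, capped at the age at death. Braak and CERAD are
  drawn in the three published coarse bins; the concrete stage within a bin
  (III vs IV, moderate vs frequent) is uniform because no finer marginal
  was published.

What the generator does *not* emulate: longitudinal spread (profiles are
cross-sectional snapshots), spatial correlation of scores beyond the
archetype mean (noise is independent across regions), inter-rater scoring
variability structure, and co-pathologies (the single MSA-type subject of
the source series). Passing recovery and concordance tests on this
generator therefore demonstrates that the analysis chain is correct and
well-calibrated under the study's published composition — not that the rule
engine would reach the same accuracy on histological reality.

## K-means validation

`fit_lrp_kmeans()` clusters LRP-positive subjects' raw profiles under
unweighted Euclidean distance. No standardization is applied: all twelve
coordinates already share the 0–4 scale, and scaling by per-region variance
would inflate the nearly-constant cortical regions. Initialization is
k-means++ with 25 restarts kept to the best within-cluster sum of squares
(WSS); Lloyd iterations run to a fixpoint or 300 rounds; everything is
deterministic given a seed. The published analysis names only "K-means" and
the "elbow method", so both are pinned concretely for reproducibility: the
elbow is the $k$ maximizing the perpendicular distance from $(k, WSS_k)$ to
the chord joining the curve's endpoints (a Kneedle-style rule), ties to the
smaller $k$. Only LRP-positive subjects are clustered — an all-zero majority
class would dominate the objective and always claim its own cluster.

Cluster solutions are made comparable to the rule labels automatically:
each centroid is rounded per coordinate to the nearest integer score and
passed through `classify_progression()` (`map_cluster_to_pattern()`), an
algorithmic stand-in for the by-eye reading of cluster mean profiles.
`concordance()` is then the fraction of subjects whose cluster's mapped
pattern equals their own rule label; subjects in a saturated
(`undetermined`-mapped) cluster count as concordant only if their rule
label is also undetermined. On the default synthetic cohort the chain
(elbow-selected $k$, mapping, concordance) agrees with the rule engine for
well over 85% of subjects, the analogue of the 90% concordance reported on
the real data; on noiseless archetype data at full extent it is exact.

## Exact tests

`fisher_exact_2x2()` and `fisher_exact_rxc()` implement the two-sided
Fisher exact test under the probability-mass rule: the p-value is the total
(multivariate) hypergeometric probability of all margin-preserving tables
no more probable than the observed one. This is the convention of
mainstream implementations; the source publication does not state its
convention, and the rule reproduces all thirteen published p-values to
their printed precision. Probability ties are compared with a relative
tolerance of $10^{-12}$ so that masses that are mathematically equal but
computed through different factorial groupings are not split by
floating-point ordering. The r×c enumeration is exact up to a configurable
cap (default $10^8$ tables; the 3×2 tables of the study enumerate a few
thousand); beyond the cap a seeded Monte-Carlo estimate over
margin-preserving tables (Patefield draws) is available. Degenerate input
is well-defined: all-zero rows or columns are dropped (they carry
probability one of themselves), and margins admitting a single table give
$p = 1$.

The 2×2 route is verified against an independent brute-force oracle for
every table with total ≤ 40, and the r×c route is required to agree with
the 2×2 route on 2×2 input to $10^{-12}$. Braak and CERAD comparisons run
on the full 3-level tables by default rather than severe-vs-rest
dichotomies: the published non-significant p-values (0.2306, 0.7622) are
reproduced exactly by the 3-level tables and not by the dichotomized
variants of the same counts. The spinal-cord association is modelled as
presence/absence of spinal LRP, the only table form consistent with the
published group counts.

`two_sample_t()` (Welch default) and `group_mean_regression()` (overall F
test of value on group indicators) cover the continuous comparisons. Both
are calibration-tested: at $n = 50$ per arm and $10^4$ null replicates the
empirical type-I error at $\alpha = 0.05$ stays within ±0.01 of nominal.
Zero-variance input to the t test is reported as a flagged degenerate
result rather than an error.

## Problem sizes and numerical choices

The test suite and acceptance script run at deliberately modest sizes
chosen to exercise the statistics without waste: cohorts of 100–500 for
behavioural tests, $10^4$ draws for distributional checks (binomial
sampling error ≈ 0.5 percentage points), the full $3^{12}$ grid for the
classifier invariants, the exhaustive ≤ 40-total sweep for the exact-test
oracle, and $10^4$ replicates for the type-I-error calibration. Scores are
validated as integers 0–4 at every entry point with errors naming the
offending row and column; cohort files are CSV/TSV with the delimiter
auto-detected from the header and the decimal point fixed, so parsing is
deterministic across locales.

## Known limitations

- The DLB typing thresholds are a reconstruction of consensus guidelines
  whose operational details live in unpublished supplementary material;
  they are exposed in `lrp_rules()` precisely because reasonable variants
  exist.
- The elbow rule pins one formalization of an inherently visual criterion;
  the cluster count it selects on real data need not match a by-eye choice
  (on the synthetic cohorts it typically selects 2–4 clusters, driven by
  the two archetypes plus severity strata, whereas the source analysis
  chose nine on real data).
- The progression tie-break (amygdala vs medulla, default caudo-rostral)
  affects only measure-zero boundary profiles under the generator but can
  matter for real ordinal data, where exact block-mean ties occur.
- Fisher enumeration cost grows quickly with table dimensions and totals;
  for large sparse r×c tables use the Monte-Carlo fallback and report its
  seed.
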