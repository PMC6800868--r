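# lrprog

Progression-pattern analysis of Lewy-related pathology (LRP) in autopsy
cohorts.

In population-based neuropathology series, α-synuclein-positive Lewy
pathology is scored semiquantitatively (0 = none … 4 = very severe) in a
fixed set of CNS regions running caudo-rostrally from the sacral spinal cord
to the parietal cortex. Two progression patterns are recognised in the very
elderly: a **caudo-rostral** pattern, with the heaviest pathology in the
spinal cord, medulla and brainstem and decreasing load toward the cortex, and
an AD-associated **amygdala-based** pattern, with the heaviest pathology in
the amygdala and limbic areas and decreasing load toward both the brainstem
and the neocortex. `lrprog` implements the full computational side of such a
study for neuropathologists and biostatisticians:

- **Rule engines.** `classify_progression()` labels each subject's
  twelve-region profile by systematic anatomical scoring: with caudal block
  mean `m_C` (spinal cord–substantia nigra, regions 1–5) and limbic block
  mean `m_L` (amygdala–cingulate, regions 6–9), a profile is amygdala-based
  when `m_L > m_C`, caudo-rostral when `m_C > m_L` (ties resolve by the
  amygdala-vs-medulla single-score comparison), `none` with no LRP, and
  `undetermined` when every region scores 4. `classify_dlb_type()` applies
  the DLB Consortium typing (brainstem, amygdala-predominant, limbic,
  diffuse neocortical, plus non-classifiable for LRP confined to
  medulla/pons/spinal cord) as an explicit precedence rule table with
  overridable thresholds. `classify_nia_ri()` and
  `classify_control_status()` give the neuropathological AD/control calls
  from Braak NFT stage and CERAD score.
- **Unsupervised validation.** `fit_lrp_kmeans()` (Lloyd iterations,
  k-means++ seeding, best-of-n restarts), `wss_curve()` and
  `select_k_elbow()` (maximum distance to the endpoint chord), with
  `map_cluster_to_pattern()` and `concordance()` to compare cluster
  structure against the rule-based labels.
- **Exact association tests.** `fisher_exact_2x2()` and
  `fisher_exact_rxc()` compute two-sided Fisher exact p-values by full
  (multivariate) hypergeometric enumeration under the probability-mass
  rule — `p = Σ P(T)` over all margin-preserving tables `T` with
  `P(T) ≤ P(observed)` — with a seeded Monte-Carlo fallback for infeasible
  tables; plus `two_sample_t()` and `group_mean_regression()`.
- **Synthetic cohorts.** `generate_cohort()` draws seeded cohorts with the
  two archetype gradients, latent disease extent, score noise and
  pattern-conditional covariates (dementia, Braak, CERAD, APOE ε4,
  substantia nigra neuron loss), retaining true pattern labels for
  recovery testing.
- **Embedded published tables.** `lrp_printed_comparisons()` ships the 13
  published contingency tables of a population-based 85+ autopsy series
  (n = 304; 180 LRP-negative, 83 caudo-rostral, 40 amygdala-based, one
  undetermined), and `reproduce_printed_statistics()` recomputes every
  published p-value from them.

## Worked example

```r
library(lrprog)
library(dplyr)

cohort <- generate_cohort(synthetic_config(n_subjects = 304), seed = 1) |>
  classify_cohort()
count(cohort, progression_pattern)
#> # A tibble: 3 × 2
#>   progression_pattern     n
#>   <fct>               <int>
#> 1 none                  192
#> 2 caudo_rostral          77
#> 3 amygdala_based         35
```

About 6 in 10 subjects carry no LRP; among carriers the caudo-rostral
pattern outnumbers the amygdala-based roughly 2:1, as configured from the
published marginals. A single profile classifies directly:

```r
classify_progression(c(0, 0, 1, 0, 1, 4, 2, 3, 2, 1, 1, 0))
#> [1] amygdala_based
```

(limbic block mean 2.75 versus caudal 0.4). The unsupervised chain validates
the rule labels:

```r
pos <- lrp_positive(cohort)
k <- select_k_elbow(wss_curve(pos, k_max = 10, seed = 1))        # 3
fit <- fit_lrp_kmeans(pos, k = k, seed = 1)
concordance(setNames(pos$progression_pattern, pos$subject_id), fit)
#> [1] 0.9910714
```

i.e. 99% of the LRP-positive subjects fall in a cluster whose mean profile
carries their rule-based pattern. And the published statistics recompute
from the embedded tables:

```r
reproduce_printed_statistics()[1:3, 1:4]
#> # A tibble: 3 × 4
#>   comparison_id          computed_p    printed_p agrees_printed
#>   <chr>                       <dbl>        <dbl> <lgl>
#> 1 dementia_amy_vs_cr   0.000448     0.000448     TRUE
#> 2 dementia_amy_vs_none 0.0000180    0.000018     TRUE
#> 3 braak_amy_vs_cr      0.0000000563 0.0000000563 TRUE
```

A thin command-line front end with `simulate`, `classify`, `cluster`,
`stats`, `reproduce` and `run` subcommands is installed under
`inst/scripts/lrprog`.

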