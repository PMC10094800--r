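# coagnet

Statistical pipeline for four-group clinical cohorts that combine
targeted plasma proteomics with functional hemostasis assays.

## The problem

Studies of post-COVID cardiovascular risk compare acute myocardial
infarction (AMI) patients and healthy volunteers, each split by
SARS-CoV-2 serostatus into a seronegative ("control") and a post-COVID
arm using the anti-nucleocapsid IgG index (cutoff 1.4). The resulting
four groups (27 / 31 / 22 / 44 subjects) are profiled with ~81 plasma
proteins quantified by targeted mass spectrometry plus rotational
thromboelastometry, thrombodynamics, impedance aggregometry and
coagulation labs. coagnet implements the downstream statistics of such
a design as a tested, reusable package, for analysts who need the same
pipeline on their own cohort or want to probe its operating
characteristics on synthetic data:

- **Group contrasts** — Mann–Whitney rank tests with continuity
  correction (continuous), two-tailed Fisher exact and chi-square tests
  (categorical), with Benjamini–Hochberg FDR control: adjusted p-values
  and rank-matched critical values *i·q/m* at *q* = 0.1, summaries as
  median [Q1; Q3].
- **Correlation networks** — per-group Spearman matrices under pairwise
  deletion (each pair uses its complete cases), optional partial
  correlations, and Fisher-z comparison of coefficients between groups:
  z = (atanh ρ_A − atanh ρ_B) / √(c/(n_A−3) + c/(n_B−3)). A
  differential edge "present in A, absent in B" requires a significant
  strong coefficient in A (p adj < 0.05, |ρ| > 0.5), a difference of at
  least 0.4, and a significant adjusted difference test.
- **Clustering** — k-medoids (PAM, 10 random restarts) on the 1 − ρ
  correlation distance, with the number of clusters chosen by a gap
  statistic against 300 permutation reference datasets and the
  first-standard-error rule; cluster correspondence across groups by
  Jaccard overlap.
- **Power** — closed-form sample sizes for the rank test (ARE-inflated
  normal-theory formula) and for detecting a Spearman correlation
  (Fisher-z formula), plus simulation checks.
- **Synthetic cohorts** — a Gaussian-copula generator reproducing the
  design's structure (group sizes, lognormal marginals, planted mean
  shifts and group-specific correlation edges, per-group covariate
  proportions, MCAR missingness 2.1% / 6.7%) with full ground truth, so
  every stage can be tested for recovery without access to subject-level
  data.

## Worked example

The `analysis/` scripts run the whole workflow on a synthetic cohort
with planted effects (AMI-arm acute-phase elevations, a
fibrinolysis–complement correlation present only in the seronegative
control group):

```sh
Rscript analysis/01_simulate.R   # write cohort, panel, ground truth
Rscript analysis/02_contrasts.R  # group contrasts + confounder screen
Rscript analysis/03_networks.R   # correlation + differential networks
Rscript analysis/04_clusters.R   # gap-selected k-medoids per group
Rscript analysis/05_power.R      # sample-size adequacy
```

`02_contrasts.R` prints the contrast table head, e.g.:

```
28 of 440 contrasts significant at q = 0.1; top hits:
 parameter  group_a      group_b   summary_a            summary_b            p_adj
 age        ami_control  control   62.5 [58.5; 69.5]    46 [42; 51.5]        2.4e-06
 sex        ami_post_covid control_post_covid 36/44     8/31                 5.7e-06
 CRP        ami_control  control   60.48 [39.8; 86.66]  22.43 [19.69; 29.39] 4.0e-04
 ...
```

The planted ×2.5 CRP elevation in the AMI arms is recovered (adjusted
p ≈ 4×10⁻⁴ against control), alongside the demographic differences the
generator builds in (age, sex, smoking, BMI). `03_networks.R` reports

```
present in control: 3 differential edges (1 fibrinolysis-inflammation/complement)
present in control_post_covid: 0 differential edges
```

recovering the planted CLT–complement C6 edge (ρ = 0.79 in control,
0.20 in control post-COVID, adjusted difference p ≈ 0.005) in the
fibrinolysis–complement subnetwork slice; the remaining control edges
are small-sample extremes that pass the thresholds honestly — at
n = 27 the largest of 5565 sample coefficients is expected near |ρ| ≈
0.8, which is exactly why the FDR machinery and the difference test are
there. `04_clusters.R` reports the gap-selected cluster numbers per
group (k = 2 in control — the planted correlated pair — and k = 1
elsewhere: with only sparse planted dependence and 22–44 subjects per
group, one cluster is the calibrated answer, illustrating the
conservatism of the permutation-reference gap statistic at small n).
`05_power.R` prints

```
 n for Spearman r = 0.6 (alpha 0.05, power 0.8)               20
 n per group for Mann-Whitney d = 0.9 (alpha 0.1, power 0.8)  18
 simulated Mann-Whitney power at that n                       0.828
 smallest group in the cohort                                 22
```

— both requirements sit below the smallest group size, the design's
adequacy claim.

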