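---
title: "Statistical methods behind coagnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind coagnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coagnet)
```

## The study design the package encodes

coagnet implements the downstream statistics of a four-arm clinical
cohort combining targeted plasma proteomics (81 proteins quantified by
multiple-reaction-monitoring mass spectrometry) with functional
hemostasis assays (rotational thromboelastometry, thrombodynamics,
impedance aggregometry, coagulation labs). Subjects are acute myocardial
infarction (AMI) patients or healthy volunteers, each split by
SARS-CoV-2 serostatus: anti-nucleocapsid (anti-N) IgG below an index
value of 1.4 defines the seronegative ("control") arm of each cohort,
values at or above it the post-COVID arm. The four groups carry
27 (control), 31 (control post-COVID), 22 (AMI control) and
44 (AMI post-COVID) subjects. The boundary value 1.4 itself is
classified post-COVID because the control arm is defined by strictly
smaller values; whether the boundary ever occurs in practice is an
assay-resolution question the data model does not need to answer.

The analysis has four stages, each a module of the package:

1. **Group contrasts** (`run_group_contrasts`): Mann–Whitney rank tests
   with continuity correction for continuous parameters, two-tailed
   Fisher exact tests for binary categoricals, Pearson chi-square for
   multi-category variables; Benjamini–Hochberg FDR with rank-matched
   critical values *i·q/m*, significance at adjusted p below *q* = 0.1.
2. **Correlation structure** (`correlation_matrix`,
   `build_differential_network`): per-group Spearman matrices under
   pairwise deletion, and Fisher-z comparison of coefficients between
   groups; an edge is "present in A, absent in B" when the A coefficient
   is significant (adjusted p < 0.05) and exceeds 0.5 in magnitude, the
   two coefficients differ by at least 0.4, and the adjusted difference
   test is significant.
3. **Clustering** (`gap_statistic`, `pam_cluster`): k-medoids on the
   1 − rho correlation distance with the cluster number chosen by a gap
   statistic over 300 Monte-Carlo reference datasets and 10 random
   initial medoid sets.
4. **Power** (`sample_size_spearman`, `sample_size_mann_whitney`):
   closed-form sample sizes showing the smallest group (22) is adequate
   for both the rank contrasts (effect size 0.9, level 0.1, power 0.8)
   and the correlation analyses (r = 0.6, level 0.05, power 0.8).

## Design choices where the procedure was open

**BH family scope.** For group contrasts the adjustment family is, by
default, one parameter block (assay) per contrast; a single global
family is available (`family = "global"`). Separate tables of clinical,
laboratory and proteomic comparisons are most naturally corrected per
table, but nothing in the procedure forces that, so both modes exist and
the choice is recorded in the output.

**Partial correlations.** The conditioning set for "partial"
correlations defaults to empty — plain Spearman — because the reported
coefficients behave as plain rank correlations; conditioning on
covariates such as age or BMI is available via `conditioning_set`, using
the first-order recursion
rho_xy·z = (rho_xy − rho_xz·rho_yz) / sqrt((1 − rho_xz²)(1 − rho_yz²))
applied recursively for larger sets. With pairwise deletion the
effective n of a partial coefficient is approximated by the pair's
complete-case count; degrees of freedom subtract the conditioning-set
size.

**Differential-edge rule.** Two readings of the edge criterion exist:
an edge requires a strong significant correlation in the *present* group
only ("present in A, absent in B"), or in *both* groups. The first is
the default (`rule = "present_absent"`), the second is selectable; they
answer different questions and the package does not guess which was
intended, it exposes both.

**Difference-test multiplicity.** The Fisher-z difference p-values are
BH-adjusted over the *screened candidate pairs* — those already showing
a strong significant coefficient in one group together with a
coefficient difference of at least 0.4 — because only those pairs are
candidate differential edges; screening before testing is the usual
convention in differential-correlation analysis and keeps the
multiplicity burden proportional to the number of candidate edges
rather than to all C(p, 2) pairs. Adjusting over every testable pair is
available (`diff_family = "all"`).

**Fisher-z variance factor.** The difference statistic divides by
sqrt(c/(n_a − 3) + c/(n_b − 3)). The package defaults to c = 1.06, the
standard variance inflation for Fisher-z of Spearman coefficients,
because every coefficient the pipeline compares is a rank correlation;
the classical c = 1 (appropriate for Pearson coefficients) is
selectable. Simulation at a common true rho of 0.5 and n = 30 per group
shows the classical factor rejecting at ~7% at the 5% level while the
Spearman factor stays near 6%, which is why the rank-adjusted factor is
the default; the residual excess reflects the known rho-dependence of
the rank-correlation variance that a constant factor cannot remove.

**Correlation distance.** "Correlation matrix as a distance matrix" is
read as d = 1 − rho: the published clusters group positively co-varying
proteins, which 1 − |rho| would conflate with anti-correlated ones. The
absolute-value transform is available.

**Gap-statistic reference.** Reference datasets permute each
parameter's subject values independently — a Monte-Carlo scheme that
preserves every marginal distribution while destroying dependence.
Uniform-box references do not apply to a distance-matrix-only view of
the data. Dispersion is W_k = Σ_clusters (pairwise-distance
sum)/(2·cluster size); gap(k) is the mean reference log W minus the
observed log W, with simulation error s_k = sd·sqrt(1 + 1/B). The
cluster number is the smallest k with gap(k) ≥ gap(k+1) − s_{k+1}
(the first-standard-error rule), falling back to the gap maximum when
no k qualifies.

**PAM restarts.** Each clustering runs the PAM swap phase from 10
random initial medoid sets (the study's setting) and keeps the
lowest-cost solution; on every random instance with at most 8 points the
suite checks the result equals the exhaustive-search optimum. k = n is
handled directly (each point its own medoid, zero cost) since the PAM
implementation requires k < n.

**Power formulas.** The Mann–Whitney sample size inflates the
normal-theory two-sample size by 1/ARE with ARE = 0.864, the worst-case
efficiency of the rank test against the t-test — deliberately
conservative; π/3 ≈ 0.955 (the normal-theory value) is selectable. Both
formulas treat the significance level as two-sided; sidedness was left
unstated, and the two-sided reading is the conservative one.

## The synthetic cohort generator

`generate_cohort` emulates the data structure the analysis assumes, not
the biology producing it. Per group it draws latent Gaussian vectors
with a planted correlation matrix and maps them through the Gaussian
copula to lognormal marginals. Because every downstream statistic is
rank-based, the choice of marginal is immaterial to the correlation and
cluster stages; lognormal matches the right-skewed positive scale of
abundance and assay data and makes planted mean shifts act
multiplicatively on the group median. Planted latent correlations rho
surface as rank correlations (6/π)·asin(rho/2) — 0.683 for rho = 0.7 —
which the test suite verifies at n = 2000.

Planted correlation matrices start from a background correlation
(default 0), set the target entries, and are repaired to positive
definite by clipping eigenvalues at 10⁻⁶ and renormalizing to unit
diagonal; the largest deviation of a planted entry from its target
after repair is recorded, and the generator's tests require it below
0.05.

Categorical covariates are Bernoulli draws with per-group probabilities
reproducing the cohort's demographics (male sex 0.37/0.26/0.73/0.84 and
smoking 0.16/0.23/0.44/0.65 across control, control post-COVID, AMI
control, AMI post-COVID); age and BMI are drawn around the per-group
medians of the cohort description. The anti-N IgG index is drawn below
1.4 for control arms and above for post-COVID arms, and group labels are
then re-derived through the assignment rule, so the generator exercises
the same code path as real data.

Missingness is MCAR at the cell level: each proteomics cell is removed
with probability 0.021 and each assay/lab cell with probability 0.067,
the study's overall missing-data fractions. The reported fractions are
ambiguous between cell-level and subject-level; cell-level MCAR is the
weakest mechanism consistent with pairwise deletion and is what the
generator documents and uses. What the generator deliberately does not
model: mass-spectrometric noise and batch effects, missing-not-at-random
censoring (e.g. below-limit-of-detection dropout), and covariate-driven
group differences beyond the planted ones. Passing recovery tests on
this generator therefore show the pipeline detects the structure it
targets under clean conditions; they do not show robustness to MNAR or
batch structure in real cohorts.

## Simulation scales used by the tests

The test suite and acceptance checks fix their problem sizes as
follows, chosen once at design time:

- *Differential-edge recovery*: 10 disjoint pairs planted at latent
  rho = 0.7 in the larger group among 20 parameters, group sizes 44 vs
  22 (the two AMI arms' sizes). Median sensitivity over 100 seeds is
  required ≥ 0.7 with at most 1 false edge — at these sizes the Fisher-z
  difference test has z ≈ 3 per true edge, so the screened-family BH
  step retains most of them.
- *Planted-k clustering*: three blocks of six parameters with
  within-block correlation 0.8, 200 subjects, B = 50 references. Two
  hundred subjects keep the sampling error of a rank correlation near
  0.03, small relative to the 0.2 within-block distance, which the gap
  curve needs in order to flatten past the true k; at the cohort's
  per-group sizes (22–44) individual correlation estimates are too noisy
  for reliable k recovery, which is a property of the statistic, not of
  the implementation.
- *Calibration*: 5000 replicates for the Fisher-z type-I error and the
  Mann–Whitney power simulation; 30 null cohorts for the FDR check.

## Degenerate inputs and numerical conventions

- Quartiles use linear interpolation (type 7); summaries print as
  `median [Q1; Q3]`.
- Mann–Whitney uses exact enumeration only for tie-free samples with
  min(n) ≤ 8; otherwise the normal approximation with midranks, tie
  correction and 0.5 continuity correction. Two completely tied samples
  return p = 1 with a warning.
- A correlation pair with fewer than 4 complete observations is marked
  unavailable rather than raising, so matrix assembly continues;
  unavailable pairs are imputed as rho = 0 (with a warning) only when a
  complete distance matrix is required for clustering.
- `|rho| = 1` cannot enter the Fisher-z comparison (infinite transform)
  and raises an error.
- All stochastic stages take explicit integer seeds; the pipeline
  derives per-stage child seeds from the master seed, and two runs with
  the same config and seed produce byte-identical output files.

## Known limitations

- The published cluster memberships and protein-level medians of the
  real cohort cannot be reproduced here: subject-level data are not
  redistributed with the package, and the synthetic generator is a
  structural stand-in, not a re-creation.
- Partial correlations under pairwise deletion use an approximate
  effective n; with strongly non-uniform missingness the difference-test
  calibration degrades.
- The gap statistic with permutation references is conservative for
  small, tight parameter blocks (it tends to split them); cluster
  numbers at small per-group n should be read as exploratory, as in any
  correlation-based clustering at n below ~100.
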