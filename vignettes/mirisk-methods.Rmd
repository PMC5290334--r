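---
title: "Methods: miRNA psychosis-risk classification and networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA psychosis-risk classification and networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirisk)
```

This vignette is the package's own account of the statistical machinery it
implements: the models and their assumptions, the parameters that matter,
what the synthetic cohort generator does and does not emulate, and the
design choices made where the design was genuinely open.

## The analysis pipeline

The package targets a three-group miRNA-seq design: unaffected comparison
subjects, clinical high-risk subjects who did not progress to psychosis
("nonprogressed"), and high-risk subjects who did ("progressed"). The
stages, in order:

1. **Quantification** — each mature miRNA sequence is counted as an exact
   contiguous substring within each read (`count_exact_matches()`). A read
   containing several distinct miRNA sequences increments each of them; a
   read containing the same sequence twice increments once. This is
   deliberate: counting is per-read membership, not per-occurrence. No
   reverse-complement search is done (small-RNA libraries are
   strand-resolved) and no mismatches are tolerated. An isoform proxy is
   available by trimming 2 nt from the 5' end and 4 nt from the 3' end of
   every canonical sequence and re-counting (`trim_mirnas()`); trimmed
   sequences are substrings of canonical ones, so trimmed counts can only
   grow.
2. **Robustness filtering** — miRNAs with at least `min_total` (default
   10000) reads summed over all samples are kept; any single miRNA holding
   more than half of all reads is dropped as superabundant. Both filters
   are single-pass over the original totals. Note the superabundance rule
   is idempotent only when removing a miRNA does not push a survivor over
   the threshold of the re-normalized total; the package applies it once,
   before normalization and z-scoring.
3. **Quotient normalization** — each sample's counts are divided by the
   mean of that sample's `top_k` (default 30) largest counts. Any
   per-sample multiplicative factor cancels exactly, which is the point:
   library size never reaches the downstream statistics. When the k-th and
   (k+1)-th counts tie, the ties are resolved deterministically (count
   descending, then miRNA id ascending) so results are reproducible.
4. **Reference z-scores** — each miRNA's quotients are standardized by the
   mean and s.d. (n−1 denominator) over the *unaffected* group only. The
   comparison groups are therefore read on the unaffected scale, and the
   unaffected samples never participate in label permutations. A
   zero-variance reference miRNA is an error, not a silent NaN.
5. **CALF training, validation, networks, sequence similarity** — described
   below.

## The CALF classifier

`calf()` fits the Coarse Approximation Linear Function: an ordered set of
at most `max_markers` miRNAs with weights in {+1, −1}, built greedily. The
selection metric is the two-sided pooled-variance Student t-test p-value of
the current weighted z-score sum between the two classes (Welch is
available via `var_equal = FALSE`). Iteration one picks the miRNA with the
smallest single-marker p-value, signed so the positive (higher-risk) class
has the higher mean — the classifier increases with risk. Every later
iteration evaluates all unused miRNAs with both signs added to the running
sum and accepts the best candidate only on strict improvement. Ties break
to the lowest miRNA id, then to weight +1. Zero-variance candidates are
assigned p = 1, so the search simply never prefers them.

Design choices worth stating:

- **Signed weights.** Weights are searched over both signs at every
  iteration. An equivalent formulation pre-orients every marker and uses
  +1 weights only; searching signs at each step is strictly more general
  and costs a factor of two.
- **Default marker limit 6** for full-data fits. Left unlimited, the greedy
  typically terminates within about ten iterations on 136-miRNA data
  because strict improvement becomes impossible.
- **Training AUC** is the Mann–Whitney probability with ties counted one
  half; `auc(s) + auc(-s) = 1` exactly, and the trapezoidal area of the
  empirical ROC equals it to machine precision.

An important caution the package makes easy to demonstrate: on pure-noise
data with permuted labels, CALF limited to six markers still reaches
training AUCs well above 0.5 (typically ~0.8 at n = 37 + 30 over 136
miRNAs). A training AUC means nothing without the validation battery
below.

## Resampling validation

`permutation_test()` permutes the class labels of the two compared groups
(class sizes preserved; the reference group is untouched) and re-runs the
*entire* training — selection included — on each pseudo data set. The true
training AUC is compared against the pseudo-AUC null with the add-one
Monte Carlo estimate p = (k+1)/(N+1), where k counts strict exceedances
(pseudo > true). A smoothed alternative fits a beta distribution to the
pseudo AUCs by maximum likelihood (`fitdistrplus::fitdist`) and reports
the fitted upper tail; it extrapolates sensibly when the true AUC lies
beyond every pseudo value, where the Monte Carlo estimate saturates at its
floor 1/(N+1).

`stability_selection()` re-trains on independent random 80% subsets of
each class (floor per class, drawn without replacement) and tallies
per-miRNA selection counts, ignoring sign. `integrate_classifier()` keeps
the full-data model's markers whose count reaches `min_count` (default
225 of 1000, scaled proportionally for other trial counts), with weights
from the full-data fit. `subset_auc_distribution()` and
`confound_extremal_subsets()` score a *fixed* model over random equal
subsets, the latter forcing a binary flag (e.g. medication) to its
maximum or minimum attainable prevalence per subset — if the two extremes
bracket the plain distribution tightly, the flag is not what the
classifier reads.

## Correlation networks

`critical_correlation(p_tail, n)` inverts the exact null distribution of
the Pearson correlation of two independent n-vectors (t-transform with
n−2 df); at p = 0.001, n = 25 it returns 0.5878. Its inverse,
`null_correlation_tail()`, is consistent with it to 1e−9 and agrees with
direct quadrature of the null density (1−r²)^((n−4)/2)/B(½,(n−2)/2).
(For two normal 136-vectors at r = 0.61 the exact tail is ≈3e−15; a value
of 9.3e−15 is sometimes quoted for this configuration but does not follow
from the exact null, which the package reports.)

`subsample_exceedance_counts()` draws `n_trials` random `subset_size`
sample subsets within one group and counts, per miRNA pair among the
top-`k` abundant nodes, the trials whose correlation strictly exceeds the
threshold. Only positive correlations count (0.5878 is the one-sided
0.001 quantile; a two-sided reading would use a different constant).
Within-subset constant columns give undefined correlations; these are
counted as non-exceedances and tallied in an attribute. Pairs exceeding in
strictly more than `edge_min` (default 500 of 1000) trials become edges;
isolated nodes stay in the node set so a miRNA's disappearance from one
group's network remains visible. Exports are plain Pajek `.net`
(`*Vertices` with quoted labels, `*Edges` with the exceedance count as
weight) and round-trip through `read_pajek()` byte-identically.

Under the independence null the expected number of exceedances per trial
among 780 pairs at p = 0.001 is 0.78, and no pair comes near the >500
edge rule — the package's acceptance tests verify both, and also that the
edge sets obtained at subset sizes 21, 23, 25 agree (Jaccard > 0.5 on
planted data), so the rule is not an artifact of one subset size.

## Sequence similarity

`smith_waterman()` is a textbook local-alignment dynamic program with a
linear (per-symbol) gap penalty and zero floor, defaulting to match +1,
mismatch −1, gap −1, returning one optimal traceback's
match/mismatch/gap decomposition. The linear gap model is the faithful
reading of a single per-symbol "gap −1" weight; with these unit weights
the score is n_match − n_mismatch − n_gap. Input sequences are
canonicalized (uppercase, T→U, stray non-alphabet characters such as a
typeset underscore stripped). `similarity_null_test()` compares the mean
pairwise score of a selected marker set against random same-size draws
from a user-supplied background pool (the appropriate pool is
study-specific, e.g. the non-selected robustly expressed miRNAs after
collapsing near-identical families); exceedance is inclusive (null ≥
observed) and the p-value is add-one Monte Carlo. All pool pair scores
are computed once, so the null draws are lookups.

## The synthetic cohort generator

`generate_cohort()` emulates the study design the analysis assumes:
default group sizes 27/37/30, 136 robustly expressed miRNAs, five planted
markers (three down, two up in the progressed group), per-sample library
size factors drawn log-uniformly from [0.5, 2], and a per-group latent
factor creating within-group miRNA–miRNA correlation.

The count model is negative binomial on a log-normal latent mean. Base
abundances span log-uniform [50, 5000] so that top-30/top-40 selections
are meaningful. Two parameters set the noise level: `biological_sd`
(default 0.4, the subject-level s.d. on the natural-log scale) and
`dispersion` (default 0.02, residual overdispersion beyond the log-normal
layer). Together they imply a subject-level CV of about 43% per miRNA —
a realistic figure for robustly expressed leukocyte miRNAs, with most
variance biological rather than technical.

Two design decisions deserve explanation:

- **Signed latent-factor loadings.** A latent factor loading uniformly on
  every miRNA is mathematically identical to a per-sample multiplicative
  scale — exactly what quotient normalization removes. Such a factor would
  vanish from every downstream statistic and the group-contrast in network
  density could never be simulated. Each miRNA therefore carries a fixed
  loading sign (±, drawn once, recorded in `truth`), giving pairwise
  correlations of ±strength² that survive normalization, as real
  co-regulation does. The progressed group's default strength (0.3) is
  well below the other groups' (0.75), mirroring the loss of miRNA
  orchestration the analysis is designed to detect. For pairs to pass the
  >500/1000 edge rule at subset size 25, their true correlation must
  exceed ≈0.59, i.e. strength ≳ 0.8; the network-contrast tests use 0.9
  for the strong groups for that reason.
- **Calibrated planted effects.** A planted "effect of 1.2 s.d." is
  delivered as Cohen's d on the normalized count scale: the log-mean shift
  δ is solved from expm1(δ) = d·CV·sqrt(w₁ + w₂e^{2δ}) so that the
  progressed-vs-unshifted contrast equals the requested d in pooled-s.d.
  units. A naive symmetric log-shift would make down-regulated markers
  markedly easier to detect than up-regulated ones (an up-shifted
  log-normal group's s.d. inflates with its mean), which is not what an
  "effect size" means downstream. Planted miRNAs carry zero latent
  loading so mean shifts and correlation structure stay orthogonal.

What the generator does **not** emulate: isomiR biology beyond the fixed
trim proxy, adapter contamination or sequencing error, batch structure,
clinical covariates beyond a binary medication flag, and any non-Gaussian
tail behavior of real subject variation. Passing tests on synthetic
cohorts therefore demonstrate the *statistical machinery* — effect
recovery, calibration, thresholds — not the biological validity of any
particular marker set.

## Numerical and testing choices

- Reproducibility: every stochastic operation takes an integer seed;
  `run_pipeline()` derives per-stage seeds deterministically from one
  master seed, and identical configurations are bit-identical.
- The problem sizes used by the test suite are the package's own choices
  for a nested-simulation design: type-I calibration of the permutation
  test uses 400 outer replicates of 40-miRNA, 18+18 cohorts with
  n_perm = 200 and a 3-marker limit (the add-one p-value's calibration is
  a rank-uniformity property and does not depend on cohort dimensions);
  planted-marker recovery uses 50 seeded replicates of the full 27/37/30 ×
  136 design at effect 1.2 with the greedy run to its natural ≤10
  termination depth — at the 6-marker full-data limit the expected
  recovery of ≥4 of 5 markers drops below 80% even on ideal Gaussian
  data, so the recovery check addresses the search, not the reporting
  limit.
- Degenerate inputs have defined behavior throughout: zero-variance t-test
  inputs return p = 1 with a flag; constant columns are correlation
  errors where a correlation is the quantity of interest
  (`duplicate_concordance`) and non-exceedances where it is one of many
  (`subsample_exceedance_counts`); beta fits clamp pseudo values into
  (0, 1) by machine epsilon.

## Known limitations

- The exact-match quantifier is deliberately mismatch-intolerant; real
  pipelines may use alignment with tolerance, and counts will differ.
- The add-one Monte Carlo p-value is conservative at its floor; with
  N = 1000 permutations no p below ~0.001 is observable. The beta-fit
  p-value smooths this but inherits the fit's parametric assumption.
- Stability counts ignore sign; a marker selected with both signs in
  different subsets is counted once per selection.
- The t-test metric is applied to z-scores of skewed quotients; the
  pooled-variance Student form is used because small reference groups make
  per-marker variance estimates noisy, but heavy-tailed miRNAs can still
  dominate a sum. Rank-based alternatives are out of scope.
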