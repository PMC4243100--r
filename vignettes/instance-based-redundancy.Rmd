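---
title: "Instance-based redundancy: the model behind resi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Instance-based redundancy: the model behind resi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resi)
```

## The model

`resi` addresses supervised feature selection for binary classification
of expression matrices in the small-n / large-m regime (tens to a few
hundred samples, thousands of genes). Its premise is that redundancy
between features should be judged by *which samples* each feature can
discriminate, not by how similar their numerical values are.

**Neighbourhood purity.** For a feature $X_p$ and sample $u$, the purity
$U(X_p^u \mid Y)$ is the fraction of $u$'s $k$ nearest neighbours — by
absolute difference on this single feature, excluding $u$ itself — that
carry $u$'s class label. Purity takes values in $\{0, 1/k, \dots, 1\}$.
A sample is *clear-discerned* when $U > \mu$ strictly, *blur-discerned*
when $U \le \mu$. The blur set of a feature is the part of the sample
space where the feature's local class signal fails; it is the feature's
"predictive power distribution" reduced to a mask.

**REMI.** The redundancy of a candidate $X_p$ to a selected feature
$X_i$ is the fraction of $X_p$'s blur samples that are also blur on
$X_i$. The *candidate* supplies the denominator: the penalty asks how
much of what the candidate cannot do is also not done by the selected
feature. REMI is 0 for fully complementary predictive power and 1 when
the selected feature leaves all of the candidate's problem samples
uncovered — for example, an exact copy of an already-selected feature.

**Relevance and merit.** Relevance is the absolute two-sample
t-statistic $|t| = |\bar x_1 - \bar x_2| / \sqrt{s_1^2/n_1 + s_2^2/n_2}$
(Welch form, sample variances). The forward search first removes
features with $|t| < \varepsilon$, seeds with the largest $|t|$, and
then repeatedly adds the candidate maximising
$|t(X_p)| - \operatorname{mean}_{X_i \in S} \mathrm{REMI}(X_p; X_i \mid Y)$.

## Parameters

* `k = 3` (neighbourhood size). Purity is then a multiple of $1/3$;
  three neighbours is the smallest odd neighbourhood that distinguishes
  "majority agrees" (2/3) from "majority disagrees" (1/3).
* `mu = 0.66` (discernment threshold, on the purity scale). With
  `k = 3` this places the clear/blur boundary exactly between 1/3 and
  2/3: purity $2/3 \approx 0.667 > 0.66$ is clear, $1/3$ is blur. The
  comparison is strict (`> mu` clear, `<= mu` blur), so a purity exactly
  equal to `mu` is blur.
* `epsilon = 0.1` (stage-1 relevance cutoff on $|t|$, dimensionless).
  Because $|t|$ is scale-free the cutoff transfers across datasets, but
  it is deliberately permissive: at $n = 60$ the null $|t|$ exceeds 0.1
  about 92% of the time, so stage 1 only prunes the clearly inert
  features and leaves redundancy elimination to stage 2.
* `max_features = 80` (stopping bound, matching the upper end of the
  benchmark dimension sweep in `default_dimensions()`).
* `min_merit` (optional early stop on the best merit) is implemented but
  disabled by default; no principled universal threshold exists because
  merits are on the $|t|$ scale of the particular dataset.

## Numerical choices

* Each sample is excluded from its own neighbourhood, the kNN-classifier
  convention; including it would add $1/k$ to every purity and make a
  lone outlier look pure.
* Distance ties are broken towards the lower sample index, and all
  argmax steps break ties towards the lower feature index, so results
  are fully deterministic.
* The greedy argmax treats merits within `1e-9` of the maximum as tied.
  Algebraically equal merit functions computed along different
  arithmetic paths (for example the joint-information and
  interaction-information forms of the same criterion) can differ by one
  ulp; without the tolerance such round-off would make equivalent
  criteria disagree on which of two exactly-tied candidates enters
  first.
* REMI with an empty denominator (a candidate with no blur sample) is
  defined as 0: a feature that clear-discerns every sample should not be
  penalised through an undefined ratio.
* A zero-variance denominator in the t-statistic yields 0 when the class
  means agree and signed infinity (maximal relevance) when they differ.
* Purity profiles and blur masks are computed once per surviving feature
  and cached as a logical matrix; each greedy step then costs one mask
  intersection (`crossprod`) across all candidates. Selecting 80
  features from a 60 × 2000 matrix takes a few seconds on one CPU.

## The information-theoretic comparators

`mi_select()` runs MIFS, mRMR, MIFS-U, mIMR, JMI, CMIM and IF in the
same greedy harness, with mutual information estimated by the plug-in
estimator in bits over Fayyad–Irani MDL-discretised features. Base 2 is
a convention only — it rescales every merit uniformly and never changes
a selection order. Three identities connect the criteria and are
asserted in the test suite: mRMR is MIFS with $\beta = 1/(p-1)$ at step
$p$; CMIM and IF give identical scores by the chain rule
$I(X_p, X_i; Y) = I(X_i; Y) + I(X_p; Y \mid X_i)$; and JMI's merit is an
affine transform of mIMR's, so their selection orders coincide. MIFS
and MIFS-U take `beta` as a required argument — no default is assumed,
since no single value is canonical.

The MDL discretizer accepts a boundary only when its information gain
exceeds $\log_2(N-1)/N + \Delta/N$ with
$\Delta = \log_2(3^c - 2) - (c\,E - c_1 E_1 - c_2 E_2)$; features with
no accepted cut discretise to a single bin, carry zero mutual
information with the label, and are excluded as irrelevant. Inside the
cross-validation harness, cut points are learned on training folds only
and applied to test folds by thresholding.

`cfs_merit()` implements the standard correlation-based subset merit
$k\,\bar r_{cf} / \sqrt{k + k(k-1)\bar r_{ff}}$ with symmetrical
uncertainty as the correlation measure. Note one boundary property:
adding an *exact* duplicate leaves the merit unchanged (with
$\bar r_{ff} = 1$ the expression collapses to $\bar r_{cf}$); the
penalty is strict only for imperfectly correlated features.

## The evaluation protocol

`benchmark()` implements repeated stratified cross-validation (default
10 × 10). Within each fold, features are standardized to zero mean and
unit sample SD on the training samples, and the test fold is mapped
with the training parameters; a zero-SD training feature maps to zeros
in both. Selectors run on the training fold only and are re-run in
every fold — the only reading of within-fold processing that is free of
selection leakage. The test suite enforces this by poisoning test folds
and checking the selection is unchanged. Scores are balanced accuracy
with the minority class as positive; a fold whose test set misses a
class scores `NA` and is excluded from means.

Six classifier adapters ship in `classifier_registry()`: linear SVM with
cost 1, polynomial-kernel SVM, 3-nearest-neighbours, logistic
regression, Gaussian naive Bayes, and a decision tree. All are
deterministic given the fold partition.

`wtl_summary()` compares selectors per (dataset, classifier) cell with a
paired two-sided t-test at $\alpha = 0.05$. The pairing unit is the
repetition mean (BACC averaged over folds and dimensions within a
repetition): fold-level scores within a repetition share training data
and are positively dependent, which inflates the effective sample size
of a fold-level test; pairing on the 10 repetition means is the more
conservative default, with `pairing = "fold"` available. An all-zero
difference vector is a tie by definition.

## The synthetic generator

`synthetic_spec()` plants four feature roles in a Gaussian
class-conditional design: *relevant* features shift the class means by
`effect_size` within-class SDs (so the expected $|t|$ is analytic,
$\approx$ `effect_size` $\cdot \sqrt{n/4}$ for balanced classes);
*duplicates* copy a relevant feature plus optional noise; *complementary
pairs* separate the classes perfectly (clusters at
$\pm$`separation`/2) on a designated stratified half of the samples and
are pure noise on the other half, so the members' blur sets are
disjoint by construction and their mutual REMI is exactly 0; and
*irrelevant* features are label-independent noise.

Defaults describe the reference recovery problem used throughout the
tests: $n = 60$ with a 21/39 class split (the shape of a typical
tumour/normal study in this size range), 2 relevant features at effect
size 1.2 — a strong but not extreme differentially expressed gene,
$E|t| \approx 4.6$ against a null max $\approx 3.2$ over 200 noise
features — one exact duplicate, one complementary pair with clusters at
$\pm 4$ SD (far enough outside the noise range that the designated half
is separated essentially perfectly; the members' $|t| \approx 7$), and
200 irrelevant features. On this problem the selector recovers every
informative role — both complementary members and a relevant feature —
before any duplicate or noise feature in well over 95% of seeds, which
the acceptance tests assert over 50 seeds.

What the generator does **not** model: probe-level noise, batch
effects, heavy-tailed expression distributions, and correlation
structure among the irrelevant features. Passing the recovery tests
therefore demonstrates the algorithmic behaviour of the merit function
under its intended geometry, not performance on real microarray data;
the benchmarking harness exists precisely so that real datasets can be
evaluated with the identical protocol.

## Known limitations

* **The redundancy penalty is bounded by 1.** A candidate whose $|t|$
  exceeds every competitor's by more than 1 is selected regardless of
  redundancy — in particular, an exact copy of an extremely dominant
  feature re-enters immediately after its source at merit $|t| - 1$.
  The penalty also *dilutes*: it is a mean over the selected set, so a
  copy's effective penalty shrinks as unrelated features accumulate in
  $S$. On duplicate-heavy simulations the selector consequently
  guarantees only never placing *more* duplicates in its top ranks than
  plain $|t|$-ranking does, with strict improvement in the regime where
  relevance differences are comparable to the penalty scale.
* Binary labels only; the t-statistic relevance has no multi-class
  analogue here.
* Purity is invariant under affine transforms of a feature but not
  under general monotone transforms (nearest neighbours depend on
  metric distances, not ranks).
* Stage 1's $\varepsilon$ applies to $|t|$ on the data as given;
  heavily pre-scaled inputs shift what "trivial" means.

## Problem sizes used by the test suite

The packaged tests run the full pipeline at reduced scale chosen to
exercise every code path while keeping the suite quick: oracle
comparisons on hundreds of datasets with $n \le 30$, $m \le 10$;
recovery over 50 seeds of the 60 × 205 reference problem; benchmark
protocol checks on 12–16-sample toy sets with 2–4 folds; a null
calibration of the paired test over 500 simulated comparisons; and one
60 × 2000 timing run selecting 80 features.
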