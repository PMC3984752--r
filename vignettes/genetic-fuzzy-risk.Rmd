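---
title: "Mining fuzzy risk rules with a genetic algorithm: models and design choices"
author: "gfsrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining fuzzy risk rules with a genetic algorithm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gfsrisk)
```

## The problem

Clinicians stratify unstable-angina patients into three ordinal risk levels
(low, medium, high) from a mix of numerical measurements (age, blood
pressures, cardiac biomarkers) and categorical findings (ECG changes,
histories, habits). Classical scores handle these inputs crisply, although
much of the information is intrinsically vague: a 73-year-old is neither
clearly "old" nor clearly not. `gfsrisk` implements a genetic fuzzy system
for this setting: numerical features are converted to linguistic terms by
data-driven fuzzy partitioning, a genetic algorithm (GA) mines fuzzy
IF--THEN rules per risk class from a labelled cohort, and a
confidence-weighted classifier turns the rule base into predictions.

## Fuzzy partitioning of numerical features

For a numerical feature $a$ with observed range $[v_0, v_{m+1}]$ and interior
midpoints $v^1 < \dots < v^m$, the package builds $m+2$ membership
functions: a left semi-trapezoid (1 below $v_0$, falling linearly to 0 at
$v^1$), interior triangles peaking at each midpoint, and a right
semi-trapezoid rising from $v^m$ and flat at 1 above $v_{m+1}$. By
construction $\sum_j \mu_{a,j}(x) = 1$ for every $x$ in the domain (a
partition of unity), which the test suite asserts on dense grids to 1e-9.

Midpoints come from one-dimensional agglomerative clustering of the observed
values. The cluster closeness measure is the average absolute cross-pair
difference
$d(c_1,c_2) = \frac{1}{|c_1||c_2|}\sum_{x \in c_1}\sum_{y \in c_2}|x-y|$
(average linkage). Merging starts from singletons, always joins the closest
pair, and stops once the smallest inter-cluster distance exceeds a threshold
$\varepsilon$; cluster centroids become the midpoints, with centroids within
`1e-9 * range` of a domain bound dropped to avoid zero-width segments.
Note the stop rule is stated for a *distance*: merging while "similarity is
below a threshold" does not terminate meaningfully for an agglomerative
process, so the measure is treated as a distance throughout.

Tunable parameters, with defaults and rationale:

* `epsilon` (per feature, default `0.15 * range`): larger values give fewer,
  broader linguistic terms. No universally right value exists; 0.15 yields
  the 2--5 sets per feature typical of clinical vocabularies.
* `max_sets` (default 5): a hard cap; merging simply continues past
  $\varepsilon$ until the partition fits. Clinically interpretable
  vocabularies rarely exceed five grades.
* Default term names are size-matched vocabularies (low/high,
  low/medium/high, ...), overridable per feature.

Ties in merge order are broken deterministically (lower centroid of the
left cluster, then scan order) so partitions are reproducible. The
implementation is exact (Lance--Williams updates in C++); tests compare it
against an exhaustive tracer that recomputes all pairwise distances from raw
members at every step, and against average-linkage `hclust` cut at
$\varepsilon$.

## Rules, chromosomes and rule quality

A rule is `IF a1 is (t1 OR t2) AND a2 is (t3) THEN risk is C`: per-feature
disjunctions of linguistic terms, conjoined across features, with a single
class consequent. A rule is encoded as one chromosome: one bit per term per
feature, in schema order (Michigan encoding -- one chromosome is one rule).
An all-zero or all-one segment means the feature is irrelevant to the rule
and is dropped when decoding; a chromosome whose every segment is irrelevant
is invalid and scores zero fitness.

For a case $\sigma$ and rule $r$ with $n$ antecedent features, the
antecedent part compatibility is
$APC(\sigma,r) = \frac{1}{n}\sum_i \max_j \mu_{a_i,j}(\sigma(a_i))$, the
average over antecedent features of the maximal membership among the
selected terms (categorical memberships are 0/1). The average runs over the
*antecedent* features only: averaging over all schema features would let
irrelevant features dilute every rule toward zero and contradict the
irrelevance semantics of the encoding. A missing value contributes 0 but
still counts in $n$ -- a rule should not fire fully on absent evidence.

Rule quality on a labelled dataset $D$:

* support: $\mathrm{Supp}(\sigma,r) = APC(\sigma,r)$ if $\sigma$'s label
  equals the rule's class, else 0, and
  $\mathrm{Support}(r) = \sum_\sigma \mathrm{Supp}(\sigma,r) / |D|$;
* confidence:
  $\mathrm{Confidence}(r) = \sum_\sigma \mathrm{Supp}(\sigma,r) / \sum_\sigma APC(\sigma,r)$,
  undefined when the rule fires nowhere (such rules score 0);
* fitness: $(\mathrm{Support} + \mathrm{Confidence})/2$, the GA's
  objective, balancing generality and accuracy.

A rule is redundant with respect to another when both predict the same
class, its selections are bitwise subsets of the other's (a feature
unconstrained by the wider rule counts as covering all terms), and the two
supports agree to 1e-9: the narrower rule adds nothing.

## The genetic miner

One GA run per risk class, consequent fixed. Defaults: population 100, 1000
generations (the stopping criterion), crossover rate 1.0 (one-point),
mutation rate 0.2, 2 elites. Selection is binary tournament. Elitism is not
strictly part of the classical description, but without it "individuals with
higher fitness survive" is not guaranteed; with it, best-in-population
fitness is provably non-decreasing, which the tests assert.

Three choices here deserve an explicit account, because each was forced by
measurement rather than taste. The experiments referenced below are the
package's own recovery benchmark (described in the last section): cohorts of
500 cases, 5% label noise, 10-fold cross-validation, five seeds.

**Mutation semantics.** Two readings of "mutation rate 0.2" coexist in the
genetic-algorithm tradition: every bit flips independently with probability
0.2, or the chromosome undergoes (with probability 0.2) a flip of one
randomly selected element. On the 26-feature schema a chromosome has ~80
bits, so per-bit mutation changes ~16 bits per child: the search degenerates
into random sampling, and because a compact rule requires ~24 of 26 segments
to be exactly all-zero or all-one, random sampling essentially never visits
one. Measured consequence: the best high-risk rule found after 100,000
evaluations had fitness 0.10 while a reachable single-feature rule scores
0.51, and planted-rule recovery was 0%. Under the single-element reading the
population converges and hill-climbs; recovery is exact. The engine
therefore defaults to `mutation_mode = "single-flip"`; per-bit mutation
remains available (`"per-bit"`) and is adequate on small spaces (it attains
the exhaustive optimum on the 10-bit toy problem in 20/20 seeds), and the
elementwise operator is exported as `ga_mutate()`.

**Initialisation.** Chromosomes are initialised segment-wise: with
probability 1/2 a segment is set all-ones (feature irrelevant), otherwise
its bits are uniform random; all-irrelevant chromosomes are resampled. A
plain 0.5-per-bit initialisation starts every rule at ~20 relevant features,
and the single-flip path down to compact optima is neutral drift that
sporadically fails in cross-validation folds. Don't-care-biased
initialisation is the canonical choice for Michigan-style fuzzy classifier
GAs and makes the discovery of compact rules reliable.

**Archive.** Under generational replacement the final population is
dominated by freshly mutated individuals, so the miner maintains a bounded
best-ever archive of distinct valid rules (positive support, defined
confidence) across all generations. After the last generation the archive
is pruned of redundant specialisations, ranked by fitness (ties: higher
confidence, then fewer antecedent features, then bit-string order), filtered
by a minimum support (`min_support`, default 0.02 -- standard
association-rule hygiene against accidental confidence-1 rules covering one
or two cases), and the top `rules_per_class` rules are returned.

**Why `rules_per_class` defaults to 1.** Classification scores (next
section) are *unnormalised sums* over each class's rules. Every additional
majority-class rule adds score mass to every case that partially matches
it -- e.g. the statistically excellent second medium-risk rule "recent
events AND no ST change" still fires with strength 1 on a high-risk case
through the shared events term. On the recovery benchmark, 10 rules per
class drove high-risk sensitivity to 0, two rules per class left it
fold-dependent (0.61--0.90 pooled), and one rule per class -- where the
decision reduces to comparing each class's best confidence-weighted rule --
recovered the planted labels exactly on every seed. Larger values remain a
single configuration switch for users who want a descriptive rule table
rather than maximal classification accuracy; mined tables of the top-k
rules per class are exactly what `rules_per_class = k` returns.

## Classification

For a case $\sigma$, each class score is
$v_{class} = \sum_{r} \mathrm{Confidence}(r)\,\beta(r,\sigma)$ over that
class's rules, where the firing strength
$\beta(r,\sigma) = \sum_i \max_j \mu_{a_i,j}(\sigma(a_i))$ *sums* the
per-feature maxima (unlike APC, which averages them) and therefore can
exceed 1 for multi-feature rules. The predicted level is the argmax of
$(v_l, v_m, v_h)$. Ties break toward the higher risk level -- clinically
conservative. A case that fires no rule at all receives an explicit,
flagged fallback label (default medium-risk, configurable), since the
argmax is undefined on the zero vector. An optional normalised mode divides
$\beta$ by the antecedent size (off by default; kept for sensitivity
analysis because the summed form systematically favours classes whose rules
carry more antecedent features).

## Evaluation

One-vs-rest confusion counts per class give sensitivity
$TP/(TP+FN)$ and specificity $TN/(TN+FP)$; classes with no positives (or no
negatives) in an evaluation report `NA` rather than an arbitrary number, and
such exclusions are counted. Agreement is the exact-match fraction against
the physician labels.

`cross_validate()` shuffles, splits into class-stratified folds (stratified
because a 9% minority class would otherwise vanish from many validation
folds), re-derives the fuzzy partitions *from each training split only* (no
information leakage), mines on the training split and predicts the held-out
fold; confusion counts pool over folds and rounds. `resubstitution()`
evaluates on the training data itself and is labelled distinctly in its
report -- a single headline agreement number can otherwise hide which of
the two protocols produced it.

## The synthetic cohort generator

No real patient-level dataset ships with the package, so testing is built
on synthetic cohorts with planted ground truth. The generator draws each of
the 26 features independently -- truncated normals within clinically
plausible spans for the nine numerical features (e.g. age 66 ± 12 years in
30--90, systolic pressure 135 ± 22 mmHg in 80--200), weighted draws for the
seventeen categorical ones -- and labels every case by scoring it against a
small set of planted rules *with the classifier's own machinery*, so the
ground truth exercises the same inference path end to end. The default
planted world: a significant ST change marks high risk; otherwise recent
heart events mark medium risk, quiescence low risk (the three planted rules
tie at confidence 1.0 and the conservative tie-break resolves ST-change
cases upward). The default class mix 16:33:5 over low:medium:high
reproduces the imbalance of a small single-centre cohort and is enforced
exactly by stratified rejection before noise; label noise then flips each
label to a uniformly different class with the configured probability.

What the generator does *not* emulate: correlated features (real biomarkers
co-vary; here only the planted labels induce association between features
and outcome), longitudinal structure, missingness patterns, and multi-rule
class concepts whose markers co-occur. Passing the recovery benchmark
therefore demonstrates that the pipeline recovers rule-expressible signal
under label noise and class imbalance -- not that it matches physician
performance on real data.

**Recovery benchmark.** Cohorts of n = 500 at 5% label noise; 10-fold
stratified cross-validation with default mining settings; five seeds. Folds
are trained on the noisy labels, and held-out predictions are compared to
the *noise-free* planted labels (recovery of the planted ground truth).
Against the noisy labels themselves, high-risk sensitivity is bounded near
0.80 by arithmetic alone: 5% uniform flips inject about 11 spurious "high"
labels per cohort against about 44 genuine ones, and no classifier can
match labels that are pure noise. The acceptance suite asserts pooled
recovery agreement >= 0.85 and pooled high-risk sensitivity >= 0.9; the
measured values in this configuration are 1.0 and 1.0 on every seed. These
problem sizes (500 cases, 150 GA runs of population 100 by 1000
generations) were chosen so the whole benchmark completes in about two
minutes.

## The worked toy example

The six-case toy cohort (`table1_fixture()`) with the four-term age
partition (`toy_age_partition()`: domain 30--87, midpoints 56 and 74)
anchors several exact checks. The six-rule reference base
(`toy_rulebase()`) reproduces hand-computable support/confidence values --
for instance "IF age is (old) AND smoke is (no) THEN medium" has support
0.339, confidence 0.465, fitness 0.402 on the toy data -- and classifies
case 1 (74-year-old male non-smoker with recent events) as medium-risk with
a score vector of roughly (0.33, 1.96, 1.78). A freshly mined base on the
same six cases depends on the seed: the toy space contains degenerate
single-feature optima (e.g. "sex is male implies high risk", fitness
0.417) that legitimately out-score the reference rules under the composite
fitness, so the mined base sometimes ranks case 1 high-risk instead. Six
cases are simply too few to pin the miner down; the package treats the
reference-base prediction as the stable worked example.

```{r}
d <- table1_fixture()
rb <- toy_rulebase(d)
classify_case(rb, get_case(d, 1), d$schema)$scores
```

## Numerical and degenerate-input policy

* Memberships of missing values are 0 everywhere; missing data are never
  imputed.
* A numerical feature with a single distinct value cannot be partitioned
  and raises an error telling the caller to treat it as categorical.
* Confidence with zero total firing is `NA`, never 0/0; fitness maps it
  to 0.
* All stochastic stages (generator, miner, fold shuffling) are driven by
  explicit integer seeds; per-class mining seeds are `seed + class rank`,
  per-fold seeds are derived arithmetically, and identical seeds reproduce
  outputs byte-for-byte (asserted in the tests).
* Categorical tokens are trimmed and lowercased on input; risk labels
  accept "low" for "low-risk" and so on.

## Known limitations

* The composite fitness is support/confidence only; rule length is not
  penalised, so descriptive mining at `rules_per_class > 1` can return
  near-duplicate variants of one concept (redundancy pruning removes only
  exact subset-equal-support cases).
* The unnormalised score sum biases multi-rule bases against minority
  classes (measured and documented above); choose `rules_per_class`
  deliberately.
* Fuzzy partitions depend on the observed min/max, so extreme outliers
  stretch boundary sets.
* The CLI and JSON formats are reproducibility plumbing, not a clinical
  interface; nothing here is a medical device.
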