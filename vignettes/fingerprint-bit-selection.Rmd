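---
title: "Selecting informative fingerprint bits by Average Information Content"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting informative fingerprint bits by Average Information Content}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aicmax)
```

## The problem

Non-hashed molecular fingerprints assign one bit per predefined
substructure pattern, which makes them interpretable but long: a
concatenation of the common families (EState, MACCS, PubChem, Substructure)
runs to well over a thousand bits, most of which are irrelevant to any
particular activity-prediction task. `aicmax` selects a short hybrid subset
of bits that jointly carries as much activity information as possible for
one or several related biological targets simultaneously.

## The score

For K targets with binary activity variables $Y_1, \dots, Y_K$ and a set of
bits $X$, the Average Information Content is

$$
\mathrm{AIC}_Y(X) \;=\; \frac{1}{K} \sum_{i=1}^{K}
  \frac{\mathrm{MI}(X; Y_i)}{\mathrm{SE}(Y_i)},
$$

the mutual information between the *joint* pattern of the bits in $X$ and
each target's labels, normalized by the label entropy and averaged over
targets. Each factor is a fraction in $[0, 1]$ — the share of that target's
activity information the bits capture — so $0 \le \mathrm{AIC} \le 1$, a
set fully determining the activity of $l$ of $k$ targets scores $l/k$, and
adding a bit can never decrease the score. Crucially, each per-target
factor is estimated on that target's own compound set, so targets may have
entirely disjoint compound sets; plain multi-target mutual information
would instead require every compound to be labeled for every target, which
screening databases almost never provide.

### Estimation choices

* **Plug-in probabilities.** All probabilities are empirical counts over
  the observed compounds, with no pseudocounts or bias correction. This is
  the estimator that reproduces the package's worked toy examples exactly;
  like every plug-in MI estimate it is biased upward on small samples,
  which is why evaluation is done on held-out folds (below).
* **The marginal $P(x)$ is per-target.** Since each factor is computed on
  target $i$'s own compounds, the bit-pattern marginal is the marginal of
  that target's joint distribution. A pooled cross-target marginal would be
  an alternative reading, but it conflicts with per-target datasets being
  assembled independently, and it would make each factor depend on the
  other targets' compound sets.
* **Base-2 logarithms** throughout, with $0 \log 0 = 0$.
* **Sparse pattern counting.** The joint variable over $m$ selected bits
  has $2^m$ conceivable patterns; only patterns actually observed are
  enumerated (at most one per compound), since unobserved patterns have
  zero empirical probability. Pattern ids are re-compressed after every
  column so they never overflow. A dense $2^m$ enumeration exists in the
  test suite as an independent oracle for $m \le 10$.
* **Clamping.** Floating-point cancellation can produce tiny negative MI
  values for independent bits; these are clamped to 0. Per-target factors
  are clamped to at most 1.
* **Degenerate targets.** If a target's labels are constant,
  $\mathrm{SE}(Y_i) = 0$ and the normalization is undefined; the package
  raises an error naming the target rather than silently dropping it, so
  the caller decides whether to exclude it.

## The greedy selector

`aic_max_select()` adds, at each of `n_select` steps, the remaining bit
maximizing the AIC of the selection plus that bit. Scoring candidates
jointly with the current selection is what prevents redundancy: a copy or a
negation of an already-selected bit has zero gain, so it is only picked
once nothing with positive gain remains.

Deliberate choices where the procedure itself leaves room:

* **Tie-breaking** is to the lowest index in feature-universe order,
  making runs deterministic and reports byte-reproducible.
* **Subsample heuristic.** With `subsample_size = n`, each iteration draws
  *one* uniform random subset of $\min(n, |\text{selected}|)$ selected bits
  and scores every candidate jointly with that same subset. Drawing one
  subset per iteration (rather than per candidate) keeps the comparison
  between candidates fair and costs one draw per step; the candidate itself
  is always appended to the conditioning set. The conventional setting for
  thousand-bit universes is `n = 10`.
* **Trace semantics.** The recorded `aic_trace` is the exact AIC of the
  full selection after each step, recomputed independently of any
  subsampling, so information curves are comparable across configurations.
  In exact mode (`subsample_size = NULL`) the trace is non-decreasing by
  MI monotonicity.
* **Stopping** is a fixed `n_select` only; there is no plateau detection.
  Typical representation sizes to compare are 25, 50 and 100 bits.
* **RNG.** The selection call owns a seeded RNG stream
  (`withr::with_seed`) and never perturbs the caller's RNG state.

`exhaustive_best_subset()` enumerates all subsets of a given size and is
the exact oracle for small universes; a guard (default $10^6$ subsets)
refuses instances where enumeration is infeasible. The greedy result can
never exceed the exhaustive optimum, and equals it when the informative
bits contribute independently.

## Evaluation protocol

`evaluate_reduced_representation()` runs k-fold cross-validation (default
$k = 10$): in each fold, selection is re-run on the pooled training
compounds of *all* targets (each target keeps its own dataset inside the
AIC computation), then a classifier is trained per target on the training
fold restricted to the selected bits and scored on the held-out fold by the
Matthews correlation coefficient

$$
\mathrm{MCC} = \frac{TP \cdot TN - FP \cdot FN}
 {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}} .
$$

Held-out compounds never influence selection or training; the test suite
verifies this by poisoning test folds and asserting the in-fold selection
is unchanged. `information_score_cv()` is the classifier-free variant,
scoring held-out normalized MI.

Further choices:

* **MCC with a zero denominator factor** (e.g. a single-class prediction)
  is defined as 0, the standard convention.
* **Stratified folds by default.** Plain random partitioning of a 9:1
  inactive:active dataset easily produces folds with almost no actives at
  small n; stratification keeps the class ratio per fold while remaining a
  random equal-sized partition. A flag restores unstratified splits.
* **The classifier is pluggable** — any `list(fit =, predict =)` pair on
  binary matrices. The default is a random forest
  (`classifier_random_forest()`), a standard strong baseline for activity
  prediction; classifier internals are outside the package's scope.

## The synthetic data generator

`generate_multitarget_data()` produces multi-target collections with known
ground truth so the whole pipeline is testable without any database access.
Per target it draws an independent compound set with:

* `n_actives` actives and `round(n_actives * inactive_ratio)` putative
  inactives; the default ratio is 9 inactives per active, the standard
  decoy ratio in virtual-screening benchmarks;
* a small set of *informative* bits that determine activity through a
  per-target rule — by default the AND of a pair of informative bits,
  pairs cycling through the pool so every planted bit matters to some
  target;
* *redundant* bits that are exact copies or negations (alternating by
  index) of informative bits, to exercise the selector's redundancy
  avoidance;
* *noise* bits independent of everything;
* optional label noise (independent flips).

Default `bit_prevalence` is 0.5, the maximum-entropy choice that makes each
planted bit individually as informative as possible and keeps the AND-rule
rejection sampling efficient; real substructure bits are typically sparser,
which lowers per-bit information but changes nothing structurally.
Actives have their informative bits drawn conditioned on the rule holding;
putative inactives are drawn at *half* the prevalence conditioned on the
rule failing, mimicking vendor-library decoys being structurally distinct
from actives — which is also why discriminating decoys needs fewer bits
than discriminating confirmed inactives.

What the generator does **not** emulate: real fingerprint bit correlation
structure (beyond exact copies/negations), potency values and the
active/inactive thresholds applied to them, chemical series effects, or
class-dependent bit sparsity. Passing the recovery tests therefore shows
the algorithm finds planted joint structure under noise and redundancy at
realistic sample sizes and imbalance — not that any particular bit count
suffices for a particular receptor family; empirical results of that kind
require real screening data.

## Problem sizes in the test suite

The packaged checks run at desk scale, chosen to finish in minutes on one
CPU while keeping the statistical claims meaningful: oracle-equivalence on
200 random instances of up to 10 features and 50 compounds; parameter
recovery on 3 targets with 5 informative + 10 redundant + 85 noise bits and
200 actives per target (2000 compounds each) over 20 seeds, requiring the
first 5 picks to cover all planted bits up to copy/negation equivalence in
at least 90% of seeds; and a 10-fold CV harness check on 200 compounds with
a label-determining bit (mean MCC exactly 1) and a 10-permutation label
null (mean MCC within 0.1 of 0).

## Known limitations

* Binary labels only; potency regression and multi-class schemes are out
  of scope, as are continuous-feature MI estimators.
* Plug-in MI overestimates on small per-pattern counts, so exact-mode
  selection of very many bits on very few compounds will look better
  in-sample than held-out; use the CV scores for honest assessment.
* The greedy search has no optimality guarantee (submodularity does not
  hold for conditional MI gains in general); the exhaustive oracle bounds
  it only at small sizes.
* Fingerprint *computation* is upstream: the package consumes bit
  matrices and reports feature provenance strings, it does not interpret
  SMARTS patterns or generate fingerprints.
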