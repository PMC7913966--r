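---
title: "Evolving shapelet sets: model, operators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolving shapelet sets: model, operators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shapevolve)
```

## The problem

A *shapelet* is a short real-valued subsequence whose distance to a time
series discriminates between classes. Given a labeled collection of `N`
univariate series (possibly of unequal lengths; `M` denotes the shortest),
the classical approach scores candidate subsequences one at a time by a
per-candidate quality measure such as information gain and keeps the top k.
That procedure has two structural blind spots. First, similar subsequences
achieve similar scores, so the top of the ranking is populated by
near-duplicates of whichever single contrast is easiest — under class
imbalance, the k "best" shapelets may all encode the same majority-class
split and none of the remaining distinctions. Second, enumeration can only
ever return subsequences of the data, yet there are problems where no
subsequence of any input series separates the classes while a synthesized
sequence does.

`shapevolve` treats the whole shapelet *set* as the unit of search and
evolves it with a genetic algorithm. The number of shapelets, their lengths
and their values are all evolved jointly; because the variation operators
can average and splice sequences, the search space includes shapelets that
occur nowhere in the data.

## Distance transform

For a shapelet $s$ and series $t$ the package uses the sliding-window
minimum of the length-normalized squared Euclidean distance,

$$ d(s, t) \;=\; \min_{0 \le o \le |t|-|s|} \frac{1}{|s|} \sum_{i=1}^{|s|}
   \bigl(s_i - t_{o+i}\bigr)^2 , $$

over all $|t|-|s|+1$ windows. Two choices here are deliberate and are worth
stating because other conventions exist:

* **Length normalization.** Individuals hold shapelets of different
  lengths and compete inside one fitness value; unnormalized sums of
  squares would systematically favor short shapelets. Dividing by $|s|$
  puts all lengths on the same per-point scale.
* **All windows, no z-normalization.** Every admissible window is scored,
  including the final one, so an exact suffix match scores 0. Neither the
  windows nor the shapelets are z-normalized by default — distances live on
  the raw measurement scale, which is what the synthetic benchmarks and
  most amplitude-coded sensor problems want. A per-series standardization
  flag is available at dataset construction for problems where offset and
  scale are nuisance parameters.

Applying $d$ to every (series, shapelet) pair yields the `N × K` distance
matrix that downstream classifiers consume. Computing one entry costs
$(M-L+1)\,L$ pointwise operations, so an individual evaluation is
$O(K N M^2)$ in the worst case; `distanceMatrix(..., countOps = TRUE)`
reports the exact count, and the test suite asserts the bound.

## Fitness

A candidate set is scored by transforming the training collection and
fitting a multinomial logistic regression with a small fixed ridge penalty
(weight decay 0.01, deterministic BFGS via `nnet::multinom`) on the
transform; the error component of the fitness is that model's *in-sample*
mean log loss. Fitness is the lexicographic pair (error, complexity) with
complexity the sum of shapelet lengths: of two sets with equal error the
more parsimonious wins. Held-out loss inside the fitness would be less
optimistic but noisier and three times more expensive; since the final
model is refit and tuned by cross-validation anyway (below), the in-sample
loss is used purely as a relative ranking signal for the search.

The fitness model is intentionally distinct from the final classifier: a
cheap, fixed, deterministic ranker inside the loop; a cross-validated,
tuned model for reporting.

## The evolutionary loop

`evolve()` runs a generational scheme with the defaults population `P =
100`, at most `G = 100` generations, early stopping after `patience = 10`
generations without strict improvement of the elite, per-operator crossover
probability 0.4 and mutation probability 0.1.

* **Initialization.** Each of the `P` individuals draws its size uniformly
  from `2..W` and is built either by K-means (cluster `max(10K, 50)` random
  subsequences of one random common length; the centroids — generally not
  subsequences of the data — form the set) or by verbatim random sampling,
  with equal probability. `W` defaults to `ceiling(sqrt(M))`: initial sets
  are deliberately small and grow through mutation, which keeps early
  generations cheap and final sets compact.
* **Selection.** Tournaments of 3, sampled without replacement, with
  selection probability proportional to the reverse fitness *rank* inside
  the tournament. Rank weighting makes the selection pressure independent
  of the scale of the loss; small tournaments preserve diversity.
* **Crossover.** Three operators, each firing independently with
  probability 0.4 on consecutive pairs of selected parents: whole-set one-
  or two-point crossover (children are recompositions of whole shapelets;
  the cut position is common to both parents, which makes identical parents
  a fixed point and conserves the multiset of shapelets); point crossover on
  the value vectors of individual shapelets (cut drawn within the shorter
  partner); and the barycenter merge, the pointwise mean of two shapelets —
  with unequal lengths, the mean of the shorter with a uniformly chosen
  window of the longer. The merge is the operator that leaves the span of
  the data: averaging two in-data subsequences generally produces an
  out-of-data sequence.
* **Mutation.** Trim a random prefix or suffix (up to half) of one
  shapelet, never below the minimum length 4; remove one shapelet (sets
  keep at least one member); or append a fresh random subsequence. Appending
  is what lets sets grow toward the problem's true complexity, and ablating
  it measurably stalls the search (a test asserts this).
* **Elitism and stopping.** The best individual ever seen is injected into
  the next generation in place of the worst offspring and is exempt from
  crossover and mutation, so the logged best fitness is non-increasing by
  construction. The run stops at `G` generations or once `patience`
  generations pass without strict lexicographic improvement.

Every source of randomness flows through R's RNG, seeded once from
`config@seed`: identical data, configuration and seed reproduce the elite
and the log bit for bit.

## Final classifier and length tuning

`fitTunedLR()` grid-searches penalty type (ridge vs lasso) crossed with
inverse strength `C ∈ {0.001, …, 1000}` — 14 configurations — by stratified
3-fold cross-validated log loss (folds shrink with a warning when the
smallest class has fewer than 3 members), then refits the winner on all
rows; exact ties resolve toward stronger regularization. The glmnet penalty
is `lambda = 1/(C·n)`, the standard mapping from an inverse-strength
convention onto a mean-loss objective.

The one hyper-parameter worth tuning per dataset is the maximum shapelet
length, which limits overfitting to long, overly specific subsequences.
`tuneMaxLen()` evaluates the grid `{M/4, M/2, 3M/4, M}` (rounded up) by
running a reduced-budget evolution per candidate (default population 25,
30 generations) and scoring each resulting transform with 3-fold CV log
loss. The reduced budget estimates the *relative* merit of the caps, not
the final model; the test suite checks on data with a motif of length M/4
that a majority of seeds select a cap below M.

## Synthetic benchmarks

The package ships three generators; they are first-class, tested code, and
all tests and the acceptance analysis run on them.

**Imbalanced three classes** (`makeImbalancedThreeClass`, 25/5/5 per class
in train and test, length 100). Class 0 is a fixed smooth aperiodic
waveform plus small noise (sd 0.05) — many near-identical series. Classes 1
and 2 share that waveform *plus* a high-frequency alternating texture
(uniform local energy), carry larger noise (sd 0.3), and differ from each
other only in a short plateau motif (positive for class 1, negative for
class 2) placed at a per-series random offset strictly inside a flat
segment common to all classes. The construction is engineered so that the
distance from any majority-class subsequence to a minority series is
controlled by the texture — identically for both minority classes — and the
motif never enters a distance-minimizing window of such a candidate:
individually ranked candidates can isolate class 0 (that split has the
highest gain) but carry no information separating classes 1 and 2, while a
single shapelet matching one of the motifs separates them trivially. The
accuracy of the independent baseline on 35 test series is therefore an
intrinsically noisy quantity — its 10 minority predictions are essentially
exchangeable — and repeated seeds scatter it by a few test series around
0.86; the evolved two-shapelet transform reaches 1.0 across seeds.

**Nested amplitudes** (`makeNestedAmplitudeTwoClass`, 4 series, length 50).
Each series is a zero baseline with one rectangular plateau of width 20 at
a fixed position; class A has amplitudes {0, 4}, class B {1, 3}. A
rectangular (not smooth) plateau is essential: flat regions act as
universal tie-breakers, pinning the distance from any in-data candidate to
every non-matching series at the candidate's own energy, so the induced
ordering always interleaves the classes and no threshold is correct on all
four series — the test suite proves this by exhaustive enumeration rather
than assuming it. (A smooth bump fails here: its monotone edges let a
candidate trade amplitude against shift.) The amplitude-2 plateau — exactly
the barycenter merge of the two class-B bumps, and a subsequence of nothing
— has distance 1 to both class-B series and 4 to both class-A series:
a perfect split with wide margin.

**Generic motif data** (`makeMotifTwoClass`): noise series with a ±plateau
motif at random positions; separable by one shapelet per class at low
noise. This is the workhorse fixture for end-to-end and stability tests.

What these generators do *not* emulate: trends, warping, variable sampling
rates, multi-modal classes, label noise. Tests passing on them demonstrate
the search and scoring machinery, not performance on any real recording.

## Numerical and degenerate-input choices

* Distances are computed by vectorized window expansion; a guard clips
  negative rounding residue in the batched cross-product path. Agreement
  with a naive double loop is asserted to 1e-9.
* Information gain evaluates thresholds at midpoints between consecutive
  distinct sorted distances; among equal-gain splits the widest distance
  gap wins, and candidate rankings additionally use that margin as the
  tie-break before preferring shorter and earlier candidates — with many
  exactly-tied gains (pure splits), the margin is what distinguishes a
  robust split from a hairline one.
* All-equal distances admit no split: gain 0.
* K-means initialization falls back to the distinct subsequences plus fresh
  random draws when the sample contains fewer distinct rows than requested
  centroids.
* Sets never shrink below one shapelet; masking never trims below length 4;
  identical constant datasets therefore reach a fixed point where early
  stopping fires after exactly `patience` generations (tested).
* DTW (for run-to-run stability) uses absolute-difference local cost, full
  alignment, no window, and no path-length normalization by default — the
  accumulated optimal path cost, with `normalize = TRUE` available.

## Problem sizes used in the tests

The shipped tests run the full 25/5/5 × length-100 imbalanced experiment
(including complete candidate enumeration over lengths 4–100, about 166k
candidates) once, the 4-series enumeration proof exhaustively, 20 seeded
monotonicity runs, a 10-seed length-tuning study at length 32, and
stability/ablation runs at population 25. These sizes were chosen so the
whole suite completes in a few minutes while still exercising every claim
at the scale the experiments define.

## Known limitations

* Fitness evaluation refits a multinomial model per modified individual;
  for collections with thousands of series a cheaper proxy loss would be
  preferable.
* Only univariate series are supported; multivariate shapelets would need a
  different individual representation and operators.
* The independent baseline deliberately performs no self-similarity
  pruning — it is the naive comparator whose failure mode the imbalanced
  benchmark demonstrates, not a faithful reimplementation of any published
  shapelet-transform pipeline.
* The heterogeneous classifier ensembles sometimes layered on shapelet
  transforms are out of scope; the tuned logistic regression is the
  supported downstream model.
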