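# shapevolve

Evolutionary discovery of time-series shapelet sets in R.

## What it does and for whom

Shapelets are short subsequences whose sliding-window distance to a time
series discriminates between classes; classifiers fed the vector of
distances to a few good shapelets are accurate *and* interpretable, which is
why shapelet pipelines are popular for biomedical and sensor signals where a
prediction needs a visible, traceable justification.

Most discovery algorithms score candidate subsequences one at a time and
keep the top k. `shapevolve` instead evolves the whole shapelet **set**
with a genetic algorithm: an individual is a set
$S = \{s_1, \dots, s_K\}$, its fitness is the lexicographic pair

$$\bigl(\; \mathcal{L}(h(\mathrm{dist}(T, S)),\, y)\;,\ \textstyle\sum_{s \in S} |s| \;\bigr),$$

where $\mathrm{dist}(T,S)$ is the `N × K` matrix of sliding minimum
distances

$$d(s,t) = \min_{o} \tfrac{1}{|s|} \sum_i (s_i - t_{o+i})^2,$$

$h$ a ridge-penalized multinomial logistic regression and $\mathcal{L}$ its
mean log loss; the complexity term makes parsimony the tie-breaker. Set
size, shapelet lengths and shapelet values are all evolved jointly
(initialization by K-means centroids or verbatim sampling; one/two-point
and barycenter-merge crossovers; trim/remove/append mutations; rank-weighted
tournament selection; elitism; early stopping). Because the merge crossover
averages sequences, the search can return shapelets that occur **nowhere in
the data** — sometimes the only way to separate the classes.

The package also provides the classical baselines (exhaustive single-
shapelet search and independent top-k by information gain), a cross-
validation tuned ridge/lasso logistic regression on the distance transform,
dynamic-time-warping comparison of shapelets across runs, UCR-style
delimited readers/writers and JSON shapelet-set serialization, a small CLI
(`exec/shapevolve`), and three synthetic benchmark generators that
reproduce the two phenomena motivating set-level search: independent top-k
failure under class imbalance, and in-data enumeration failure against an
out-of-data shapelet.

## Worked example

```r
library(shapevolve)

# two classes of noisy series, distinguished by a short implanted motif
train <- makeMotifTwoClass(nPerClass = 10, length = 60, motifLength = 8,
                           noise = 0.1, seed = 1)
test  <- makeMotifTwoClass(nPerClass = 10, length = 60, motifLength = 8,
                           noise = 0.1, seed = 2)

res <- evolve(train, evolutionConfig(popSize = 50, generations = 40, seed = 7))
res$best
#> ShapeletSet: 8 shapelets, lengths 7/7/7/7/7/7/7/7 (complexity 56)
#>   fitness: error = 0.00151837, complexity = 56

tail(res$log, 1)
#>    generation   bestError bestComplexity bestSize  meanError evaluations
#> 11         10 0.001518371             56        8 0.07175238         481
res$reason
#> [1] "patience"

set.seed(7)
lr <- fitTunedLR(distanceMatrix(res$best, train), seriesLabels(train))
lr
#> TunedClassifier: ridge multinomial logistic regression, C = 1000
#>   classes: 1, 2 (3-fold CV)
evaluateAccuracy(lr, res$best, test)
#> [1] 1
```

The evolution log shows the elite's loss falling monotonically (elitism
guarantees it) until ten stagnant generations trigger early stopping; the
tuned classifier then separates the held-out collection perfectly — on this
toy the motif is the whole signal, and one evolved shapelet per class
captures it.

The same flow from the shell:

```sh
exec/shapevolve fit --train train.tsv --out S.json --seed 7
exec/shapevolve predict --train train.tsv --test test.tsv --shapelets S.json --seed 7
exec/shapevolve demo --experiment imbalance --seed 1
```

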