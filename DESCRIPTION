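Package: shapevolve
Title: Evolutionary Discovery of Time-Series Shapelet Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers sets of discriminative subsequences (shapelets) from
    labeled univariate time-series collections with a genetic algorithm. A
    candidate solution is a whole shapelet set whose sliding-window minimum
    distance transform is scored by the in-sample loss of a penalized
    multinomial logistic regression, so set size, shapelet lengths and
    shapelet values are evolved jointly and discovered shapelets need not be
    subsequences of the input series. Includes exhaustive and top-k
    information-gain baselines, a tuned logistic-regression classifier on the
    distance transform, dynamic-time-warping stability comparison of runs,
    and generators for structured benchmark datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    nnet,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'dataset.R'
    'shapelet-set.R'
    'distance.R'
    'config.R'
    'fitness.R'
    'operators.R'
    'evolve.R'
    'baselines.R'
    'classify.R'
    'synthetic-data.R'
    'stability.R'
    'io.R'
    'cli.R'
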