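---
title: "Methods: GA-optimised MLP classification for screening tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GA-optimised MLP classification for screening tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`gamlp` couples two components. The *inner* component is a two-hidden-layer
feedforward perceptron for binary classification: hidden layers of sizes
$(h_1, h_2)$ with a shared hidden activation, a sigmoid output unit, and
binary cross-entropy loss with a small L2 weight penalty
($\alpha = 10^{-4}$). The *outer* component is a generational genetic
algorithm whose chromosomes are four real genes in $[0, 1)$ decoding, by
scaled flooring, to the network design: activation (identity, logistic,
tanh, relu), solver (L-BFGS, gradient descent with momentum, Adam), and
$h_1, h_2 \in \{1, \dots, 50\}$. The fitness of a chromosome is the
stratified 5-fold cross-validated accuracy (as a percentage) of the
network it decodes to, trained under a fixed regime: learning rate 0.001,
momentum 0.90 (used by the momentum solver only), at most 200 iterations.

The decoding is total and deterministic: $\mathrm{activation} =
\lfloor 4 g_1 \rfloor$, $\mathrm{solver} = \lfloor 3 g_2 \rfloor$,
$h_i = \lfloor 50\, g_{i+2} \rfloor + 1$. Real-valued genes keep crossover
and mutation closed over valid chromosomes; the decoded space has
$4 \times 3 \times 50 \times 50 = 30{,}000$ points, far fewer than the
number of fitness calls a full GA run could make, so fitness values are
cached by decoded chromosome and each distinct design is trained at most
once per dataset.

### GA operators and their defaults

| Parameter | Default | Role |
|---|---|---|
| population size $n$ | 50 | chromosomes per generation (must be even) |
| generations $g_{max}$ | 200 | stopping criterion |
| crossover probability $P_c$ | 1.0 | single-point suffix exchange, cut $\in \{1,2,3\}$ |
| mutation probability $P_m$ | 0.001 | per-gene Bernoulli, uniform resample on $[0,1)$ |
| tournament size $k$ | 4 | parents sampled without replacement, fittest wins |

Replacement is generational and non-elitist: each generation performs
$n/2$ rounds of (select two parents, cross over, mutate both children),
and the $n$ children replace the parents wholesale. Because the population
itself can lose its best member, a global-best *archive* outside the
population records the best chromosome ever evaluated, which makes the
reported best fitness non-decreasing by construction. Ties in tournaments
go to the lowest population index, so runs are bit-reproducible given the
seed.

Two operator details are deliberate design choices where the field's
conventions vary: mutation is per-gene (not per-chromosome) with a full
uniform resample rather than a local perturbation, and tournament
contestants are drawn without replacement. Both choices favour
reproducibility and simplicity; neither changes the search's qualitative
behaviour on this small a gene space. A consequence worth knowing:
single-point crossover never creates new gene *values*, so novel
hidden-layer sizes can enter the population only through the initial draw
and through mutation. With $P_m$ at its default, discovery of any
particular extreme decoded value (say $h_1 = 50$, a 2% slice of gene
space) is driven almost entirely by the initial population, and the
probability that a short scaled-down run ever samples it is well below 1.
Raising $P_m$ or $n$ raises that probability in the obvious way.

### MLP training

All three solvers run full-batch with the analytic backpropagation
gradient. L-BFGS delegates to `stats::optim`; gradient descent uses
classical momentum $v \leftarrow \mu v - \eta \nabla$, and Adam uses the
standard $(\beta_1, \beta_2, \epsilon) = (0.9, 0.999, 10^{-8})$. Weights
are Glorot-uniform initialised from the training seed, biases start at
zero. Output probabilities are clipped to $[10^{-12}, 1 - 10^{-12}]$
before the loss; a non-finite loss aborts training with an error rather
than returning a silently broken model. Prediction thresholds the output
probability at 0.5. Full-batch training was chosen over minibatching for
exact reproducibility; at the row counts this pipeline targets (hundreds
of patients) it is also faster in R.

## The pipeline around the model

**Preprocessing.** The canonical screening table has 32 risk factors and
four binary test outcomes, with `?` marking refusals. Factors 27 and 28
(time since first/last STD diagnosis) are dropped as mostly missing, every
row with a remaining missing cell is removed, and continuous factors are
min-max scaled to $[0, 1]$ (binary 0/1 factors pass through; constant
columns map to 0). Min-max was chosen over standardisation because it
keeps MLP inputs bounded and commensurate with the untouched binary
columns. The row-filter rule is the one point the upstream protocol leaves
genuinely open; complete-case filtering on retained columns is the rule
that reproduces the reference row count (668 of 858), and `preprocess()`
warns if an 858-row input lands elsewhere.

**Balancing.** Random oversampling duplicates minority rows uniformly with
replacement to exact balance. Duplication (rather than SMOTE-style
interpolation) is the protocol this pipeline family defines; its
interaction with cross-validation is discussed below.

**Feature selection.** Four modes per target: `pca2` (scores on the two
leading principal components), `all30` (identity), `top18` and `top10`
(columns of the leading factors of a random-forest Gini-importance
ranking, in ranking order). The packaged reference rankings are the
published orderings for the four targets and are the default for defining
scenarios; `ranking_source = "recompute"` refits a 500-tree seeded forest
instead. PCA components follow a fixed sign convention (largest-magnitude
loading positive) so fitted models are platform-reproducible. No varimax
or oblique rotation is applied: rotation would change none of the scenario
definitions, and no rotated loadings exist to compare against.

**Evaluation.** Metrics come from the confusion matrix with disease as the
positive class: accuracy, sensitivity, specificity, precision, and F1
$= 2 S P / (S + P)$ on the percentage scale. Zero-denominator cases return
0 and are flagged `undefined` rather than erroring or returning `NaN`, so
degenerate folds stay visible but aggregable. Folds are stratified
(shuffled within class, dealt round-robin); per-fold metrics are
macro-averaged by default, with pooled-count aggregation available (the
two differ once folds are uneven or degenerate).

### Leakage placement

The upstream protocol balances the dataset (step 1) before cross-validating
(step 4) without stating whether balancing ever sees test data. Both
placements are therefore first-class here:

- `fold_safe` (default): oversampling, PCA, and importance rankings are
  fitted on the training folds only and applied to the untouched test
  fold. This is the scientifically sound protocol.
- `paper_global`: the full dataset is balanced and the feature context
  fitted once, before splitting. Duplicates of a test row can then sit in
  the training folds, which inflates every metric — duplicate-sensitive
  methods like k-NN approach 100% sensitivity on rare-positive data under
  this mode, which is exactly the signature the published headline numbers
  show. The test suite checks the direction of the gap rather than any
  particular magnitude.

Because of this under-specification (and because the real table must be
downloaded separately), the published headline accuracies are treated as a
reproducible *experiment* (`paper_global` mode on the real CSV), not as a
correctness target for the package.

## The synthetic generator

`generate_synthetic()` emulates the schema, not the joint distribution, of
the real table: right-skewed continuous factors (an age-like column and
years-like columns from gamma draws), Bernoulli binary factors, and one
binary outcome per configured target drawn from a logistic model on its
standardised signal factors with the intercept at the target prevalence.
After the Bernoulli draw, labels of the rows nearest the decision boundary
are flipped until the positive count equals `round(n * prevalence)`
exactly — this makes prevalence assertions deterministic instead of
approximate. Defaults are the emulated schema's study conditions: 858
rows, 30 factors, prevalences 4.5/9.4/5.8/6.7%. What the generator does
*not* emulate: the real table's factor correlations, its structured
missingness (refusals cluster by patient and by question block), and its
measurement noise. Tests passing on synthetic data therefore demonstrate
the pipeline's mechanics and statistical sanity, not clinical performance
on the real table.

`make_separable()` is the complementary extreme: two spherical Gaussian
clouds with means `margin` apart along a random direction, balanced
labels. At margin 6 the Bayes error is ~0.1%, so any adequately trained
classifier should approach 100% — it isolates harness bugs from modelling
difficulty.

## Problem sizes and numerical choices

The packaged checks run at deliberately desk-scale sizes, chosen once as
the smallest sizes at which each property is sharply testable: the
end-to-end GA-MLP check uses 400 rows, 30 features, margin 6, a
population of 10 over 10 generations; the null-data check uses 400 rows at
prevalence 0.5 with a 6×4 GA; planted-signal recovery uses 600 rows,
prevalence 0.15, three factors with log-odds effects of 2 per SD, and
20 seeds of a 500-tree forest; the GA's analytic-fitness checks use the
full 50×200 configuration since they need no network training. The full
protocol (population 50, 200 generations, all 160 experiments) is exposed
through the same functions and the `grid` CLI command; it is a
compute-budget decision for the user, not a different code path.

Numerical conventions worth recording: min-max scaling maps constant
columns to 0; PCA pads with zero-variance components (with a warning) when
the matrix rank falls below the requested dimension; importance ties break
by ascending factor number; tournament ties break by lowest population
index; the Adam/SGD iteration cap counts epochs while the L-BFGS cap is
passed to `optim` as its iteration limit; division-by-zero metrics are 0
with a flag. A single global seed fans out to per-component seeds through
a fixed derivation, so the fold split, the oversampling draw, each fold's
network initialisation, and the GA stream are all independently
reproducible.

## Known limitations

- The MLP trainer is full-batch; very large tables would want minibatched
  solvers.
- CD-KNN follows the centroid-displacement idea (assign the class whose
  local centroid among the k nearest neighbours moves least when the query
  joins it); the originating description is not fully specified in this
  pipeline's sources, so the implementation documents itself as an
  approximation.
- AdaBoost is discrete SAMME over depth-1 stumps, the textbook variant.
- No imputation, SMOTE, RFE, or cost-sensitive learning; these are out of
  scope by design.
- Recomputed importance rankings will generally not equal the packaged
  reference rankings, since forest settings and the fitting population
  (balanced vs raw) are not recorded upstream; both sources are exposed so
  users can compare.
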