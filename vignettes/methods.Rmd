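---
title: "Methods: partial-correlation networks and Bayesian DAG averaging for questionnaire data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partial-correlation networks and Bayesian DAG averaging for questionnaire data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psynet)
```

## The analysis this package implements

`psynet` implements a two-stage network analysis of questionnaire data of
the kind used to map psychological constructs — here the emulated study
design is dissociative experiences ("felt sense of anomaly") measured
alongside eleven candidate mechanisms (cognitive appraisals, responses to
dissociation, affect intolerance, alexithymia, attentional control, body
vigilance, anxiety sensitivity, self-efficacy, perseverative thinking,
negative meta-emotion, and beliefs about being overwhelmed) in a large
online sample.

**Stage 1 (undirected).** After exclusions, imputation, scale scoring and
a rank-based inverse normal transform, the scale totals are modelled as a
Gaussian graphical model (GGM): missing entries of the precision matrix
$K$ encode conditional independencies and the edge weights are partial
correlations $r_{ij} = -K_{ij}/\sqrt{K_{ii}K_{jj}}$.  Sparsity is chosen
by unregularized refitting with extended-BIC (EBIC) model selection — the
procedure known in this literature as `ggmModSelect` — and the result is
assessed by non-parametric bootstrap (edge accuracy, edge-difference
tests) and case-dropping bootstrap (centrality stability).

**Stage 2 (directed).** The same gaussianized totals are scored against
directed acyclic graphs (DAGs) with a Gaussian marginal likelihood
(BGe-type score).  A Markov chain Monte Carlo sampler draws a large DAG
sample from the structure posterior, and quantities of interest are
posterior model averages over that sample: the share of DAGs containing a
directed pathway between two constructs, the mean standardized total
causal effect conditional on the pathway being present (with equal-tailed
5th–95th percentile credible intervals), the share of path-present DAGs
containing the direct edge, and a thresholded "mixed graph" retaining
pairs present in over 50% of sampled DAGs and drawing arrowheads only for
orientations stable in over 90% of them.

Because participant-level questionnaire data of this kind is typically
not shareable, the package ships a synthetic-data generator that plays
the role of ground truth: every stage of the pipeline is validated by
parameter recovery against known structures, by exact small-instance
oracles, or by hand-enumerable fixtures.

## The synthetic-data generator

The generator is first-class, tested code, and defines the conditions
under which the pipeline is validated:

* **Structural model.** A weighted DAG over the constructs with a
  linear-Gaussian structural equation per node,
  $X_j = \sum_{k \in pa(j)} w_{kj} X_k + \varepsilon_j$.  The DAG
  machinery downstream assumes multivariate normality after
  gaussianization, so this is the matching generative family.  The
  implied covariance $(I-W)^{-\top} D (I-W)^{-1}$ is available in closed
  form and is used as a test oracle.  `unit_variance_noise()` rescales
  residual SDs so that marginal variances are exactly 1, making the edge
  weights directly comparable with standardized effect estimates.
* **Measurement model.** Each construct is emitted as `n_items` parallel
  Likert items: item latent $= \lambda z + \sqrt{1-\lambda^2}\,e$,
  discretized at equiprobable standard-normal thresholds.  Equiprobable
  thresholds keep category frequencies balanced and make Cronbach's
  alpha approximable by large-sample Monte Carlo, which is how the
  scoring stage is tested.  Reverse-coded items are emitted flipped so
  that scoring must un-flip them.  The default loading is
  $\lambda = 0.8$ per scale, chosen to land the emitted alphas in the
  0.7–0.97 band questionnaire batteries of this kind report.
* **Scale battery.** `default_scale_specs()` mirrors the twelve
  instruments of the emulated study (e.g. 35 items scored 0–4 giving a
  0–140 dissociation total; 10 items scored 1–4 giving a 10–40
  self-efficacy total).  Which items are reverse coded is not derivable
  from published score ranges, so the reverse sets are synthetic choices
  that exercise the code path.
* **Missingness** is MCAR only, applied cellwise at a default 2% rate
  (enough to exercise imputation and to push a realistic share of rows
  over the 20%-per-scale exclusion threshold, mainly through the
  4-item body-vigilance scale).  No MAR/MNAR mechanisms are modelled:
  the exclusion and imputation logic under test does not depend on the
  mechanism, and the study itself does not state one.
* **Ages** are drawn from a normal distribution with mean 45.6 and SD
  14.7 years (the emulated cohort's values), rounded, floored at 16 so
  that under-age rows exercise the inclusion filter.
* **Default dimensions** are 12 constructs and n = 6161 respondents;
  tests use smaller n so the suite stays fast, and state the sizes they
  use.

What passing tests do *not* show about real data: the generator has no
item-level differential functioning, no ordinal-polychoric structure, no
informative missingness, and its constructs are exactly
linear-Gaussian.  Recovery results are therefore statements about the
implementation, not about the robustness of the method to violations of
those assumptions.

## Preprocessing

Exclusions are applied in a fixed, logged order with one primary reason
per row: (1) below the minimum age 18; (2) more than 20% missing items
in *any single* scale; (3) age strictly above mean + 2 SD, with the mean
and SD computed on the rows surviving the inclusion step.  With a cohort
mean of 45.6 and SD of 14.7 this puts the cutoff at 75, so 76-year-olds
are excluded — the boundary the tests pin down.  A single filtering pass
defines the cohort; the filter is not iterated to a fixed point (trimming
a tail always lowers the recomputed cutoff slightly, so iterating would
not terminate at the published rule).

Missing items are imputed by chained equations with predictive mean
matching (k = 5 donors), cycling linear models over item columns;
observed cells are never altered and imputed values stay in the item's
observed support.  Imputation runs at item level, before scoring,
because the reliability coefficients are item-level quantities.  How an
analysis should pool several imputations into one network is genuinely
open; the package's convention is to estimate the correlation matrix in
each of the `m` completed datasets (default m = 5) and average the
matrices before network estimation, with `m = 1` available as a single
stochastic imputation.  The DAG stage consumes the first completed
dataset; a posterior-across-imputations convention is deliberately out
of scope.

Gaussianization is the rank-based inverse normal transform
$\Phi^{-1}((\mathrm{rank} - 0.5)/n)$ with ties averaged, then an exact
centre/scale to mean 0, SD 1.  The offset and tie rule are one of
several dialects in circulation; this one is fully rank-based, so the
transform is invariant to any strictly monotone transformation of the
raw totals, which is the property the tests assert.

## GGM estimation

`ggm_model_select()` implements the unregularized EBIC stepwise search:

1. A graphical-lasso path (100 log-spaced penalties from the largest
   absolute off-diagonal correlation down to 1% of it, warm-started)
   proposes candidate sparsity patterns.  The penalty is used *only* to
   seed candidates; no regularized estimate is ever reported.
2. Every distinct pattern is refitted without penalty — the
   maximum-likelihood concentration matrix under zero constraints, by
   node-wise regressions iterated to a $10^{-12}$-scale tolerance — and
   scored by $\mathrm{EBIC} = -2\ell + E\log n + 4\gamma E\log p$ with
   $\gamma = 0.5$, the field's customary default, exposed in the
   configuration.
3. Best-first stepwise search: every single-edge addition or removal is
   refitted and scored, the best strictly improving move is taken, and
   the search stops when none improves.  Best-first (rather than
   first-improvement) makes the search deterministic and independent of
   edge enumeration order.

The refit guarantees $(K^{-1})_{ij} = S_{ij}$ on edges and the diagonal
to $10^{-6}$ and *exact* structural zeros elsewhere — a checkable oracle
the acceptance suite enforces.  Inputs are correlation matrices; data
are gaussianized to unit variance upstream, so correlation and
covariance coincide, and anything else is converted with a warning.

Centrality follows the conventions of this literature: strength is the
sum of absolute edge weights; closeness and betweenness use edge lengths
$1/|w|$, with betweenness counting shortest-path memberships (endpoints
excluded, ties split equally) — validated against a brute-force
Floyd–Warshall path-count oracle.

## Bootstrap stability

Non-parametric bootstrap resamples rows with replacement and re-runs the
full model selection per replicate; absent edges enter the draw matrix as
exact zeros so inclusion frequencies and rectangular summaries fall out
directly.  The resampling plan depends only on `(seed, B, n)`, never on
the estimator.  Per-edge 95% intervals are empirical quantiles; two
edges are "significantly different" when the interval of their weight
difference excludes zero.  The full-scale profile uses B = 5000
replicates; the test profile uses 200–500.

The case-dropping bootstrap recomputes centralities on subsamples at
drop fractions 0.05–0.75 and reports the CS coefficient: the largest
drop fraction at which the correlation with the full-sample centrality
stays at or above 0.7 in at least 95% of replicates, with every smaller
fraction also qualifying (a monotone reading of the convention).  The
correlation flavour is Spearman by default and configurable, since the
source literature varies.

## DAG posterior

**Score.** The Gaussian (BGe-type) local score with normal-Wishart
hyperparameters $a_\mu$ (default 1) and $a_w$ (default $p+2$, weakly
informative), prior mean zero and prior scale $t I$ with
$t = a_\mu(a_w - p - 1)/(a_\mu + 1)$.  The score is score-equivalent —
Markov-equivalent DAGs receive identical totals, which the suite checks
over covered-edge reversals to $10^{-8}$.  All $p\,2^{p-1}$ local scores
are precomputed into full per-node tables (requiring $p \le 16$; at the
study's $p = 12$ this is 24,576 determinants of principal submatrices,
computed once).  A per-edge log-penalty can be folded into the tables as
a sparsity prior; it defaults to 0 (uniform structure prior).

**Prior and oracle.** All samplers and the exact oracle target the same
posterior, proportional to the product of local scores under a uniform
prior over DAG structures.  This choice is deliberate: the partition
sampler below targets exactly this posterior (each DAG has a unique
layering), and an order-modular prior would have made the sampler and
any order-based oracle target different distributions.  The exact oracle
therefore sums over *DAGs*, not orders, using the inclusion–exclusion
recurrence over sink sets — exponential in $p$, refused above $p = 14$,
and validated against brute-force enumeration of all 25 DAGs at
$p = 3$.

**Samplers.** `edge_mh` is Metropolis–Hastings over single-edge
additions, deletions and reversals: an ordered pair is proposed
uniformly; an existing edge flips a coin between deletion and reversal;
acyclicity violations are rejected; the asymmetry between add and
delete proposals contributes the exact factor 2 Hastings correction.
`partition` (the default, matching the method named by this literature)
moves on ordered node partitions — the unique layering of a DAG in which
each node has at least one parent in the immediately preceding block —
scoring a partition by marginalizing each node's parent sets with
subset-sum (zeta-transformed) tables, then drawing a concrete DAG
conditional on the partition for each retained sample.  Node moves
re-insert a removed node uniformly over the $2k'+1$ slots of the reduced
partition (a symmetric proposal), plus occasional two-node swaps.  Both
samplers agree with the exact oracle to well under 0.05 max-absolute
edge-probability gap at the tested sizes.

The full-scale preset is $10^7$ iterations retaining 50,000 DAGs after
20% burn-in; tests and the demo profile use $2\times10^5$ iterations at
$p \le 12$, where the chains already pass the exact-oracle and
between-chain checks.  Burn-in, thinning and the hyperparameters are
recorded in the output metadata rather than asserted as anyone's
original settings.

## Causal-effect averaging

For each sampled DAG the path coefficients are refitted by least squares
of each node on its parents (normal equations on the cross-product
matrix; collinear parents fall back to a minimum-norm solution with a
warning).  Refitting per structure is the simplest estimator consistent
with the reported pipeline; drawing coefficients from a parameter
posterior is out of scope.  The total effect of $x$ on $y$ in one DAG is
the $(x,y)$ entry of $(I-W)^{-1} - I$, identical to the sum over
directed paths of coefficient products (checked to $10^{-10}$ on 1000
random DAGs).

The reported summary for an ordered pair follows the conventions of the
two-block effect tables: `pathway_present_pct` is the share of *all*
sampled DAGs with a directed path; the causal effect and its 90%
credible interval (equal-tailed 5th–95th percentiles) are computed over
the path-present DAGs only; `direct_edge_pct` is a share *of the
path-present subset*; and the direct effect averages only over DAGs
containing the direct edge.  "Effects" are standardized (the variables
are gaussianized to unit variance), which is how the z-scored effect
convention is interpreted here.  The credible intervals reflect
variation across sampled DAGs only, not across imputations.  With a
concentrated discrete posterior the mean of the qualifying effects can
in principle fall just outside the percentile interval; with realistic
posterior spread it does not.

The mixed graph applies strict thresholds: a pair is retained when its
inclusion frequency (both orientations pooled — orientations are
mutually exclusive within one DAG, so the frequencies add) is strictly
above 0.50, and an arrowhead is drawn only when one orientation holds in
strictly over 0.90 of the retaining DAGs.  Frequencies exactly at a
threshold are excluded, and the tests pin the boundary on hand-counted
fixtures.  Pooling the orientations for the inclusion rule (rather than
thresholding each orientation separately) is the package's reading and
is stated in the output rather than asserted as unique.

A note on what "recovery" can mean here: from observational data a DAG
is identifiable only up to its Markov equivalence class.  When the
generating DAG has compelled edges only (unshielded colliders plus
orientation propagation), the posterior concentrates on the true DAG and
the averaged effects recover the generating weights closely; the
effect-recovery validation uses such a generator.  When orientations are
not compelled, posterior mass legitimately spreads over the class,
per-direction pathway shares split (summing to ~100% for adjacent
pairs), and conditional effects mix across members — a property of the
method, not a defect of the implementation.

## Pipeline, profiles and reproducibility

`run_pipeline()` sequences simulate → preprocess → GGM + bootstrap → DAG
sampling → effect averaging, writing CSV tables, GraphML/DOT graphs, a
JSON manifest with MD5 checksums of every artifact, and line-oriented
logs.  Every stage seed is a deterministic hash of the master seed and
the stage name, so skipping or reordering stages never changes another
stage's random stream; two runs from one configuration and master seed
are byte-identical, including the MCMC outputs.  Two presets exist:
`test` (n = 2000, B = 200, $2\times10^5$ iterations) sized for
continuous testing, and `full` (n = 6161, B = 5000, $10^7$ iterations,
50,000 retained DAGs) mirroring the emulated study's scale.  The
`psynet` script in `inst/scripts/` exposes the same stages as
subcommands.

## Numerical choices and limitations

* Constrained-MLE refits converge linearly; the iteration cap raises an
  explicit convergence error carrying the residual norm.
* The EBIC stepwise acceptance requires strict improvement
  ($>10^{-9}$), making the trace strictly decreasing by construction.
* Score tables are full-table caches, not LRU caches; this bounds the
  sampler at $p \le 16$, which covers the 12-construct design with
  headroom.  Above that the functions refuse with guidance rather than
  degrade.
* The exact posterior oracle is $O(3^p)$ per edge and intended for
  $p \le 14$ validation work only.
* Inclusion–exclusion sums use per-node normalized linear-space alphas;
  for pathological score spreads the alternating sum could lose
  precision, which the enumeration cross-check would expose at small p.
* Under an independence generator, single-dataset posterior edge
  probabilities are small on average but fluctuate with the sample
  (one pair in a few can reach ~0.1–0.3 at n = 2000); validation
  therefore reads the median across replicate datasets.
* The imputer assumes items are roughly linear in each other, which is
  adequate for Likert totals but is not an ordinal model; polychoric
  data models are explicitly out of scope.
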