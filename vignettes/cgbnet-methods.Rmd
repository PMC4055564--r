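---
title: "Conditional Gaussian Bayesian networks for phenotype prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional Gaussian Bayesian networks for phenotype prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgbnet)
```

## The model

`cgbnet` works with conditional Gaussian Bayesian networks (CGBNs): directed
acyclic graphs over a mix of discrete and continuous random variables. A
discrete node carries a conditional probability table (CPT) indexed by the
joint states of its discrete parents. A continuous node $X$ with continuous
parents $Z$ and discrete parents $\Delta$ is conditionally Gaussian,

$$X \mid Z = z, \Delta = j \;\sim\; N\!\left(\beta_{0j} + \beta_j^\top z,\ \sigma^2_j\right),$$

with a separate intercept, coefficient vector and residual variance per
discrete-parent configuration $j$. One structural restriction makes exact
inference tractable: a discrete node may never have a continuous parent.
The joint over mixed variables is then, for every full discrete assignment,
a multivariate Gaussian over the continuous layer — a finite Gaussian
mixture — and posterior queries have closed forms.

The intended use is case-control modeling: one binary discrete node is the
phenotype, the remaining variables (omics measurements, genotypes, clinical
covariates) are candidate predictors, and the object of interest is
$P(\text{phenotype} \mid \text{measurements})$.

## Scoring

Structure learning maximizes the Bayesian marginal likelihood of the data,
which decomposes into per-family terms.

*Discrete children* are scored by the BDeu form of the Dirichlet-multinomial
marginal likelihood: with $r$ child states, $q$ parent configurations,
equivalent sample size $\alpha$ (default 1) and cell counts $N_{ijk}$,

$$\log m = \sum_j \left[\log\Gamma(\tfrac{\alpha}{q}) - \log\Gamma(\tfrac{\alpha}{q}+N_{ij})\right] + \sum_{j,k}\left[\log\Gamma(\tfrac{\alpha}{rq}+N_{ijk}) - \log\Gamma(\tfrac{\alpha}{rq})\right].$$

*Continuous children* are scored, per discrete-parent configuration, by the
marginal likelihood of a Bayesian linear regression of the child on an
intercept plus its continuous parents under the conjugate
normal–inverse-gamma prior
$\beta \mid \sigma^2 \sim N(0, \sigma^2/\nu\, I)$,
$\sigma^2 \sim \mathrm{InvGamma}(\nu/2,\ \nu\sigma_0^2/2)$ (defaults
$\nu = 1$, $\sigma_0^2 = 1$). This form is proper, conjugate and standard
for conditional linear Gaussian scoring; the test suite pins it to direct
numerical quadrature of the defining integral rather than to any particular
closed-form reference. Empty configurations contribute zero — the marginal
likelihood of no data is one. All scores are natural logarithms computed
through `lgamma`, and parent-configuration indexing is row-major over
alphabetically sorted parents with each parent's states in declared order,
so parameter tables serialize identically across runs.

The same machinery yields the Bayes-factor screen
(`bayes_factor_filter()`): $\log BF$ of a candidate is its family score with
the phenotype as sole parent minus its parentless score. It is the intended
first step for domains with thousands of variables.

## Structure search

Four searches are provided, each respecting acyclicity (depth-first-search
cycle checks), the no-continuous-into-discrete restriction, and a
per-node parent cap (default 3, the main defense against data
fragmentation — the exponential growth of CPT cells with discrete parents):

* **K2 ordered search** (`learn_k2()`): nodes may only take parents earlier
  in an ordering. The default ordering (`k2_order()`) places the phenotype
  first — prediction is best when the phenotype has many children and no
  parents — and sorts the rest by ascending log Bayes factor of association
  with the phenotype, so the most plausibly independent nodes get the
  fewest candidate parents. Classical treatments of K2-style search leave
  the ordering statistic open; reusing the filter statistic is this
  package's documented choice. Parents are added greedily per child, and
  when the parent cap binds an add-one/drop-one swap is considered.
  Continuous families are learned before discrete families.
* **Greedy exhaustive hill-climbing** (`learn_greedy_exhaustive()`): from
  the empty graph, repeatedly apply the single best strictly improving edge
  addition (optionally also removals with `backtracking`). Deterministic
  tie-breaks by (parent, child) name.
* **Phenotype-centric search** (`learn_pheno_centric()`): builds only the
  phenotype's Markov blanket — first phenotype→variable edges, then
  co-parents of the accepted children. Cheapest option, and the phenotype
  never acquires parents.
* **Simulated annealing** (`learn_simulated_annealing()`): uniform random
  single-edge proposals; worsening moves accepted with probability
  $\exp(\Delta/T)$. $T_0$ is calibrated as the median absolute score change
  over 100 probe proposals. The default cooling factor is chosen so the
  geometric schedule reaches the floor ($10^{-8}$) exactly at the end of
  the proposal budget (default $n^3$): a fixed per-step factor would leave
  the chain hot for small budgets and effectively frozen for large ones.
  The best structure visited is returned, not the last.

All searches expose instrumentation (`n_evals`, greedy's
`max_sweep_evals`): the test suite checks the candidate-evaluation counts
against the intended complexity envelopes ($\tfrac{k}{2}n^2$ for K2,
$n^2 + kn^2$ per greedy sweep, $n + kn^2$ for phenotype-centric).

## Parameter learning and exact prediction

`fit_parameters()` uses posterior means: CPT entries
$(N_{ijk} + \alpha/rq)/(N_{ij} + \alpha/q)$ — never exactly zero, so
prediction cannot be derailed by empty cells — and, per configuration, the
normal–inverse-gamma posterior mean coefficients with residual variance
$b_n/(a_n - 1)$ (falling back to $b_n/a_n$ when the posterior shape does
not exceed one, and to the prior $\beta = 0$, $\sigma^2 = \sigma_0^2$ for
configurations with no data).

`predict_posterior()` computes the exact posterior of a discrete target
given arbitrary partial evidence: it enumerates the configurations of the
unobserved discrete variables and, for each, marginalizes the unobserved
continuous variables analytically (the continuous layer is jointly Gaussian
given the discrete assignment, built by topological recursion on means and
covariances). This is result-equivalent to conditional Gaussian
junction-tree propagation; the test suite verifies equality to an
independent dense-enumeration oracle at $10^{-10}$ and against
million-sample forward-simulation frequencies. A guard refuses queries
whose unobserved discrete space exceeds $2^{20}$ configurations — after
parent-capped structure learning, practical networks stay far below it.

`predict_dataset()` scores whole datasets row by row. Because every
variable in the phenotype's Markov blanket is observed, the posterior
factorizes over the phenotype's own family and its children's families; no
summation is needed and the computation vectorizes over rows. Values
outside the blanket provably cannot change the result (also verified
against full-evidence enumeration). Unseen discrete states in prediction
data are rejected with an error naming the offending value rather than
silently smoothed.

## Validation machinery

`roc_auc()` reports the Mann–Whitney AUC (ties count one half), the ROC
points, the area under the upper convex envelope (the performance
achievable by randomizing between thresholds), and a 95% confidence
interval from the DeLong structural-component variance
($AUC \pm 1.96\,SE$, clipped to $[0,1]$); the single-AUC interval reuses
the DeLong variance for coherence with the paired test. `delong_test()`
is the two-sided DeLong comparison of two score vectors on the same rows;
identical vectors return $p = 1$ by convention, and a degenerate
zero-variance difference returns the limiting value.

`cross_validate()` uses seeded stratified folds (small case-control sets
make unstratified folds fragile). Structure and parameters are re-learned
per fold from the training portion only — nothing from a held-out row ever
touches the model that scores it, which the suite checks by permuting
held-out labels and asserting the trained structure is bit-identical. Both
per-fold AUCs and the pooled AUC over concatenated held-out scores are
reported; the pooled value is the headline number because fold-level AUCs
are unstable at small $n$. With `tune = TRUE` a grid over
$\alpha, \nu \in \{0.5, 1, 2, 5, 10\}$ is searched by pooled CV AUC, ties
resolved toward the smaller (more regularizing at fixed scale) values.

`bootstrap_networks()` learns one structure per bootstrap resample and
reports per-edge inclusion fractions; resamples that lose a phenotype class
are redrawn. `consensus_network()` then rebuilds a single model by adding
edges in descending bootstrap frequency — skipping, not stopping at, edges
that would create a cycle or violate the CG restriction — and records the
fixed-structure cross-validated AUC after each addition, so the point of
diminishing returns is visible in the output path. Opposite edge directions
are counted as distinct edges; reconciling them into an undirected
consensus is a documented alternative this package does not take.

## The synthetic-data generator

`random_cgbn()` draws networks along a random node permutation with the
phenotype first, candidate edges only forward along the permutation (never
continuous→discrete), CPT rows from a symmetric Dirichlet(1), and
conditional Gaussian parameters with configuration-separated intercepts.
Defaults were chosen once to emulate a small case-control omics study and
then frozen:

* The phenotype is binary with a *uniform* marginal — balanced
  case-control designs are the norm, and heavily skewed Dirichlet draws
  would make $n = 25$ sampling and stratified CV degenerate.
* The phenotype parents each later *continuous* node with probability 0.7
  (a large Markov blanket of informative features, the regime where the
  true network predicts near the ceiling even at $n = 25$), while discrete
  background nodes — genotype-like structure — connect at the baseline
  edge probability 0.25. Phenotype-to-discrete signal would bypass any
  discretization of the continuous layer, which is exactly the phenomenon
  the discretization benchmark measures.
* Effect sizes: intercept separation per discrete-parent step and
  regression coefficients are drawn from $\pm[0.8, 1.3]$ with residual
  variances in $[0.8, 1.2]$ — standardized effects around one residual SD,
  typical of reproducible omics effect sizes. Much larger effects survive
  coarse binning nearly unscathed; much smaller ones make even the mixed
  model fail at small $n$.

`sample_dataset()` forward-samples in topological order.
`discretize_equal_width()` bins each continuous column into `bins`
equal-width intervals between its observed minimum and maximum; the maximum
falls in the last bin; training-derived edges can be reused on test data,
with out-of-range values clipped into the boundary bins, so no test
information leaks into the binning grid. Binned columns declare the full
`1..bins` state list (not only observed bins): with 25 training rows and 10
bins, test data routinely contain bins unseen in training, and a shared
state universe is what lets training-fitted CPTs score them.

What the generator does *not* emulate: heavy-tailed or skewed measurement
noise, missingness, batch effects, correlated noise across features, and
non-linear dependence. Passing tests therefore demonstrate correctness of
the algorithms and the qualitative economics of discretization, not
performance claims about any particular real assay.

## The benchmark experiments

`discretization_benchmark()` reproduces the mixed-versus-binned comparison:
10 random networks of 5 discrete + 15 continuous variables, training sets
of 25 rows, test sets of 400 rows (the test size only sets the precision of
the AUC estimate), greedy search with default priors, and the same pipeline
rerun after 10-bin equal-width discretization on the training grid. Under
the frozen defaults the mixed pipeline averages in the mid-to-high 90s (%)
while the binned pipeline loses on the order of 25 AUC points — the
data-fragmentation regime: a binned child's 2×10 CPT estimated from 25 rows
rarely justifies its BDeu complexity cost, so binned structure learning
finds far fewer of the true blanket members.

`discretization_gap()` probes the variables-comparable-to-samples regime:
25-node networks with node kinds chosen by a fair coin and uniform
phenotype connectivity, trained at $N = 25$, evaluated on 200 held-out
rows, 20 replicates, averaging the per-network difference between mixed
and binned test AUC. Replicates with exactly zero difference carry no
information about the cost of binning and are excluded from the average.
The mean loss comes out near 10–20 percentage points; it shrinks toward
zero as $N$ grows, which can be verified by passing larger `n`.

`scripts/acceptance.R` reruns both experiments from scratch at a
caller-supplied seed and writes the three summary numbers as JSON.

## Numerical and degenerate-input choices

* Scores and densities are accumulated in log space; mixture sums use
  log-sum-exp.
* Normal-equation solves use Cholesky factorizations of
  $\nu I + X^\top X$, which is positive definite for any design.
* Posterior-mean smoothing ($\alpha > 0$) means learned models have no
  zero CPT cells; a degenerate-evidence error can only arise from
  user-supplied zero-probability parameters.
* Constant columns discretize to a single-state column with a warning.
* Rows with missing values are dropped at construction with a reported
  count; the package is complete-case throughout by contract.
* Ties in every search and in the consensus ordering break
  lexicographically, making all procedures deterministic given their seed.

## Known limitations

Continuous phenotypes are out of scope (discrete targets only), as are
latent variables, dynamic networks, missing-data imputation and
multi-class AUC. Exact inference costs grow exponentially in the number of
*unobserved* discrete variables; the complexity guard makes the failure
explicit rather than silent. The conditional Gaussian restriction means
discrete-on-continuous dependence cannot be modeled directly — the standard
workaround is to reverse the modeling direction where the domain allows it.
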