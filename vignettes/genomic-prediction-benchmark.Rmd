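---
title: "Benchmarking genomic prediction for repeated litter-size records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking genomic prediction for repeated litter-size records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsbench)
```

`gsbench` replicates, at desk scale and on synthetic data, a benchmark
design for genomic prediction of pig reproduction traits: corrected
phenotypes derived from a pedigree repeatability model are predicted by
GBLUP, single-step GBLUP, a horseshoe Bayesian marker regression, and four
machine-learning regressors, under repeated five-fold cross-validation and
a forward split by birth date. This vignette documents the models, the
simulator, the numerical choices, and the limits of what the package's
passing tests demonstrate.

## The repeatability model and corrected phenotypes

Litter size is recorded once per parity, so a sow contributes one to three
records. The analysis model is

$$ y = Xb + Z_a a + Z_{pe}\,pe + e, \qquad
   a \sim N(0, A\sigma^2_a),\;
   pe \sim N(0, I\sigma^2_{pe}),\;
   e \sim N(0, I\sigma^2_e), $$

with herd-year-season (HYS) as the only fixed effect, $A$ the numerator
relationship matrix, and a permanent-environment effect absorbing
non-genetic covariance among a sow's parities. The default variance
components emulate total number born: $\sigma^2_a = 1.26$,
$\sigma^2_e = 8.95$, $h^2 = 0.12$. Only two of the three components are
published together with the heritability; the permanent-environment
variance is set to $\sigma^2_{pe} = 0.29$, the unique value that reconciles
$h^2 = \sigma^2_a / (\sigma^2_a + \sigma^2_{pe} + \sigma^2_e) =
1.26 / 10.50 = 0.12$.

Corrected phenotypes — the response used by every genomic method, so that
parental information is not double counted — are
$y_c(i) = \widehat{EBV}(i) + \overline{\hat e}_i$, the animal's EBV plus the
mean of its own estimated record residuals. Recordless animals receive
$y_c = \widehat{EBV}$ and are flagged; by default they are excluded from
reference sets, since a response that is pure parent-average information
carries no own-performance signal.

## AI-REML

`estimate_reml()` maximizes the restricted likelihood with
average-information updates. Numerically, the likelihood is evaluated
through the mixed-model equations rather than the marginal covariance:

$$ -2\ell_R = n\log\sigma^2_e + q_a\log\sigma^2_a + \log|A|
   + q_{pe}\log\sigma^2_{pe} + \log|M| + y'Py, $$

with $M$ the full MME coefficient matrix, factored sparsely (CHOLMOD via
the Matrix package). $\log|A|$ is the sum of log Mendelian-sampling
variances, a by-product of the same recursion that produces inbreeding
coefficients (Meuwissen–Luo) and Henderson's sparse $A^{-1}$. The score
uses the classical trace identities $\mathrm{tr}(A^{-1}C^{aa})$ and
$\mathrm{tr}(C^{pe,pe})$, computed as Frobenius norms of triangular solves
against the Cholesky factor; the AI matrix comes from the working vectors
$Z_a\hat a/\sigma^2_a$, $Z_{pe}\widehat{pe}/\sigma^2_{pe}$,
$\hat e/\sigma^2_e$. The unit tests verify the likelihood against a dense
GLS evaluation and the analytic gradient against central finite
differences.

Guards, chosen once and fixed:

* components are floored at $10^{-6}\,\mathrm{var}(y)$, so boundary
  estimates (e.g. $\sigma^2_a \to 0$ on null data) are representable;
* an AI step that leaves the parameter space or decreases the likelihood is
  retried damped (step fractions 1, 1/2, 1/4, 1/10, clamped at the floor)
  and, failing that, replaced by an EM step, which ascends by construction;
* components at the floor whose gradient points outward are held fixed
  (active set) — without this, the $1/\sigma^4$ terms of a boundary
  component poison the AI system and the optimizer crawls;
* convergence is a relative parameter change below $10^{-8}$, at most 200
  iterations; non-convergence returns the best iterate flagged
  `converged = FALSE`.

The heritability standard error is a delta-method transform of the inverse
AI matrix.

## Relationship matrices

`build_A()` is the tabular recursion (with inbreeding);
`build_A_inverse()` applies Henderson's rules with Meuwissen–Luo
inbreeding. `build_G()` uses VanRaden's first method,
$G = MM'/(2\sum_j p_j(1-p_j))$ with observed allele frequencies — the
construction is not uniquely fixed by the benchmark description, and this
is the default of the animal-breeding software family the design follows.
Frequencies are computed once on the full genotyped set, not per fold,
because $G$ is built once per dataset in the original workflow.

The single-step matrix uses the standard correction
$H^{-1} = A^{-1} + \mathrm{blockdiag}(G_w^{-1} - A_{22}^{-1}, 0)$ with
$G_w = (1-w)G + wA_{22}$ and $w = 0.05$ by default (exposed as a
parameter). $A_{22}^{-1}$ is a dense inversion of the genotyped block —
adequate at desk scale and documented so the partitioned sparse algorithm
can be swapped in. A blended $G_w$ that is still not positive definite is
an error, not silently repaired: increasing $w$ is the intended remedy.

In `fit_gblup()` the mixed-model solution is evaluated through the
equivalent covariance form
$\hat g = \sigma^2_g\,G[\cdot,\mathrm{ref}]\,V^{-1}(y-\hat\mu)$ rather than
by inverting $G$: with observed-frequency centering the columns of $M$ sum
to zero, so an unblended $G$ is always singular, while the covariance form
is the identical BLUP wherever $G^{-1}$ exists and extends it to the
positive semi-definite case. The equivalence with SNP-BLUP (ridge
regression of $y_c$ on centered dosages at
$\lambda = \sigma^2_e/(\sigma^2_g / 2\sum p_jq_j)$) is asserted to
$10^{-6}$ in the tests. Variance components are re-estimated per training
fold by REML — an eigendecomposition profile likelihood for GBLUP, and a
sparse MME profile in the variance ratio for ssGBLUP; the two routes are
cross-checked against each other on cases where both apply. Validation
animals stay in $G$ or $H$ but their phenotype rows are removed.

## Horseshoe marker regression

`fit_bayeshe()` is a Gibbs sampler for
$y_c = 1\mu + X\beta + e$ with
$\beta_j \sim N(0, \lambda_j^2\tau^2\sigma^2_e)$ and half-Cauchy priors on
$\lambda_j$ and $\tau$, implemented with inverse-gamma auxiliary variables
so every conditional is closed-form. Scaling the slab by $\sigma^2_e$
keeps the $\sigma^2_e$ update conjugate and the sampler stable. The exact
hierarchy of the Bayesian method the benchmark names ("the first form")
is published only in a separate methods paper; whether it uses a half-$t$
with $\nu \neq 1$ or an extra slab component is not stated in the
benchmark itself. Rather than guess, the package implements the standard
horseshoe and flags the difference here. The published chain settings
(50,000 cycles, 20,000 burn-in, thin 50; exactly 600 retained draws) are
the `"paper"` preset; tests use a `"test"` preset (5,000/2,000/5) at which
the null-shrinkage and spike-recovery checks already pass. Monomorphic
training markers carry no likelihood information after centering and their
effects are fixed at zero. Chains are exactly reproducible under a seed;
the sampler aborts with the iteration index on a non-finite draw.

## Machine-learning regressors

Features are raw dosages 0/1/2 without standardization, as in the
benchmark. SVR is libsvm's epsilon-insensitive dual (e1071); its objective
is tested against an independent interior-point QP solution. When every
training point lies inside the epsilon tube libsvm returns an empty model;
the fit then predicts the flat solution (the training mean). KRR is the
closed form $\alpha = (K+\lambda I)^{-1}y$ — the method *is* its formula,
so it is implemented directly and tested against primal ridge. RF is
`ranger` with `mtry` defaulting to all features, matching the regression
default of the reference implementation the benchmark used; tree count and
depth are the tuned hyperparameters.

Adaboost.R2 follows Drucker: the benchmark's description leaves the
per-sample loss and $\beta_t$ undefined, and adopting Drucker's linear loss
with $\beta_t = \varepsilon_t = \bar L_t/(1-\bar L_t)$ makes its two
equations exactly Drucker's algorithm. Weak learners are fitted on
weighted bootstrap resamples (size $n$, probabilities $D_t$) because
closed-form KRR has no native sample weights — a documented approximation.
A perfect weak learner floors $\beta_t$ at $10^{-10}$ and dominates the
weighted median; the fit is flagged.

Grid search scores each combination by the mean Pearson correlation over
an internal five-fold split of the training data only. The default
lattices (C ∈ {1,3,5,7,10,14}, γ ∈ {1e-6,1e-5,5e-5,1e-4,1e-3},
λ ∈ {0.01,0.07,0.1,0.9,1}, trees ∈ {100,250,400,430,500},
depth ∈ {∞,5,10}, rounds ∈ {50,60,70}) span the published optima. Ties
break toward stronger regularization (smaller C, larger λ, fewer trees) so
the argmax is reproducible under floating-point ties; an inner fold with
zero-variance predictions scores 0 with a warning. The package defaults of
each regressor are the published cross-validation optima, so benchmarks
can run without tuning.

## Evaluation protocol

`make_cv_plan()` partitions the genotyped animals into five groups per
replicate, 20 replicates by default; 2,566 animals give folds of 514/513
(the remainder goes to the earliest folds — the published "513 each" is
approximate). Every method consumes the identical plan, whose hash is
recorded in the result. `make_forward_split()` validates on animals born
after a cutoff (default January 2020). Accuracy is $r(y_c, PV)$;
unbiasedness the OLS slope of $y_c$ on $PV$; MSE/MAE per fold.

The Hotelling–Williams test compares two accuracies sharing $y_c$:

$$ t = (r_{12}-r_{13})\sqrt{\frac{(n-1)(1+r_{23})}
   {2\frac{n-1}{n-3}|R| + \bar r^2(1-r_{23})^3}}, \quad df = n-3, $$

the standard Williams form (the benchmark names the test without printing
a formula). It is applied per replicate to predictions pooled across the
five folds — each animal is predicted exactly once per replicate — a
pooling choice the source leaves open; per-pair, per-replicate results are
returned so other poolings can be computed. Its type-I error is verified
by simulation (2,000 null replicates of $n = 500$: rejection rate
0.05 ± 0.01). No multiplicity correction is applied, matching pairwise
reporting at $\alpha = 0.05$.

## The simulator, and what the tests do not show

`simulate_pedigree()` breeds discrete generations: each female of the
previous generation is mated to a random male, with a fixed litter size and
one birth year per generation. `simulate_genotypes()` gene-drops unlinked
markers from founder frequencies drawn in the configured MAF range.
`simulate_phenotypes()` builds breeding values from a random subset of
markers (QTL stay in the panel, since prediction uses the full panel) with
effects scaled so the founder additive variance equals $\sigma^2_a$ in
expectation, then adds HYS effects, permanent-environment effects and
residual noise. Genotyping status is a random subset
(`genotyped_fraction = 0.66`, reproducing the roughly 2,566-of-3,893
genotyped structure). One master seed yields deterministic per-stage child
seeds, so stages can be rerun independently and identical configurations
reproduce byte-identical datasets.

Two preset scales are used throughout: the desk default (~800 animals,
2,000 markers, 100 QTL) and `study_config()` (~4,000 animals, ~2,000 sows
with two records each, 20 HYS levels, 1,000 markers with 300 QTL — a
polygenic architecture appropriate for litter size; variance-component
recovery needs the polygenic signal, not a dense panel).

Deliberate omissions, hence limits on inference from green tests: markers
are unlinked (no LD — the analysis uses positions only for QC), there is
no selection or assortative mating, HYS levels are assigned at random
rather than by calendar structure, and the two-panel imputation step of
real data is out of scope (the concordance metrics are provided; the
imputation software is not run). Passing tests show the machinery is
correct under the generative model; they do not certify accuracy levels on
real populations, which the source data's proprietary status puts out of
reach.

## Acceptance computation

`scripts/acceptance.R` recomputes the recovery study end to end: 20
replicate `study_config()` populations, AI-REML per replicate, and the
replicate means of $h^2$, $\sigma^2_a$ and $\sigma^2_e$ written as JSON.
At these sizes a replicate costs a few seconds, the full script a few
minutes on one CPU. The same computation backs the first acceptance test,
with the test suite's other end-to-end checks (oracle equivalences,
Adaboost mechanics, test size, horseshoe shrinkage and recovery, protocol
fidelity) each under a minute.
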