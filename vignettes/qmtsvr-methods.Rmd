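---
title: "Multitask SVR genomic prediction: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multitask SVR genomic prediction: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mtsvr)
```

This vignette documents the statistical machinery in `mtsvr`, the design
choices that were genuinely open, and what the test suite does and does not
establish. It states no empirical result beyond what the package's tests and
`scripts/acceptance.R` themselves compute.

## The quasi-multitask SVR

### Single-trait ε-SVR on a precomputed kernel

For training records $(y_i, \mathbf{m}_i)$ with $\mathbf{m}_i$ a $p$-vector
of SNP dosages (0/1/2), the support vector regression
$y = b_0 + \phi(M)\beta + e$ is fitted by minimizing
$\tfrac12\beta'\beta + C \sum_i L_\varepsilon(e_i)$, where the
ε-insensitive hinge loss $L_\varepsilon$ ignores residuals inside
$\pm\varepsilon$ and penalizes the excess linearly. The dual is a box- and
equality-constrained QP in the multipliers $\alpha_i, \alpha^*_i \in [0, C]$
that touches the data only through a kernel matrix $K$, so any similarity
structure over individuals can be plugged in. Predictions depend only on the
dual solution: $f(x) = \sum_j (\alpha_j - \alpha^*_j) K_{xj} + b_0$, and
records with nonzero multipliers (support vectors) are the only
contributors — the ε-tube induces sparsity.

`svr_fit()` solves this dual by sequential minimal optimization in compiled
code, using the net-multiplier representation $\beta_j = \alpha_j -
\alpha^*_j$ (complementarity makes $\alpha_j \alpha^*_j = 0$ at the optimum,
halving the state). Working pairs are the maximal KKT-violating pair with
lowest-index tie-breaks, so the solver is deterministic. The bias is the
average implied bias over free support vectors ($0 < |\beta_j| < C$), with
the midpoint of the feasible bias interval as fallback. Convergence is
declared when the violating-pair gap falls below `tol` (default $10^{-3}$);
non-convergence within `max_iter` raises a typed error carrying the best
iterate.

### The multitask extension by data expansion

Rather than solving a true multitask SVR with $t$ simultaneous equality
constraints (a generalized SMO), the records of $t$ traits are stacked into
a single response (trait-major), each trait standardized by z-score using
training-row statistics, and the single-trait machinery is reused on a
block-structured kernel:

$$
Q = \begin{bmatrix}
\exp(-\theta_{11} \tilde D) & \rho_{12}\exp(-\theta_{12} \tilde D) \\
\rho_{12}\exp(-\theta_{12} \tilde D) & \exp(-\theta_{22} \tilde D)
\end{bmatrix},
\qquad \tilde D = D \circ D / p,
$$

with $D \circ D$ the element-wise squared Euclidean distance matrix over all
genotyped individuals and $p$ the marker count. Sharing $b_0$, $C$ and
$\varepsilon$ across traits keeps a single equality constraint, so the
standard SMO applies unchanged once $Q$ is precomputed. One display of the
stacked dual admits a per-trait-constraint reading; that is inconsistent
with a shared bias (one bias implies one constraint), and the
single-constraint reading is what is implemented.

Notes on this construction:

* **Squared distances are stored directly** (`sq_edm()`), never square
  roots — the RBF consumes $D\circ D$ and the round trip would only lose
  precision. Raw 0/1/2 coding is used; pairwise differences are invariant to
  column centering, so centering is a no-op for distances.
* **Missing genotypes are mean-imputed per SNP** before distances — the
  expectation-preserving default; real missingness patterns are out of
  scope.
* **θ must be symmetric** by construction (an asymmetric θ would not yield a
  valid kernel); the constructor rejects asymmetric θ or ρ.
* **Q need not be PSD** for arbitrary (θ, ρ). `stabilize_psd()` repairs it
  by adding $|\lambda_{\min}| + 10^{-8}$ to the diagonal when the smallest
  eigenvalue is below `-1e-8`. Jitter (rather than eigenvalue clipping)
  preserves every off-diagonal similarity, costs one eigendecomposition, and
  the applied amount is recorded on the object.
* **Validation designs.** `ST` uses target-trait training records only.
  `CV1` adds all training individuals' secondary-trait records. `CV2`
  additionally includes the secondary-trait records of *test* individuals —
  the scenario where indicator traits are already measured on selection
  candidates. Standardizers, SNP effects and allele frequencies are always
  computed from training rows only; the suite verifies that perturbing test
  phenotypes leaves CV1 predictions bit-unchanged (no leakage).
* **"Standardized to the same scale"** is implemented as the per-trait
  z-score. Min–max scaling was the alternative; the z-score makes the shared
  $\varepsilon$ and $C$ comparable across traits and leaves the
  correlation-based tuning fitness invariant.
* A **linear SVR** (genomic relationship matrix as the kernel) is available
  by passing a precomputed kernel to the single-trait path.

### Weighted kernels

The weighted variant replaces, per trait pair $(k, k')$, the squared
distances by $\sum_l w_l (m_{il} - m_{jl})^2$ and the scale $p$ by
$\sum_l w_l$, with

$$
w_{l(kk')} = \frac{|2 q_l (1 - q_l)\, \delta_{lk}\, \delta_{lk'}|}
                  {\max_l |2 q_l (1 - q_l)\, \delta_{lk}\, \delta_{lk'}|},
$$

so $w \in [0, 1]$ with maximum exactly 1 — the locus' share of genetic
(co)variance on the allele-substitution scale. The $\delta$'s come from
per-SNP least-squares fits of all traits on intercept, dosage and the first
30 genomic principal components (population-structure adjustment; the count
defaults to $\min(30, N_\mathrm{train} - 2)$). With a shared design, the
multivariate point estimates coincide with equation-by-equation OLS, so the
implementation residualizes responses and dosages on the covariates once
and computes all $p$ slopes vectorized. Degenerate SNPs (monomorphic after
subsetting) get $\delta = 0$ — hence weight 0 — instead of being dropped, to
keep locus indexing aligned. PCs are computed once on the training set
rather than refit per tuning fold: refitting would multiply cost for a
covariate adjustment whose leading components are extremely stable. With
uniform weights the weighted kernel is *identical* to the unweighted one
(the normalization cancels), which the suite checks exactly.

## Hyperparameters

| parameter | meaning | search bounds | notes |
|---|---|---|---|
| `C` | regularization (penalty on tube violations) | 0.1 – 4 | shared across traits |
| `epsilon` | tube half-width on the standardized scale | 1e-4 – 0.1 | sparsity control |
| `theta_kk` | trait-specific bandwidth | 0.2 – 7 | larger = more local kernel |
| `theta_kk'` | trait-common bandwidth | 0.2 – 7 | controls cross-trait sharing decay |
| `rho_kk'` | cross-trait association constant | 0.1 – 0.3 | may be fixed a priori (e.g. at the genetic correlation), removing it from the search |

With $t$ traits the space is $2 + t^2$-dimensional, reducing to
$2 + t(t+1)/2$ when ρ is fixed. Each parameter is encoded in 8 bits
(256 levels, a 48-bit chromosome for two traits) — enough resolution that
encoding granularity is far below the fitness noise, while keeping the
search space mixable. The GA defaults mirror the intended use: 30
generations of 25 chromosomes (750 candidate models), crossover rate 0.9,
per-bit mutation rate 0.05, tournament size 4, elitism 1 (the minimum that
guarantees monotone best-so-far fitness; the algorithm description names the
elite count without fixing it). Fitness is the Pearson correlation between
observed and predicted target records on an inner validation window —
trailing training generations held out from the GA fits — and solver
failures or zero-variance predictions map to fitness −1 rather than
propagate. Fitness ties break toward smaller `C`, then the smaller encoded
integer: a deterministic preference for less complex models. A
chromosome-keyed cache avoids refitting duplicated candidates without
changing the `PS × NG` accounting. The inner window is configuration, not
hard-coded: the tuning narrative in the field sometimes trains to an
earlier cutoff than the final retraining window, so `forward_split()` takes
`inner_validation` explicitly.

## Benchmark mixed models

`gblup()` / `mt_gblup()` fit the Bayesian kernel mixed models
$y = 1\mu + u + e$, $u \sim N(0, K\sigma^2_u)$ (and the $t$-trait analogue
with $\mathrm{vec}(U) \sim N(0, \Sigma_u \otimes K)$, row-residuals
$N(0, \Sigma_e)$) by Gibbs sampling, with scaled-inverse-χ² /
inverse-Wishart priors (df = 5, scale at half the observed phenotypic
(co)variance — an equal prior partition, weakly informative) and a diffuse
normal intercept prior with variance $1000 \times$ the maximum phenotypic
variance. GBLUP and RKHS regression are one implementation with two kernels
(G or RBF K). The kernel is eigendecomposed once; genetic values are sampled
in the eigenbasis, where components decouple and each sweep costs two
$N \times N$ multiplications.

**Missing records are handled by data augmentation**: each sweep draws the
missing phenotypes from their conditional normal given the observed traits,
current genetic values and $\Sigma_e$. Augmentation keeps every full
conditional conjugate (conditioning on observed records only would break
the inverse-Wishart update for $\Sigma_e$ and forbid the eigenbasis
decoupling) and introduces no external information — augmented records are
redrawn from the model every sweep. CV1/CV2 semantics follow directly:
under CV1 all test records are masked, under CV2 only the target trait is;
the suite verifies that permuting test-set secondary records changes CV2
predictions and leaves CV1 predictions unchanged. The reference chain
length is 20,000 sweeps with 5,000 burn-in and thinning 5; tests use
shorter chains (600–3,000 sweeps) because the models there are small enough
to mix quickly. All chains draw through R's RNG, so `set.seed()` makes them
exactly reproducible.

## Predictive-ability metrics

For test records $y$ and predictions $\hat u$:

* **ACC** $= r(y, \hat u) / \sqrt{\overline{\mathrm{rel}}}$ — correlation
  corrected by the mean reliability of the records, recovering accuracy on
  the true-merit scale when responses are noisy pseudo-phenotypes.
* **RMSE\*** $= \mathrm{RMSE} / \mathrm{sd}(y)$. The field's notation for
  this quantity is ambiguous between dividing by the variance and the SD;
  the SD is implemented — it is the dimensionless choice, consistent with
  relative errors just under 1 for usable predictors.
* **b** $= \mathrm{cov}(y, \hat u) / \mathrm{var}(\hat u)$ — the dispersion
  slope of observed on predicted; 1 is ideal.
* **ACCpar**: a bivariate kernel mixed model is fitted *on the testing set*
  with (observed, predicted) as the two traits; each retained draw yields
  $\sqrt{h^2_{\hat u}} \times r_g(y, \hat u)$ — the selection-index estimate
  of accuracy, free of the environmental covariance that can inflate the
  plain correlation under CV2. The kernel defaults to G (any PSD kernel can
  be passed). **λACC** contrasts pair two independently run chains by draw
  index and report $P[\lambda < 0]$; a joint model across the two fits is
  not attempted, and the index pairing is a documented convention.

Undefined correlations (constant vectors) are errors in the metric
functions but map to fitness −1 inside the GA — two different contracts,
both explicit.

## The simulator: what it emulates, what it does not

`sim_population()` generates a discrete-generation breeding population:
founder genotypes from binomial(2, q) with q uniform on `maf_range`, then
random mating (optionally truncation selection of the parent pool on a
noisy trait-1 phenotype, emulating an indicator trait under selection) with
Mendelian transmission, so drift and selection shape allele frequencies
across generations. QTL effects for $t$ traits are multivariate normal with
the requested genetic correlation; optional pairwise epistasis contributes
a chosen fraction of genetic variance; residuals carry the requested
residual correlation; residual variances are set against the realized
sample variance of the true breeding values so realized heritabilities
match their targets up to residual-sampling noise. Default trait
architecture (h² = 0.56/0.34, r_g = 0.23, residual correlation 0.47)
mirrors a carcass-trait/growth-trait pair in a commercial broiler setting —
a high-heritability target with a moderately heritable, weakly correlated
indicator.

Deliberately not modeled: overlapping generations (the labels are discrete;
forward validation only needs ordered cohorts), linkage maps and
coalescent LD (founder loci are independent; LD arises only from
relatedness and selection), pedigree-based EBV estimation and deregression
(reliabilities are simulated stand-ins drawn uniform per record, playing
only their role as the ACC denominator and as a QC filter). Consequently,
passing tests show that the estimators recover the parameters of *this*
generative process and that the method's structural identities hold; they
do not certify performance under real LD structure, genotyping artifacts,
or the heteroskedastic reliabilities of deregressed proofs.

## Numerical choices and degenerate inputs

* SMO tolerance $10^{-3}$ (KKT gap) by default; solver-oracle comparisons
  in the tests tighten it to $10^{-6}$. The iteration cap defaults to
  $10^4 \times n$ pair updates.
* $\varepsilon = 0$ is allowed (degenerates toward a least-absolute-type
  fit); the GA's lower bound is $10^{-4}$ regardless.
* A constant training response is a valid zero-multiplier optimum for the
  solver (bias = the constant) but an error in `stack_traits()` (z-score
  undefined) and in the correlation metrics.
* Kernel eigenvalue clamping: eigenvalues below $10^{-8} \times
  \lambda_{\max}$ of a benchmark kernel are treated as zero-rank directions
  (their genetic-value components are fixed at zero and excluded from the
  variance updates).
* All simulator and sampler randomness flows through R's RNG from a single
  seed per run; GA runs replay bit-identically from their seed.

## Problem sizes in the test suite

Unit tests run populations of 40–500 individuals with 100–1,000 markers and
chains of 300–3,000 sweeps; the end-to-end checks use the configurations the
method targets at reduced scale — a 750-candidate GA on a 120-individual,
300-marker population; solver-oracle agreement on 50 random duals up to
n = 50; bi-trait parameter recovery at N = 500 with 2,000-sweep chains; and
a 20-replicate CV1/CV2 comparison at N = 400 with 500 markers. These sizes
were chosen so the full suite exercises every code path in well under an
hour on one core while keeping Monte-Carlo error far below the asserted
tolerances.

## Known limitations

* Only `t = 2` is exercised end-to-end (trait pairs are the practically
  relevant case); the data structures accept arbitrary `t`.
* The true multitask SVR (t simultaneous equality constraints via
  generalized SMO) is intentionally not implemented — the data-expansion
  scheme is the method of interest.
* Locus weights come from single-SNP regressions; weights from multivariate
  shrinkage regressions or tree ensembles are out of scope.
* QMTSVR predictions conditioned on indicator traits are not breeding
  values: conditioning changes the variance decomposition, and predicted
  values live on the scale of the training variables.
* The λACC convention (independent chains paired by draw index) understates
  nothing about location but has no joint-posterior interpretation.
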