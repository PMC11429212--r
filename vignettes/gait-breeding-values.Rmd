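---
title: "Breeding values for gait visual scores: models, simulation and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breeding values for gait visual scores: models, simulation and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Gaited horses such as the Campolina are evaluated with visual scores —
dissociation (Di), comfort (C), style (S), regularity (R) and development
(De) — assigned by association technicians at registration, around 36 months
of age.  These scores are cheap and fast but subjective: the person scoring
the horse (the technician, or appraiser) explains a large share of the
phenotypic variance, and heritabilities are low (around 0.08–0.11).  `gaitbv`
implements the full evaluation chain for such data: pedigree machinery,
ordinary least squares for fixed effects, a multi-trait animal model with a
random technician effect (variance components by EM-REML, breeding values by
BLUP), machine-learning EBV predictors trained on the model's output, and
validation by the LR (linear regression) method.  Because the real stud-book
data are proprietary, the package ships a synthetic-data generator that
emulates their statistical structure; every pipeline stage is exercised and
validated on simulated data with known truth.

## Models

### Fixed-effect (OLS) stage

Each score is first modelled with fixed effects only,

$$y = \mu + \beta_1\,\mathrm{age} + \beta_2\,\mathrm{age}^2 + CG + Stud + e,$$

where the contemporary group $CG$ is the concatenation of birth year, sex and
registration year, and the stud (breeding farm) is a separate cross-classified
effect.  Age enters raw (in months) with its square; the columns are strongly
collinear with the group blocks, and the normal equations are solved by the
Moore–Penrose pseudoinverse, giving the minimum-norm solution.  Only
$X\hat\theta$ and the adjusted phenotypes $\hat e = y - X\hat\theta$ are
consumed downstream, and both are invariant to the choice of generalized
inverse (a property the tests verify by comparing against a pivoted-QR fit).

### Multi-trait animal model

The evaluation model adds random animal and technician effects:

$$y = X\theta + Z_1 u + Z_2 t + e,\qquad
\mathrm{Var}\begin{pmatrix}u\\t\\e\end{pmatrix} =
\begin{pmatrix}\Sigma_u\otimes A&0&0\\0&\Sigma_t\otimes I&0\\0&0&\Sigma_e\otimes I\end{pmatrix},$$

with $A$ the numerator relationship matrix and $\Sigma_u,\Sigma_t,\Sigma_e$
the 5×5 genetic, technician and residual covariance matrices.  Records may
miss any subset of traits; the residual term of a record uses the inverse of
the $\Sigma_e$ submatrix of its observed-trait pattern.

Henderson's mixed-model equations are assembled with $A^{-1}$ built directly
from pedigree recursions (Meuwissen–Luo inbreeding, Henderson's rules with
inbreeding) — dense $A$ is never inverted.  Fixed-effect blocks are per
trait, over the records observing that trait, with aliased columns detected
by a scaled pivoted Cholesky and dropped; this keeps the coefficient matrix
nonsingular without constraining the estimable functions.

### EM-REML

Variance components are estimated by expectation-maximization REML.  Each
iteration solves the MME and computes the exact conditional expectations

$$\Sigma_u \leftarrow \frac{\hat U' A^{-1} \hat U + \mathrm{tr}\,(A^{-1} C^{uu})}{q},\qquad
\Sigma_t \leftarrow \frac{\hat T'\hat T + \mathrm{tr}\, C^{tt}}{q_t},$$

with the residual update completing missing traits through the current
$\Sigma_e$ (conditional-expectation completion).  The trace terms require
selected entries of the inverse coefficient matrix; these are computed
exactly with the Takahashi equations on the sparse Cholesky factor (the same
sparse-inverse-subset approach used by dedicated REML software), implemented
in C++ and verified against dense inversion in the tests.  The restricted
log-likelihood is evaluated every iteration and is non-decreasing — a test
asserts this at every step.

Plain EM converges slowly near the optimum, so a squared (SQUAREM-style)
extrapolation is attempted after every cycle of two EM steps; a proposal is
accepted only if it stays strictly inside the PSD cone **and** does not
decrease the restricted log-likelihood, with step-length backtracking toward
the plain EM step otherwise.  Monotonicity is therefore preserved with or
without acceleration.

Numerical choices: convergence is declared when the maximum relative
parameter change falls below `tol` (default `1e-6`), or when the restricted
log-likelihood gain drops below `1e-8 (1 + |logL|)` on two consecutive EM
steps — a likelihood plateau, where any remaining parameter drift runs along
an essentially flat ridge; starting values are one
third of the phenotypic covariance for each component (EM is
initialization-sensitive, and this neutral split needs no prior knowledge);
updates that leave the PSD cone through rounding are projected back by
eigenvalue truncation.  Estimates at the default tolerance agree with a
dense restricted-likelihood optimizer to about four decimals on test
problems.

### BLUP and theoretical accuracy

Breeding values are predicted for every pedigree animal (phenotyped or not)
by solving the MME at the estimated covariances, using the raw (uncleaned)
records and the full pedigree: cleaning protects variance-component
estimation, while prediction benefits from all information.  The theoretical
accuracy uses the prediction-error variance from the exact selected inverse:
$r_i = \sqrt{1 - \mathrm{PEV}_i / ((1+F_i)\,\hat\sigma^2_u)}$.

### Machine-learning predictors

The three predictors are implemented from first principles (reference
libraries appear only as test oracles):

* **ANN** — a 4–6–4–1 multilayer perceptron with sigmoid, tanh, tanh hidden
  activations and a GELU output ($x\Phi(x)$, exact Gaussian CDF), trained by
  RMSprop on mean absolute error with an L2 weight penalty
  ($\alpha = 0.1$, $\lambda = 0.001$, 100 epochs, batch size
  $\lfloor n/2\rfloor$).
* **SVR** — $\varepsilon$-insensitive support vector regression with an RBF
  kernel, solved in the dual by a maximal-violating-pair SMO to a KKT gap of
  $10^{-6}$ ($\varepsilon = 0.1$, $\lambda = 1$ so $C = 1/\lambda$,
  $\gamma = 0.0125$).  The customary bias term of the dual formulation is
  included: without it, predictions of mean-shifted targets are
  systematically biased.
* **RFR** — 200 bagged regression trees, best-variance-reduction splits
  among $m = \lceil 0.3\,p\rceil$ randomly drawn features, terminal node
  size 5, per-tree seeded RNG streams so the forest is reproducible and
  independent of tree order.

Their feature matrix `X_MLT` concatenates, per record: the five adjusted
phenotypes; the per-effect fitted components ($CG$, stud, age-linear,
age-quadratic) for each trait — the per-effect decomposition was chosen over
a single fitted-value column because the effect-wise solutions are what the
fixed model actually communicates, and a configuration with one column per
trait would be a strict linear function of it; technician dummy variables
with the most-frequent technician dropped (ties broken by smallest id); and
the first ten eigenvectors of $A$ restricted to the phenotyped animals
(population-structure coordinates).  Columns are centered on the training
means, and validation rows are transformed with those stored means — never
re-centered — to avoid information leakage.  The training target is the
whole-data MTM EBV of the training animals.

### Validation (LR method) and trends

The LR method splits animals by birth year into training and focal cohorts
and compares whole-data with partial-data predictions of the focal animals:
accuracy $acc = \mathrm{cov}(\hat u_w,\hat u_p)/((1-\bar F)\sigma_u^2)$,
level bias $\delta = (\bar{\hat u}_p - \bar{\hat u}_w)/\sigma_u$, dispersion
$b_1 = \mathrm{cov}(\hat u_w,\hat u_p)/\mathrm{var}(\hat u_p)$, plus the
plain correlation and MSE.  The accuracy is reported as the ratio itself by
default, matching the printed formulation; `sqrt_acc = TRUE` gives the
canonical square-root form, and both are covered by tests.  $\sigma_u^2$ is
taken from the whole-data REML estimate.  Covariances use the $n-1$
denominator.  With $\hat u_p \equiv \hat u_w$ the identities $\delta = 0$
and $b_1 = 1$ hold to machine precision.

Genetic trends subtract the base-cohort mean EBV per trait (the earliest
simulated cohort by default, mirroring a foundation-year genetic base) and
regress the adjusted EBVs on birth year.

## The synthetic-data generator

The generator emulates the structure of the real stud-book data rather than
any particular records:

* **Pedigree** — founders spread over nine cohorts, then one mating season
  per year with dams aged 4–16 each producing at most one foal, and a small
  active-sire pool with rank-skewed usage; stallions therefore accumulate
  several-fold more offspring than mares, as in the source population
  (21.5 vs 3.4 foals on average).
* **Breeding values** — recursive Mendelian sampling: founders
  $\sim N(0, \Sigma_u)$, offspring = parent average + deviation with
  covariance $d_i\,\Sigma_u$, $d_i = \tfrac12 - \tfrac14(F_s + F_d)$, so
  $\mathrm{Var}(u_i) = (1+F_i)\Sigma_u$ exactly.
* **Phenotypes** — one record per scored animal at a Gaussian age around
  39.65 ± 3.39 months; registration year = birth year + 3 ± 1 (registration
  near 36 months); contemporary-group and stud effects drawn per level with
  SDs of 0.4 and 0.3 phenotypic SDs (the published effect-wise solution
  summaries only bound these qualitatively; the values are configurable);
  technician effects $\sim N(0,\Sigma_t)$ with a skewed workload
  distribution so the most frequent technician is unique; residuals
  $\sim N(0,\Sigma_e)$; per-trait missingness completely at random with
  default rates matching the observed per-trait record counts (about 25%
  for Di, S, R, De; none for C).
* **Scores stay continuous.**  The analysis models them as continuous, and
  rounding to the integer scales would distort variance-component recovery;
  a rounding flag exists for realism experiments.

The default covariance matrices (`campolina_covariances()`) are anchored at
the published estimates: heritabilities 0.08 (Di, C, De), 0.11 (R) and 0.09
for S (only the range endpoints are printed; S is placed mid-range);
technician fractions 0.33 (S) and 0.43 (C) with the remaining three placed
inside that range (0.40, 0.36, 0.38); genetic correlations from 0.65 (Di, C)
to 0.95 (R, De); residual correlations from 0.34 (De, C) to 0.78 (De, R);
technician correlations from 0.52 (C, R) to 0.98 (R, De) with 0.91 for
(Di, S).  Cells not individually printed were fixed once, inside the printed
ranges, subject to all three matrices being positive definite; phenotypic
scales are the raw-score standard deviations.  What the generator does *not*
emulate: selection decisions over time (trends in simulated data are null by
construction), rider effects, repeated records per horse, and non-Gaussian
score distributions.  Passing tests therefore demonstrate correctness of the
machinery under the stated model, not robustness to violations of it.

## Parameter recovery and problem sizes

`recovery_experiment()` is the package's validation workhorse: simulate
replicates under the published ratios, clean, truncate the pedigree to three
ancestral generations, re-estimate by EM-REML, and compare with the truth.
With the default scale (about 1,900 phenotyped animals, 30 technicians) the
mean heritability for R across 10 replicates lands within ±0.03 of 0.11, the
mean technician fraction for C within ±0.05 of 0.43, and the mean bivariate
genetic correlation (R, De) within ±0.05 of 0.95.  The acceptance script
runs exactly these experiments; the test suite runs smaller smoke versions
(about 700 records per replicate) of the same code path.  The bivariate runs
use a slightly smaller cohort (about 1,500 records) and a convergence
tolerance of `3e-5`: the genetic correlation moves by under 0.01 beyond that
point, far inside the assessment band.

Truncation counts generations by the longest ancestor path from any
phenotyped descendant, so `generations = 0` keeps only the phenotyped
animals (all as founders) and no retained animal has an ancestor path longer
than the cut — the counting rule is documented in `?truncate_pedigree` and
is deliberately strict; stud-book software sometimes uses laxer
membership-based rules, and the published post-truncation animal count is
not reproducible without the original data.

## Degenerate inputs and tie-breaks

* Unknown parents are coded 0 in files and mapped to a null sentinel
  internally; parents never listed as animals become phantom founders dated
  one year before the earliest record.
* Eigenvector signs follow the largest-magnitude-component-positive rule so
  feature columns are reproducible across platforms.
* Technician dummy ties (equal record counts) drop the smallest id.
* A single-technician table yields an empty dummy block with a warning; a
  technician unseen in training yields an all-zero dummy row with a warning.
* Cleaning iterates the small-level filter to a fixed point and is
  idempotent; a table whose records are all removed is an error.
* EM updates that leave the PSD cone are projected back; an identity-free
  data set (zero phenotypic variance) is an error, not a silent NaN.

## Reproducibility

Every stochastic stage derives its seed from the master seed and a stage
name (`derive_seed()`), so adding a stage never perturbs existing streams,
and rerunning a configuration reproduces all artifacts exactly — the test
suite asserts byte-level equality of two full pipeline runs.

## Known limitations

* Dense relationship matrices (and hence eigenvector features) are limited
  to desk scale (~20,000 animals); national-scale evaluations would need
  iteration-on-data solvers and approximate accuracies, which are out of
  scope.
* The EM residual update with missing traits assumes missingness completely
  at random, matching the generator; informative missingness would bias it.
* The ML stage predicts from one fitted feature snapshot; it does not
  propagate the uncertainty of the OLS solutions or of the EBV targets, so
  its validation statistics inherit the benchmark model's noise.
* The LR accuracy is reported on the printed-ratio scale by default; users
  comparing against other software should check which convention it uses.
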