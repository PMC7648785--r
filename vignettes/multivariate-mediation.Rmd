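---
title: "Multivariate mediation for exposure mixtures: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multivariate mediation for exposure mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The setting and the causal estimands

`mixmediate` addresses mediation analysis when the exposure is a *mixture*
— dozens of correlated analytes organized in chemical classes — and the
mediators are a high-dimensional panel of endogenous biomarkers organized
in biological groups, measured in a nested case-control sample. The
running design has n = 161 subjects (52 preterm cases oversampled from a
larger pregnancy cohort, 109 controls), p = 38 exposure analytes in 4
classes, q = 61 biomarkers in 7 groups, 6 covariates, and gestational age
at delivery (weeks) as the continuous outcome.

All estimators build on the linear structural mediation model

$$M_i = \alpha_a A_i + \boldsymbol\alpha_c' \mathbf C_i + \epsilon_i,
\qquad
Y_i = \beta_a A_i + \beta_m M_i + \boldsymbol\beta_c' \mathbf C_i + \delta_i.$$

Under sequential ignorability (no unmeasured confounding of the
exposure–outcome, mediator–outcome, and exposure–mediator relations, no
exposure-induced mediator–outcome confounders) and temporal ordering, the
natural indirect effect is the product of coefficients
$\mathrm{NIE} = \alpha_a\beta_m$, the natural direct effect is
$\mathrm{NDE} = \beta_a$, and for the continuous outcome
$\mathrm{TE} = \mathrm{NDE} + \mathrm{NIE}$. These identities are exact
for nested weighted least squares with common weights, and the package's
tests assert them at 1e-10 (decomposition) and 1e-8 (product vs.
difference of nested models). Exposures and mediators are right-skewed
concentrations and always enter on the log scale; score-based stages
additionally z-score each column, so effects are per log-SD.

### Case-control sampling and weighting

Because cases are oversampled, every regression is weighted by inverse
probabilities of selection: weight = 1 / P(selected | case status),
constant within stratum (`compute_ipw`). All fits use HC0 sandwich
("design-robust") variances; with IPW the model-based variance is
inconsistent, and the sandwich form is also what a survey-weighted engine
reports by default. Whether the original analyses used design- or
model-based variances is not determinable; design-robust is this
package's documented default. For binary outcomes (overall and
spontaneous preterm birth) the outcome model is a weighted logistic
regression; the product-of-coefficients NIE is then on the log-odds scale
and exact only for rare outcomes. With ~32% cases this caveat matters, so
every binary-outcome result carries a structured warning, and the total
effect is taken from the mediator-omitted outcome model (the difference
of nested models), since log-odds effects do not decompose additively.

## The synthetic cohort

`generate_cohort(sim_config())` draws the full source cohort (default
1600 pregnancies), then samples the analytic subset by case status.

* **Exposures**: Gaussian on the log scale with block-exchangeable
  correlation — `within_class_rho = 0.65`, `between_class_rho = 0.1` —
  then exponentiated, so downstream log-transformation recovers exact
  Gaussianity. The real panel's extreme pairs (up to ρ ≈ 0.97) are not
  reproduced by an exchangeable block; 0.65 was chosen once as a strong
  but positive-definite class-level summary.
* **Mediators**: linear in the log-exposures (`alpha_matrix`, q × p) plus
  covariate effects plus group-correlated Gaussian noise
  (`within_group_rho = 0.4`), exponentiated to positive raw values.
* **Outcome**: mean 39.5 weeks plus sparse direct effects (`beta_a`),
  mediator effects (`beta_m`), covariate effects, and N(0, 1.45²) noise.
  The default effect pattern routes three phthalate analytes through four
  cytochrome p450 mediators (α = 0.4, β\_m = −0.15) with a weak direct
  effect (−0.08). These values were fixed once so that the full outcome
  model explains roughly 30% of outcome variance and the cohort preterm
  prevalence (< 37 weeks) is about 8% — a realistic epidemiologic signal
  regime — and are not revisited.
* **Ground truth** is defined on the log-standardized scale of the
  analytic models: per-pair NIE = α(l,j)·β\_m(l); the per-exposure TE adds
  the direct effect and all mediated contributions, and the per-pair NDE
  is TE − NIE by construction.

What the generator does **not** emulate: assay detection limits, batch
effects, missingness (complete data are generated), non-linear
dose-response, exposure–mediator interactions, and the real panel's
heterogeneous correlation profile. Passing recovery tests therefore shows
the estimators are correct under the linear Gaussian data-generating
model, not that real-data estimates are unbiased.

The full-cohort case count that anchors the IPW weights is a free
parameter (`n_cohort`); the source study does not state it, and weights
follow from whatever cohort the generator draws.

## Environmental risk scores

Per class k, `fit_adaptive_elastic_net` minimizes

$$\frac1n\sum_i (Y_i - \boldsymbol\gamma_c'\mathbf C_i -
\boldsymbol\gamma_k' \mathbf A_{ik})^2
+ \lambda_1 \sum_j w_j |\gamma_{kj}|
+ \frac{\lambda_2}{2}\sum_j \gamma_{kj}^2$$

with covariates unpenalized. Numerical choices:

* The unpenalized block is partialled out exactly once
  (Frisch–Waugh–Lovell), and cyclic coordinate descent runs in covariance
  form; KKT stationarity is verified at the solution (tolerance 1e-6 in
  tests; observed violations ~1e-10).
* Adaptive weights $w_j = (|\gamma^{init}_j| + 1/n)^{-1}$ with the initial
  fit a ridge regression at its own cross-validated penalty. The cited
  adaptive estimator leaves the weight exponent open; exponent 1 with a
  1/n stabilizer is its common form, and a pure ridge initializer is the
  collinearity-robust special case of the "ridge-heavy" initial elastic
  net.
* λ1 runs over 50 log-spaced values spanning four decades down from the
  smallest all-zero penalty; λ2 ∈ {0, 0.01, 0.1, 1, 10}. The two are
  selected *jointly* on the grid by seeded 5-fold CV of prediction error
  (profiling λ2 would be cheaper but the joint grid is unambiguous; the
  question was left open by the source description).
* CV folds are a pure function of (seed, n); CV-phase solves use a looser
  tolerance (1e-7) than the final fit (1e-10), which affects only fold
  errors, not the returned solution.
* A class whose every weight is zero at the selected penalty is a
  *degenerate* score: flagged with a warning, score set to constant zero,
  never an error — a null class is a finding, not a failure.

The score ERS = A·γ̂ is standardized. The same outcome used to estimate
the weights is reused in downstream mediation (no sample splitting),
exactly as the framework prescribes; the resulting optimism is a known
limitation.

## Bayesian shrinkage mediation

`fit_bayes_mediation` Gibbs-samples the joint model in which all q
mediators of one exposure appear simultaneously; each entry of the
exposure-to-mediator vector and of the mediator-to-outcome vector carries
a two-component normal mixture prior (continuous spike and slab), with
Bernoulli(0.5) membership and inverse-gamma hyperpriors on the component
variances. A mediator's posterior inclusion probability is the posterior
frequency with which *both* of its path coefficients occupy the slab.

Design choices worth recording:

* The slab keeps an IG(2, 1) hyperprior, but the spike's rate is scaled
  down by 100 (IG(2, 0.01)). With IG(2, 1) on both — prior mean 1 for a
  component meant to represent "essentially zero" — the slab ≥ 100 ×
  spike ordering is almost never satisfiable and PIPs are uninformative.
  A spike concentrated near zero restores the intended semantics; the
  ordering is enforced by rejection with a deterministic clip after 20
  tries. Both variances can be fixed by the user (`prior_spec`), and
  setting spike = slab collapses the mixture to a ridge-like single
  normal — a degenerate case the tests exploit.
* Coefficient updates: the outcome equation is drawn jointly (one
  Cholesky of dimension 1 + q + r per iteration); the mediator equations
  use scalar conjugate updates vectorized across mediators. Same seed ⇒
  bit-identical chains.
* IPW enters as a weighted likelihood (weights exponentiate subject
  contributions). This is an approximation — the source method is
  unweighted, and whether the original Bayesian runs weighted at all is
  unstated — and can be disabled (`use_weights = FALSE`).
* The method is restricted to continuous outcomes.
* Defaults in `run_shrinkage_over_exposures` are sized for the study
  scale; the package's calibration tests run 1,500 iterations (750
  burn-in) at q = 20, where split-chain diagnostics sit near 1 and null
  max-PIPs near 0.03.

The global mediation effect is reported in two forms, computed per draw
and then summarized: the conventional signed sum of products
$\sum_\ell (\alpha_a)_\ell(\beta_m)_\ell$, and the sum of *squared*
products, a non-negative pathway-activity magnitude. The framework's
printed definition uses the squared form while the conventional global
NIE is unsquared; which one the original software reported cannot be
determined from the text, so both are first-class outputs and no default
silently chooses.

## Directions of mediation and group effects

For a mediator group g, `estimate_direction` finds the unit-norm loading
vector w maximizing the Gaussian profile log-likelihood of the
two-equation system with M·w as the single mediator. Because both
equations are linear, the profile likelihood reduces to closed form in
the covariate-residualized weighted cross-products
(G = M'R'WRM, b = M'R'WRy, c₀ = y'R'WRy):

$$\ell(w) \propto -\log(w'Gw) - \log\!\big(c_0 - (b'w)^2 / w'Gw\big),$$

maximized on the unit sphere by projected gradient ascent with
backtracking (monotone by construction, tolerance 1e-8), from the first
principal component of the residualized group plus 20 seeded random
restarts (the source decomposition's optimizer is unspecified; restarts
guard against local maxima on the sphere). The sign is fixed by making
the largest-magnitude loading positive; only the first direction per
group is extracted. The induced mediator group effect MGE = M·w is then
mediated as a single variable, giving s + 1 group-level results per
exposure (5 eligible groups of at least 5 biomarkers, plus all mediators
jointly; oxidative stress and protein damage are too small for a
meaningful within-group direction and are excluded from by-group runs but
retained in the joint run).

Groups whose members are all essentially uncorrelated with the exposure
(max |ρ| < 0.1) carry no estimable mediation direction; they surface with
a typed `sparse_signal` status rather than an error, mirroring how such
groups drop out of reported forest plots.

`sparse_pc_mediation` is the companion sensitivity: L1-penalized power
iteration with projection deflation builds sparse components of the full
mediator matrix until a cumulative explained-variance target (default
80%) is reached, and each component score is mediated one-at-a-time. At
zero penalty the procedure reduces exactly to PCA (asserted at 1e-8
against `prcomp`), which keeps the penalized algorithm honest.

## Penalized pathway selection

**Pathway lasso.** The joint objective penalizes each pathway product:

$$\tfrac1{2n}\|M - a\alpha'\|^2_F + \tfrac1{2n}\|y - a\beta_a - M\beta\|^2
+ \lambda\sum_j\big(|\alpha_j\beta_j| + \phi(\alpha_j^2+\beta_j^2)\big)
+ \omega\sum_j\big(|\alpha_j| + |\beta_j|\big).$$

Covariates are partialled out exactly (they are unpenalized in every
stage). Rather than ADMM, the solver is block coordinate descent in the
(α\_j, β\_j) pairs: because the loss separates, each 2 × 2 subproblem is
solved *exactly* by enumerating the two axes and the four sign quadrants
(each quadrant a 2 × 2 linear system, strictly convex whenever
φ ≥ 1/2; default φ = 2). This gives a guaranteed monotone objective and a
clean convergence check (max coefficient change < 1e-8), which an ADMM
implementation of the same objective does not.

Two tuning choices departed from the initially sketched regime, for
reasons visible in simulation: with ω = 0.1λ the plain-L1 floor sits an
order of magnitude below the coefficient noise scale at any CV-selected
λ, and the path never sparsifies. The default is ω = λ — the stronger-L1
variant of the cited method — and λ is selected by 5-fold CV on the
combined residual loss with the **one-standard-error rule**, because the
raw CV minimum is almost always the densest fit (the q unpenalized-fit
mediator equations dominate the combined loss). Under these defaults
active pathways are recovered with high recall and the selected set is
several-fold sparser than the panel, but users should treat the selected
*set* as a screen, not an inference: precision of the product-nonzero
rule is modest.

**MCP + joint significance.** Three stages: (1) sure independence
screening keeps the d = ⌈2n/log n⌉ mediators most conditionally
associated with the outcome; (2) an MCP-penalized outcome regression over
survivors (exposure and covariates unpenalized), coordinate descent with
the exact firm-threshold operator, tuned by BIC along a 30-step path
(concavity γ = 3; the operator provably interpolates soft thresholding at
γ → ∞ and hard thresholding at γ → 1⁺, asserted against closed forms);
(3) mediators with nonzero MCP coefficients get p\_α from the mediator
model and p\_β from an unpenalized joint refit; the joint-significance
p-value is the maximum of the two, adjusted by both Benjamini–Hochberg
and Bonferroni. The stage-3 p-values are post-selection quantities with
no selective-inference correction, as in the source procedure; an empty
selection is a status, not an error.

## Sensitivity analyses

* **Error-correlation curve** (`rho_sensitivity`): positing correlation ρ
  between the two equations' errors re-identifies
  β\_m(ρ) = β̂\_m − ρσ̂\_Y/(σ̂\_M√(1−ρ²)) in closed form — exact, no
  simulation — so NIE(ρ) = α̂·β\_m(ρ) anchors at the point estimate at
  ρ = 0. The crossing where the NIE vanishes is bisected on the grid
  (default −0.9…0.9 step 0.01) and equals the partial correlation of
  mediator and outcome given exposure and covariates; it is also reported
  as the product of variance-explained fractions an unmeasured confounder
  would need in the two models (both the total-variance and
  residual-variance parameterizations, since reported thresholds in this
  literature use the product form).
* **E-value** (`evalue_continuous`): the standardized effect maps to an
  approximate risk ratio RR = exp(0.91·β) (the 0.91 constant follows the
  cited E-value methodology and is configurable), and
  E = RR + √(RR(RR−1)) after inverting RR < 1. The confidence bound uses
  the interval limit *closer to the null* — the conventional reading when
  a "lower bound" is quoted — and is 1 when the interval crosses the
  null.
* **Covariate-subset scan** (`covariate_combination_scan`): the mediation
  model is refitted under every non-empty subset of the conceptual
  covariates (63 for 6), reporting the NIE range and sign-stability
  fraction; rank-deficient subsets are flagged rows.

## Problem sizes in the test suite

The suite validates counting identities at the full study scale
(2,318 and 244 models, 63 subsets, n = 161), algebraic identities at
machine precision, and statistical calibration at sizes chosen for a
single-CPU run: 500 replicates at n = 1000 for pathway recovery and CI
coverage; 50 seeds each for Bayesian null/signal calibration (q = 20,
n = 500–1000, 1,500 iterations) and direction-of-mediation recovery
(q = 10, n = 1000, 5 restarts); 200 replicates for the global-null
calibration of joint-significance selection (q = 61, n = 500). The
acceptance script reruns the full framework on the default design and
reports only quantities it computes at run time.

## Known limitations

* Binary-outcome mediation is odds-ratio-scale and approximate outside
  the rare-outcome regime; no exposure–mediator interactions are modeled.
* ERS weights and downstream mediation share one sample; effect estimates
  for the scores are optimistic.
* The weighted-likelihood treatment of IPW in the Bayesian stage is an
  approximation without design-based uncertainty.
* Pathway-lasso selection has modest precision; joint-significance
  p-values are post-selection.
* The generator's exchangeable correlation blocks understate the most
  extreme real-data collinearity.
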