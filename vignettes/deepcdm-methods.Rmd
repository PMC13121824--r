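---
title: "Deep cognitive diagnosis models: model, estimator, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep cognitive diagnosis models: model, estimator, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deepcdm)
```

## The model

A deep cognitive diagnosis model (DeepCDM) is a directed generative model
with $D$ layers of binary latent attributes above a layer of $J$ binary item
responses. Writing $A^{(0)} = X$ for the responses, the joint distribution
factorizes top-down along the ladder

$$
P(X, A^{(1)}, \dots, A^{(D)})
  = P(A^{(D)}) \prod_{d=1}^{D} P\!\left(A^{(d-1)} \mid A^{(d)}\right),
$$

with the deepest layer following a saturated categorical distribution over
its $2^{K_D}$ attribute profiles, and units within each layer conditionally
independent given the layer above. Each adjacent pair of layers forms an
ordinary cognitive diagnosis model: the success probability of unit $j$ of
layer $d-1$ given the parent profile $\alpha \in \{0,1\}^{K_d}$ is

$$
P(a_j = 1 \mid \alpha) = f\!\left(\beta_{j,0} +
  \textstyle\sum_{S} \beta_{j,S} \prod_{k \in S} \alpha_k\right),
$$

where the set of interaction subsets $S$ defines the measurement model:
singletons only (*main-effect*, the LLM/ACDM family), all nonempty subsets
(*all-effect*, the LCDM/GDINA family), or the single interaction of a
required attribute set (*DINA*, whose coefficients this package stores
inside the all-effect basis — DINA is exactly the all-effect model with all
lower-order terms constrained to zero). All estimation uses the inverse
logit link $f$; the identity link is supported for model evaluation and
simulation but deliberately not for fitting (a probability-constrained
least-squares M-step is a documented extension, not implemented).

The binary matrix $Q^{(d)}$ with rows indexed by the units of layer $d-1$
records which parent attributes reach each unit; it is the support pattern
of the non-intercept coefficients. In the exploratory setting *all*
Q-matrices are unknown and recovered from the penalized coefficient
estimates.

Profiles are indexed canonically: profile $m \in \{0, \dots, 2^K-1\}$ has
attribute $k$ equal to bit $k$ of $m$, attribute 1 least significant
(`enumerate_profiles()`). Every proportion vector, posterior matrix and
transition matrix in the package uses this order.

## Layer-wise estimation

Marginalizing the deeper layers out of a DeepCDM leaves an ordinary
one-layer restricted latent class model at the bottom. `fit_exploratory()`
exploits this: it estimates the model bottom-up, one layer at a time.

1. **Input.** Layer 1 sees the observed responses. Layer $d > 1$ sees
   pseudo-observations: `impute_pseudo_samples()` draws $M$ iid profiles
   from the previous layer's fitted marginal profile distribution
   (default $M = N$; marginal sampling is the default because posterior or
   MAP imputation concentrates on high-posterior profiles and biases deeper
   layers — both alternatives are retained for comparison).
2. **Initialization.** The spectral initializer below produces starting
   coefficients, a provisional Q-matrix, and starting proportions.
3. **Penalized EM.** `fit_one_layer()` maximizes the marginal log-likelihood
   of the layer minus $\lambda \sum_j \sum_S |\beta_{j,S}|$ (intercepts
   unpenalized, matching standard coordinate-descent practice). The E-step
   is the saturated-profile posterior computed in log space; the
   coefficient M-step is an IRLS + cyclical coordinate descent with soft
   thresholding (compiled, `src/cd_mstep.cpp`), the proportion M-step is
   the closed-form posterior average. The penalty is on the likelihood
   scale of the total log-likelihood (not divided by $N$).
4. **Selection.** The layer is fitted along a $\lambda$ path and the fit
   with the smallest BIC is kept, where
   $\mathrm{BIC} = -2\,\hat\ell + \log(N)\,\big(\#\{\hat\beta \ne 0\} +
   2^{K_d} - 1\big)$. The effective sample size for deeper layers is the
   pseudo-sample count ($M = N$ by default).
5. **Q recovery.** `recover_q()` truncates small coefficients and applies
   the per-model rule (surviving main effects; the largest surviving
   coefficient's subset for all-effect and DINA layers).

The fitted proportion vector of the layer becomes the sampling distribution
for the next layer's pseudo-observations. After the deepest layer, the
package assembles cascade marginals $\hat p^{(d)}$ by pushing the deepest
proportions down through the fitted transition matrices, and per-person
layer-1 posteriors and MAP profiles.

`fit_confirmatory()` runs the same flow with known Q-matrices: effect
design columns are restricted to the Q-support (for DINA, only the
required-set interaction), no Q recovery, $\lambda = 0$ by default.
`fit_full_em_bruteforce()` implements the classical full EM by joint
enumeration of all latent configurations (guarded at $2^{12}$ states); it
serves as the baseline against which the layer-wise estimator is validated.

### Numerical choices in the EM

* Convergence is declared when the *per-observation* change of the
  penalized objective falls below `tol`. Defaults are $10^{-4}$ for layer 1
  and $10^{-5}$ for deeper layers — a relaxed first layer (it has by far
  the most parameters), a standard practice for these estimators; the
  specific values are this package's own calibration, chosen because a
  visibly under-converged layer-1 EM degrades Q-matrix recovery.
* The EM uses squared-extrapolation (SQUAREM-style) acceleration with an
  objective safeguard: an extrapolated step is accepted only if it does not
  lower the penalized objective, otherwise the plain EM step is used. The
  ascent property of the trace is therefore preserved exactly and is tested.
* The coefficient M-step runs a small number of IRLS passes per EM
  iteration (a generalized EM with the same fixed points); a per-unit
  backtracking guard ensures the M-step never lowers its objective.
* The $\lambda$ path (default 15 log-spaced values from
  $\lambda_{\max}/1000$ up to $\lambda_{\max}$, where $\lambda_{\max}$ is
  the smallest penalty zeroing every slope at the initial posterior) is
  traversed **upward** with warm starts. This direction matters: the
  all-slopes-zero solution at $\lambda_{\max}$ is an exact EM fixed point —
  with flat coefficients the posterior equals the prior and the weighted
  score of every slope is identically zero — so a descending warm-started
  path can never escape it. The path is explored at a relaxed tolerance
  (`max(tol, 1e-3)`) and only the BIC winner is refined at `tol`.
* E-step degeneracies: a person with zero total likelihood is impossible in
  log space by construction; probabilities of exactly 0/1 (possible under
  the identity link) are floored inside logs so that impossible events
  contribute a large finite penalty rather than NaN.

## Spectral initialization

`spectral_init()` is the non-iterative starting-value pipeline, run per
layer on that layer's (pseudo-)data matrix:

1. **Denoise**: rank-$r$ truncated SVD of the binary matrix, $r = K + 1$
   (signal plus an intercept direction), clipped to
   $[\varepsilon, 1-\varepsilon]$, $\varepsilon = 10^{-3}$.
2. **Linearize**: entrywise inverse link (logit).
3. **Rotate**: column-center, second SVD, retain $K$ right-singular
   directions scaled by singular values ($/\sqrt N$), Kaiser-normalized
   Varimax rotation. Rotation is orthogonal, so the loading Frobenius norm
   is preserved.
4. **Threshold and binarize**: loadings below $\tau$ are zeroed and the
   survivors' pattern becomes $Q_0$; columns are sign-fixed so the largest
   surviving loading is positive; an emptied column has its largest
   original loading restored (with a warning) so no attribute starts
   unmeasured. The default threshold is
   $\tau = 2\sqrt{K \log(\max(N, M))/N} \cdot \max(1, s)$ with $s$ the
   median over attributes of the largest absolute rotated loading. The
   scale factor is essential: loading magnitudes are proportional to the
   (unknown) coefficient scale, so any fixed absolute cut either drowns in
   cross-talk when coefficients are large or deletes everything when they
   are small; the $\sqrt{\log/N}$ term handles sampling noise and serves
   as an absolute floor.
5. **Rescale**: per attribute, persons are scored by projecting the
   centered linearized matrix onto the loading column and binarized at the
   midpoint of a deterministic 2-means split (centers initialized at the
   10%/90% score quantiles; an empty cluster falls back to the median with
   a warning). The empirical distribution of these provisional profiles is
   $\pi_0$, and per-unit least-squares regression of the linearized rows on
   the provisional-profile effect design, restricted to the $Q_0$ support,
   gives correctly scaled $B_0$. This concrete realization of the rescaling
   step is isolated behind `rescale_and_score()` so it can be swapped.

Before EM, `fit_exploratory()` floors the starting proportions
($0.9\,\pi_0 + 0.1/2^K$): an empirical profile distribution at moderate $N$
contains exact zeros, and a profile with zero prior mass can never be
revived by EM.

A comparison variant that skips denoising and rotates the loadings of the
raw (clipped, linearized) matrix is available behind
`varimax_direct = TRUE`; it is off by default.

## The synthetic world

`make_design()` builds the benchmark generating model used throughout the
tests: a $D = 3$ ladder with widths $(J, K_1, K_2, K_3) = (30, 7, 4, 2)$,
layer 1 following the requested measurement model and the deeper layers the
parsimonious main-effect model. These widths, the coefficient scales, and
the sample sizes $N \in \{500, 1000, 2000\}$ used in the tests are
configurable stand-ins — the benchmark designs in the published literature
report such setups only qualitatively, without their generating constants —
so absolute recovery numbers here are properties of *this* stated world,
not reproductions.

* **Q-matrices** are `[I; I; random rows]`: identity blocks first (at most
  two), then rows drawn uniformly from nonzero binary patterns,
  rejection-sampled until every attribute is measured by at least three
  rows (or as many as the layer allows — the $7 \times 4$ second-layer
  matrix cannot contain two disjoint identity blocks, a structural limit of
  the default widths that `check_ladder_structure()` reports). For the
  all-effect and DINA cases the random rows are capped at three attributes:
  a conjunctive item requiring four or more of seven attributes is almost
  never answered correctly and carries no signal, which is not how such
  items are written in practice.
* **Coefficients**: nonzero main effects equal $c_d$ and intercepts
  $-c_d/2$, with $c = (3.0, 2.2, 1.8)$ — shallow-layer relationships are
  deliberately stronger than deep ones, so deeper layers are noisier and
  harder, as in real assessments. For all-effect units with $|S| \ge 2$ the
  mains get $c/(2|S|)$ and the top interaction $c/2$ (lower-order
  interactions zero), keeping the top interaction the largest coefficient;
  DINA units get the single interaction $c$.
* **Deepest proportions**: a Dirichlet(5) draw — mildly non-uniform.
* **Reproducibility**: every design and sample is a pure function of
  `(case, N, seed, …)`; each layer consumes its own derived RNG substream,
  and the caller's RNG state is never touched.

What a green recovery test establishes, and what it does not: the estimator
recovers layer-1 structure and probabilities accurately, and improves with
$N$, *in this world* — binary complete data, a correctly specified ladder,
moderate coefficient scales. It says nothing about missing responses,
polytomous items, misspecified depth or widths, or the magnitudes one would
obtain under any particular published benchmark's unpublished constants. Deep-layer recovery
(layers 2 and 3) is markedly noisier than layer 1, as expected: deeper
layers sit behind two stochastic relationships and see only pseudo-data.

## Evaluation and label switching

An exploratory fit is identified only up to permutation and complement
recoding (reflection) of each layer's attributes. `align_fit()` searches
permutations (exhaustive up to $K = 8$, greedy beyond) maximizing Q-matrix
entry agreement, breaking ties by $\theta$ RMSE, then chooses reflections
minimizing $\theta$ RMSE; a layer's permutation consistently re-indexes the
rows of the next layer's Q-matrix, and a reflected attribute flips its
conditional probabilities as a unit of the layer below. Reflections are
included because nothing in an exploratory fit distinguishes an attribute
from its complement. `p_theta_metrics()` then reports, per layer, RMSE and
mean absolute error of the marginal profile distribution $p^{(d)}$ and of
the full conditional probability table $\theta^{(d)}$;
`q_accuracy()` reports exact-row and entry proportions.
`run_replication_study()` wraps simulate–fit–align–measure over
replications; per-replication RMSEs are averaged, with the
root-of-mean-MSE variant reported alongside (`*_rmse2`) since the two
conventions differ and the field uses both.

## Known limitations

* Fitting is logit-link only; identity-link (ACDM/GDINA) estimation would
  need box-constrained weighted least squares in the M-step.
* No missing data; a cell that is not 0/1 is an error, never imputed.
* $D$ and the layer widths are taken as known; no automatic dimension
  selection.
* DeepDINO is not implemented; by DINA/DINO duality, recoding responses
  ($x \mapsto 1-x$) maps one to the other.
* The two-identity-blocks structural check is a heuristic screen common to
  restricted latent class identifiability results, and advisory only; it is
  not a verification of the formal identifiability conditions.
* Deep-layer estimates inherit the error of every shallower layer through
  the pseudo-sampling step; at the default scales, layer-3 proportion
  estimates are qualitative at best for $N \le 2000$.
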