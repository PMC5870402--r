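---
title: "Sparse principal covariates regression: model, tuning and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse principal covariates regression: model, tuning and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Principal covariates regression (PCovR) summarises a block of predictors
$\mathbf{X}$ ($I \times J_x$) by a few component scores
$\mathbf{T} = \mathbf{XW}$ and uses those scores both to reconstruct the
predictors and to predict outcomes $\mathbf{Y}$:

$$
\mathbf{X} = \mathbf{T}\mathbf{P}_x^T + \mathbf{E}_x, \qquad
\mathbf{Y} = \mathbf{T}\mathbf{P}_y^T + \mathbf{E}_y .
$$

All variables are centred and scaled to sum of squares one
(`center_scale()`), so a block's squared Frobenius norm equals its number of
variables.  The criterion minimised is the convex combination

$$
L = (1-\alpha)\,\frac{\lVert \mathbf{Y}-\mathbf{XWP}_y^T \rVert^2}
  {\lVert \mathbf{Y} \rVert^2}
  + \alpha\,\frac{\lVert \mathbf{X}-\mathbf{XWP}_x^T \rVert^2}
  {\lVert \mathbf{X} \rVert^2},
$$

equivalently $\lVert \mathbf{Z} - \mathbf{XWP}^T \rVert^2$ with the weighted
concatenation $\mathbf{Z} = [w_1\mathbf{Y}\; w_2\mathbf{X}]$,
$w_1 = \sqrt{1-\alpha}/\lVert\mathbf{Y}\rVert$,
$w_2 = \sqrt{\alpha}/\lVert\mathbf{X}\rVert$
(`build_concatenated_target()`).  $\alpha = 1$ gives principal components
regression, $\alpha = 0$ ordinary (multivariate) regression.  The sparse
extension (SPCovR) adds an elastic-net penalty on the component weights
only:

$$
L_{pen} = L + \lambda_1 \lvert \mathbf{W} \rvert_1
            + \lambda_2 \lVert \mathbf{W} \rVert_2^2 .
$$

The weights are the selection device: a variable with an all-zero row of
$\mathbf{W}$ does not contribute to any component score.  The loadings are
left unpenalised and carry the identification constraint instead — either
unit-length columns of the concatenated loading matrix (the default; allows
correlated loadings) or orthonormality.  Without a loading constraint the
penalty could be satisfied trivially by shrinking weights and inflating
loadings.

## Estimation

`solve_pcovr()` computes the exact non-sparse solution under orthonormal
scores: the optimal scores are the top eigenvectors of
$H_X \mathbf{ZZ}^T H_X$ (with $H_X$ the projector onto the column space of
$\mathbf{X}$), obtained from the eigendecomposition of a Gram matrix no
larger than $\min(I, J_x)$, so both tall and wide blocks are handled.

`fit_spcovr()` alternates two conditional updates until the relative change
of the penalised loss drops below `tol`:

* **Weights** (`update_weights()`, compiled): cyclic coordinate descent.
  Each $w_{jr}$ update is the exact univariate elastic-net minimiser — soft
  thresholding of the partial-residual covariance at $\lambda_1/2$, divided
  by $\lambda_2 + \lVert p_r \rVert^2 \lVert x_j \rVert^2$.  The residual is
  carried incrementally within a component and recomputed from the scores
  at every component cycle, which bounds floating-point drift (an internal
  check errors if any conditional step increases the loss by more than
  1e-8).
* **Loadings** (`update_loadings()`): in unit-length mode, each column is
  the normalised cross-product of the deflated target with its score
  column, cycled until stable; in orthogonal mode, the orthogonal
  Procrustes solution from the SVD of $\mathbf{T}^T\mathbf{Z}$, with an
  equivalent $R \times R$ eigendecomposition path used when the number of
  variables is large.

The loss is non-increasing across every conditional step, and since it is
bounded below the alternation converges to a stationary point.  Local
optima are handled by multistart: the rational start is the exact
non-sparse solution re-expressed under the active loading constraint
(column norms or a rotation folded into the weights, so it reproduces the
exact loss), plus `n_random_starts` random configurations (default 5)
scaled to unit score variance.  Fits are deterministic given `seed`.
`refit_fixed_support()` re-estimates any zero pattern without penalties,
undoing the shrinkage bias of the lasso before interpretation or
prediction.

## Tuning pipeline

* **Weighting $\alpha$** — `maximum_likelihood_alpha()` sets
  $\alpha = J_x / (J_x + J_y\,\sigma^2_{\epsilon x}/\sigma^2_{\epsilon y})$.
  The error variances are plug-in moment estimates: the residual mean
  square of the $r$-component principal component approximation of
  $\mathbf{X}$, and the residual mean square of the regression of
  $\mathbf{Y}$ on those component scores.  With many predictors the
  expression approaches one; it is capped at 0.99 because a model fitted
  with $\alpha = 1$ ignores the outcome entirely.
* **Number of components** — `scree()` evaluates the exact criterion for
  $r = 1, \dots, r_{max}$ and reports the loss curve for visual inspection;
  an automated elbow (largest drop ratio between successive loss
  decrements) is supplied for pipelines and flagged low-confidence when no
  ratio dominates, as for unstructured noise.
* **Ridge $\lambda_2$** — tied to the lasso as a fraction
  (`lambda2_frac`, default 0.05).  The ridge stabilises the coefficients
  and groups strongly correlated variables.  The default fraction suits
  weakly correlated predictors; when the variables loading on a component
  are nearly collinear (as in a low-rank block with little per-column
  noise), 5% is too weak to group them — each refit then keeps an arbitrary
  subset of the correlated columns and resampling-based selection
  probabilities stall well below any sensible threshold.  For such data a
  grouping-strength ridge (`lambda2_frac` near 1) makes correlated columns
  enter and leave together; the stability-selection checks in the test
  suite use that setting on purpose.
* **Lasso $\lambda_1$** — `run_stability_selection()`.  The path runs from
  `compute_lambda_max()` (the smallest value at which a coordinate sweep
  from zero stays at zero) down to $10^{-4}\lambda_{max}$, log2-equispaced
  (`build_lambda_path()`, 50 values by default).

## Stability selection

A set of $N$ resamples (default 500; fraction $f = 0.5$ of the rows, drawn
with replacement) is fixed up front and re-analysed — including re-centring
and re-scaling, so the penalty acts on the same scale as the full-data fit
— at every lasso value, warm-started from the full-data reference at that
value.  Because components are identified only up to permutation and sign,
every resample solution is matched to the reference scores by maximal
Tucker congruence before its zero pattern is recorded.

A coefficient counts as selected in a resample once it has been non-zero at
any lasso value traversed so far; the selection probability
$\pi_{jr}$ is the fraction of resamples in which that has happened.  This
cumulative definition matters in practice: with correlated predictors,
coefficients enter and leave the path through substitution, and the
per-value selection frequencies never accumulate even when every resample
selects the coefficient somewhere along the range.  The per-value
probability matrices are still computed and reported.

The range is extended while $q_\Lambda$ — the average number of distinct
coefficients selected per resample so far, the quantity whose expectation
the false-positive bound controls — stays at or below

$$
q_R = \big\lfloor R\sqrt{J\,(2\pi_{thr}-1)\,E(V)} \big\rfloor
$$

(`q_bound()`; defaults $\pi_{thr} = 0.90$, $E(V) = 1$), or a user override
`q_override` when the target sparsity is known, as in benchmark studies.
The stable set is $\{(j, r): \pi_{jr} \ge \pi_{thr}\}$ and the final model
is its unpenalised refit.

## The simulation generator

`generate_dataset()` reproduces a two-component benchmark: initial weights
from the first two right singular vectors of a scaled standard-normal
$100 \times 200$ matrix; 80% of the $400$ weight entries set to zero at
random (320 zeros); weight columns rescaled so the component-score
variances match the designed relative strengths (levels 0.10/0.50/0.90 for
the first component); an initial outcome from fixed regression weights
$b = (1, -0.02)$, so the first component drives the outcome; a fixed-zero
PCovR refit with orthogonal loadings to make the noise-free blocks exactly
rank-two (the weights are rescaled once more after the refit); and normal
noise with one variance per block, calibrated so the signal fraction of the
expected total sum of squares equals the nominal VAF (levels 0.01/0.40/0.70
for the predictors, 0.02/0.50/0.80 for the outcome).  Test sets reuse the
weights, loadings and noise levels with a fresh signal draw
(`generate_test_set()`).

Two caveats documented for users of the generator truth: the true weights
are defined against the base matrix, not the noise-free block, so they are
not a fixed point of the model on the generated data ($P^TW \neq I$);
recovery there is meaningfully measured on the component scores (Tucker
congruence, `tucker_congruence()`, with $\ge 0.95$ read as equal components
and $0.85$–$0.94$ as fair similarity) and on test-set prediction (`press()`:
squared prediction error normalised by the observed total variation), not
on the exact zero pattern.  For support-recovery checks the test suite
plants a model-consistent instance instead ($P_x = W(W^TW)^{-1}$, so
$\mathbf{XW} = \mathbf{T}$ exactly).  Second, the generator emulates
homoscedastic normal noise and exactly rank-two signal; real expression
data have heavier tails, per-probe variance differences and many weak
components, so passing benchmarks here demonstrates correctness of the
machinery, not performance guarantees on real data.

`run_study()` crosses conditions, replicates and methods, and emits a tidy
table of congruence and PRESS values; `spcovr_study_method()` packages the
benchmark analysis (walk the lasso path to a target non-zero count, default
80, then refit the support) at each weighting value.

## Problem sizes and numerical choices

The shipped tests run the benchmark at its native size ($I = 100$,
$J = 200$, $R = 2$) with 5 replicates per condition and $N = 100$ resamples
in the stability checks, a deliberate scale-down of the published 20
replicates and $N = 500$ that keeps every property measurable on a laptop
in minutes; the module defaults remain at the published settings.
Convergence uses `tol = 1e-6` on the relative penalised loss with
`max_iter = 500`; ties in the elbow rule break toward fewer components;
degenerate situations (all-zero weights, a dead loading column, constant
columns in a resample) are caught explicitly and reported rather than
propagated as NaNs.  When the weighting parameter sits at a boundary
($\alpha \in \{0, 1\}$) the loadings of the unweighted block are recovered
by least squares on the scores so predictions remain defined.

## The vaccine-study recipe

`expression_difference_scores()` (post- minus pre-vaccination expression,
then per-probeset centring and scaling) and `hai_outcome()` (per subject,
the maximum over assays of the log fold change in antibody titers, centred;
natural logarithms) reproduce the preprocessing of a public influenza
vaccination study; `run_flu_recipe()` chains them into a config-driven
stability-selected SPCovR analysis ($R = 2$, $\alpha = 0.99$,
$\lambda_2 = 0.05\lambda_1$, $N = 500$, $\pi_{thr} = 0.90$, $E(V) = 1$; see
`inst/extdata/flu_recipe.cfg`).  The outcome enters centred but unscaled,
matching how the change scores are described; with a univariate outcome
this only rescales $w_1$.  Downloading or normalising the underlying array
data is out of scope; the recipe runs on any delimited-text expression
matrices, and the test suite exercises it end-to-end on a synthetic cohort
of 26 subjects by 2000 probesets.

## Known limitations

* The per-coefficient selection probabilities are meaningful only relative
  to the ridge strength; near-duplicate predictors need the
  grouping-strength ridge discussed above.
* The alternating algorithm guarantees a stationary point, not the global
  optimum; the multistart default (rational + 5 random) has been adequate
  on all tested instances, but heavily penalised fits occasionally retain a
  start dependence.
* Resampling uses the bootstrap as specified (with replacement); half-rate
  bootstrap resamples contain about 39% distinct observations, which makes
  selection probabilities conservative compared to half-subsampling without
  replacement.
* Missing values are not supported anywhere in the pipeline; filtering and
  imputation must happen upstream.
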