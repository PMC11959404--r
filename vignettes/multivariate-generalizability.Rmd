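---
title: "Multivariate generalizability analysis of paired operative ratings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multivariate generalizability analysis of paired operative ratings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvgtheory)
```

## The measurement model

Each assessed procedure yields a four-dimensional observation: the faculty
surgeon and the trainee each rate autonomy (4-level Zwisch scale) and
performance (5-level readiness scale). Rater role and item are *fixed*
facets — they are exhaustively represented in every observation — so they do
not contribute error terms; they define the four coordinates of a
multivariate design. The procedure is the *random* facet: each trainee's
observed procedures are a sample from a universe of procedures, and the
question is how well their mean generalizes to that universe.

For variable $v$, trainee $i$, procedure $j$:

$$y_{vij} = \mu_v + t_{vi} + p_{vj} + (tp)_{vij}$$

with effect vectors $t_i \sim N(0, \Sigma_t)$, $p_j \sim N(0, \Sigma_p)$,
$(tp)_{ij} \sim N(0, \Sigma_{tp})$. With one observation per cell, the
interaction and the residual cannot be separated and are carried as a single
$tp$ component. $\Sigma_t$ is the universe-score covariance matrix: its
diagonal drives reliability, and its off-diagonal faculty–trainee blocks
drive the dis-attenuated inter-rater correlations.

### Assumptions

* Ordinal ratings are analyzed as numeric scores (1–4, 1–5). This mirrors
  standard practice for these instruments, whose published means and SDs are
  computed on the numeric codings.
* Effects are independent across trainees, procedures, and cells, and
  homoscedastic within a stratum. Stratifying by postgraduate year (PGY) and
  case complexity before estimation is how heterogeneity across training
  stages and case difficulty is handled — components are estimated per
  stratum, never pooled.
* Procedures are crossed with trainees (with missing cells), not nested in
  them: different trainees assessed on the same procedure make the
  procedure component identifiable. A disconnected trainee–procedure
  incidence graph triggers an identifiability warning.

## Estimators

**Balanced closed form** (`estimate_balanced`). On a fully crossed design,
mean squares and cross-products from trainee marginal means, procedure
marginal means, and the interaction residual solve the expected-mean-square
equations

$$\hat\Sigma_{tp} = MS_{tp}, \qquad
  \hat\Sigma_t = (MS_t - MS_{tp})/n_p, \qquad
  \hat\Sigma_p = (MS_p - MS_{tp})/n_t.$$

The test suite checks this estimator entry-by-entry against a brute-force
double-loop summation oracle on every grid size from 2×2 to 6×6.

**Unbalanced REML** (`estimate_unbalanced`). Per variable, a crossed
random-effects model is fitted by REML (via `lme4`, with optimizer
tolerances tightened to `1e-12` so that on balanced data the fit reproduces
the closed form to better than `1e-6` relative — a tested contract).
Covariance components use the sum/difference identity: fitting the same
model to $y_u + y_v$ and $y_u - y_v$ gives, per effect,
$\widehat{\mathrm{cov}}(u,v) = (\hat\sigma^2_{sum} - \hat\sigma^2_{diff})/4$.
This is exact in balance and simple to verify, which is why it was chosen
over a joint multivariate likelihood; the two routes coincide on every
balanced fixture in the suite.

**Truncation.** Negative variance estimates are truncated to zero and
covariances clipped to $|\mathrm{cov}| \le \sqrt{v_u v_v}$ — the standard
reporting convention. Raw untruncated estimates are retained in
`attr(x, "raw")` and are what the oracle tests compare, so truncation never
masks an estimator defect.

## Composite D studies

Composite weights $w$ (nonnegative, normalized) collapse the four variables.
**The default is equal weights (1/4 each)**: nothing in the source analyses
this package mirrors states a weighting, and equal weighting treats the two
raters and two items symmetrically. Weights are configurable and logged in
every report. Then, for a design with $n_p$ procedures:

* universe score variance $\sigma^2_\tau = w'\Sigma_t w$;
* relative error $\sigma^2_\delta = w'\Sigma_{tp}w/n_p$ (affects
  rank-ordering);
* absolute error $\sigma^2_\Delta = w'(\Sigma_p{+}\Sigma_{tp})w/n_p$
  (affects the score level);
* $E\rho^2 = \tau/(\tau{+}\delta)$, $\Phi = \tau/(\tau{+}\Delta)$,
  $SEM = \sqrt{\Delta}$.

Both coefficients are monotone in $n_p$, so `min_procedures` finds the
smallest $n_p$ reaching a threshold by bisection; for $\Phi$ the closed form
$n^* = \lceil \tfrac{thr}{1-thr}\, w'(\Sigma_p{+}\Sigma_{tp})w / \sigma^2_\tau \rceil$
is used as an independent oracle in tests. Facet sizes are integers only —
procedures are discrete.

**Confidence margins.** `ci95_margin_paper` is $1 \cdot SEM$, matching the
±margin convention used in the reports this package emulates (e.g.
$\sqrt{0.020} \approx 0.14$); a conventional normal-theory 95% half-width
would be $1.96 \cdot SEM$ and is emitted alongside as
`ci95_margin_normal`. Reporting both, with the 1-SEM value explicitly
labeled, avoids silently endorsing either convention. Relatedly, published
margin tables of this kind are not always internally consistent: one
upstream stratum prints ±0.16 where $\sqrt{0.024}$ rounds to 0.15; the
package always computes margins from the error variance.

A note on printed variance-proportion tables: `proportion_table` computes
each effect's share from the components themselves. In the published
senior-stratum table that motivated the worked examples, the parenthesized
proportions of the two middle columns are mutually swapped relative to their
own components; the package reports computed proportions and does not
reproduce the misprint.

## Dataset-construction rules

`stratify` partitions rows by (PGY, complexity). `sample_balanced` then
applies, **once each and in this order**: (1) drop procedures assessed for
fewer than `min_trainees_per_procedure` (default 50) distinct trainees;
(2) drop trainees left with fewer than `procedures_per_trainee` (default 3)
procedures; (3) thin each surviving trainee to exactly that many procedures,
uniformly at random under the configured seed. Re-checking rule (1) after
thinning could cascade (thinning lowers per-procedure counts, dropping a
procedure un-balances trainees, …), and the construction being emulated is a
simple two-rule filter, so a single pass was chosen. A consequence worth
knowing: re-applying `sample_balanced` to its own output is a no-op only
when post-thinning per-procedure counts still meet the threshold — true on
the dense designs the rule targets (expected count
`n_trainees * k / n_procedures` well above the threshold), and that is the
regime in which the property is tested. Trainees with fewer than `k`
eligible procedures are excluded rather than retained with fewer, keeping
the thinned design balanced.

Rows missing any of the four scores are dropped at load time (pairing rule:
multivariate estimation needs the complete vector — both raters must have
completed the assessment within the instrument's submission window).

## The synthetic-data generator

`generate_dataset` draws the model above directly: latent multivariate
normal effects, optional ordinal discretization by fixed thresholds
(level $k$ iff the latent value falls in $(c_{k-1}, c_k]$), uniform
procedure linkage, and independent row deletion at `missing_rate`.

* **Continuous mode is the test surface.** The latent model's components are
  exactly the generating matrices, so parameter-recovery tests are sharp.
  Discretization biases components toward zero (coarse categorization loses
  variance), which is realism, not a test oracle — recovery tolerances are
  only stated for continuous output.
* **Default truth** (`senior_truth()`): variance magnitudes follow published
  senior-resident analyses — trainee diagonal ~0.03–0.10, procedure
  ~0.01–0.08, dominant interaction ~0.15–0.32, grand means 3.35/3.16/3.98/3.65
  on the two scales. Off-diagonals are illustrative: true-score correlation
  0.87 between the autonomy ratings and 0.45 between the performance
  ratings (the published dis-attenuated range), 0.55–0.60 across items,
  weak (0.1–0.5-scaled) procedure and interaction correlations. Published
  sources print only the variance diagonals, so the covariance structure is
  a modeling choice, made once and documented here.
* **What it does not emulate:** rater identity beyond the role dichotomy
  (every pair is "a faculty" and "the trainee"), clustering of procedure
  assignment by subspecialty or site, drift across calendar time, and the
  assessment-expiry workflow (modeled only as the pairing filter). A green
  recovery test therefore establishes estimator correctness under the
  declared model, not robustness to these real-data features.

## Numerical choices and degenerate inputs

* Monte-Carlo test tolerances are ~3 sampling SEs of the relevant estimator
  at the fixture's design size, computed from the estimator's sampling
  distribution (note the grand mean's SE includes $\sigma^2_t/n_t$ and
  $\sigma^2_p/n_p$ terms — shared effects, not just cell count).
* Zero total variance makes proportions undefined (error, not `NaN`);
  zero universe-score variance makes reliability 0 and any positive
  threshold "not attainable"; zero variance in *both* numerator and error
  yields an explicit `NA` with a warning, never a silent `0/0`.
* Thinning with exactly `k` eligible procedures is deterministic (no RNG
  draw), so forced selections do not perturb the seed stream of later
  strata; each stratum gets its own derived seed.
* PSD checks on generator inputs allow eigenvalues down to `-1e-8` (scaled)
  to tolerate floating-point symmetrization, and the MVN sampler uses an
  eigendecomposition so exactly singular (e.g. all-zero) covariances work.

## Limitations

* The rater facet is fixed: with one faculty rating per cell the faculty
  variance component is not separable, so "inter-rater reliability" here is
  the dis-attenuated role correlation, not a rater variance share.
* Covariance components are estimated pairwise, not jointly; in severe
  unbalance a joint multivariate REML could be more efficient.
* The per-variable REML fits assume Gaussian effects; with 4- and 5-level
  ordinal data treated as numeric this is an approximation, inherited
  knowingly from the analyses being reproduced.
* No standard errors or confidence intervals for the variance components
  are produced.
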