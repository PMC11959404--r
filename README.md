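# mvgtheory

Multivariate generalizability-theory analysis of paired operative ratings.

## The problem

Workplace-based operative assessment tools (for example smartphone apps in
the SIMPL family) collect, after each procedure, a *pair* of ratings: the
supervising faculty surgeon and the trainee each rate the trainee's
intraoperative **autonomy** (4-level Zwisch scale) and **performance**
(5-level readiness scale). How reliable is the mean of such ratings, and how
many distinct procedures does a resident need to be observed on before that
mean is trustworthy? The procedures a trainee happens to be assessed on vary
in number and difficulty, so "reliability" must account for
procedure-to-procedure variation, not just rater noise.

`mvgtheory` answers this with **multivariate generalizability (G) theory**
for a trainees × procedures design in which the rater role and the item are
*fixed* facets (they define four score variables, ordered faculty-autonomy,
trainee-autonomy, faculty-performance, trainee-performance) and the
procedure is a *random* facet. It is aimed at psychometricians and surgical-
education researchers working with this kind of paired rating data.

## The model

For score variable *v* on trainee *i* and procedure *j*:

    y_vij = mu_v + t_vi + p_vj + (tp)_vij

with 4×4 covariance components **Σ_t** (trainees; universe-score
(co)variance), **Σ_p** (procedures), **Σ_tp** (trainee × procedure
interaction, confounded with residual — one observation per cell). A G study
estimates the three matrices; a composite D study with weights **w**
(Σw = 1) projects them onto a design with *n_p* procedures:

    sigma2_tau   = w' Σ_t  w                      (universe score)
    sigma2_delta = w' Σ_tp w / n_p                (relative error)
    sigma2_Delta = w' (Σ_p + Σ_tp) w / n_p        (absolute error)
    Erho2 = tau/(tau + delta)   Phi = tau/(tau + Delta)   SEM = sqrt(Delta)

`Erho2` is the norm-referenced generalizability coefficient, `Phi` the
criterion-referenced index of dependability. The minimum number of
procedures with `Phi >= 0.8` has the closed form
`ceil( 0.8/0.2 * w'(Σ_p+Σ_tp)w / sigma2_tau )`. The dis-attenuated
faculty–trainee correlation for an item is the universe-score correlation
`Σ_t[u,v] / sqrt(Σ_t[u,u] Σ_t[v,v])`, free of procedure-sampling
attenuation.

Estimation is by closed-form expected mean squares/cross-products on fully
crossed balanced data and by REML (crossed random effects, missing cells)
otherwise; covariance components come from fitting the sums and differences
of variable pairs, `cov = (var_sum − var_diff)/4` per effect.

## Worked example

```r
library(mvgtheory)

tr  <- senior_truth()                       # illustrative PGY-5-like truth
sim <- simulation_config(n_trainees = 300, n_procedures = 10,
                         sigma_t = tr$sigma_t, sigma_p = tr$sigma_p,
                         sigma_tp = tr$sigma_tp,
                         grand_means = tr$grand_means, seed = 2026)
tab  <- generate_dataset(sim)                           # 3000 rows
thin <- sample_balanced(tab, sampling_config(3, 50, seed = 2026))  # 900 rows
cp   <- estimate_unbalanced(thin)
composite_dstudy(cp, n_p = 3)
```

```
Composite D study (n_p = 3)
  universe score variance: 0.050
  relative error variance: 0.036
  absolute error variance: 0.044
  generalizability coefficient (Erho2): 0.584
  index of dependability (Phi): 0.532
  SEM (absolute): 0.21
```

With 3 procedures the composite dependability is 0.53: an average over 3
procedures rank-orders trainees only moderately well under this (noisy)
truth, and a reported mean sits within ±0.21 rating points of the true score
(1 SEM). Continuing:

```r
min_procedures(cp, threshold = 0.8, n_max = 50)        # -> 11
disattenuated_correlation(cp, "autonomy")              # -> 0.89
observed_correlation(thin, "autonomy")                 # -> 0.36
```

Eleven distinct procedures would be needed for `Phi >= 0.8`. Faculty and
trainee *true* autonomy scores correlate at 0.89 even though the raw
observed correlation is only 0.36 — the difference is attenuation by
procedure-sampling and interaction error, which the G-study components
remove.

The same pipeline is scriptable:

```sh
inst/cli/mvgt simulate --config sim.json data.csv
inst/cli/mvgt sample --procedures-per-trainee 3 --min-trainees 50 \
    --seed 7 data.csv thinned.csv
inst/cli/mvgt gstudy thinned.csv components.json
inst/cli/mvgt dstudy --threshold 0.8 --criterion dependability components.json
inst/cli/mvgt run-all --config run.json --out-dir results/ --seed 7
```

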