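# dcvwalk

Heterogeneous random walk analysis of dense-core vesicle (DCV) transport.

## The problem

Dense-core vesicles carried by dynein along a neurite move retrogradely in
short pixel-sized steps, with frequent immobilisation. Across an ensemble of
kymograph-traced tracks, the mean displacement grows linearly with time but
the displacement **variance grows like t²** — ballistic superdiffusion that
an ordinary (homogeneous) random walk cannot produce. `dcvwalk` is for
researchers quantifying single-particle transport from kymograph tracker
output who want a mechanistic, fittable model of that behaviour rather than
a descriptive MSD exponent.

## The model

A vesicle attempts one step of size *a* (one pixel, 0.092 µm) every
τ = 0.01563 s and succeeds with probability *p*. The population is
heterogeneous: each vesicle's *p* is fixed for the track but drawn from a
beta density

f(p) = B⁻¹(α, β) p^(α−1) (1 − p)^(β−1),

where α measures the level of successful movement and β the degree of
failure (immobilisation). Marginalising the binomial step count over f(p)
gives a **beta-binomial** displacement law at t = nτ,

P(k | n) = C(n, k) · B(k + α, n − k + β) / B(α, β),

with

⟨x⟩ = α/(α+β) · a t/τ,
var(x) = αβ/[(α+β)(1+α+β)] · a²t/τ + αβ/[(α+β)²(1+α+β)] · a²t²/τ²,

whose quadratic term — pure population heterogeneity — is the
superdiffusion. The first passage time to a distance z = ka follows a
**beta-negative-binomial** law with the *same* α, β:

F(n | k) = C(n−1, k−1) · B(k + α, n − k + β) / B(α, β),
⟨t⟩ = (τz/a)(α+β−1)/(α−1)  (α > 1).

Fitting (α, β) to displacement histograms by maximum likelihood therefore
predicts the FPT distribution with no further fitting — the model's key
testable claim.

The package provides the distributions (`dbetabinom()`, `dbnb()`, moments),
the MLE (`fit_betabinom()`, a classed fit with the usual `summary`/`coef`/
`predict`/`simulate`/`plot` methods), a Monte-Carlo simulator
(`simulate_walks()`), a kymograph track pipeline (`read_tracks()`,
`dedupe_timepoints()`, `classify_tracks()`, `displacements_at_lag()`,
`empirical_fpt()`), and a labelled synthetic-data generator
(`generate_dataset()`, `strain_preset()`) so the whole chain is testable
without experimental recordings. `inst/cli/dcvwalk.R` is a thin command-line
front-end over the same functions.

## Worked example

Generate a synthetic wild-type-like dataset (a labelled mixture of
retrograde, stationary and anterograde tracks), run the pipeline, and fit:

```r
library(dcvwalk)
cfg   <- strain_preset("wild_type", n_tracks = 2000L)
paths <- run_generate("demo", cfg, seed = 1)
res   <- run_analyze(paths$csv, "demo-out", pipeline_config(strain = "wild_type"))
fit   <- run_fit(res$displacements, lag_s = 1.563, strain = "wild_type")
#> fit [wild_type] t=1.563 s: alpha=8.288 beta=12.68 (-logLik 3964.59, n=1029)
summary(fit)
#> Coefficients:
#>       Estimate Std. Error z value
#> alpha   8.2881     0.4380   18.92
#> beta   12.6848     0.6762   18.76
#>
#> Mean movement probability <p> = 0.3952
#> Overdispersion (intra-track correlation) rho = 0.0455
```

The fit recovers the generating parameters (α = 8.19, β = 12.95) within
about one standard error: 1029 retrograde tracks survive classification and
span the 1.563 s lag, and each contributes one step count k ∈ [0, 100].
The fitted parameters then predict first-passage behaviour with no extra
fitting:

```r
wp_hat <- walk_params(coef(fit)[["alpha"]], coef(fit)[["beta"]])
bnb_mean(1.84, wp_hat)        # mean FPT to 1.84 um: 0.857 s
sqrt(bnb_var(1.84, wp_hat))   # its standard deviation: 0.318 s
betabinom_moments(c(1.563, 3.126), wp_hat)
#>     t_s   n mean_um  var_um2
#> 1 1.563 100 3.63567 1.113780
#> 2 3.126 200 7.27134 4.068931
```

Note the variance nearly quadrupling as t doubles — the t² signature.
`demo-out/` also receives classification, displacement, moment and FPT
tables as CSV and an advisory PDF of the histogram/overlay figures.

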