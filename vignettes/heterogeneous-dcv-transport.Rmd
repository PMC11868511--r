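---
title: "Methods: a heterogeneous random walk model of retrograde vesicle transport"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a heterogeneous random walk model of retrograde vesicle transport}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The model and its assumptions

`dcvwalk` models the dynein-driven retrograde movement of dense-core
vesicles (DCVs) as a one-sided discrete random walk on the camera's
space-time lattice. In each elementary interval of length $\tau$ the vesicle
either advances one step of size $a$ (probability $p$) or stays put
(probability $1-p$). The model's essential ingredient is **population
heterogeneity**: $p$ is constant within a track but varies between tracks
with a beta density
$$f(p) = \frac{p^{\alpha-1}(1-p)^{\beta-1}}{B(\alpha,\beta)},
  \qquad \alpha, \beta > 0 .$$
$\alpha$ quantifies successful movement, $\beta$ the degree of failure; the
mean movement probability is $\langle p\rangle = \alpha/(\alpha+\beta)$ and
small $\alpha+\beta$ means a highly heterogeneous population.

Three consequences carry all of the package's statistics:

* **Displacements** at $t = n\tau$ are beta-binomial,
  $\bar P(k\mid n) = \binom{n}{k} B(k+\alpha, n-k+\beta)/B(\alpha,\beta)$
  (`dbetabinom()`).
* **Moments** are
  $\langle x\rangle = \tfrac{\alpha}{\alpha+\beta}\tfrac{at}{\tau}$ and
  $\mathrm{var}(x) = \tfrac{\alpha\beta}{(\alpha+\beta)(1+\alpha+\beta)}
  \tfrac{a^2 t}{\tau} + \tfrac{\alpha\beta}{(\alpha+\beta)^2(1+\alpha+\beta)}
  \tfrac{a^2t^2}{\tau^2}$ (`betabinom_moments()`). The $t^2$ term is strictly
  positive for finite $\alpha,\beta$ and vanishes only in the homogeneous
  limit $\alpha+\beta\to\infty$: heterogeneity alone produces ballistic
  superdiffusion, with no cooperativity or memory.
* **First passage times** to $z = ka$ are beta-negative-binomial with the
  *same* $(\alpha,\beta)$ (`dbnb()`): fitting displacements predicts the FPT
  law with no further fitting. This cross-prediction is the model's main
  falsifiable claim and the package tests it end to end on synthetic data.

Assumptions worth keeping in view: the walk is one-sided (reversals are not
modelled; the data motivating the model show low reversal rates), $p$ has no
spatial or temporal variation within a track, and steps are independent
given $p$.

## Parameters, units, defaults

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `alpha`, `beta` | beta-density shapes | — (fitted) | strain-dependent |
| `step_size` | $a$, µm per elementary step | 0.092 | one camera pixel |
| `step_time` | $\tau$, s per elementary step | 0.01563 | 1/10 frame interval |
| `steps_per_frame` | model steps per camera frame | 10 | ties $\tau$ to the 0.1563 s frame |
| `retro_threshold_px_per_frame` | classification speed cut | 1.6 (wild type), 1.0 (mutants) | near the local minimum between retrograde and stationary speed peaks |
| `fpt_thresholds_um` | FPT distances | 1.84, 3.68 | 20 and 40 pixels |

With these constants the reference lag $t = 1.563$ s is exactly $n = 100$
step attempts, so displacement histograms in "pixel steps" are directly the
beta-binomial support $k \in 0..100$.

The three strain presets (`strain_preset()`) carry the displacement-fit
parameters wild type $(8.19, 12.95)$, klc-1 null $(3.18, 4.15)$ and klc-2
reduced-function $(5.12, 12.87)$, and track counts sized so the expected
retrograde yield matches the published histogram sizes (851, 438, 1118).

## The first-passage variance formula

The FPT mean exists only for $\alpha > 1$ and the variance only for
$\alpha > 2$ (the law has a power tail $\sim n^{-(\alpha+1)}$). The variance
implemented is the standard beta-negative-binomial form
$$\mathrm{var}(t) = \beta\,\frac{\tau^2 z}{a}\,
  \frac{(z/a+\alpha-1)(\alpha+\beta-1)}{(\alpha-2)(\alpha-1)^2}.$$
A variant of this formula circulates with $(z/a+\alpha+1)(\alpha+\beta+1)$
in the numerator. The two disagree, and the package resolves the question by
oracle rather than by citation: at $\alpha=3,\beta=1,k=1$ direct integration
of $E[(2-p)/p^2]$ under $f(p)=3p^2$ gives $\mathrm{var}(n) = 9/4$, which the
$-1$ form reproduces exactly and the $+1$ form (giving $25/4$) does not. The
test suite repeats the arbitration numerically against truncated pmf sums at
the strain parameter pairs; the $+1$ variant fails by design.

## Fitting

`fit_betabinom()` minimises the negative beta-binomial log-likelihood over
$(\log\alpha, \log\beta)$ — positivity without constraints — boxed to
$[-7, 7]$, using `optim(method = "L-BFGS-B")` with a tightened convergence
tolerance (`factr = 1e5`) so that log-space and natural-space optimisation
agree to well below reporting precision (a tested invariant). Starting
values come from the standard beta-binomial method of moments
(`momest_betabinom()`); underdispersed or degenerate samples fall back to
$(1,1)$ with a warning. Standard errors are from the numerically
differentiated observed information at the optimum and are reported as
approximate; $\hat\alpha$ and $\hat\beta$ are strongly correlated (their
ratio — the mean movement probability — is much better determined than
either alone). Samples that sit entirely on one support boundary (all $k=0$
or all $k=n$) are rejected: the beta mixture is not identifiable there.

Observations taken at different lags can be fitted jointly under one
$(\alpha,\beta)$ (`fit_betabinom_joint()`, or per-observation `size`). The
joint likelihood treats a track's displacements at different lags as
independent, which overlapping windows on the same track are not; the
default analysis therefore fits the single reference lag $t=1.563$ s and the
joint fit is an option, not the default.

## Track pipeline

The pipeline consumes the tabular dialect of kymograph tracers (`track_id`,
`frame`, sub-pixel `x_px`; 0-based frames). Choices that were genuinely open
and the positions taken:

* **Duplicate time points** (two positions at one frame) are replaced by
  their arithmetic mean (`dedupe_timepoints()`).
* **Classification** uses a mean-speed cut: a track with net displacement
  $|d|$ px over $F$ frames spanned is *directed* when
  $|d| \ge \mathrm{thr}\cdot F$, with `>=` at the boundary (and a $10^{-9}$ px
  tolerance so exact boundaries survive floating-point representation);
  direction then separates retrograde from anterograde. This mean-speed
  reading is the only dimensionally consistent interpretation of a
  "threshold × number of frames" rule; the threshold is a config knob, as is
  the sign convention (`direction_sign`), because kymograph orientation
  depends on how the line was drawn.
* **Displacements at a lag** are measured from each track's first point
  only — no sliding windows, so samples are independent across tracks and
  per-lag counts shrink as the lag grows. Retrograde displacement is mapped
  to positive $k = \mathrm{round}(|d|/a)$ clamped to $[0, n]$; small
  anterograde excursions clamp to 0 and are counted in a warning.
* **Empirical FPTs** record the first frame at which the cumulative
  retrograde displacement reaches the threshold; tracks that end earlier are
  reported as censored, never silently dropped.

## Synthetic data: what it emulates and what it does not

`generate_dataset()` produces labelled track files with the statistical
structure the analysis assumes: retrograde tracks are the heterogeneous walk
observed at frame resolution (per-frame increments
$\mathrm{Binomial}(10, p)$, $p$ drawn once per track), stationary tracks
jitter about a constant, anterograde tracks drift oppositely at constant
speed, and every point optionally receives additive independent Gaussian
localisation noise (default $\sigma = 0.5$ px — localisation error is not
characterised in the motivating data, so this is a documented choice).
Track durations are uniform on 10–500 frames (500 frames is the acquisition
length). Class fractions default to 0.5/0.35/0.15
(retrograde/stationary/anterograde); the real proportions are unpublished
and these are deliberately arbitrary.

The generator does **not** emulate reversals, pauses with memory,
photobleaching or detection dropouts, tracker linking errors, or any
spatial variation of $p$. Passing end-to-end tests therefore demonstrates
internal consistency of the method on data that satisfy the model's
assumptions — not robustness of the pipeline to every artefact of real
recordings.

## Selection truncation: a known, quantified effect

The speed classification and the model interact: the cut at
$\mathrm{thr}/10$ on the per-frame success rate removes the slowest tail of
the beta population (about 0.7–1.9% of truly retrograde tracks at the
default thresholds and strain parameters). The displacement MLE on
classified tracks therefore converges not to the generating
$(\alpha,\beta)$ but to the pseudo-true parameters of the *truncated*
population — a shift of a few percent upward in both parameters, which is
several standard errors at $10^4$ tracks. The test suite quantifies exactly
this: fits bypassing the classifier (true labels) are unbiased, and fits
through the classifier land on the truncated-population optimum computed
independently by quadrature. Analyses that need unbiased population
parameters should treat the classified sample as what it is — the
super-threshold subpopulation — or lower the threshold where the data allow.
For the same reason, the model-consistency check between displacement fits
and FPT histograms is run with ground-truth labels, and its goodness of fit
conditions both data and model on a common 60-frame observation horizon to
remove finite-track length bias.

## Numerical choices

* All pmf evaluation is in log space via `lgamma`/`lbeta`/`lchoose`;
  exponentiation happens last, so $n$ in the hundreds cannot overflow.
* Infinite BNB sums truncate when the power-tail estimate
  $n\,\bar F(n)/\alpha$ drops below $10^{-12}$, capped at $10^6 k$.
* Chi-square goodness of fit merges adjacent categories until each bin's
  expected count reaches 5 (remainder folded into the last bin); degrees of
  freedom subtract one per parameter estimated from the same sample.
* The simulator draws serially under a single `set.seed`, which is
  bit-reproducible for the serial execution the package performs.
* The log–log variance regression over $t \in [1.5, 5.5]$ s has an exact
  model value slightly below 2 (about 1.90 at the wild-type parameters):
  the linear variance term, with coefficient ratio
  $A/B = (\alpha+\beta)\tau$, still contributes ~18% at $t = 1.5$ s.
  "Variance $\sim t^2$" is exact only asymptotically; tests compare
  simulations against the exact windowed slope, not against 2.

## Problem sizes used by the tests

The suite simulates $10^4$ walkers for moment and slope checks, $10^6$
walkers (via the walk's geometric waiting times) for the first-passage
Monte-Carlo oracle, and $2\times10^4$-track mixtures (about $10^4$
retrograde) for the end-to-end chain — sizes chosen to make 3-standard-error
comparisons meaningful while keeping the default test run inside a few
minutes on one CPU.

## Limitations

Beyond the generator's idealisations listed above: the model is one-sided
and cannot represent bidirectional tug-of-war transport; $(\alpha,\beta)$
are assumed common across lags (tested, not derived); FPT moments do not
exist for small $\alpha$ (heavy tails), so mutant-like parameter regimes
near $\alpha \le 2$ should be summarised by quantiles, not variances; and
standard errors are asymptotic observed-information approximations.
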