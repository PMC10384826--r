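---
title: "Growth and killing models for CTL control of tumor cells in collagen-fibrin gels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth and killing models for CTL control of tumor cells in collagen-fibrin gels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The assay and the data

Collagen–fibrin gels support in-vivo-like migration of T cells, which makes
them a useful middle ground between plate assays and intravital imaging for
quantifying how cytotoxic T lymphocytes (CTLs) eliminate target cells. In the
assay this package models, SIINFEKL-pulsed B16 melanoma cells are inoculated
into 0.1 mL gels at a desired concentration $T_a$ (cell/mL), alone or together
with activated OT1 CD8 T cells at concentration $E$ (cell/mL, constant over the
experiment); at chosen times the gel is digested and the surviving B16 cells
are counted by a clonogenic assay. A record is therefore
(dataset, experiment, replicate, $T_a$, $E$, time in hours, measured
concentration), which is exactly the CSV schema of `gel_schema()`.

Two quirks of the assay shape the whole analysis. First, the clonogenic count
recovers only a fraction $1/\alpha$ of the inoculated cells (typically around
0.35), so the effective initial condition is $T(0) = T_a/\alpha$ with $\alpha$
a free parameter shared across conditions. Second, occasional gels yield zero
cells; a log-scale analysis cannot use them, so `gel_filter()` either excludes
zero-count gels or imputes them at a limit of detection in the 2–10 cell/mL
range, as a re-run option rather than a change to the stored data.

## The model family

All models assume the tumor population follows
$$\frac{dT}{dt} = \left(f_g(E) - f_k(E)\right) T,$$
with per capita growth rate $f_g$ and kill rate $f_k$ (per day). With $E$
constant the log solution is linear in time,
$$\ln T(t) = \ln\frac{T_a}{\alpha} + (f_g(E) - f_k(E))\,t,$$
and the members of the family differ only in the two rate functions:

| model | $f_g(E)$ | $f_k(E)$ | parameters |
|---|---|---|---|
| MA | $r$ | $kE$ | $\alpha, r, k$ |
| Sat | $r$ | $kE/(h+E)$ | $\alpha, r, k, h$ |
| Power | $r$ | $kE^n$ | $\alpha, r, k, n$ |
| SiGMA | $g_0 + g_1/(1+E/g_2)$ | $kE$ | $\alpha, g_0, g_1, g_2, k$ |

The scientific contrast is between purely lytic control (MA, Sat, Power) and
the SiGMA model, in which CTLs also suppress tumor growth non-lytically: the
CTL-free growth rate is $r = g_0 + g_1$, and already moderate CTL
concentrations ($E \sim g_2$) halve the suppressible component $g_1$. Three
further forms address the early post-inoculation dynamics without CTLs:
plain exponential growth (EG), a per-desired-concentration-rate variant
(EG\_vr) for probing density-dependent growth, and two lag models — Alt1, an
algebraic-sigmoid per-capita rate integrated to
$\ln T = \ln(T_a/\alpha) + r(\sqrt{1+(t-t')^2} - \sqrt{1+t'^2})$, and Alt2, a
mixture in which a fraction $f_d$ of cells dies at rate $d$ while the rest
grow at rate $r$. The printed sqrt-form of the Alt1 solution circulating for
this assay omits the additive constant that anchors $T(0)=T_a/\alpha$; we
treat the anchored form as the intended model because it preserves the
stated sign-switching behavior and the three-parameter count, and expose the
raw form behind `model_spec("Alt1", raw_form = TRUE)` for comparison.
Finally, `SiGMA_ratio` replaces the mass-action kill term by the
ratio-dependent $kE/(1 + a_1 T + a_2 E)$; because $f_k$ then depends on $T$,
it is the one member solved by numerical integration (adaptive `lsoda`,
relative tolerance $10^{-8}$) rather than in closed form. Every `var_alpha`
variant replaces the single $\alpha$ by one per desired concentration.

Units are fixed once: times enter in hours and are converted to days in a
single place (`hours_to_days()`); all rates are per day; all concentrations
are cell/mL.

## Fitting and model comparison

Fits minimize the sum of squared residuals between $\ln$ measured and $\ln$
predicted concentrations, jointly over all conditions with shared parameters
(`fit_model()`). Because $k$, $h$, $g_2$, $a_1$, $a_2$ legitimately span many
orders of magnitude, they are optimized on $\log_{10}$ scale within
$[10^{-12}, 10^{12}]$; $\alpha$ is bounded to $[1, 20]$, rates to $[0, 10]$
per day ($[-10, 10]$ for the per-concentration EG\_vr rates, which can be
negative), $f_d$ to $[0,1]$. The optimizer is Levenberg–Marquardt with box
bounds, restarted from a fixed documented start plus Latin-hypercube draws
(50 starts by default; the small simulated-replicate fits of the power
analysis use 8–10). Fits are deterministic given the seed, boundary-pinned
estimates are flagged, and every start's objective is kept in the fit's
diagnostics.

Model comparison uses the Gaussian least-squares AIC
$$\mathrm{AIC} = n\ln\!\left(\frac{2\pi\,\mathrm{SSR}}{n}\right) + n + 2(K+1),$$
with $K$ the parameter count; we use the full-constant form because it is
what standard nonlinear-regression tools report, and AIC differences
$\Delta_i = \mathrm{AIC}_i - \min_j \mathrm{AIC}_j$ — the quantity model
selection actually rests on — are independent of that constant:
$\Delta = n\ln(\mathrm{SSR}_1/\mathrm{SSR}_2) + 2(K_1-K_2)$. Akaike weights
are $w_i = e^{-\Delta_i/2}/\sum_j e^{-\Delta_j/2}$; exact ties go to the
model with fewer parameters. Nested models can be compared by the F-test
or the likelihood-ratio $\chi^2$ ($n\ln(\mathrm{SSR}_r/\mathrm{SSR}_f)$);
both are exposed because both are in routine use for the varying-$\alpha$
comparison and they can disagree slightly at moderate $n$. Replicated
conditions allow a lack-of-fit F-test that splits the SSR into pure error
and lack of fit; residual normality is checked by Shapiro–Wilk. Confidence
intervals are linearized $t$-intervals from the Jacobian at the optimum,
computed on the optimization scale and back-transformed (hence asymmetric
for the $\log_{10}$-scale parameters); a residual-resampling bootstrap is
available when the Jacobian is ill-conditioned.

## Derived efficacy quantities

The time to kill 90% of the initially present targets is
$$t_{90}(E) = \frac{\ln 10}{f_k(E) - f_g(E)},$$
with an explicit `Inf` ("never") when killing does not outpace growth. The
control concentration $E_c$ is the smallest $E$ with $t_{90}(E)$ below a
horizon (100 days by default), found by bracketing and bisection of the net
kill rate on $[0, 10^9]$ cell/mL (relative tolerance $10^{-6}$, automatic
bracket expansion to $10^{12}$); saturating kill rates can make the target
unreachable, and that is reported as `Inf` rather than an error. Because
$E_c$ divides a rate difference by $k$-scale parameters, it is sensitive to
rounding in the parameters used: third-significant-digit changes in $k$ or
$g_0$ move $E_c$ by several percent (and by >10% for SiGMA), which is worth
remembering when comparing against published point values.
`efficacy_metrics()` tabulates $f_g$, $f_k$, the per capita kill rate
$f_k/E$, and cells killed per day over the first 24 h — the growth-only
minus full-model prediction at 24 h, $(T_a/\alpha)(e^{f_g} - e^{f_g-f_k})$
— dividing by $E$ after forming the difference, not before.

The regression view of the same data (`net_growth_rates()`,
`death_rate_power_fit()`) estimates a net growth rate $r_{net}$ per
condition as the least-squares slope of $\ln T$ against time over all
available time points (identical to the endpoint formula for two-point
conditions), averages over desired concentrations where several probe the
same $E$, forms the CTL-attributable death rate $K = r_0 - r_{net}$, and
fits $K = cE^n$ by unweighted OLS on the log–log scale (points with
$K \le 0$ cannot enter a log regression and are excluded with a report;
no precision weighting is applied). Under mass action the exponent is 1;
growth suppression produces an apparent $n < 1$ because the non-lytic
effect inflates $K$ at low $E$ — this is the diagnostic that motivates the
SiGMA model.

## The synthetic-data generator

`generate_dataset()` emulates what the analysis assumes about the assay: a
design grid of $(T_a, E)$ conditions crossed with time points and
replicates, a ground-truth model evaluated through the same
`log_prediction()` used in fitting, and ln-scale measurement noise, either
Gaussian or resampled with replacement from a residual pool. Pools are
built as deviations of $\ln T$ from the per-(condition, time) group mean
(`build_residual_pool()`), pooled globally across groups. The Gaussian
surrogate scale 0.51 is the root mean square ln-residual implied by the
reference SiGMA fit (SSR 112 over 431 gels) and is the default wherever
real residuals are unavailable. `simulate_study_data()` assembles replicas
of the five dataset designs — 451 gels, with 13 zero-count gels placed
deterministically in the high-CTL late-time cells where they occur in this
assay — so the full record accounting (451 → 438 after zero exclusion →
431 after capping CTLs at $10^7$ cell/mL) is reproducible offline. The
per-cell replicate counts (six, with small deterministic trims) reproduce
the published totals; the exact within-cell replicate structure of the
original experiments is not public, so only the totals are matched.

What the generator deliberately does not emulate: biological birth–death
stochasticity within gels (noise is measurement-scale only), time-varying
CTL concentrations, between-experiment random effects, heavy-tailed or
skewed residuals, and any spatial structure of the gel. Tests passing on
these synthetics therefore validate the estimation and selection machinery
under the model family's own assumptions; they do not certify that real
gel data satisfy those assumptions — on real data the residuals are known
to fail normality checks, and quantities that measure real-data misfit
(e.g. a large lack-of-fit F for exponential growth) will not reproduce on
replicas generated from the fitted family itself.

## Power analysis for experimental design

`weight_matrix()` asks how often a design lets model selection recover the
generating model among the saturating, power-law, and growth-suppression
alternatives (the mass-action model is omitted from the triple, as it is
never competitive on this assay; it can be included via `generators`). For
each generator, 100 replicate experiments are simulated, all three models
fit to each, and the best-by-Akaike-weight tallied into a column of
frequencies — columns sum to one, and the matrix entries are selection
frequencies, not averaged weights (an averaged-weight mode exists as a
sensitivity check). Designs are compared by
$$|\Delta D| = \big|\,|\det A| - |\det B|\,\big| \in [0, 1],$$
the gap between the parallelepiped volumes spanned by the two matrices'
columns: identity (perfect recovery) has $|\det| = 1$, an uninformative
matrix with equal columns has 0.

Two significance assessments are provided. The Monte-Carlo null draws pairs
of random column-stochastic matrices with columns uniform on the 2-simplex
(flat Dirichlet — the stated "columns normalized to unity" constraint admits
other samplers, e.g. normalized uniform cube draws, which change the null,
so the choice is documented and fixed), computes $|\Delta D|$ per pair, and
reports the exceedance fraction with the add-one correction
$(1+\#\{\mathrm{null} \ge \mathrm{obs}\})/(n+1)$, keeping p-values in
$(0,1]$; the default is $10^5$ draws (configurable upward; estimates
stabilize well below that). The permutation test pools the six observed
columns and enumerates all $\binom{6}{3} = 20$ reassignments into
pseudo-designs, counting ties as exceedances so that identical matrices
give $p = 1$; within-matrix column orderings ($3!\times3! = 36$ per split)
are enumerated in the default mode for transparency even though $|\det|$
is invariant to them, and an unordered-only mode gives the identical
p-value. With only 20 distinct splits the permutation p-value has a
resolution floor of 0.05, which is why the Monte-Carlo null is the primary
assessment and the permutation test the confirmation.

## Problem sizes and numerical choices in the test suite

The package's own checks run on: the 451-gel study replica for the
end-to-end comparison (50 starts per model); zero-noise designs of 96
observations for identifiability (recovery to $10^{-6}$); a 100-replicate
D1-type recovery matrix (8 starts per fit) for the power analysis; and
$10^4$–$10^5$ draws for Monte-Carlo self-consistency. These sizes keep the
full suite within a desk-scale run while leaving every statistical
assertion inside its sampling tolerance; all are ordinary function
arguments and scale up directly.

Other fixed numerical choices: SSR of exactly zero maps to AIC $-\infty$
(with a warning) so noiseless truth always wins selection; zero-count gels
are imputable only within the 2–10 cell/mL LOD range; the bisection for
$E_c$ refuses non-monotone net-rate profiles rather than silently returning
one of several roots; and all randomized procedures (start draws, noise,
bootstrap, null draws) restore the caller's RNG state and are reproducible
from their seed arguments.

## Limitations

The models are deterministic mean-field descriptions with constant CTL
concentration; no censored-data likelihood is offered for zero-count gels
(exclusion or LOD imputation only); confidence intervals are linearized
unless bootstrapped; and the power analysis evaluates the candidate designs
given to it rather than searching a design space.
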