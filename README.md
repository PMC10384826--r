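# ctlgels

Quantifying how cytotoxic T lymphocytes (CTLs) control tumor cell growth in
collagen–fibrin gels.

In the underlying assay, SIINFEKL-pulsed B16 melanoma cells are co-inoculated
into 3D collagen–fibrin gels with varying concentrations of antigen-specific
OT1 CTLs, and the surviving tumor concentration is counted over 0–96 h. The
package is for modelers and experimentalists who want to (i) decide *how*
CTLs exert control — pure killing versus killing plus non-lytic growth
suppression — from such count data, (ii) translate fitted models into
actionable quantities like the CTL concentration needed to eliminate a tumor,
and (iii) choose future experimental designs that can actually discriminate
between the candidate mechanisms.

## The models

All candidate models share the skeleton

    dT/dt = (f_g(E) − f_k(E)) · T,   ln T(t) = ln(Ta/α) + (f_g(E) − f_k(E)) t

where `T` is the tumor concentration (cell/mL), `Ta` the desired inoculum,
`1/α` the recovery fraction of the counting assay, `E` the CTL concentration,
and `f_g`, `f_k` per capita growth and kill rates (per day):

| model | f_g(E)              | f_k(E)      |
|-------|---------------------|-------------|
| MA    | r                   | k·E         |
| Sat   | r                   | k·E/(h+E)   |
| Power | r                   | k·E^n       |
| SiGMA | g0 + g1/(1 + E/g2)  | k·E         |

plus exponential-growth variants (EG, per-concentration-rate EG_vr), two
early-lag models (Alt1, Alt2), and a ratio-dependent killing variant
(SiGMA_ratio, solved by numerical integration). Models are fit to ln counts
by bounded multistart least squares, compared by AIC differences and Akaike
weights, and probed with nested-model, lack-of-fit, and residual-normality
tests. Derived quantities include `t90(E) = ln 10 / (f_k − f_g)` (time to
kill 90% of targets) and the control concentration `Ec` achieving `t90`
within a horizon. A simulation-based power analysis scores experimental
designs by model-recovery matrices and the determinant-difference statistic
`|ΔD|`, with Monte-Carlo null and permutation tests.

## Worked example

The package ships a synthetic-data generator that replicates the five-dataset
study design (451 gels, including 13 zero-count gels), so everything below
runs offline. With real gel data, replace the first line by
`read_gel_csv("your_gels.csv")`.

```r
library(ctlgels)

gels <- simulate_study_data(seed = 1)             # 451 gels, 5 dataset designs
filtered <- apply_filter(gels, gel_filter(max_ctl_conc = 1e7))
res <- run_fit_pipeline(filtered, n_starts = 50, seed = 1)
print(res$comparison)
```

    Model comparison (n = 431 gels):
     model n_params   ssr   aic  delta    weight
        MA        3 161.2 807.4 172.06 4.343e-38
       Sat        4 118.8 677.7  42.42 6.152e-10
     Power        4 115.7 666.4  31.11 1.760e-07
     SiGMA        5 107.2 635.3   0.00 1.000e+00
    Best model: SiGMA

Filtering kept the 431 gels with positive counts and CTL concentrations of at
most 1e7 cell/mL. The SiGMA model — mass-action killing plus non-lytic growth
suppression — carries essentially all the Akaike weight; the mass-action-only
model is decisively worse (Δ ≈ 172).

```r
best <- res$comparison$fits$SiGMA
print(best)
```

    Model SiGMA fit: n = 431, SSR = 107.17, AIC = 635.297
           estimate  ci_lower  ci_upper
    alpha 2.582e+00 2.417e+00 2.747e+00
    g0    1.082e-01 3.177e-02 1.847e-01
    g1    6.103e-01 5.260e-01 6.946e-01
    g2    2.879e+03 2.843e+02 2.916e+04
    k     3.300e-07 3.185e-07 3.419e-07

Read: only 1/2.58 ≈ 39% of inoculated cells are recovered at time zero; the
CTL-free growth rate is g0 + g1 ≈ 0.72/day, of which the g1 ≈ 0.61/day
component is suppressed at CTL concentrations above g2 ≈ 3e3 cell/mL; each
CTL per mL adds k ≈ 3.3e-7/day to the tumor death rate. The choice of model
matters practically:

```r
control_concentration(best$spec, best$par, horizon_days = 100)      # 4.11e5
ma <- res$comparison$fits$MA
control_concentration(ma$spec, ma$par, horizon_days = 100)          # 1.48e6
```

the mass-action model demands ~3.6-fold more CTLs (1.48e6 vs 4.11e5 cell/mL)
to eliminate 90% of the tumor within 100 days. The regression view shows the
diagnostic that rules mass action out — the CTL-attributable death rate
`K = r0 − r_net` scales sublinearly with CTL concentration:

```r
print(run_growth_pipeline(filtered)$death_curve)
```

    CTL-attributable death rate K = r0 - r_net, r0 = 0.705 /day
    Power-law fit K = c * E^n: n = 0.302 , c = 0.0224

For design planning, `run_reproduce("power")` compares two-time-point vs
four-time-point, short vs long, and closely vs widely spaced CTL designs via
model-recovery matrices; `weight_matrix()` exposes a single design's matrix.

A command-line wrapper with `fit`, `growth`, `t90`, `simulate`, `power`, and
`reproduce` subcommands is installed at
`system.file("cli", "ctlgels.R", package = "ctlgels")`.

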