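# biomarkergame

Eco-evolutionary dynamics of functional cancer biomarkers under therapy.

Cancer biomarkers (PSA, CA-125, circulating tumour DNA, ...) are used as
proxies for tumour burden, but many of them do work for the tumour:
production can speed proliferation, improve cell–cell competition and buy
resistance to chemotherapy — while exposing the producing cell to a
biomarker-targeted therapy. When the trait that is being *measured* is also
under *selection*, the readout drifts and therapy reshapes the tumour's
composition. This package is for mathematical oncologists and evolutionary
ecologists who want to explore those feedbacks quantitatively.

## The model

Per-cell biomarker production `v > 0` is a heritable trait. A rare variant
`v` in a resident population (trait `u`, density `C`) has per-capita growth
rate given by the fitness-generating function

    G(v, u, C) = r(v) (1 − a(v, u) C / K) − δ(v) − E_C(v) τ_C − E_T(v) τ_T

with growth benefit `r(v) = r0 (v/v0)^βr`, survival cost
`δ(v) = δ0 exp(βδ (v − v0))`, a logistic competition kernel `a(v, u)`
scaled to `a(v, v) = 1` and decreasing in the focal trait, chemotherapy
effectiveness `E_C(v) = ζC exp(−mC (v − v0))` (resistance rises with
production) and targeted effectiveness `E_T(v) = ζT (v/v0)^mT`
(vulnerability rises with production). Population and mean trait evolve as

    dC/dt = G(v, v, C) C,     dv/dt = k ∂G/∂v |(v = u)

with evolvability `k`. On top of this the package provides ESS solvers and
pairwise invasibility plots, a therapy-protocol engine (fixed phases,
sequential evolutionary traps, threshold-triggered adaptive schedules with
weekly physician visits) and experiment drivers for efficacy-bias,
trap-comparison, threshold-sweep and sensitivity analyses.

## Worked example

```r
library(biomarkergame)
p <- model_params()          # baseline parameter set

ess_table(p)
#>   treatment    v_ess     C_ess
#> 1      none 1.476967 0.5636517
#> 2     chemo 1.965817 0.3492902
#> 3  targeted 0.718271 0.5266032
```

Three evolutionary endpoints: left alone, competition pushes production to
1.48 — above the baseline `v0 = 1` that would maximise the population
(a cellular tragedy of the commons; equilibrium density 0.56 < 0.6).
Chemotherapy selects production up to 1.97; targeted therapy selects it
down to 0.72.

```r
balance_point(p)
#> [1] 1.19749
```

At trait 1.20 the two therapies are equally effective; adaptive thresholds
near this balance produce frequent switching and tight control, thresholds
far from it set evolutionary traps.

```r
trap_evaluation(p)
#>        protocol    min_C t_min final_v
#> 1    chemo_only 0.100000     0  1.5955
#> 2 targeted_only 0.100000     0  0.7872
#> 3    sequential 0.009266  2552  0.8259
```

Neither 16-week monotherapy ever pushes the population below its starting
density (0.1). The sequential protocol — chemotherapy first, which drives
the trait up and maximises vulnerability, then targeted therapy — crashes
it an order of magnitude lower: the evolutionary trap.

```r
rbind(efficacy_bias(protocol_preset("chemo_16wk"), p),
      efficacy_bias(protocol_preset("targeted_16wk"), p))
#>        protocol pop_ratio marker_ratio bias_direction
#> 1    chemo_only    0.5617       0.8383  underestimate
#> 2 targeted_only    0.8539       0.6287   overestimate
```

Judged by total biomarker, chemotherapy removed 16% of the tumour when it
actually removed 44% (efficacy underestimated); targeted therapy looks
better than it is (overestimated). With evolvability zero the two columns
agree exactly — the bias is purely evolutionary.

A command-line wrapper is installed with the package
(`exec/biomarkergame`): subcommands `ess`, `balance`, `pip`, `simulate`
and `sweep`, with YAML/JSON configs and reproducible JSON run manifests.

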