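# neutroqsp

A quantitative systems pharmacology (QSP) simulator for drug-induced
neutropenia caused by a **block of late-stage neutrophil maturation** — the
mechanism of cereblon E3 ligase modulator (CELMoD) compounds such as
avadomide (CC-122). It is aimed at pharmacometricians and translational
modelers who need to screen dose/schedule combinations for maturation-block
compounds *in silico*: predict the incidence, duration, and reversibility of
grade-3/4 neutropenia in a virtual patient population before committing a
clinical cohort to a schedule.

## The model

Six compartments track the neutrophil life cycle (cells/L, time in hours):
a proliferating precursor pool *P*, three maturation transit stages
*T₁–T₃*, a bone-marrow reservoir *R* of mature cells, and the circulation
*C* (the model's ANC). The drug acts only on the transit-2 → transit-3
maturation flux, which is Michaelis–Menten rather than first-order so that
cells accumulating behind the block cannot push through it:

    dP/dt  = k_prol (T₂ʰ/T₂)^γ P − k_tr1 P
    dT₁/dt = k_tr1 P − (k_tr2 + k_d) T₁
    dT₂/dt = k_tr2 T₁ − V_max·E(t)·T₂/(K_M + T₂) − k_d T₂
    dT₃/dt = V_max·E(t)·T₂/(K_M + T₂) − (k_tr4 + k_d) T₃
    dR/dt  = k_tr4 T₃ − (k_d + k_out (Cʰ/C)^β) R
    dC/dt  = k_out (Cʰ/C)^β R − k_elim C

with an inhibitory-Emax PD effect `E = 1 − Emax·Cₚ^n/(EC₅₀^n + Cₚ^n)`
driven by a two-compartment oral PK model, and two feedbacks: weak
proliferative stimulation (exponent γ) and strong egress acceleration
(β = 20) that holds ANC at baseline until the marrow reservoir runs dry —
the signature plateau-then-drop ANC trajectory of maturation-block
neutropenia.

A patient is four numbers (baseline ANC, reservoir ratio R₀/C₀, Michaelis
fraction K_M/T₂ʰ, and γ); every rate constant follows from the homeostatic
cascade `derive_homeostatic_parameters()`. On top of the simulator the
package provides Nelder–Mead fitting of longitudinal ANC data, virtual
cohort generation by kernel density estimation of fitted traits,
dose-by-schedule virtual trials with CTCAE grade-3/4 endpoint scoring,
two-sample Kolmogorov–Smirnov cohort validation, Latin-hypercube/PRCC
sensitivity ranking, and a synthetic clinical-study generator with known
ground truth (the original trial data are not public).

## Worked example

```r
library(neutroqsp)

# 1. The homeostatic cascade for the GBM median patient
gbm <- derive_homeostatic_parameters(patient_traits(4.5e9, 3, 0.6, 0.02))
gbm
#> Neutrophil life-cycle parameters (homeostatic cascade)
#>   rates (1/h):
#>     k_prol  0.0291049
#>     k_tr1   0.0291049
#>     k_tr2   0.0281049
#>     k_tr3   0.0271049
#>     k_tr4   0.0261049
#>     k_out   0.00770164
#>     k_elim  0.0231049
#>     k_d     0.001
#>   v_max:   1.95155e+08 cells/L/h
#>   k_m:     2.7e+09 cells/L
#>   gamma 0.02, beta 20
#>   levels:  Circ0 4.5e+09, Reserv0 1.35e+10 cells/L
```

Every rate is back-calculated from the four traits under the steady-state
assumption: with a 30 h neutrophil half-life, k_elim = ln2/30 ≈ 0.0231/h,
and the egress/transit chain follows (k_out 0.0077, k_tr4 0.0261, … ,
k_prol 0.0291/h).

```r
# 2. Simulate the median DLBCL patient on 3 mg daily
s <- simulate_patient(disease_traits("dlbcl"), reg = parse_regimen("3mg 28/28"))
s
#> ANC series: 673 points over 28.0 days; baseline 4.5e+09, nadir 1.66e+09 cells/L
time_to_nadir(s)
#> [1] 25
```

ANC holds near the 4.5E9 baseline for the first ~10 days (the reservoir
buffers the block), then declines to a nadir of 1.66E9 cells/L around day
25 — no grade-3 event for the median patient at 3 mg.

```r
# 3. A small virtual trial: 200 synthetic DLBCL-like patients
cohort <- synthetic_cohort(200, seed = 1)
scenario_grid(cohort, c(4, 6), c("5/7", "21/28"))
#>  dose_mg schedule n_doses gr3_single_pct gr4_single_pct gr3_7day_pct
#>        4      5/7      20            8.5            0.0          1.0
#>        6      5/7      20           24.0            0.0         12.5
#>        4    21/28      21           18.5            0.0         18.0
#>        6    21/28      21           49.0            4.5         41.0
#>  gr3_recovered_pct modal_nadir_day
#>                0.0              27
#>                0.0              27
#>               18.5              21
#>               49.0              21
```

The trade-off the tool exists to expose: at matched dose, 21/28 delivers
one more dose than 5/7 but roughly doubles grade-3 incidence and extends
events past 7 days — while its 7-day holiday lets every affected patient
recover above the grade-2 threshold within the cycle (recovered% equals
the incidence), which the 2-day holiday of 5/7 never achieves. Nadirs are
schedule-locked (day 21 for 21/28, end-of-cycle for 5/7). These are
structural trends; absolute percentages depend on the synthetic trait
distributions, since the original cohort's fitted distributions were never
released.

A thin CLI wraps the same functions:
`inst/cli/neutroqsp synth|simulate|fit|vpop|trial|endpoints|validate|gsa`,
each writing a `*.manifest.json` (full configuration, seed, version) next
to its output so any run can be replayed.

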