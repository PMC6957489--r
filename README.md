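# fusepore

Quantitative analysis of exocytotic fusion-pore kinetics from single-channel
planar-bilayer recordings and single-molecule FRET traces.

## The problem

During exocytosis, SNARE proteins open a nanometer-scale fusion pore between
a vesicle and the plasma membrane. In the nanodisc / black-lipid-membrane
(ND-BLM) configuration a single trans-SNARE-driven pore is trapped between a
nanodisc and a planar bilayer and read out as a unitary ionic current at a
fixed holding potential (Δψ = −60 mV, downward openings), while smFRET on
labelled SNARE pairs reports the zippering state of the same complexes.
Resolving the kinetic intermediates of pore assembly and disassembly then
comes down to a chain of statistical analyses:

* **idealization** of the current trace into closed / (partially open) /
  open segments by half-amplitude threshold crossing with hysteresis and a
  dead time;
* **dwell-time kinetics** — empirical CDFs of open and closed dwell times
  fitted with constrained exponential mixtures
  `CDF(t) = 1 − Σ Aᵢ exp(−kᵢ t)` (`Aᵢ ≥ 0`, `Σ Aᵢ = 1`, `kᵢ > 0`), the
  number of components chosen by `AIC = n ln(RSS/n) + 2(k + 1)` with
  `k = 2m − 1`;
* **conductance** — Gaussian-mixture fits of the current histogram,
  `γ = |ΔI| / |Δψ| × 1000` pS, and an approximate pore diameter from the
  cylinder-plus-access-resistance relation `1/γ = 4Lρ/(πd²) + ρ/d`;
* **fraction open** — open time / (open + closed time);
* **Ca²⁺ dose–response** — Hill fits
  `r(c) = floor + (ceiling − floor)·cʰ/(EC₅₀ʰ + cʰ)` for open time and
  percentage of occurrence, plus Pearson χ² occurrence contingency tests;
* **smFRET** — ratio `R = (I_A − 0.05·I_D)/(I_D + I_A)`, single-molecule
  selection by a single-photobleach step rule, and 2–3-component Gaussian
  mixture fits of the pooled ratio histograms.

Because the raw recordings behind the published analyses are not deposited,
the package ships first-class synthetic generators — a continuous-time
Markov pore-gating simulator with Hill-type Ca²⁺ rate modulation, Gaussian
recording noise, 4-pole Bessel filtering at 5 kHz and 10 kHz sampling, and a
two-colour smFRET simulator with 5 % donor crosstalk, per-channel noise and
single-step photobleaching — so every stage is validated against data with
known ground truth at the reported parameter values.

## Worked example

Simulate a large, Ca²⁺-triggered pore (open conductance 902 pS, the
reported ND9L/syt1 + Ca²⁺ condition) gating at 20 s⁻¹ opening / 5 s⁻¹
closing, then run the full analysis chain:

```r
library(fusepore)

model <- two_state_model(902, opening_rate_per_s = 20, closing_rate_per_s = 5)
report <- run_pipeline(list(seed = 1, model = model, duration_s = 40,
                            noise_sd_pA = 5.4, m_max = 3,
                            condition_tag = "ND9L/syt1 + Ca2+"))
summarize_report(report)
#> trace: 400000 samples @ 10000 Hz, 302 segment(s)
#> fraction open: 0.8340
#> closed dwells: n = 150, selected m = 1
#> open dwells: n = 150, selected m = 1
#> conductances: closed = 0.0 pS, open = 901.4 pS

estimate_pore_diameter(report$conductance$conductances_pS$open,
                       L_nm = 15, rho_ohm_cm = 100)
#> Approximate pore diameter: 4.624 nm (L = 15 nm, rho = 100 Ohm cm)
#>   model: cylinder + Hall access resistance, single effective resistivity
```

Reading the output: the idealizer segmented the 40-s trace into 302
dwells; the pore was open 83.4 % of the time (the generating stationary
value is 20/25 = 0.80); AIC correctly identifies single-exponential
opening and closure kinetics (the fitted rates are 22.1 s⁻¹ for opening
and 4.5 s⁻¹ for closure, against generating values of 20 and 5); the
current-histogram fit recovers the programmed 902 pS open conductance to
0.1 %, which corresponds to an approximate pore diameter of 4.6 nm under
the default geometry assumptions.

The geometry calculators reproduce the printed reconstitution numbers
directly:

```r
nd_surface_density(3, 13)        # 0.0226 copies/nm^2  (printed: 0.022)
nd_surface_density(3, 30)        # 0.0042
nd_surface_density(9, 30)        # 0.0127              (printed: 0.013)
blm_lipid_fraction(40, 50, 150)  # 0.00178 %           (printed: 0.0018 %)
```

## The analysis workflow

Numbered drivers under `analysis/` run the package end to end and write
their tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate_pores.R` | simulates the four headline nanodisc conditions (170–902 pS) as 20-s recordings |
| `02_pore_kinetics.R` | idealizes them; conductance, diameter, fraction open, AIC component counts |
| `03_dose_response.R` | Hill recovery at the reported EC₅₀/h values; a mechanistic Ca²⁺ titration; occurrence χ² |
| `04_smfret.R` | smFRET simulation, photobleach selection, 3-state mixture fit (0.2 / 0.5 / 0.7) |
| `05_geometry.R` | nanodisc densities and the BLM lipid fraction |

Run them in order from the repository root, e.g.
`Rscript analysis/01_simulate_pores.R`.

## Documentation

The methods vignette (`vignettes/fusion-pore-kinetics.Rmd`) describes the
gating and smFRET models, the idealization rules, why the exponential-
mixture RSS is computed on equal-probability CDF increments rather than
per-point ECDF residuals, the model-selection admissibility guards, all
tunable parameters with their defaults and units, and what the synthetic
benchmarks do and do not establish about real recordings.
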