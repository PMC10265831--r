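# mitcm

Quantitative analysis of solute clearance from the brain with dynamic
contrast-enhanced (DCE) MRI, for researchers studying glymphatic transport
and CSF–ISF exchange under different anesthetic or physiological conditions.

After intrathecal infusion of a low-molecular-weight contrast agent, the
tracer spreads through CSF spaces into brain tissue and is cleared again.
`mitcm` turns the resulting region-wise time signal curves (TSCs, percent
signal change from the pre-contrast baseline) into interpretable kinetic
quantities, and ships a synthetic-cohort generator with planted ground truth
so the whole pipeline is testable without animal data.

## What it computes

**TSC parameterization** — for each region curve `TSC(t)`:
arrival time `t_a` (first of three successive signal increases), peak
(`t_max`, `S_max`), area under the curve
`AUC = ∫₀^{6h} TSC(t) dt`, and the tail decay rate from a mono-exponential
fit `a·e^{−b·t}` over the window starting 90 min after the peak (fits with
`b ≤ 0` or a too-late peak are discarded).

**Mechanism-independent two-compartment model (MITCM)** — a region (e.g.
neocortex) is split into a closed outer envelope of uniform voxel thickness
`s` (6-connected erosion) and the enclosed inner rest. With compartment
curves `I_out`, `I_in` (voxel sums of percent change), the model

    dI_in/dt = k₁·I_out(t) − k₂·I_in(t),   I_in(0) = 0

is solved by the causal convolution
`I_in(t) = k₁ ∫₀ᵗ e^{−k₂(t−l)} I_out(l) dl`, and `(k₁, k₂)` are estimated
by least squares against the measured `I_in`. Total tracer volumes are the
curve integrals `V_out`, `V_in`; exchanged volumes are
`V_out→in = k₁·V_out`, `V_in→out = k₂·V_in`; the **net exchange ratio**

    NER = V_in→out / V_out→in

summarizes clearance efficiency (NER < 1: net retention in the inner
compartment over the experiment). A thickness search over `s = 1…17`
selects the envelope with the smallest percent misfit.

**Also included**: calcium-trace band power (zero-phase 20/40 Hz lowpass,
resampling to 60 Hz, 2-min segments every 12 min → 30 periodogram spectra
per 6-h recording, band sums for 0.1–1 / 1–4 / 1–20 Hz); mono-exponential
ADC fitting across b-values and a single-shell aqueductal flow surrogate;
and the study-style statistical tree (Lilliefors-corrected KS normality
gate → ANOVA or Kruskal–Wallis → t-test or Mann–Whitney post-hocs, boxplot
summaries with 5/25/75/95 percentiles).

## Worked example

```r
library(mitcm)
times  <- default_time_grid()                     # 40 frames over 6 h
specs  <- cohort_specs("MED", n = 8, seed = 42)   # planted k1, k2 + jitter
cohort <- generate_cohort(specs, times, seed = 42)

an <- cohort$animals[[1]]
tsc_parameters(an$outer, strict = FALSE)
#>   label condition animal_id      t_a    t_max    S_max      AUC        a
#> 1 outer       MED    MED_01 9.230769 83.07692 30.55044 3874.022 264.3344
#>            b decay_valid
#> 1 0.01818911        TRUE

fit <- fit_exchange_rates(curve_pair(an$outer, an$inner))
fit
#> exchange_fit: k1 = 0.01875, k2 = 0.01579 1/min, NER = 0.9547 (usable)
#>   residual 3.03 (3.32% of ||I_in||), V_out 3874, V_in 4393 a.u.
planted_ner(an)
#> [1] 0.9621232
```

The tracer arrives in the outer envelope after ~9 min, peaks at +30.6% at
83 min, and decays at 0.018 min⁻¹. The fitted exchange rates recover this
animal's planted values (k₁ = 0.0185, k₂ = 0.0156 min⁻¹) within the noise,
and the fitted NER 0.955 sits close to the planted 0.962 — slightly below
1, i.e. a small net retention over the 6-h experiment.

A full two-cohort comparison (MED vs ISO+MED, 8 animals each):

```r
res <- run_pipeline(default_config(seed = 1))
res$comparisons$NER
#> normality verdict: normal
#> omnibus ANOVA: statistic = 49.94, p = 5.626e-06
#>   ISO_MED vs MED (t-test): p = 5.626e-06 ***
```

The planted NER difference between the regimens (≈0.964 vs ≈0.943) is
recovered as a highly significant group effect.

## Command line

```sh
inst/cli/mitcm simulate --out sim/ --seed 2
inst/cli/mitcm tsc --in sim/tsc_MED.tsv --out params.tsv
inst/cli/mitcm fit --curves pair.tsv --out fit.json
inst/cli/mitcm run --config cfg.json --out run_out/
```

## Documentation

The methods vignette (`vignettes/clearance-kinetics.Rmd`) describes the
model and its assumptions, the synthetic world the generator emulates,
numerical choices and known limitations.
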