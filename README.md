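# cmrquant

Quantitative analysis of cardiovascular magnetic resonance (CMR) studies
for longitudinal myocardial therapy trials: first-pass perfusion
quantification by Fermi-model deconvolution, late gadolinium enhancement
(LGE) scar partitioning by remote-referenced SD thresholds, planimetric
ventricular function, and paired cohort statistics. A synthetic phantom
generator with known ground truth makes every stage testable without
clinical data.

## What it computes

**Myocardial blood flow and perfusion reserve.** Segmental tissue
signal-intensity curves are deconvolved against the arterial input
function (AIF) measured in the basal LV blood pool, using a Fermi
impulse response

> h(t) = A · (1 + e^(−w/k)) / (1 + e^((t − t_d − w)/k)),  t ≥ t_d

fitted by bounded Levenberg–Marquardt least squares over the first-pass
window. The plateau amplitude A is the myocardial blood flow (MBF,
mL/min/g); the myocardial perfusion reserve (MPR) is stress MBF / rest
MBF, aggregated over targeted and non-targeted coronary territories of a
16-segment short-axis model.

**Infarct core and peri-infarct zone.** With μ, σ the mean and sample SD
of a remote normal region on the same slice: total enhancement is
myocardium > μ + 2σ, core is > μ + 3σ, peri-infarct is the 2–3σ band.
Masses are voxel count × voxel volume × 1.05 g/mL; the package reports
%MDE_total (of LV mass) and core/peri as percentages of total, plus
transmural extent classes.

**Ventricular function.** EDV/ESV by Simpson slice summation of contour
polygon areas, EF = 100·(EDV−ESV)/EDV, LV mass = (epi − endo volume) ×
1.05 g/mL, and percent systolic wall thickening from ray-based sector
wall thickness.

**Paired statistics.** Two-sided paired Student t tests (α = 0.05) for
baseline vs 6-month and targeted vs non-targeted comparisons, reported
as mean ± SD with p values.

## Worked example

```r
library(cmrquant)

# Phantom rest/stress pair with ischaemic targeted territory
cfg   <- phantom_config(grid_shape = c(48L, 48L), n_frames = 40L)
model <- segment_model()                      # targeted = RCA territory
rest   <- generate_perfusion_study(cfg,
            ifelse(model$label == "targeted", 0.67, 0.97), "rest",  model)
stress <- generate_perfusion_study(cfg,
            ifelse(model$label == "targeted", 0.83, 2.01), "stress", model)
quantify_perfusion(rest, stress)$regions
#>         label mbf_rest mbf_stress      mpr
#> 1 nontargeted     0.97       2.01 2.072165
#> 2    targeted     0.67       0.83 1.238806
```

The targeted territory's reserve of 1.24 (printed as 1.2) against 2.07
(2.1) in the non-targeted territory is the signature of inducible
ischaemia: stress flow barely rises above rest where the supplying
vessel is diseased.

```r
# LGE phantom with a planted 40-voxel core and 60-voxel peri-infarct rim
set.seed(1)
ph   <- generate_lge_phantom(cfg, n_core = 40L, n_peri = 60L)
part <- partition_infarct(ph)
c(core = sum(part$core), peri = sum(part$peri),
  pct_core = part$pct_core_of_total, pct_peri = part$pct_peri_of_total)
#>     core     peri pct_core pct_peri
#>       40       60       40       60

# Function metrics from a contour phantom
vf <- quantify_function(generate_contour_set(edv_ml = 150, esv_ml = 73.5,
                                             mass_g = 180,
                                             thickening_pct = 48.1))
round(c(vf$edv_ml, vf$ef_pct, vf$mass_g), 2)
#> [1] 150.00  51.00 180.00
```

The full pipeline (simulate → perfusion → function → LGE → cohort
statistics) runs from one call and writes a CSV/JSON report bundle:

```r
run_pipeline(demo_pipeline_config("out", seed = 1))
```

A thin CLI over the same functions ships in `inst/cli/cmrquant.R`
(subcommands `simulate`, `perfusion`, `lge`, `function`, `cohort`,
`run`; exit codes 0/1/2 for ok/validation/compute).

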