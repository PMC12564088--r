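# gliomech

How much image quality does an MRI-informed tumor growth model actually
need? `gliomech` answers that question in silico for a mechanically coupled
reaction-diffusion model of glioma: it grows virtual tumors with known
parameters as noiseless ground truth, degrades the simulated data to chosen
signal-to-noise (SNR), spatial-resolution (SR) and temporal-resolution (TR)
levels, recalibrates the model from the degraded time courses, predicts
forward, and quantifies how parameter recovery and prediction accuracy
decay across the acquisition grid. It is aimed at computational oncology
groups designing pre-clinical imaging protocols for model calibration.

## The model

Tumor cells `N_t(x,t)` and vasculature `N_v(x,t)` are volume fractions
evolving by coupled reaction–diffusion dynamics with cross-diffusion:

    ∂N_t/∂t = ∇·[ D_t ( (1 − N_v/θ_tot) ∇N_t + (N_t/θ_tot) ∇N_v ) ]
              + k_t N_t (1 − N_t/θ_tot)

    ∂N_v/∂t = ∇·[ D_v ( (1 − N_t/θ_tot) ∇N_v + (N_v/θ_tot) ∇N_t ) ]
              + k_v N_v (1 − N_v/θ_tot) d(x)  −  k_dv N_v (1 − d(x))

with a vasculature-dependent carrying capacity `θ_tot ∈ [θ_min, θ_max]`,
angiogenesis at the tumor rim (`d → 1`) and vessel regression in the core
(`d → 0`). Diffusion is suppressed by mechanical stress,
`D = D_0 exp(−γ σ_vm)`, where the von Mises stress `σ_vm` solves linear
elastic equilibrium driven by the tumor gradient (`∇·σ = λ_f ∇N_t`) in a
two-tissue brain (shear modulus 800 Pa white / 466 Pa gray matter).
Calibration estimates the four global parameters `(D_t0, D_v0, k_t, k_v)`
by Levenberg–Marquardt least squares on voxelwise residuals of both
species; predictions are scored against same-resolution noiseless ground
truth with Dice overlap and Lin's concordance correlation coefficient
(CCC), and parameter recovery with percent error.

See `vignette("predictability-study")` for the full model description,
numerical scheme and design choices.

## A worked example

Degrade one acquisition condition (SNR 40, 0.063 mm³ voxels, calibration
days 1/3/5), recalibrate the central tumor twice with independent noise,
and score the day-6/10 predictions:

```r
library(gliomech)
cohort <- build_virtual_cohort()
cond   <- experiment_conditions()
one    <- cond[cond$snr == 40 & cond$voxel_volume == 0.063 & cond$tr == "3", ]
tbl    <- run_experiment_grid(cohort["central"], one, replicates = 2, seed = 7)
tbl[, c("replicate", "k_t_hat", "pe_kt", "pe_Dt", "pe_Dv",
        "dice_day6", "ccc_tumor_day10", "ccc_vasc_day10")]
```

```
 replicate k_t_hat pe_kt pe_Dt  pe_Dv dice_day6 ccc_tumor_day10 ccc_vasc_day10
         1   0.452 0.403 0.785 0.0756         1           0.999              1
         2   0.452 0.349 1.181 3.1229         1           0.999              1
```

Reading this: the true tumor proliferation rate is `k_t = 0.45`/day and
both replicates recover it to within 0.5% despite 2.5% multiplicative
noise on every voxel of every calibration day (`pe_*` are percent errors).
The day-6 tumor masks of prediction and ground truth overlap perfectly
(Dice 1) and the voxelwise day-10 agreement is near-exact for both species
(CCC ≈ 1). At this mid-range image quality the model is, as in the
full-scale study, essentially fully recoverable; the interesting decay
happens toward SNR 5–10 and the 0.50 mm³ resolution.
`summarize_metrics(tbl)` aggregates such tables into median ± interquartile
summaries per condition, tumor and metric.

A thin command-line front end over the same functions ships in
`inst/cli/gliomech.R` (`generate`, `run-grid`, `summarize`).

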