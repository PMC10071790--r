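# petdosim

Quantitative analysis chain for preclinical zirconium-89 immuno-PET:
from framed time–activity curves to human radiation-dose projections.

Antibody tracers labelled with long-lived positron emitters (⁸⁹Zr,
half-life 3.3 d) are characterized preclinically along a standard
chain: dynamic ¹⁵O-water PET for tissue perfusion, serial blood
sampling for plasma pharmacokinetics and tracer integrity, ex vivo
gamma counting and autoradiography for biodistribution, and whole-body
organ kinetics extrapolated to a human phantom for dosimetry.
petdosim implements that chain as tested, reusable R functions for
analysts who start from extracted regional curves and count tables
(image reconstruction and ROI delineation are upstream and out of
scope), together with a seedable synthetic-data module that generates
ground-truth inputs for every stage.

The models at the core:

* **1TCM perfusion** — dC_t/dt = K₁·C_a(t) − k₂·C_t(t), fit by
  bounded multi-start Levenberg–Marquardt against an image-derived
  arterial input; K₁ (mL·mL⁻¹·min⁻¹) is the reported perfusion.
* **Decay correction & SUV** — C·2^(t/T½); SUV = C/(A₀/W).
* **Plasma NCA** — linear-up/log-down AUC, terminal log-linear fit,
  CL = A₀/AUC₀→∞; blood-to-plasma ratio and a monoexponential
  intact-fraction model f₀e^(−rt) from SDS-PAGE percentages.
* **MIRD dosimetry** — residence times τ = ∫f(t)dt (physical decay
  included), rabbit→human scaling by relative organ mass
  f_h = f_r·(m_o,h/m_TB,h)/(m_o,r/m_TB,r), organ doses
  D = Σ τ_s·S(t←s) from a user-supplied S-value matrix, and ICRP-103
  effective dose E = Σ w_T·H_T.

## Worked example

Simulate one study, fit perfusion, run the plasma NCA and carry the
organ kinetics through to a human dose projection:

```r
library(petdosim)

cfg <- sim_config(seed = 1)                     # ground truth: K1 = 2.00 for UUO cortex
inp <- sim_input_function(cfg)                  # arterial input, 26-frame water schedule
tt  <- sim_tissue_tac(cfg, "uuo_cortex", inp, noisy = TRUE)
fit_1tcm(tt, inp, frame_value = "midpoint")
#> 1TCM fit [uuo_cortex]: K1 = 1.98 mL/mL/min, k2 = 2.095 /min (converged)

p  <- sim_plasma_series(cfg)                    # biexponential, CL_true = 10.1 mL/h
auc_and_clearance(p$time_h, p$plasma_kBq_per_mL, cfg$subject,
                  blood_kBq_per_mL = p$blood_kBq_per_mL,
                  intact_pct = p$intact_pct)
#> Plasma NCA (12 points): AUC(0-inf) = 728.2 kBq.h/mL, CL = 9.89 mL/h
#>   blood-to-plasma ratio 0.60

bio   <- sim_organ_biokinetics(cfg)             # liver-dominant organ fractions
pc    <- pipeline_config(seed = 1)              # synthetic masses + S values
human <- scale_rabbit_to_human(bio, pc$masses_rabbit, pc$masses_human)
(rt   <- remainder_and_total(residence_times(human)))
#> Residence times (h):
#>   liver            24.620
#>   spleen            5.276
#>   ...
#>   remainder        59.100
#>   total           114.261

effective_dose(organ_doses(rt, pc$smatrix))     # mSv/MBq, ICRP-103 weights
#> [1] 1.144
administered_dose(0.702, 37)                    # reported coefficient, 37-MBq dose
#> [1] 26
```

The fitted K₁ of 1.98 recovers the configured 2.00 mL/mL/min within
noise; the NCA clearance of 9.89 mL/h sits within 2% of the
generating biexponential's analytic 10.07 mL/h; organ residence times
plus remainder conserve the physical bound T½/ln 2 = 114.3 h; and the
reported effective-dose coefficient of 0.702 mSv/MBq projects a
37-MBq administration to 26 mSv. The shipped organ-mass and S-value
tables are synthetic placeholders (see their file headers), so the
effective-dose coefficient computed from them is illustrative of the
formalism, not a phantom-library result.

`run_pipeline(pipeline_config(seed = 1))` executes all five stages in
order and writes one provenance-stamped JSON report per stage; a thin
CLI with `simulate` / `perfusion-fit` / `pk` / `biodist` /
`dosimetry` / `run-all` subcommands lives at
`inst/cli/petdosim-cli.R`.

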