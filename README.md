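# eipdt: error inflection point-discriminant technique for pollen records

Pollen-based climate reconstruction assumes that vegetation — and hence
the pollen rain it sheds — is arranged along temperature and
precipitation gradients. Vegetation reshaped by people (clearance,
agriculture, plantations, settlements) breaks that assumption, both in
the modern samples used to calibrate pollen-climate transfer functions
and in the fossil samples being reconstructed. `eipdt` is for
paleoecologists who need a *quantitative, repeatable* rule for (i)
deciding which modern samples belong to the native-vegetation calibration
set, (ii) deciding which fossil samples come from human-affected
vegetation, and (iii) reconstructing past climate from the native
material only.

## The method

The core statistic is the cross-validated regression error of a
pollen-climate transfer function, viewed as a function of the Human
Influence Index (HII, a global 0-64 index of human pressure):

1. **Calibrate** — fit WA-PLS (weighted-averaging partial least squares)
   or modern-analogue transfer functions for mean annual temperature
   (MAT, °C) and precipitation (MAP, mm) on modern samples within 800,
   1,000, 1,200 and 1,400 km of the target site; obtain per-sample
   leave-one-out residuals.
2. **Error curve** — on the grid of integer HII values, place the
   bin-mean absolute residual ē(h) within the fitted normal error model,
   F(h) = Φ((ē(h) − m)/s), and plot Φ⁻¹(F) against HII
   (probability-percentage coordinates). Error regimes appear as straight
   segments.
3. **Inflection points** — fit 1-3 continuous line segments by least
   squares (grid search + golden-section refinement), choose the count by
   BIC, and pool the fitted breakpoints across radii and variables with a
   residual-resampling bootstrap for the uncertainty. The breakpoints
   ip1 (native/secondary) and ip2 (secondary/artificial) are the HII
   thresholds between vegetation systems.
4. **Discriminate** — threshold HII at the IPs to form a priori groups,
   fit a linear discriminant on √-transformed percentages (with a
   variance-retaining orthogonal projection), and classify fossil spectra
   native vs nonnative at the 0.5 posterior level; merge per-sample calls
   into phases.
5. **Reconstruct** — compare calibrations restricted to HII ≤ ip1,
   HII ≤ ip2 and all samples by RMSEP/R²; reconstruct MAT and MAP from
   the winning (native) calibration with bootstrap-plus-RMSEP error bars,
   flagging nonnative phases as unreliable (never deleting them).

A synthetic-data module generates a calibration world with Gaussian taxon
responses, planted HII thresholds (22 and 38 by default) and an
alternating native/anthropogenic fossil core, so the entire pipeline is
validated by parameter recovery — no external data needed.

## Worked example

```r
library(eipdt)

cfg  <- synthetic_config(seed = 1)          # planted thresholds 22 / 38
gm   <- generate_modern(cfg)                # 1,500 modern samples
ds   <- gm$dataset
ds$pollen <- to_percentages(ds$pollen)
ds   <- modern_dataset(ds$pollen, ds$meta)
spec <- radius_spec(120, 30)                # 800-1,400 km ladder

ips <- estimate_ips(ds, spec, n_boot = 200, seed = 1)
ips
#> HII inflection points (8 radius x variable fits, 200 bootstrap reps each)
#>   ip1 (native/secondary):  28.5 +/- 2.5
#>   ip2 (secondary/artificial): 38 +/- 4.7
```

`ip2` recovers the planted secondary/artificial threshold (38) almost
exactly. `ip1` sits above the planted onset (22): when disturbance
intensity ramps up gradually, the first detectable error inflection is an
*upper bound* on the true onset — see the methods vignette
(`vignettes/eipdt-methods.Rmd`) for why, and for when the bias vanishes.

```r
labels <- assign_groups(ds$meta, ips)
loo_confusion(ds$pollen, labels)
#>   per-group correct %: 90.9 / 100.0 / 100.0

core  <- generate_fossil_core(cfg)          # six-phase synthetic core
fc    <- classify_fossil(pollen_lda(ds$pollen, labels),
                         to_percentages(core$record$pollen))
call_phases(fc, core$record$age_calbp)
#>   phase      call age_young age_old n_samples
#>       1 nonnative        25     475        10
#>       2    native       525    1775        26
#>       ...                                      (6 phases, exactly as planted)

compare_training_sets(ds, ips, spec)$winners
#>  variable subset radius_km   n  rmsep     r2
#>       mat native      1200 341  0.904 0.9756
#>       map native      1400 485 79.514 0.9715
```

The native-vegetation subset wins the training-set comparison for both
variables (the full set validates ~4× worse), and reconstruction of the
core's native phases from that calibration correlates with the planted
temperature trajectory at r ≈ 0.94 with errors below the model RMSEP.

The whole workflow is also available as one call, `run_eipdt(config)`,
which writes every intermediate table plus a JSON manifest, and as a thin
command-line front end in `inst/cli/eipdt.R` (subcommands `simulate`,
`calibrate`, `detect-ip`, `run-all`).

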