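# dgim

Simulation and Level-A in vitro–in vivo correlation (IVIVC) analysis for
transfer dissolution testing of weakly basic drugs.

## The problem

Weakly basic BCS class IIb drugs (the bundled presets describe
ketoconazole) dissolve freely in the acidic stomach but are poorly soluble
at intestinal pH. On gastric emptying they transiently supersaturate and
then precipitate — the "spring and parachute" — so a single-vessel
dissolution test poorly predicts oral absorption. Two in vitro systems are
modelled:

* **DGIM** — a dynamic gastrointestinal model: three stirred vessels
  (stomach → duodenum → jejunum) connected by programmed pumps, with
  first-order gastric emptying (half-emptying time *t½* = 8 min),
  biorelevant secretion (1 mL/min of 4× concentrate) and *n*-octanol
  absorptive phases on the intestinal vessels.
* **USP II pH-shift** — one vessel, 250 mL gastric medium under 200 mL
  octanol, diluted 3-fold with concentrated intestinal medium at 20 min.

On top of the simulators sits the complete Level-A IVIVC chain used to
compare such apparatuses against rat pharmacokinetics.

## Models

* pH–solubility of a weak base (modified Henderson–Hasselbalch):
  `Cs(pH) = C_U (1 + 10^(pKa − pH))`, fitted by least squares on
  log-solubility with the intercept profiled in closed form.
* Pump programme: `va(t) = (ln2/t½)·Vg0·e^(−ln2·t/t½) + 1` mL/min,
  `vb = va + 1`, pumps stop at 40 min (gastric volume
  `Vg(40) = 300·2⁻⁵ = 9.375 mL`).
* Luminal kinetics (synthetic-data generator): precipitation flux
  `kp·V·max(C − Cs(pH), 0)`, octanol transfer `ka·V·C`, cup pH depressed
  in proportion to the gastric-origin volume fraction. Total drug mass is
  conserved to floating point.
* Degree of supersaturation `DS = C/Cs`, summarized by `DS_max` and
  `DS_AUC` (trapezoid, dimensionless·h).
* Double Weibull dissolution model
  `F(t) = F∞[f₁(1−e^(−((t−Tlag)/MDT₁)^b₁)) + (1−f₁)(1−e^(−((t−Tlag)/MDT₂)^b₂))]`
  with AIC-based selection against the single Weibull.
* IVIVC engine: polyexponential unit impulse response fitted to i.v. data
  (weighted LS, AICc order selection, ≤3 terms), non-negative staircase
  deconvolution, Level-A correlation
  `Fabs = AbsScale · Diss(Tscale·t − Tshift)`, segment-exact convolution
  back to plasma, and FDA-style prediction errors
  (`%PE = 100·(pred − obs)/obs`; qualification: mean |PE| ≤ 10%,
  individual ≤ 15%).
* NCA: Cmax/Tmax, linear-trapezoid AUC_last, absolute bioavailability.

## Worked example

```r
library(dgim)

res <- run_pipeline(tempfile("dgim"), seed = 42, noise_sigma = 0.05)
res$correlation
#> <IVIVC: Fabs = 1.0037 * Diss(1.5893 t - 0.01374)>
res$report
#>  metric   group  observed predicted pe_percent     role
#>    Cmax control  71330.42  69715.44 -2.2640760 internal
#>    Cmax   PVPVA  95989.22  92768.88 -3.3548962 internal
#>    Cmax    HPMC  94625.91  92587.55 -2.1541302 external
#>     AUC control 225584.54 228968.18  1.4999422 internal
#>     AUC   PVPVA 233907.07 234924.68  0.4350461 internal
#>     AUC    HPMC 232281.79 233424.89  0.4921164 external
#> mean |PE|: Cmax 2.59%, AUC 0.81%
res$validation
#>   metric mean_abs_pe max_abs_pe pass_mean pass_individual pass
#> 1   Cmax   2.5910341   3.354896      TRUE            TRUE TRUE
#> 2    AUC   0.8090349   1.499942      TRUE            TRUE TRUE
```

The pipeline simulates the three formulation groups (no inhibitor,
PVPVA, HPMC) through the transfer model, fits Weibull models to the in
vitro absorbed fractions, generates oral plasma from a known ground-truth
correlation (`AbsScale = 0.9757`, `Tscale = 1.629`, `Tshift ≈ 0`) with 5%
measurement noise, then runs the full deconvolution/correlation/convolution
chain and recovers that truth: the fitted `Tscale = 1.589` is within 2.5%
and every prediction error is far inside the qualification limits. With
`noise_sigma = 0` the recovery is exact to about 1e-14.

A single simulated run:

```r
run <- simulate_dgim(scenario = group_scenario("PVPVA"))
cmax_tmax(run$duodenal_aq)
#> $Cmax 4128.163   $Tmax 7       # ug/mL, min: early supersaturation peak
ds_metrics(ds_profile(run$duodenal_aq, run$pH_d,
                      run$scenario$solubility_fit))
#> <DS metrics: DS_max = 25.63 at t = 1, DS_auc = 14.51 h>
```

A command-line interface covers the same workflow
(`Rscript -e 'dgim::dgim_cli()' run-pipeline --outdir out --seed 1`; see
`?dgim_cli` for the other subcommands).

## Vignette

`vignettes/methods.Rmd` documents the model assumptions, the synthetic
data generator's stated world and its limits, numerical choices and known
limitations.
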