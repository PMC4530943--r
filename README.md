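# murretrend

Hierarchical Bayesian trend estimation for Marbled Murrelet radar counts.

Marbled Murrelets (*Brachyramphus marmoratus*) are secretive, threatened
seabirds that nest solitarily in old-growth forest and fly inland before
dawn. Marine radar at watershed mouths counts these pre-dawn inbound
flights, and a network of 58 monitoring stations in six conservation
regions of coastal British Columbia (HG, NC, WC, CC, EV, SC) provides the
longest population index for the species in Canada. `murretrend` is for
quantitative ecologists and monitoring programs who need defensible trend
estimates from such sparse, noisy, covariate-laden count series — at the
site, region and coast-wide scale, with honest uncertainty.

## The model

The expected count for survey $i$ at site $s$ in year $y$ is

$$
\hat C_{s,y,i} = \bigl(b_{0,s} + b_{1,s}(y-\bar y_s)\bigr)
\,(1 + Y_{R,y})\,\bigl(1 + a_R (D_i - c_R)^2\bigr)\,(1 + t\,T_i),
$$

a site-level linear trend (intercept referenced to the site's mean survey
year) multiplied by a region-wide year effect $Y_{R,y}$ (shared
interannual deviations, e.g. ocean conditions), a per-region quadratic
day-of-year detection curve ($D_i$ = day of year − 182), and a linear
radar-tilt detection factor. Observed counts are lognormal around
$\hat C$ with a region-specific residual SD. Site intercepts
($\mathrm{LogNormal}$), slopes ($\mathrm{Normal}$) and year effects are
exchangeable random effects with estimated hyperparameters; year effects
are anchored by reference years fixed at zero. The model is fitted by
adaptive random-walk Metropolis within Gibbs (compiled core), gated by
split-chain Gelman–Rubin and Monte Carlo error checks, and summarized as
proportional rates of change $r_s = b_{1,s}/b_{0,s}$ with probabilities of
decline, aggregated within posterior draws. See
`vignettes/murrelet-trend-model.Rmd` for the full account.

## Worked example

The `analysis/` scripts form the package's workflow on a synthetic
study-shaped dataset (the real supplementary count table is not
redistributable; `simulate_study_standin()` generates a calibrated
synthetic stand-in with the same design — 58 sites, 6 regions, ~912
surveys, 170 free parameters):

```sh
Rscript analysis/01_simulate.R           # generate the stand-in table
Rscript analysis/02_fit.R --production   # fit by MCMC (~2-6 min)
Rscript analysis/03_summarize.R          # trend tables + figures
Rscript analysis/04_recovery.R           # simulation-based calibration
```

`02_fit.R` reports the convergence gate:

```
Convergence gate: PASS (max split-Rhat 1.0093 over slopes/intercepts, max MC-error/SD 0.0289)
```

and `03_summarize.R` prints the headline trends (numbers from the run
above; your machine reproduces them exactly — fits are seeded):

```
Coast-wide rate of change: -0.9%/yr (95% CI -2.2% to 0.5%), P(decline) = 0.90
  CC: -0.3%/yr [-1.9%, 1.3%], P(decline) 0.66
  EV: -5.7%/yr [-11.0%, -0.1%], P(decline) 0.98  (95% CI excludes 0)
  HG: -0.7%/yr [-3.2%, 1.8%], P(decline) 0.71
  NC: 0.7%/yr [-0.7%, 2.1%], P(decline) 0.17
  SC: -1.5%/yr [-3.8%, 0.7%], P(decline) 0.91
  WC: -0.1%/yr [-1.7%, 1.4%], P(decline) 0.58
9 of 30 estimated year effects have 95% intervals excluding zero.
Detection multiplier at 12.3 degrees tilt: median 2.18, mean 2.18
```

Read: a moderate coast-wide decline (90% probability), driven by a strong
decline on East Vancouver Island, with nearly a third of the shared year
effects significantly different from zero — the generative signals the
stand-in was built with, recovered through the full pipeline. Region
rates at well-identified low-count regions (EV, SC) come back close to
their generative values; high-count regions shrink toward the coast-wide
mean, as the vignette discusses. The recovery study (`04_recovery.R`)
reports 95% interval coverage of 0.987 for site slopes and 0.95 for the
year-effect SD over 20 replicates.

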