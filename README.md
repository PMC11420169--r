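# motorsteps

Trajectory analysis for single-molecule recordings of processive
cytoskeletal motors. The motivating system is endogenous dynein walking
along axonal microtubules in live neurons, tracked at nanometre/millisecond
resolution: the motor advances in discrete ~8 nm steps, rarely steps
backward, and its runs are interrupted by pauses and direction reversals.
`motorsteps` turns raw 2D localization traces into the quantities that
characterise that behaviour, and ships a ground-truth simulator so every
stage is testable without instrument data.

The chain, for a trace of positions $(x_i, y_i)$ at times $t_i$ with
localization noise $\sigma_{loc}$:

1. **Step detection** — a bias-free piecewise-constant fit. Change points
   are placed by exact penalized least squares (PELT), first on the raw 2D
   coordinates, then refined on the axis-projected 1D signal, with a
   counter-fit acceptance criterion gating the whole fit. No prior on step
   number or size; all thresholds scale with the trace's own noise.
2. **On/off-axis decomposition** — each step displacement is projected onto
   the local direction of motion (windowed PCA of plateau centroids):
   $s_{on}$ signed retrograde-positive, $s_{off}$ perpendicular.
3. **Segmentation** — maximal same-direction runs become
   retrograde/anterograde segments; gaps between runs are pauses (same
   direction) or reversals (direction change), with speeds in µm/s
   (1 nm/ms = 1 µm/s).
4. **Markov chains** — two candidate mechanisms for reversals (regulated,
   with direction-specific pause/reversal states, vs tug-of-war with one
   pooled pause state) estimated as discrete-time chains; stationary
   distribution $\pi$ solves $\pi P = \pi$.
5. **Dwell-time kinetics** — intervals between steps fitted by left-truncated
   maximum likelihood under `exp1` ($k e^{-k\tau}$), `erlang2`
   ($k^2\tau e^{-k\tau}$) and `hypoexp2`
   ($\frac{k_1 k_2}{k_2-k_1}(e^{-k_1\tau} - e^{-k_2\tau})$), compared by
   Akaike weights $w_i = e^{-\Delta_i/2}/\sum_j e^{-\Delta_j/2}$ — the
   one-ATP-per-step vs two-ATPs-per-step question.
6. **Kymographs** — directional Fourier filtering splits a time–position
   image into retrograde and anterograde components exactly
   (retro + antero − axial = original), plus line-speed utilities.

See `vignettes/motor-trajectory-analysis.Rmd` for the models, assumptions,
frozen calibration constants and known limitations.

## Worked example

```r
library(motorsteps)

# simulate one dynein-like trace (8.7 nm steps, p_back = 0.04, exp1 dwells
# at 90/s, 3.5 nm localization noise, 1 ms sampling)
cfg <- sim_config(seed = 42, max_duration_ms = 1500)
sim <- simulate_trace(cfg, seed = 42)
sim$trace
#> <localization_trace 'sim-1': 298 points, 297.0 ms, site DHC>

fit <- decompose_steps(fit_steps(sim$trace))
fit
#> <step_fit 'sim-1': 298 points, 20 steps, rss 7174.3 nm^2>

fit_dwell_model(dwell_times(fit), "exp1", tau_min_ms = 3)
#> <dwell_fit exp1: k=84.07 | logL 65.20 AIC -128.40 | n=19 (+0 excluded < 3 ms)>

classify_motion(fit)
#> <motion_segmentation 'sim-1': retrograde=1, unclassified=2>
```

The trace carried 24 true steps; 20 survive detection (steps shorter than
the 3-sample plateau minimum merge — the left censoring that motivates the
3 ms truncation bound), the recovered dwell rate 84 s⁻¹ is within one
standard error of the configured 90 s⁻¹, and the single uninterrupted
retrograde run is classified as one processive segment.

An end-to-end cohort run:

```r
rep <- run_pipeline(pipeline_config(seed = 42, n_traces = 12,
                                    sim = list(max_duration_ms = 1500)))
rep
#> motorsteps run report (seed 42)
#>   traces: 12 | steps: 759 | segments: 68
#>   mean forward on-axis step: 12.41 nm | backstep fraction: 0.042
#>   off-axis > large threshold: 0.128 | > jump threshold: 0.0000 | median sigma_step: 1.59 nm
#>   retrograde speed: median 0.82 um/s (MAD 0.11, n=19)
#>   anterograde speed: median 0.88 um/s (MAD 0.14, n=9)
#>   traces with reversal: 54.5% | with pause: 63.6% | uninterrupted: 27.3% (n=11)
#>   pause/reversal median duration ratio: 2.6
#>   intra-event stepping: 11.8% of 17 events
#>   dwell: n=748 used, 0 excluded below 3 ms
#>   dwell model comparison (truncated):
#>     exp1      w(AIC)=0.731 rates=81.8 s^-1
#>     hypoexp2  w(AIC)=0.269 rates=81.8,8.447e+04 s^-1
#>     erlang2   w(AIC)=0.000 rates=139.5 s^-1
```

Reading this: the detected backstep fraction (0.042) matches the configured
0.04; the mean *detected* forward step (12.4 nm) exceeds the configured
8.7 nm because in this millisecond-dwell world sub-resolution dwells merge
adjacent steps — exactly why dwell fits are left-truncated; the single
exponential carries the largest Akaike weight (one rate-limiting transition
per step), with the unequal-rates model collapsing onto it
($k_2 \to \infty$) and the equal-rates model firmly rejected.

Command line (installed under `inst/exec/`):

```sh
motorsteps run --config run.json --out outdir/
motorsteps fit-steps --in traces.csv --out steps.csv
motorsteps dwell-fit --in traces.csv --tau-min 3 --out fits.json
```

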