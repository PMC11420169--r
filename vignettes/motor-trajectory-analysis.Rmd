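---
title: "Step detection, segmentation and dwell-time kinetics for motor-protein trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Step detection, segmentation and dwell-time kinetics for motor-protein trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motorsteps)
```

## Scope and model of the data

`motorsteps` analyses nanometre-precision localization traces of processive
cytoskeletal motors — the motivating system is endogenous dynein tracked in
live neurons, where a motor walks along an axonal microtubule in discrete
~8 nm steps, occasionally steps backward, pauses, or reverses direction.
A trace is a time-ordered sequence of 2D positions $(x_i, y_i)$ at times
$t_i$ (ms), each position being the true motor position corrupted by
isotropic Gaussian localization noise of standard deviation
$\sigma_{loc} \approx 3.5$ nm. The true position is piecewise constant
between steps: the signal is a 2D staircase.

The analysis chain is

1. **step detection** — a piecewise-constant (change-point) fit;
2. **axis estimation and decomposition** — each step displacement is split
   into an on-axis component $s_{on}$ (along the local direction of motion,
   retrograde positive) and an off-axis component $s_{off}$;
3. **segmentation** — runs of same-direction steps become processive
   retrograde/anterograde segments; gaps between runs become pauses (same
   direction on both sides) or direction reversals (opposite directions);
4. **Markov modelling** — two candidate discrete-time chains for the
   reversal mechanism are estimated from the segment sequences, with
   stationary distributions $\pi$ solving $\pi P = \pi$;
5. **dwell-time kinetics** — the intervals $\tau$ between successive steps
   are fitted by maximum likelihood under three models with left truncation,
   and compared by Akaike weights.

Every stage can be driven by the built-in generative simulator, which
produces traces with full ground truth, so each claim the package makes is
testable without instrument data.

## Units and conventions

All positions are in nm, times in ms, rates in s⁻¹ and speeds in µm/s
(1 nm/ms = 1 µm/s exactly). On-axis step sizes are signed with *retrograde
positive*: the retrograde direction is taken from trace metadata when
declared, otherwise from the trace's net displacement. In kymographs, rows
are time, columns are position with the soma at low column index, so
retrograde lines have negative slope.

## The step detector

### Architecture

The detector makes no prior assumption about the number or size of steps;
all thresholds are expressed in units of the trace's own noise, which is
estimated robustly from the median absolute successive difference
($\hat\sigma = \mathrm{median}|\Delta x| / (0.6745\sqrt2)$ per coordinate).
It proceeds in two passes:

1. a **2D pass**: change points minimising
   $\sum_{\text{segments}} \mathrm{SSE}_x + \mathrm{SSE}_y$ plus a
   per-change penalty $\beta_{2D} = 5(\hat\sigma_x^2 + \hat\sigma_y^2)$,
   solved *exactly* by the PELT dynamic program with a minimum plateau
   length of 3 samples. This pass assumes nothing about the direction of
   motion.
2. a **1D pass** on the positions projected onto the overall motion axis
   (principal direction of the pass-1 plateau centroids), with penalty
   $\beta_{1D} = 6.5\,\hat\sigma_u^2$. Because a motor step displaces
   almost entirely along the axis while the noise is isotropic, the
   projection improves the step-to-noise contrast by $\sqrt2$; pass-1
   change points far from any pass-2 change point (purely lateral jumps,
   e.g. track changes) are kept alongside.

The union is polished by coordinate-descent position refinement, backward
elimination of steps whose on-axis displacement is below $2.5$ uncertainties
(with a $4.5\sigma$ 2D override so large lateral jumps are never deleted),
a remove-and-reinsert move search, and a windowed exact re-solve of every
run of six consecutive change points. Finally a counter-fit acceptance
criterion in the style of classic step-finding validators is applied to the
whole fit: the ratio of the SSE of a "counter fit" (change points at the
plateau midpoints of the fit) to the SSE of the fit must exceed 1.25,
otherwise the trace is declared step-free.

Why not the classic greedy step-fit/counter-fit recursion alone? Measured on
simulated staircases, greedy placement is myopic (it leaves ~15% of true
change points unrecovered even when they are well resolved) and the global
counter-fit quality curve has no usable peak when dwell times are broadly
distributed: its maximum under-fits a 100-step exponential-dwell trace by a
factor of three. The counter-fit ratio is retained where it is sound — as a
whole-trace gate that sends constant noisy traces to zero steps (≤ 5% of
200 constant traces with 3.5 nm noise yield any step;
`scripts/tune_threshold.R` reproduces the calibration and the frozen
constants 1.25 / 2.5 / 5 / 6.5).

### What detection can and cannot do

With $\sigma_{loc} = 3.5$ nm and ~10 samples per plateau, the standard
error of a step estimate is
$\sigma_{step} = s\sqrt{1/n_1 + 1/n_2} \approx 1.6$ nm, so steps below
about 4 nm are fundamentally ambiguous against noise excursions: a
detector that keeps them pays with spurious steps of both signs, one that
drops them merges their displacement into neighbours. Two consequences
matter for interpretation:

* a true step smaller than ~4 nm that is dropped *inflates a neighbouring
  detected step* (displacement is conserved);
* dwell times shorter than the minimum plateau length (3 samples) cannot be
  resolved — the corresponding steps merge. This is the same left-censoring
  that motivates the 3 ms truncation bound in the dwell-time fits.

### Dwell times

The dwell time of a step is the duration of the plateau preceding it. The
first plateau of a trace starts at an unknown offset into its dwell, so the
first dwell is left-boundary censored; `dwell_times()` drops it by default.

## Axis estimation and decomposition

The local axis of step $i$ is the principal direction of the plateau
centroids inside a window of five steps centred on it (windows shrink at
the ends), oriented to point retrograde. $s_{on} = \mathbf d \cdot \mathbf u$
and $s_{off} = \mathbf d \cdot \mathbf u_\perp$ with $\mathbf u_\perp$ the
axis rotated by +90°; magnitudes are preserved exactly. Off-axis steps
larger than 6 nm are tallied as "large" and larger than 25 nm as
track-change candidates in the pipeline report.

## Segmentation rules

A processive run is a maximal sequence of same-sign on-axis steps with at
least 3 steps and 20 nm net displacement. Because a pause does not change
the sign of any step, runs are additionally split where the interval since
the previous step exceeds 10 median dwells; for exponential dwells this
mis-fires on ~0.1% of steps, while stationary intervals shorter than that
are indistinguishable from a long dwell — pauses below roughly one decad of
the median dwell are therefore systematically missed, which is a physical
resolution limit, not a tunable.

Events are delimited by the last step of the preceding run and the first
step of the following run, so an event's duration is exactly the inter-run
interval; a gap between same-direction runs must last at least one median
dwell and keep an internal speed below 0.1 µm/s to count as a pause, else
it is merged into the flanking movement. Gaps between opposite-direction
runs are reversals. Leading/trailing spans without processive movement are
labelled `unclassified` and excluded from event statistics, and trace-level
category fractions (contains-reversal / contains-pause / uninterrupted,
deliberately non-exclusive) are computed only over traces with at least one
processive segment.

Intra-event stepping — the signature of a brief tug-of-war between opposing
motors — is scored when an event's interior contains two *consecutive*
steps of opposite sign, each at least 4 nm: requiring adjacency suppresses
incidental combinations of unrelated sub-processive steps, which otherwise
contaminate a fifth of all events.

## Markov chains for the reversal mechanism

Two chains are estimated from the segment sequences. The `regulated` chain
distinguishes direction-specific event states
(R, A, Pause$_{R\to R}$, Pause$_{A\to A}$, Rev$_{R\to A}$, Rev$_{A\to R}$);
the `tug_of_war` chain pools all interruptions into one Pause state with
exits to either direction. Each segment contributes
$\mathrm{round}(d/\Delta t)$ dwell ticks followed by one transition tick
into the next segment's state ($\Delta t$ = 10 ms by default, the order of
a median step dwell); pooled tick counts are row-normalised. States never
observed keep a flagged self-loop instead of pseudocounts, so they cannot
silently bias $\pi$; the stationary distribution is the normalised left
eigenvector of $P$ polished by power iteration, computed per closed
communicating class, with classes consisting only of flagged unobserved
states excluded as bookkeeping artifacts.

`persistence_ratio()` reports how much more persistent pauses are than
reversals as the ratio of per-tick *escape* probabilities,
$(1 - p_{rev,self})/(1 - p_{pause,self})$; as $\Delta t \to 0$ this
converges to the ratio of mean event durations, and for the example pair
$p_{pause,self} = 0.8$, $p_{rev,self} = 0.2$ it equals 4.

The discretization is a deliberate simplification: segment durations are
not geometric, so the chain is an approximation of a semi-Markov process.
Halving $\Delta t$ changes $\pi$ only within estimation error (tested), and
mechanism *selection* is out of scope — the biological argument rests on
event durations, not on chain likelihoods.

## Dwell-time models and inference

Three models for the interval between steps, with rates in s⁻¹ and
$\tau$ in seconds:

* `exp1`: $f(\tau) = k e^{-k\tau}$ — one rate-limiting transition per step
  (one ATP);
* `erlang2`: $f(\tau) = k^2 \tau e^{-k\tau}$ — two sequential transitions
  with equal rates (two ATPs per step);
* `hypoexp2`: $f(\tau) = \frac{k_1 k_2}{k_2 - k_1}(e^{-k_1\tau} -
  e^{-k_2\tau})$, $k_1 < k_2$ — two sequential transitions with unequal
  rates.

The hypoexponential density and survival are evaluated through an
`expm1`-based form that is continuous in the Erlang limit $k_2 \to k_1$ and
decays to `exp1` as $k_2 \to \infty$ (both limits tested numerically).

Short dwell times are under-represented because steps faster than the
sampling resolution are partially missed; following the convention of the
field this is handled as **left truncation** at $\tau_{min}$ = 3 ms:
samples below the bound are excluded and counted, and the density is
renormalised by $1 - F(\tau_{min})$. A true left-*censored* likelihood
(keeping each excluded observation as a $\log F(\tau_{min})$ term) is
available via `censoring = "censor"`. The truncated `exp1` MLE has the
closed form $\hat k = 1/(\bar\tau - \tau_{min})$ by memorylessness; it is
computed as an analytic cross-check of the numeric optimum (they agree to
$10^{-6}$ relative on a thousand random data sets in the test suite).
`erlang2` is optimised over $\log k$; `hypoexp2` over
$(\log k_1, \log(k_2 - k_1))$, which enforces identifiability, from a
multi-start grid spanning 10–10⁴ s⁻¹, with a boundary flag when the fit
collapses to $k_2 \to \infty$ (equivalent to `exp1`). Standard errors come
from the observed information (numerical Hessian in rate space); a
bootstrap alternative is provided because the original error convention is
not stated.

Model comparison uses plain Akaike weights,
$w_i = e^{-\Delta_i/2} / \sum_j e^{-\Delta_j/2}$ with
$\Delta_i = \mathrm{AIC}_i - \min_j \mathrm{AIC}_j$ and
$\mathrm{AIC} = 2p - 2\log L$ ($p$ = number of free rates). AICc is not
used: at $n \approx 10^3$ the correction is negligible. On data simulated
from `exp1` (or `erlang2`) at $n = 1000$, the generating model receives
the largest weight in ≥ 90% of replicates (tested), mirroring the
one-ATP-per-step conclusion drawn from the real traces.

## The synthetic-data generator

`simulate_trace()` emulates the reported world: a semi-Markov motion-state
chain (retrograde / anterograde / pause / reversal) with exponential state
durations; steps emitted inside processive states as a renewal process
driven by one of the three dwell models (default `exp1` at 90 s⁻¹); forward
step sizes from a truncated normal (mean parameter 8.7 nm, spread 3.8 nm);
backsteps with probability 0.04; a Gaussian off-axis component (3 nm
spread) plus rare 30 nm lateral jumps (1% of steps); localization noise
3.5 nm; 1 ms sampling; exponential photobleach truncation (mean 1.5 s,
cap 3 s). Pauses emit no steps; reversals flip the run direction at the end
of the event; with probability 0.102 an event instead contains tug-of-war
stepping (alternating ±full-size steps with no net displacement). Defaults
that the source world does not pin down were chosen once as plausible for
axonal transport and frozen: state mean durations 500/400/150/15 ms
(pauses ~10× longer than reversals, reversals about one step dwell),
pause-vs-reversal split 50/50, start state retrograde.

The forward step-size floor is 4 nm, matching the observed on-axis
step-size support (4–16 nm). This is not cosmetic: in a world with a 0 nm
floor, even an oracle detector that knows the true number of steps returns
a backstep fraction of ~0.09 and a mean forward step of ~9.6 nm, because
true sub-noise steps flip sign irreducibly — no implementation could
recover the configured statistics there.

`simulate_staircase()` generates single-run staircases with *controlled*
plateau lengths (e.g. uniformly 8–12 samples, i.e. ~10 per plateau); it is
the right input for characterising the detector itself, where the heavy
short-dwell tail of the kinetic models would confound the measurement.
`simulate_kymograph()` renders anti-aliased constant-speed lines with
exponential background noise and returns the realised truth lines.

What a green test does *not* establish: the generator's staircase world has
no microtubule curvature beyond what the axis window handles, no
heterogeneous per-trace noise, no photophysics (blinking), and its state
chain is memory-one; recovery results transfer to real data only insofar as
those idealisations hold.

## Kymograph filtering

The 2D Fourier transform of a constant-speed line concentrates along a
line through the origin whose quadrant pair is set by the slope sign.
`directional_filter()` therefore zeroes the two quadrants of the opposite
sign and inverse-transforms. The axial component (zero-frequency and
Nyquist rows/columns: static background and unresolvable-slope structure)
is retained in both outputs, making the decomposition exactly
complementary — retrograde + anterograde − axial = original to machine
precision — and the filter exactly linear. A hard quadrant mask is used
rather than an apodized edge: the resulting ringing is acceptable for the
energy-separation contract (≥ 80% of a line's energy under the matched
filter, ≤ 20% under the opposite one, both tested), and apodization would
break the exact reconstruction identity. Kymographs are carried as plain
matrices with a text serialization; no TIFF codec is assumed.

## Numerical choices and degenerate inputs

* Change-point ties break toward the smaller index (deterministic fits).
* Exactly noiseless traces (estimated noise zero) use an absolute penalty
  floor of $10^{-9}(\mathrm{SSE}_0 + 1)$ so zero-gain splits are never
  accepted; a noiseless staircase is recovered exactly.
* An all-constant trace yields zero steps, not an error; a trace shorter
  than two minimum plateaus is an error.
* Rows of a transition matrix that were never observed are flagged
  self-loops, and `stationary_distribution()` warns on genuinely reducible
  chains and averages the per-class solutions.
* `hypoexp2` with exactly equal rates is rejected for simulation (use
  `erlang2`) but evaluated by a stable limit in the density.
* All randomness flows through explicit integer seeds; the same seed and
  configuration reproduce byte-identical outputs, and the pipeline fans a
  single seed out into per-stage child seeds.

## Known limitations

* Step detection is quadratic-free but iterative; a 3 s trace at 1 ms
  sampling (~3000 points, ~200 steps) takes a few seconds in pure R.
* Pauses shorter than ~10 median dwells are invisible by construction (see
  segmentation), so event statistics under-count brief pauses.
* The Markov chains are discrete-time approximations of semi-Markov
  dynamics; $\Delta t$ must be smaller than the shortest segment.
* The dwell-time likelihoods assume i.i.d. intervals; correlations between
  successive dwells (e.g. from load variation) are not modelled.
* Kymograph line extraction (tracing endpoints in real images) is manual
  by design; the package consumes line annotations.
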