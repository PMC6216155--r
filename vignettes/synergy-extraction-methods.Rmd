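---
title: "Extracting muscle synergies from running EMG: models, choices, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting muscle synergies from running EMG: models, choices, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgsynergy)
```

## The model

Surface EMG of locomotion is highly redundant: 13 lower-limb muscles do not
produce 13 independent activation time courses. The muscle-synergy model
expresses the conditioned activation matrix $V$ ($m = 13$ muscles $\times$
$n$ time points) as a low-rank non-negative product

$$ V \approx V_R = W H, $$

where the columns of $W$ ($m \times r$) are *motor modules* — time-invariant,
non-negative muscle weightings — and the rows of $H$ ($r \times n$) are
*motor primitives* — non-negative activation coefficients over the gait
cycle. The rank $r$ is the number of synergies. In treadmill running of
young, healthy adults, four fundamental synergies describe the gait cycle:
weight acceptance (knee extensors and glutei), propulsion (plantar flexors),
early swing (dorsiflexors) and late swing (knee flexors and dorsiflexors).

`emgsynergy` implements the complete chain from raw 1 kHz recordings to
classified synergies, together with a synthetic-data generator whose ground
truth makes every stage testable.

## Conditioning raw EMG

`make_envelope()` builds the linear envelope of each channel:

1. zero-phase high-pass at 50 Hz — a 2nd-order Butterworth design applied
   forward and backward, giving a 4th-order magnitude response with no phase
   distortion. We read "4th-order zero-phase" in the conventional EMG sense
   of the *effective* order after bidirectional application; the alternative
   (a 4th-order design run bidirectionally, i.e. 8th-order magnitude) would
   sharpen both transition bands but is not what the lineage of this
   pipeline uses.
2. full-wave rectification;
3. zero-phase low-pass at 20 Hz (same construction);
4. negative values are clipped to zero, and every zero is replaced by the
   smallest non-zero value of the series. The floor matters: multiplicative
   NMF updates cannot move an entry away from an exact zero, so the
   factorization expects strictly positive data. The floor's scope is per
   muscle and per trial, which keeps channels independent.

`normalize_amplitude()` divides each muscle by its maximum over *both*
trials of a participant, so per-muscle maxima equal 1 across the trial pair
(MVC-style normalization variants are out of scope). `time_normalize()` then
resamples every gait cycle to 200 points — 100 for stance (touchdown to
touchdown + stance duration), 100 for swing (stance end to next touchdown) —
by piecewise-linear interpolation on the 1 kHz grid. Linear interpolation is
monotone and artifact-free; each phase grid includes both phase endpoints
but excludes the next touchdown so no sample is duplicated across cycles.
The first 30 cycles of a trial enter the analysis, giving $n = 6000$
columns. The chain order is filter → amplitude-normalize → time-normalize;
amplitude normalization commutes with linear resampling only approximately,
and this order normalizes on the raw grid where the true maxima live.

One boundary convention deserves note. A cycle-times table has one row per
gait cycle (touchdown time, stance duration), and extracting $k$ complete
cycles needs touchdown $k+1$. When the table holds exactly $k$ rows, the
swing end of the last cycle is estimated as its stance end plus the median
swing duration of the preceding cycles. With constant cycle durations the
estimate is exact; with realistic variability it warps only the final
half-cycle's time base slightly, which the 30-cycle averages downstream
render negligible.

## Factorization

`nmf_factorize()` minimizes squared (Gaussian) reconstruction error with the
classical multiplicative updates, per iteration first

$$ H \leftarrow H \circ \frac{W^T V}{W^T W H}, \qquad
   W \leftarrow W \circ \frac{V H^T}{W H H^T}, $$

with the already-updated $H$ entering the $W$ update. Denominators are
floored at $10^{-12}$; $W$ and $H$ start from seeded i.i.d. uniform draws on
$(0, 1)$, strictly positive so no entry is absorbed at zero. Reconstruction
quality is the coefficient of determination $R^2 = 1 - SSE/SST$ over all
entries, evaluated once per iteration after both updates. Convergence is
declared when the spread of $R^2$ over the last 20 iterations falls below
0.01% — implemented as $(\max - \min)$ of the rolling window $< 10^{-4}
\times$ the current $R^2$, the relative reading; with $R^2 \approx 0.9$ the
absolute reading would nearly coincide. The iteration cap is 1000; the
window rule normally fires long before. The update loop is compiled
(RcppArmadillo), and the per-iteration $SSE$ uses the trace identity
$\|V - WH\|_F^2 = \|V\|_F^2 - 2\,\mathrm{tr}(V^T W H) +
\mathrm{tr}((W^T W)(H H^T))$, so the dense $m \times n$ reconstruction is
never formed.

Because multiplicative updates only find local minima, `rank_sweep()` runs
10 independently seeded restarts per rank for ranks 1 to 10 (10 stays below
the 13 recorded muscles) and keeps the highest-$R^2$ solution per rank.
Restart seeds derive deterministically from the master seed, making every
sweep bit-reproducible. The outputs are raw factorization results; no
post-hoc normalization of $W$ columns or $H$ rows is applied.

## How many synergies?

`select_order()` avoids an arbitrary threshold on $R^2$ itself. On the
best-of-restarts $R^2$-versus-rank curve it iterates: fit an ordinary
least-squares line, compute the mean squared residual; if it is below
$10^{-5}$ (strict less-than) stop, otherwise drop the lowest-rank point and
repeat, stopping in any case at two points. The selected order is the first
rank of the final, most linear segment — the rank where reconstruction
quality stops improving faster than linearly. Residuals are invariant to
adding a constant to the whole curve, so the selection is shift-invariant;
the tests exercise this property and check the loop against an independent
enactment of the same procedure.

## Fundamental and combined synergies

A synergy whose cycle-averaged primitive has a single major activation peak
is *fundamental*; two or more peaks mark a *combined* synergy (a blend).
"Single peak" needs a convention, which the source analyses leave
unspecified; ours is: smooth the 200-point cycle average with a 5-point
centered moving average, take local maxima at or above 10% of the
primitive's maximum, and merge maxima closer than 25 points (12.5% of the
cycle) into the highest. All three constants are exposed as configuration
(`classify_primitive()`, `run_config()`). No circular wrap is applied at the
cycle boundary — touchdown is a true discontinuity. Fundamental synergies
receive a functional label from the quadrant holding their main peak:
points 1–50 weight acceptance, 51–100 propulsion, 101–150 early swing,
151–200 late swing.

## Gait parameters

`summarize_cycles()` reads contact time directly from the stance column,
takes cycle duration as the interval between successive touchdowns, swing as
cycle minus contact, and cadence as $2 \times 60 /$ cycle duration — both
feet counted, two steps per single-limb gait cycle. The 2$\times$ convention
is the one consistent with running cohorts reporting $\approx$ 163 steps/min
at 740 ms cycles; a per-foot convention would halve it. `strike_index()`
projects the center of pressure at impact onto the heel–toe axis and divides
the heel distance by foot length (0 = heel strike, 1 = toe strike; values
below 0.333 classify as rearfoot). Off-axis pressure points are projected
because the index is one-dimensional along the foot. Upstream
touchdown/lift-off detection from plantar-pressure images is out of scope;
cycle tables are inputs.

## The synthetic generator

`make_ground_truth()` draws $W_{true}$ and $H_{true}$ with the structure the
running literature reports. Primitive templates are single Gaussian bumps
(s.d. 15 points, i.e. 7.5% of the cycle — the literature shows, but does not
parameterize, primitive shapes), unit peak, centered in the four functional
quadrants for rank 4 (evenly spaced otherwise). Modules emphasize the
functional muscle groups with weights uniform on (0.6, 1) in-group and
(0, 0.15) off-group. `synthesize_trial()` draws contact and swing durations
from truncated normals (defaults 288 ± 42 ms and 452 ± 45 ms), warps the
templates onto each cycle, applies multiplicative truncated-Gaussian
envelope noise (`noise_sd`, default 0.1, the generator's study condition),
and modulates a zero-mean band-limited (20–450 Hz) Gaussian carrier, scaled
to unit mean absolute value so its rectified, low-passed version
approximates the envelope. Raw amplitudes are arbitrary units by design —
amplitude normalization removes any scale.

What the generator does *not* emulate: electrode crosstalk, motion
artifacts, heartbeat contamination, inter-cycle waveform changes beyond
multiplicative noise, or biophysical motor-unit statistics. Passing the
recovery tests therefore shows the chain is correct and robust to the
modeled noise, not that every real recording will factorize as cleanly.

## Problem sizes and validation

The test suite and the acceptance script validate on desk-scale problems
chosen as the package's own conditions: single 30-cycle trials (13 × 6000
matrices) for structural and recovery checks; 20 seeded replicates for the
rank-recovery rate (expected ≥ 90% at `noise_sd` 0.1, with matched module
and primitive cosine similarity > 0.9); 6 × 40 matrices at rank 2 against a
1000-restart brute-force oracle for factorization quality (within 1% in
Frobenius error); and fixed 10-point curves against an independent
enactment of the order-selection loop. Cross-checks are implemented
independently of the code paths they test: a hand-derived Butterworth
bilinear transform with an explicit difference-equation loop for the
filters, a naive full-matrix update loop for the NMF, direct arithmetic for
gait summaries.

## Known limitations

- The multiplicative updates have the usual permutation and diagonal-scale
  ambiguity; comparisons are only meaningful up to `match_synergies()`.
- The convergence rule watches a window of $R^2$ values; pathological
  plateaus longer than 20 iterations followed by renewed progress would stop
  early. We have not observed this on realistic data.
- On noisy data the selected rank can exceed the generating rank (extra
  components absorb noise), mirroring the 4–5 synergies (mean 4.7) reported
  for real running cohorts; combined synergies also appear, which is why
  classification operates on whatever rank was selected.
- Trials shorter than the requested 30 cycles are rejected rather than
  padded; partial-cycle analysis is out of scope.
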