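---
title: "Modelling unfused tetanic contractions of motor units"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling unfused tetanic contractions of motor units}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutet)
```

## The problem

A motor unit (MU) stimulated by a train of pulses at physiological rates
produces an *unfused tetanus*: an oscillating force that is the sum of
overlapping twitch-like responses to the individual stimuli. These responses
are not copies of the single twitch — in slow units they can be several-fold
stronger and markedly slower than the first twitch, and the change is driven
mainly by the force level already developed when each stimulus arrives.
`mutet` implements a forward model that predicts every successive
contraction (and hence the whole tetanic curve) from three inputs: the six
parameters of the single twitch, the maximal fused-tetanus force
$F_{mftf}$ (measured at 150 Hz), and the stimulation pattern. It also
implements the inverse problem — decomposing a recorded tetanus into its
contractions — and the calibration pathway connecting the two.

## The twitch curve

Each contraction is a bell-shaped curve parameterized by
$(F_{max}, T_{lead}, T_{hc}, T_c, T_{hr}, T_{tw})$, with the five times
satisfying $0 < T_{hc} < T_c < T_{hr} < T_{tw}$ and all times beyond the
lead measured from the contraction onset. The curve is built from the
kernel $g(u) = u\,e^{1-u}$ on normalized time $u = \tau / T_c$, in three
pieces:

* rising phase on $[0, T_c]$: $f = F_{max}\, g(u)^{k_1}$ with
  $k_1 = \log(1/2) / \log g(T_{hc}/T_c)$, so the half-contraction anchor is
  hit exactly and $g(1) = 1$ puts the peak at $T_c$;
* early relaxation on $[T_c, T_{hr}]$: $f = F_{max}\, g(u)^{k_2}$ with
  $k_2$ pinning $f(T_{hr}) = F_{max}/2$;
* tail on $[T_{hr}, T_{tw}]$:
  $f = \tfrac{F_{max}}{2} (g(u)/g(u_{hr}))^{k_3}$ with $k_3$ pinning
  $f(T_{tw}) = 10^{-4} F_{max}$ (force "decayed to 0.01%"), continuous at
  $T_{hr}$ by construction.

All three exponents have closed forms, so no iterative solving is needed and
the four anchors (half-contraction, peak, half-relaxation, end) are exact to
machine precision. The curve is continuous, non-negative, unimodal with its
single maximum at $T_{lead} + T_c$, and is truncated (not tapered) to zero
beyond $T_{lead} + T_{tw}$, leaving a jump of $10^{-4} F_{max}$ that is
irrelevant at the working precision. Units are fixed at milliseconds and
millinewtons; every model equation uses dimensionless ratios, so the units
cancel. This construction is this package's own realization of a
six-parameter analytical twitch: any curve satisfying the same six anchors
could be substituted behind `build_twitch()` without affecting the rest of
the machinery.

## Prediction equations

The amplitude of the $i$-th contraction depends on the force level
$F_{tetmin}(i)$ at which it starts through an MU-specific angle $\alpha$:

$$F_{max}(i) = \left(1 + \cot(\alpha)\, \frac{F_{tetmin}(i)}{F_{max}(1)}\right) F_{max}(1).$$

$\alpha$ is the angle between the unit's amplitude-versus-force line and
the ordinate: below 90° amplitudes grow with the starting level, at 90° they
are constant, above 90° they shrink and are clamped at zero once
$F_{tetmin}/F_{max}(1)$ reaches $-1/\cot\alpha$ (about 1.94 at the maximal
angle 117.2°). The angle follows a power law in the force ratio
$x = F_{mftf}/F_{max}(1)$, with two published calibrations selectable via
`prediction_config()`: $108.8\,x^{-0.2603}$ (`eq1`) and the ameliorated
$117.2\,x^{-0.3144}$ (`eq9`), the latter spanning 45.6966°–117.2° over the
physiological twitch-to-tetanus ratio range $p \in [0.05, 1]$.

Contraction and half-relaxation times prolong linearly with
$x_i = F_{tetmin}(i)/F_{max}(1)$:

$$T_c(i) = (1.04 + 0.274\,x_i)\,T_c(1), \qquad
  T_{hr}(i) = (2.397 + 0.3509\,x_i)\,T_c(1),$$

and $T_{hc}$, $T_{tw}$ scale proportionally to $T_c$ and $T_{hr}$
respectively; the lead time is constant across the train. Two remarks on
choices that were genuinely open:

* The intercept of the $T_c$ line is quoted in two places with different
  values (1.04 in the equation, 1.104 in the corresponding figure caption);
  the package defaults to 1.04, which is also closer to the physiologically
  forced value of 1 at $x = 0$. Both coefficient pairs are overridable in
  `prediction_config()`.
* The $T_{hr}$ line multiplies $T_c(1)$, not $T_{hr}(1)$ — its intercept
  2.397 only makes sense against $T_c(1)$ — and is implemented that way.
* A contraction starting from a fully relaxed unit ($F_{tetmin} = 0$) is
  taken to be the single twitch itself rather than pushed through the time
  laws (whose intercepts at $x = 0$ would otherwise prolong it by 4% and
  leave a discontinuity against the first contraction). This makes a
  single pulse predict exactly one single twitch and two fully separated
  pulses predict two identical twitches.

The **full prediction** (`full_predict()`) is iterative: contraction 1 is
the single twitch; the starting level of contraction $n$ is the sum of all
previously predicted contractions evaluated at the $n$-th pulse time, which
feeds the equations above. The starting level may alternatively be read at
the pulse time plus one lead time (`lead_offset_in_sampling = TRUE`), which
matches where the contraction physically begins; the default evaluates at
the pulse time, matching the published algorithm. When measured local minima
are available, `predict_with_observed_minima()` substitutes them, and
`sum_equal_twitches()` provides the naive equal-twitch baseline.

Nothing in the equations caps the positive feedback between force level and
amplitude: for $\alpha < 90°$ and stimulation fast relative to the twitch,
the predicted force can grow without physiological limit. The experimental
protocol the model was built on avoided that regime by choosing, per unit,
a rate that evokes a *moderately fused* tetanus (peak at 30–70% of
$F_{mftf}$); `choose_mean_frequency()` reproduces exactly that choice by
bisecting the rate until the predicted peak sits mid-band. Additional
amplitude constraints would be needed for strongly fused tetani; none are
imposed here.

## Similarity coefficients

Two curves on a shared grid are compared by
$FitCo = 100\,(1 - \sqrt{\tfrac1N \sum_i \Delta_i^2})$, where $\Delta_i$ is
the per-sample difference normalized by the common maximum of both curves
(read as the joint maximum, the simplest reading under which identity gives
exactly 100), and by $AreaCo$, the ratio of trapezoidal areas
(reference over model). $FitCo$ is invariant under a common positive
rescaling; $AreaCo(a,b)\,AreaCo(b,a) = 1$.

## Decomposition

`decompose_tetanus()` splits a recorded curve into one twitch model per
stimulus by sequential subtraction and bounded least squares
(Levenberg–Marquardt via `minpack.lm`). Numerical choices:

* **Parameterization.** Times are fitted as positive increments
  $(T_{hc}, T_c - T_{hc}, T_{hr} - T_c, T_{tw} - T_{hr})$, so the ordering
  invariant holds throughout optimization.
* **Lead time.** Fitted freely only for the first contraction and then held
  fixed: the onset is weakly identified (the curve leaves zero with zero
  slope), and letting it float lets it trade against the shape of
  overlapping neighbours.
* **Pass 1.** For contraction $i$ only the segment up to the next
  contraction's onset is uncontaminated, and it may cover little more than
  the rising phase; each fit is therefore confined to a trust region around
  the previous contraction's fit (amplitude within 2.5-fold, times within
  1.6-fold), reflecting the gradual change of successive contractions.
* **Refinement.** Block-coordinate sweeps refit each contraction over its
  full support ($3 (T_{lead}+T_{tw})$ window) against the recording minus
  all other current models, within global bounds of $[0.2, 8]\times$ the
  first contraction (decomposed amplitudes of slow units reach roughly
  seven-fold the single twitch). Single-contraction sweeps are followed by
  *pair sweeps* that refit adjacent contractions jointly; these resolve the
  amplitude/duration trade-offs between strongly overlapping neighbours at
  which single refits stall. Defaults (2 single + 3 pair sweeps) reconstruct
  noiseless 41-pulse model tetani with $FitCo > 99$ across unit types; short
  trains converge to the generating parameters essentially exactly with a
  few more sweeps.
* **Degenerate input.** An all-zero residual yields, configurably, a
  zero-amplitude sentinel contraction or an error.

`local_minima()` reads each contraction's starting level as the minimum over
$[t_{pulse},\ t_{pulse} + T_{lead} + 2\,\Delta t]$ — the true minimum falls
between the pulse and the contraction onset — with the first level 0 by
definition.

On noiseless model-generated tetani the round trip
(predict → decompose → reconstruct) is an exact-recovery problem, and the
reconstruction is near-perfect; late-train contractions of strongly
overlapping tetani can still trade parameters pairwise with little effect on
the reconstruction, so individual parameter recovery is tight for short or
moderately fused trains and looser deep inside heavily fused ones.

## Calibration

`sensitivity_scan()` rescans the angle over the integer part of the starting
angle ±20° in 0.1° steps (both configurable), re-running the full prediction
at each grid angle against a reference curve. The published selection rule
asks for $FitCo$ closest to 100 *and* $AreaCo$ closest to 1 without stating
a combination; the package maximizes $FitCo$ — the primary comparison
statistic — and breaks ties within 0.01 by the smallest $|AreaCo - 1|$.
`fit_power_model()` refits $y = a x^b$ by nonlinear least squares in linear
space (the criterion by which the power model was originally selected),
seeded by log-log OLS; `fit_time_param_lines()` refits the two linear time
laws with Pearson correlations. A corpus-level property test confirms that
decomposing a synthetic population and refitting the power law recovers the
generating coefficients to within Monte-Carlo error.

## Synthetic data

The generator emulates the statistical frame of the experimental data set:

* twitch-to-tetanus ratios drawn per type from the reported means and
  standard deviations (0.13±0.05 for S, 0.19±0.06 for FR, 0.28±0.08 for FF),
  truncated to (0.05, 1);
* contraction times uniform on 30–70 ms (S) and 12–25 ms (FR/FF); lead times
  1–3 ms; twitch amplitudes 5–30 mN (S), 20–100 mN (FR), 50–200 mN (FF);
* the remaining times by fixed proportions $T_{hc} = 0.55\,T_c$,
  $T_{hr} = 2.2\,T_c$, $T_{tw} = 8\,T_c$ — synthetic conventions chosen for
  plausibility; only their ordering matters to the algorithms under test;
* 41-pulse patterns with interpulse intervals i.i.d. uniform within 50–150%
  of the mean interval, and per-unit rates picked by
  `choose_mean_frequency()` to land in the moderately fused band, exactly as
  the experimental protocol did;
* optional Gaussian measurement noise (fraction of $F_{mftf}$, clipped at
  zero force), behind a single seed.

What the synthetic data do *not* emulate: fatigue and potentiation drift of
$F_{mftf}$ and twitch amplitude during an experiment, nonlinear summation
across multiple units, recording baseline artefacts, and the real
(unpublished) per-unit parameter values. Passing round-trip tests on these
data therefore demonstrates the internal consistency of the
prediction/decomposition machinery, not agreement with any particular
recorded unit.

## Problem sizes and reproducibility

The test suite and examples run 41-pulse tetani sampled at 0.5 ms (0.1 ms is
the package default for single-twitch work), a round-trip corpus of 12
noiseless tetani across the three types, a calibration corpus of 50
synthetic units, and 33-point power-law fits. All randomness flows through
explicit integer seeds (`withr::with_seed`), so every result in the tests,
README and acceptance script is bit-reproducible.

## Known limitations

* The prediction equations are calibrated for moderately fused tetani of rat
  medial gastrocnemius units; other muscles or species need recalibration
  via the provided pathway, and strongly fused regimes need amplitude
  constraints the model does not define.
* The amplitude law can transiently predict contraction amplitudes above
  $F_{mftf}$; no upper inequality constraint is imposed.
* Decomposition assumes one contraction per stimulus and a trace covering
  the full relaxation tail; missed or extra stimuli are out of scope.
* The onset (lead time) of a noisy contraction is identified only to a few
  tenths of a millisecond; decomposition therefore pins it across the train.
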