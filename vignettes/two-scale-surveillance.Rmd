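---
title: "Two-scale stochastic modeling of T cell immune surveillance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-scale stochastic modeling of T cell immune surveillance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcellsurv)
```

## The problem

Only a handful of naive T cells in a mouse recognize any given antigen.
For an immune response to start, these rare cells must (i) home to a
secondary lymphoid organ (SLO) that actually contains the antigen and
(ii) find and stably engage antigen-bearing dendritic cells (DCs) inside
it. `tcellsurv` models both scales — circulation *between* organs and
search *within* them — as coupled stochastic processes, and ships the
statistical machinery to confront the within-LN model with two-photon
cell-track data.

## Priming models: signal integration versus probabilistic priming

T cell priming proceeds in phases: serial brief DC contacts (phase I),
then a stable arrest (phase II). Two hypotheses explain why phase I lasts
hours at low antigen dose:

* **Signal integration** — the cell accumulates signals and arrests after
  `n` successful cognate contacts.
* **Probabilistic priming** — each new contact independently triggers
  arrest with probability `p`; unsuccessful contacts are forgotten.

With contacts arriving as a Poisson process at rate $\lambda$ per hour and
per-contact success probability $p$, successful contacts arrive at rate
$\mu = \lambda p$ and the time to retention is Gamma distributed with
shape $n$ and rate $\mu$:

$$F(t) = P(A \le t) = \frac{\gamma(n, \mu t)}{\Gamma(n)}.$$

Both hypotheses are limits of this one law: probabilistic priming is
$n = 1$ (exponential, gradual) and pure signal integration is $p = 1$
(switch-like for large $n$). Only $\mu = \lambda p$ is identifiable from
retention timecourses — a 2 h waiting time at 50% success is
indistinguishable from a 4 h waiting time at 100% success — so all
comparisons in this package are made at equal *effective* contact rates.
Because roughly 2/3 of the contacts of a persistent random walker in a
large 3D tissue are with a new DC, `uniqueContactFactor()` exposes the
2/3 conversion for scenarios that instead require equal *true* contact
rates; it is never applied implicitly, and an idempotence guard prevents
double application.

```{r priming}
p_si <- primingParams(contact_rate = 1, success_prob = 1, required_contacts = 8)
p_pp <- primingParams(contact_rate = 1, success_prob = 1/8, required_contacts = 1)
c(si = retentionMean(p_si), pp = retentionMean(p_pp))       # both 8 h
c(si = retentionVariance(p_si), pp = retentionVariance(p_pp)) # PP much wider
```

## Organ geometries and transit laws

**Lymph node.** The T cell zone is an absorbing sphere of radius $R$;
cells enter at the centre (a high endothelial venule) and random-walk with
motility coefficient $M$ (3D mean-squared displacement $6Mt$) until they
hit the surface (sinusoids) and egress. The mean transit is $R^2/(6M)$ and
the full survival function is the alternating eigen-series
$S(t) = 2\sum_{k\ge1}(-1)^{k+1}e^{-k^2\pi^2 Mt/R^2}$. Unlike an
exponential egress model, this law has an entry-to-exit *lag*: essentially
no cell leaves during the first hour.

**Spleen.** The periarteriolar lymphoid sheath is a cylinder whose axial
position is irrelevant to egress, so transit is simulated in the 2D
cross-section: a disc with a reflecting boundary (B cell areas) except an
absorbing arc diametrically opposite the entry point (the exit bridging
channel).

Parameter choices (units matter — motility in µm²/min, rates per hour,
times in hours):

* $M = 60$ µm²/min, the two-photon scale estimate for naive T cells.
  Only $R^2/M$ affects dynamics, so $M$ is a labeled convention and the
  radii are calibrated.
* LN radius $R = \sqrt{6 M \cdot 13.5\,\mathrm{h}} = 540$ µm, giving the
  classical 13.5 h mean LN dwell; an anatomically reasonable T-zone size.
* Spleen disc radius $R_S = 120$ µm (PALS cross-section scale) with the
  aperture angle calibrated to the classical 6 h mean spleen dwell:
  $\alpha = 1.865$ rad, obtained by bisection with 2×10⁴ explicit
  transits per evaluation at step 0.2 min (achieved mean 6.0 h,
  reproducible across seeds to ~1.5%). The calibration is re-runnable via
  `calibrateSpleen()`, which stores its settings and achieved mean as an
  attribute.

Numerical choices: the eigen-series is truncated when terms fall below
1e-12 (at most 2000 terms) and short-circuits to survival 1 for
$Mt/R^2 < 10^{-5}$, where the true deficit is far below machine
precision. The production LN sampler inverts a 1500-knot tabulated CDF
(values beyond the table, cumulative mass ~1e-21, clamp to the last
knot); explicit Brownian walks (`sampleLnTransitBrownian`) are retained
as an independent oracle and agree with the series to a sup-deviation
below 0.02. Disc walks reflect by radial projection and use a step guard
$\sqrt{4M\,dt} < R_S/10$; halving the default 0.2 min step moves the mean
by well under 5%.

## Circulation between organs

Cells alternate between the blood and one of 40 organ compartments: the
spleen (entry rate 1.0/h) and 39 LN spheres sharing a combined entry rate
of 1.5/h. Thirty named LNs map onto the spheres — the six large paired
LNs (axillary, brachial, inguinal) get two spheres each, the mesenteric
four, all others one — so that entry rate scales with LN size while
egress does not. These two rates are adopted from classical migration
analyses; together with the 13.5 h / 6 h transit laws they *predict* a
24 min mean blood residence and a steady-state distribution of about 74%
in LNs, 22% in spleen and 4% in blood, matching the printed reference
values (25 min, 74/23/3) well within their uncertainty.

The simulator is an exact kinetic Monte Carlo: blood dwell exponential
with rate $\Lambda(t)$ (the sum of entry rates), destination chosen
proportionally to rates. Infections designate draining LNs (dLNs), whose
entry rate can ramp (default: linear 9-fold increase over 4.5 days,
emulating inflammation-driven vascular growth; a step shape is also
available). Time-varying rates are handled by Ogata thinning against
$\Lambda_{max}$, which is exact; a unit test checks the thinned sojourn
law against fine-grained numerical integration on an exaggerated ramp.
Cohorts are desynchronized by a per-cell burn-in of $1+u$ weeks
($u \sim U[0,1)$) before $t = 0$.

One deliberate implementation choice: within the circulation loop, spleen
dwells are drawn from the empirical transit-time distribution generated
once per geometry by the explicit disc simulator (2×10⁴ walks on an
isolated RNG stream), rather than re-walking the disc at every visit.
Dwells are i.i.d. across visits, so this is statistically equivalent and
orders of magnitude faster; the explicit simulator remains the
user-facing function and the acceptance checks call it directly.

## Capture times and the transit-time trade-off

An infection places antigen in a fraction $f$ of the LN spheres. The
*capture time* is the time from antigen appearance until an initially
circulating cognate cell is retained in a dLN. Per dLN visit the
retention probability is $P = P(A < T)$; for a fixed dwell $T_{det}$ this
is the Gamma CDF, and for probabilistic priming with stochastic transit
the closed form $P = 1 - z\,\mathrm{csch}(z)$, $z = R\sqrt{\mu/M}$,
applies (for $n > 1$ the package integrates the Gamma density against the
transit survival numerically).

For deterministic transit the expected capture time has the closed form

$$E[T_{cap}] = t_0 + E[N]\,(T_{det} + \tau_b) + E[A \mid A < T_{det}],$$

with $N$ geometric in $fP$, $\tau_b$ the mean blood-plus-spleen time
between consecutive LN visits, and the truncated-Gamma mean computed via
$E[A\,1(A<T)] = (n/\mu)F_{n+1,\mu}(T)$. Design choices where the
derivation leaves latitude:

* $\tau_b$ is computed analytically from the body rates,
  $\tau_b = (1/p_{LN})(1/\Lambda) + ((1-p_{LN})/p_{LN})\,\bar T_{spleen}
  \approx 4.7$ h at baseline, and cross-checked by simulation.
* $t_0$, the mean time to the first LN entry, has no closed form and is
  estimated by a short cached Monte Carlo (4000 cells on an isolated RNG
  stream). The default convention (`"next_entry"`) counts the first LN
  *entry* at or after $t=0$, so cells inside a LN at $t=0$ first finish
  their residual dwell; the alternative (`"in_ln_counts"`) assigns them
  $t_0 = 0$. The conventions differ by well under an hour at baseline.
* The Monte Carlo capture estimator excludes cells already inside a dLN
  when the antigen appears (matching the derivation, which follows a cell
  *not* in a dLN at that time); `initial_dln = "include"` keeps them.
* `optimalTransitTime()` minimizes the $T$-dependent part
  $E[N](T+\tau_b) + \theta(T)$ on (0, 96] h after a 400-point grid
  pre-scan. At a fixed steady state $t_0$ is an additive constant; making
  $t_0$ depend on $T$ (deterministic-transit steady state) would shift
  the optima by only ~0.2–0.5 h, well inside the reported tolerance.
  Absolute capture times are convention-sensitive at the ±25% level for
  the same reason; the optima and fold ratios are the robust outputs.

At baseline ($f = 0.25$, one effective contact per hour) the optima are
~3.8 h for a 2-contact antigen and ~11.9 h for an 8-contact antigen, and
Monte Carlo capture means reproduce the analytic values to a few percent.
`benefitRiskMatrix()` tabulates the fold difference between optimized
deterministic transit and stochastic transit across doses: the diagonal
benefit is at most about 2-fold, while off-diagonal risks reach
order-50-fold — stochastic transit is the dose-robust strategy.

## The track-statistics pipeline

The two-photon pipeline mirrors standard intravital analysis:

1. **Motility coefficient** per track,
   $\hat M = \sum_i d_i^2 / (6\sum_i|t_i - t_{mid}|)$, with $d_i$ the
   distance to the track's middle position (averages of the two central
   samples for even length). The normalization makes $\hat M$ exactly
   unbiased for Brownian tracks — a regression test recovers $M$ on
   simulated Brownian motion to within 5% — while short persistent-walk
   tracks are biased low, which is acceptable because gating is purely
   relative to controls measured the same way.
2. **Gating**: the threshold is $\gamma \cdot M^*$, where $M^*$ is the
   duration-in-frames-weighted median of the control-cell coefficients.
   The factor $\gamma = 0.4$ is a package calibration: on synthetic data
   it makes the background-corrected retention recover the generating
   CDF to about ±0.05 across the curve (smaller $\gamma$ leaves a
   false-free ceiling from noisy arrested segments; larger $\gamma$
   inflates the control background). $\gamma$ is exposed everywhere, and
   fitting results should be read with this sensitivity in mind.
3. **Retained fraction** per window: track-duration-weighted fraction of
   segments below the threshold — duration weighting corrects for
   non-retained cells having shorter tracks.
4. **Background correction**: controls never arrest, so the control
   fraction $r_{ctrl}$ is pure gating noise. The correction is the affine
   map $r' = \max\{0, (r - r_{ctrl})/(1 - r_{ctrl})\}$, the unique affine
   function sending $r_{ctrl} \mapsto 0$ and $1 \mapsto 1$ (a
   reconstruction; floored subtraction is available behind a flag). The
   background is measured on control tracks split into the *same* 20-min
   windows, so control segments share the short-segment estimator bias.
5. **Windowing**: three 20-min windows per 60-min video; tracks crossing
   a boundary are split with an interpolated sample at the cut so
   duration is conserved, and sub-2-min slivers are dropped (the same
   2-min rule applied to whole tracks on reading). Window midpoints are
   reported relative to LN entry, which occurs on average 1 h after
   injection. A coarser 1 h binning with track-level bootstrap 95%
   intervals (`binRetentionSeries`) supports population-level views.

## Fitting and model selection

`fitRetentionModel()` minimizes duration-weighted squared error between
logit-transformed observed and predicted fractions (fractions clipped to
[0.01, 0.99] — corrected fractions of exactly 0 occur at early times).
Sharing structures for $E$ experiments: the general model fits per-
experiment $(n_e, \mu_e)$ ($k = 2E$; 12 for six experiments); pure signal
integration shares one $\mu$ ($k = E+1 = 7$); pure probabilistic priming
fixes $n = 1$ ($k = E = 6$). The shape is continuous during optimization.
The general fit is separable per experiment and multi-started over a
shape×rate grid; the shared-rate fit profiles the inner shapes over an
outer rate search. BIC uses the standard least-squares convention
$N\ln(RSS/N) + k\ln N$ (the likelihood behind the published BIC is not
stated; with this convention ΔBIC values are comparable, not
bit-identical). ΔBIC labels follow the conventional scale (>10 "very
strong").

## The synthetic-data generator

`generateTrackSet()` emulates the structure of the in vivo experiments:
six independent experiments across three doses (two each), three 1 h
videos per experiment at 1, 4 and 7 h post synchronized LN entry, and
cognate plus control cells per video. Cognate cells draw a retention time
from the dose's priming law and switch from a persistent velocity-jump
walk (speed 10 µm/min, persistence 1.8 min, long-time motility
$v^2\tau/3 = 60$ µm²/min matching the circulation model) to low-motility
Brownian jitter (5 µm²/min, well below the gate). Tracks are censored by
an exponential duration model (mean 15 min) truncated to the video.

Condition choices, made once: the default low dose is $n = 8$ contacts at
$\mu = 2$/h, placing the retention switch near 4 h post entry — inside
the imaged 0–8 h range, as observed in vivo at low dose (an 8-h-mean
law would put the switch mostly beyond the last video and make the shape
poorly identified by construction). Default cell counts are 120 cognate
and 120 control per video, a few-fold reduction of the in vivo scale
(~580 tracks per video).

What the generator does *not* emulate: state-dependent track censoring
(in vivo, arrested cells yield longer tracks — the very effect duration
weighting corrects; here durations are state-independent, so the
weighting is exercised but not stressed), imaging drift, track breakage
and re-linking, tissue boundaries, and DC-side dynamics. Passing
closed-loop tests on these data therefore validates the pipeline's
statistics, not its robustness to imaging artifacts.

Closing the loop at these conditions: the general model recovers the
generating low-dose parameters with median error well inside ±2 contacts
and ±30% on the rate, and model selection penalizes disabling signal
integration by ΔBIC > 10 while disabling probabilistic priming costs
< 2 — in about 80% of replicates. That fraction is genuinely marginal:
with three videos per experiment the per-experiment (shape, rate) pair is
identified mainly along a ridge, and the near-saturated late video has
high leverage on the logit scale, so the general model occasionally
absorbs experiment-level noise that the shared-rate restriction cannot.
This mirrors the information limits of the real experimental design
rather than a fixable defect of the fit.

## Problem sizes and reproducibility

All stochastic results are reproducible from a single seed; internal
caches (the spleen transit table, $t_0$) run on isolated RNG streams so
that memoization never perturbs a caller's stream. The shipped checks use
10⁵ samples for distribution-level comparisons, 10⁴ cells for
steady-state circulation and arrival fractions, 10⁴ explicit Brownian
first-passage walks (0.1 min steps), 1500–3000 cells per capture-time
Monte Carlo, and 50 generator replicates for the model-selection closure;
these sizes keep every Monte Carlo standard error several times smaller
than the tolerance it is checked against.

## Known limitations

* The priming law assumes constant antigen dose and DC numbers; peptide
  decay on MHC (relevant for low-affinity peptides) is out of scope.
* Egress shutdown after infection (<1 day) is not modeled; dLN retention
  acts only through priming.
* The spleen model collapses the cylinder to its cross-section and uses
  a single aperture; microanatomy (FRC networks, chemokine gradients,
  directed egress) is intentionally absent — directed migration is the
  model's counterfactual, not a feature.
* Fitted shape/rate pairs from 2–3 videos per experiment are
  ridge-identified; treat per-experiment point estimates with care and
  prefer the model-comparison statistics.
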