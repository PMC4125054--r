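# tcellsurv

Two-scale stochastic modeling of T cell immune surveillance in mice: how
rare antigen-specific T cells circulating between blood, spleen and lymph
nodes (LNs) manage to locate antigen-bearing dendritic cells (DCs) within
days. The package is aimed at quantitative immunologists and modelers who
want to simulate lymphocyte trafficking, analyze two-photon cell-track
data, or study the interaction between within-LN priming kinetics and
between-organ migration.

## What it implements

**Priming within a draining LN.** Cognate DC encounters arrive as a
Poisson process with rate λ (per hour); each contact transmits a signal
with probability p, and retention (stable arrest) occurs at the n-th
success. The time to retention is Gamma distributed with shape n and rate
μ = λp:

    P(A ≤ t) = γ(n, μt) / Γ(n)

Pure *probabilistic priming* is the n = 1 (exponential) limit; pure
*signal integration* fixes p = 1 and yields switch-like kinetics for
large n. Only μ = λp is identifiable from retention data.

**Transit through organs.** LN T cell zones are absorbing spheres entered
at the center (Brownian motion, motility M = 60 µm²/min, mean transit
R²/6M = 13.5 h, survival given by the exact eigen-series); the splenic
PALS is a reflecting disc with an absorbing aperture opposite the entry
point, calibrated to a 6 h mean transit. Both laws show the
characteristic entry-to-exit lag absent from exponential egress models.

**Circulation.** A kinetic Monte Carlo of independent cells over blood,
spleen (entry 1.0/h) and 39 LN spheres (1.5/h combined), with draining-LN
designation, a 9-fold entry-rate ramp for local infections, steady-state
burn-in, occupancy/arrival statistics, and retention inside dLNs.

**Capture times.** Closed-form expected capture time for fixed LN dwell
(geometric number of unsuccessful dLN visits, truncated-Gamma final
dwell), the csch closed form for probabilistic priming with stochastic
transit, Monte Carlo capture simulation, optimal-transit-time search, and
a benefit/risk matrix of transit optimization across antigen doses.

**Track statistics & fitting.** The two-photon pipeline (per-track
motility coefficients, duration-weighted median gating against controls,
background correction, 20-min windows relative to LN entry, bootstrap
intervals) and logit-scale fitting of the general/pure priming models
with BIC model selection (12/7/6 parameters for six experiments).

**Synthetic data.** A generator of two-photon-like track sets with known
ground truth (persistent walks switching to arrest jitter, exponential
track censoring) and ready-made infection scenarios for the circulation
model.

## Worked example

```r
library(tcellsurv)
set.seed(1)

# steady-state circulation of 10,000 cells over two weeks
sim <- simulateCohort(1e4, bodyConfig(), horizon = 336)
round(100 * occupancyFractions(sim), 1)
#> blood spleen     ln
#>   3.7   22.3   74.1

# ~74% of cell-time is spent in LNs, ~22% in the spleen, ~4% in blood;
# the blood sojourns between organ visits average ~24 min

# how long until a circulating cell is captured by an infection
# affecting 25% of the LN spheres, at 8 required contacts (1/h)?
p8 <- primingParams(contact_rate = 1, success_prob = 1, required_contacts = 8)
expectedCaptureTime(0.25, p8, T_det = 12)
#> Expected capture time 74.21 h (3.09 d)
#>   components: t0 = 10.1 h, tau_b = 4.71 h, E[N] = 3.393, P = 0.9105, theta = 7.42 h

# the LN dwell that detects this antigen fastest
optimalTransitTime(0.25, p8)
#> [1] 11.93224
#> attr(,"objective_h")
#> [1] 64.12239

# close the loop on synthetic imaging data: fit the priming models to a
# generated low-dose track set and compare them by BIC
gen <- generateTrackSet(syntheticTrackSpec(doses = list(low = primingParams(2, 1, 8))))
win <- windowRetentionSeries(gen$tracks)
modelSelectionReport(data.frame(experiment_id = win$experiment_id,
                                time_h = win$time_h, fraction = win$fraction,
                                weight = win$weight_min))
#>               family  k       rss        bic delta_bic evidence_against
#> 1            general 12  19.28243  -7.740824   0.00000
#> 2 signal_integration  7  21.10926 -22.797811 -15.05699             weak
#> 3      probabilistic  6 304.33020 117.306883 125.04771      very strong
```

Disabling signal integration (bottom row) is heavily penalized on
switch-like low-dose data, while disabling probabilistic priming costs
essentially nothing — the signature of signal integration.

A thin command-line front end over the same functions is installed at
`inst/cli/tcellsurv.R` (subcommands `simulate-circulation`,
`simulate-capture`, `analyze-tracks`, `fit-retention`,
`make-synthetic`).

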