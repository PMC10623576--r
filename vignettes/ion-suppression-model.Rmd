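---
title: "Modeling and measuring gas-phase ion suppression in SESI-MS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and measuring gas-phase ion suppression in SESI-MS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Secondary electrospray ionization (SESI) ionizes gaseous analytes — most
prominently breath volatiles — by charge transfer from an electrospray
plume. The method is only semiquantitative: abundant matrix compounds such
as acetone (0.5–1 ppm in normal breath, far more in ketosis) suppress the
ionization of other analytes. `sesisuppress` packages the quantitative
machinery needed to study this effect end to end:

1. a **Henry's-law gas-standard calculator** (`outlet_ppm()`,
   `required_stock()`, `concentration_ladder()`) for the
   evaporation-chamber / mixing-chamber delivery system,
2. a **seeded synthetic SESI-MS data generator** (`generate_scenario()`)
   with a competitive, gas-phase-basicity-ordered suppression model and
   mzML output,
3. a **signal-extraction pipeline** (average spectrum, peak picking with a
   height filter, integration bounds at a height fraction, per-scan
   trapezoidal traces, SIM-window stitching),
4. exact **l2 change-point segmentation** of the pulsed delivery traces
   with last-10-scan pulse summaries, and
5. **dose–response metrics** (normalization to a zero-suppressor control,
   Spearman trend classification, fractional loss, decade drops, required
   dilution).

Real instrument data cannot be redistributed here, so the generator is a
first-class, tested component: it fixes a known ground truth (delivered
concentrations, true suppression factors, true steady intensities) against
which every pipeline stage is validated.

## Gas-standard generation

A stock solution of molarity $c_{aq}$ equilibrates with its headspace
according to Henry's law, $c_{gas} = c_{aq}/(10^3 H)$, where $H$ is the
dimensionless Henry constant as conventionally printed for headspace work
(0.67 for acetone, 2.73 for pyridine, 99.15 for acetic acid; deuterated
compounds use the value of the unlabeled analogue). The $10^3$ scale
reflects that these printed values are literature dimensionless liquid/gas
partition coefficients divided by 1000 (acetone's full dimensionless
coefficient is ≈ 670); `henry_scale` exposes the convention because the
primary sources do not print units. The ideal gas law converts the
headspace molarity to a mole fraction ($RT/P = 24.4655$ L/mol at 298.15 K
and 101325 Pa) and the mixing chamber dilutes it by
`dilution_flow / chamber_flow` — exactly 1600 for the nominal 8 L/min over
5 mL/min. The alternative `(dilution+chamber)/chamber` convention (1601) is
available but non-default, matching the printed factor. Titration ladders
rise in half-logarithmic steps (`concentration_ladder()`), typically 1000×
over 7 levels.

## The suppression model

The essential physics the generator must emulate is *ordering*: a
gas-phase base suppresses every weaker base, with pyridine
(898.1 kJ/mol) ≫ acetone (782.1) > acetic acid (752.8), and with higher
suppressor concentrations required under humid conditions. The generative
stand-in is a saturable competition with exponential basicity weights:

$$F_i = \Big(1 + \sum_{j \ne i} e^{(GB_j - GB_i)/\beta}\, c_j/c_{50}\Big)^{-\gamma}$$

* $\beta = 20$ kJ/mol sets the selectivity: a 29.3 kJ/mol basicity gap
  (acetone over acetic acid) weights the competitor ×4.3, a 116 kJ/mol gap
  (pyridine over acetone) ×330.
* $\gamma = 2$ lets two decades of suppressor increase produce up to four
  decades of signal loss, the saturating regime the titrations show.
* $c_{50,dry} = 0.01$ ppm and $c_{50,humid} = 15$ ppm place the suppression
  onsets. Both values are calibration constants fixed **in closed form**
  from the headline observations the scenarios must reproduce: under dry
  conditions acetic acid must lose ≈ 4 decades as acetone rises from 0.011
  to 1.1 ppm, which forces $e^{29.3/\beta} c/c_{50,dry} \approx 500$ at
  1 ppm; under humid conditions a volatile panel with basicities just below
  acetone must lose ≈ 30% at 1 ppm, which forces
  $e^{22/\beta}/c_{50,humid} \approx 0.2$. The resulting
  $c_{50}$ ratio (1500×) is larger than the ~10× onset shift one would
  read off the dry/humid thresholds alone; under this functional form the
  two printed endpoint observations cannot be reconciled with a 10× ratio,
  and the endpoints won. A consequence worth knowing: the humid condensate
  curve loses ~89% at the 11 ppm top level, somewhat more than the 20–80%
  band reported for real condensate at 10 ppm.
* Isotopologues carry equal weights (equal GB), so an isotopologue pair at
  equal concentration suppresses each other symmetrically.

Humidity additionally divides the instrument response by
`humid_sensitivity_ratio` (default 10), reproducing the observed
dry-over-humid intensity advantage at equal delivery.

The suppression load of a measurement level is evaluated at the level's
*plateau* concentrations and held constant within the level. Tracking the
load scan-by-scan through the mixing-chamber washout would make a strongly
suppressed analyte surge two decades *between* pulses (its competitor's
load releases faster than the analyte itself washes out), a trace shape
real pulsed measurements do not exhibit, and one that defeats least-squares
pulse segmentation. The washout still shapes each pulse: every delivered
compound follows a first-order rise/decay (`delivery_profile()`, time
constant 3 s, small against the 30 s pulses) around the rectangular flow
program.

## What the generator emulates — and what it does not

Each scenario delivers its compounds in the standard flow program — 30 s
on, 30 s off, three pulses — preceded by a 10 s baseline lead-in. The
lead-in makes the trace consist of $2n_{pulses}+1$ piecewise-steady
segments, so the design-fixed change-point count $K = 2 n_{pulses}$ is
exact, and it gives every measurement an in-run baseline. Scans cycle
round-robin over the configured SIM windows (one window per scan); profile
peaks are Gaussian with FWHM $= m/z / R$ ($R = 140\,000$), sampled at
$\sigma/4$ over ±12σ neighborhoods around each expected ion. Noise is
additive Gaussian baseline ($\sigma = 100$ a.u., clipped at zero as in real
profile data) plus a 5% signal-proportional term, all drawn from one seeded
generator; a fixed scenario seed fixes the dataset (and its ground-truth
table) completely.

Shipped scenarios:

* `scenario_binary()` — acetic acid constant at its 7.0e-4 ppm set point,
  acetone 0.011 → 1.1 ppm, single 64–66 Th window, 1 s scans.
* `scenario_ternary()` — acetic acid and acetone constant, pyridine
  2.7e-4 → 0.85 ppm, three 1-Th windows at 64.1/65.1/80.1, 0.5 s scans.
* `scenario_condensate()` — 12 "condensate volatile" features with
  basicities drawn uniformly from 745–780 kJ/mol (just below acetone, the
  population most susceptible to it), delivery concentrations log-normal
  around 3e-4 ppm, against an acetone ladder 0.011 → 11 ppm. The suppressor
  contributes two *increasing* channels of its own ion chemistry (hydrate
  and proton-bound dimer at 0.5× and 0.15× its response). Three wide
  windows (60–90–120–150 Th) are cycled instead of many 1-Th stitched
  windows so each trace is sampled every 1.5 s — the last-10-scan pulse
  summary needs ≥ 10 samples per 30 s pulse, which a dozen cycled 1-Th
  windows could not deliver at realistic scan rates.
* `scenario_sensitivity()` — one analyte alone, far below $c_{50}$, run
  dry and humid to recover the sensitivity ratio.

In the condensate emulation all compounds — features and suppressor — share
the pulsed program. A real condensate chamber flows continuously while only
the acetone chamber pulses; but then feature traces would pulse *inverted*
(dips during suppressor pulses) at strong suppression and be flat at the
control level, and no single per-trace rule recovers "the three pulses"
across levels. Co-pulsing keeps every trace pulse-shaped while the
last-10-scan plateau measures exactly the same steady-state suppressed
intensity.

Not modeled: electrospray droplet physics and liquid-phase suppression
(spray-side additions are representable only as a constant background
channel), ligand-switching kinetics, space-charge effects, isotope fine
structure, temperature-dependent Henry constants, and evaporative depletion
of the stock. Passing tests therefore demonstrate that the *pipeline*
recovers a *known* competitive-suppression truth through realistic
acquisition artifacts (SIM cycling, washout, noise, peak shape) — they do
not validate the functional form against real instrument data.

## The extraction pipeline

Following standard practice for this delivery design:

1. **Average spectrum** over all measurements of a run, per SIM window
   (`extract_features()` pools every concentration level so the feature
   list is identical across levels and strongly suppressed levels are still
   traced at known positions).
2. **Peak picking** keeps local maxima with apex ≥ 1e4 a.u.
3. **Integration bounds** sit where the intensity first falls below
   *90% of the apex height* (linear interpolation between grid points).
   This narrow-tip reading is implemented literally; because the sentence
   could also mean the 10% level, the fraction is a parameter
   (`bound_fraction`). For a Gaussian the 0.9-bounds width is
   $2\sigma\sqrt{2\ln(1/0.9)} \approx 0.918\sigma$, verified against the
   closed form to within one grid step.
4. **Traces** are per-scan trapezoidal integrals over the bounds; scans
   from other SIM windows are skipped.
5. **Segmentation**: exact O(K n²) dynamic programming for the l2 cost
   with $K = 2 n_{pulses}$ fixed by the design (no tuning parameter; a
   BIC-like penalized mode exists but is non-default), ties broken toward
   the earliest indices, verified against exhaustive enumeration for
   n ≤ 40, K ≤ 4. Constant series are refused as degenerate. On-pulses are
   the segments whose mean exceeds the midpoint of the extreme segment
   means; a wrong on-count raises a `pulse_count_mismatch` error — in a
   full run such a failure (typically a feature suppressed into the noise
   at a high level) is recorded as `NA` for that feature × level and
   reported, never repaired.
6. **Pulse summary**: mean of the last 10 scans of each pulse with its
   within-pulse standard error (sd/√10); segments shorter than 10 scans
   are summarized whole, with a warning. Because the wording of "standard
   error" is ambiguous for triplicate pulses, the replicate-level spread —
   the standard error of the three pulse means — is reported as well, and
   it is the level error bar used in dose–response curves.

## Dose–response analysis

Level means (mean of the three pulse means) form per-feature curves.
Normalization is to the zero-suppressor control level; without a control,
the lowest level is used with a warning. Trends are classified by Spearman
rank correlation of intensity against log-concentration over the nonzero
levels (|ρ| ≥ 0.8): the suppressor's hydrate and dimer channels come out
*increasing*, the condensate volatiles *decreasing*; the median across
decreasing features summarizes the panel (robust, and the natural reading
of "most features"). Continuous queries interpolate log-linearly between
levels and refuse extrapolation; decade drops are computed between measured
levels and error out (as "below detection") on non-positive intensities.
`required_dilution()` solves the piecewise-log-linear loss curve exactly
for the smallest dilution meeting a loss bound and rounds it up to one
significant figure.

## Numerical choices and problem sizes

Scenario runs used throughout the tests and the acceptance script are
moderate by design: 190–380 scans per level (0.5–1 s scan periods over the
190 s program), 6–9 levels per run, and five seeds per condensate condition
— a full acceptance evaluation, including every mzML round trip, runs in
about a minute on one CPU. The required-stock inverse is analytic (round
trip exact to 1e-12 relative); m/z grids place each expected apex exactly
on a grid point; trace integration interpolates the bound endpoints
linearly; the change-point DP uses prefix sums, so segment costs are O(1).
The mzML writer (via `mzR`/ProteoWizard) embeds a timestamp, so determinism
is asserted on the re-read data — identical spectra, times and window tags
under a fixed seed — rather than on raw bytes.

## Known limitations

* The suppression functional form is a calibrated invention; only its
  ordering and its calibrated end points carry evidence.
* The humid/dry $c_{50}$ ratio implied by the calibration (1500×) should
  not be interpreted physically (see above).
* Electrospray-side experiments are represented only schematically.
* `mzR` writes ~1e-7 relative intensity rounding into mzML; all
  quantitative checks tolerate this.
* The exact DP is quadratic in the trace length; for traces beyond ~1e4
  scans a pruned or binary-segmentation method would be preferable.
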