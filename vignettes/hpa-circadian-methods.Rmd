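---
title: "Modelling circadian HPA-axis regulation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling circadian HPA-axis regulation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`hpaclock` implements a semi-mechanistic model of the circadian
hypothalamic–pituitary–adrenal (HPA) axis: a Goodwin-type limit-cycle
oscillator for the hormonal cascade CRH → ACTH → corticosterone (CORT),
closed by glucocorticoid-receptor (GR) pharmacodynamics, and entrained
by a square-wave light schedule through a phototransduction cascade.
The state has 14 variables:

* **Photic input** (7): two three-compartment transfer chains
  (`light_TCsynth_1..3`, driven by the light square wave, and
  `light_TCdeg_1..3`, driven by its complement) and the dimensionless
  `light_effect`, produced by an ultrasensitive Hill function of the
  terminal synthesis compartment and degraded at a rate enhanced by the
  terminal degradation compartment.  The transfer chains give the
  photic effect its onset lag (about 1.5 h after lights-on at the
  default transfer rate `k_t = 2` h⁻¹) and a sharp shut-off after
  lights-off.
* **HPA cascade** (4): CRH synthesized at the zero-order rate `k_p1`
  under nuclear-receptor inhibition `K_p1 / (K_p1 + DRN)`; ACTH
  synthesized first-order from CRH under inhibition constant `K_p2`;
  CORT synthesized from ACTH with the adrenal sensitivity `k_p3`;
  GR mRNA transcribed under DR(N) repression.  All three hormones decay
  by Michaelis–Menten kinetics; operating the degradation reactions
  near saturation (small `K_d`) supplies the effective nonlinearity
  that lets a feedback loop with Hill coefficient one oscillate.
* **Receptor pharmacodynamics** (3): free GR, the cytosolic
  CORT–GR complex DR, and the nuclear complex DR(N) which carries the
  negative feedback; a fraction `r_f` of the nuclear complex recycles
  to the free-receptor pool.

Light acts by enhancing CRH degradation: the loss term is multiplied by
`1 + light_effect / (1 + light_effect)`, i.e. light can at most double
the CRH turnover — consistent with photic suppression of CRH in
nocturnal animals.

### Why the degradation chain is driven by darkness

The source equations drive the second transfer chain with a signal that
is never defined in their main text.  Driving it with the same light
square wave as the first chain would make the two chains identical
state-for-state (same ODE, same input), leaving one of them redundant.
The package therefore drives the degradation chain with the complement
of the light signal by default (`light_deg_signal = "dark"`), which
gives the photic effect a delayed, sharp decay after lights-off and
makes the second chain functionally meaningful.  The literal
same-signal reading remains available via
`light_schedule(light_deg_signal = "light")`.

### Default parameters and their phasing

The shipped constants (`default_parameters()`) are repository defaults
chosen by the package authors, not fitted experimental values: rates
are O(0.1–1) h⁻¹, concentrations in arbitrary units.  They were tuned
so that

* the unforced system free-runs with period τ ≈ 24.3 h and a
  pulse-like CORT waveform of amplitude ≈ 3 a.u.;
* under the 14 h light : 10 h dark schedule (lights on 07:00–21:00) the
  system entrains exactly to 24 h with a clear cosinor rhythm.

One known limitation: the entrained CORT acrophase sits near the middle
of the light phase (~12:30) rather than at the light/dark transition
where nocturnal rodents peak.  With light coupled through enhanced CRH
degradation, the stable entrained phase of this oscillator family lies
in the photophase for every parameter regime we explored (τ from 21.7
to 30 h, weak to saturating coupling, photic lags 1.5–3 h); dusk
phasing evidently requires parameter or structural detail beyond what
the model's public description provides.  Because the calibration
target is generated from the model itself (see below), every
downstream analysis is phase-consistent; only the absolute clock
position of the peak differs from the rodent phenotype.  Time-of-day
anchors are therefore defined relative to the rhythm: the
"mid-inactive-phase" stressor onset is 7 h before the CORT acrophase
(`mid_inactive_onset()`), which coincides with the lights-on midpoint
(14:00) under nocturnal dusk phasing.

## Numerical integration

The square wave makes the vector field discontinuous in time.  The
integrator (compiled, Dormand–Prince 5(4) adaptive) therefore never
steps across a switching time: the schedule is compiled into
piecewise-constant forcing segments and integration restarts at every
boundary.  Trajectory extraction uses `rtol = 1e-8`, `atol = 1e-10`;
Floquet analysis tightens to `1e-10`/`1e-12`; subspace screening
relaxes to `1e-5`/`1e-7` (the calibration decision is insensitive to
this at the acceptance-band scale, which is ~10% of the signal).  The
compiled right-hand side and its analytic Jacobian are both
cross-checked in the test suite against an independently written R
implementation and central finite differences.

Limit-cycle convergence compares consecutive cycles of the CORT profile
in sup-norm relative to the cycle amplitude (default `tol = 1e-4`;
screening uses `1e-3`).  In constant darkness the free-running period
differs from 24 h, so convergence is instead declared on the stability
of the peak-to-peak interval, and for Floquet analysis the period is
then refined by Newton iteration on a Poincaré section normal to the
flow; this yields the neutral (trivial) Floquet multiplier equal to 1
to ~1e-9.

## Calibration and the synthetic target

The study calibrates the model to a circadian CORT profile summarized
by cosinor parameters (mesor, amplitude, acrophase at fixed 24 h
period).  Cosinor fitting uses the exact linear reparameterization
(mean, cosine and sine coefficients) with delta-method standard
errors.  A candidate parameter set passes calibration when each of the
three cosinor parameters lies within one target standard deviation of
the target, with the acrophase compared circularly.

The experimental reference data are not redistributable, so the
`synthetic_target_spec()` / `make_calibration_target()` generator
replaces them: it simulates the entrained model at a known *generating
triple* (defaults: `K_p1 = 0.3`, `K_p2 = 0.4`, `k_p3 = 1.0`), fits the
cosinor, optionally perturbs it with seeded Gaussian noise (truncated
to keep the amplitude positive), and attaches acceptance SDs of 10% of
mesor and amplitude and 1 h of acrophase.  These SD values are
surrogates standing in for experimental cosinor uncertainty; they are
deliberately of the magnitude typical for rodent CORT cosinor tables.
What the generator does *not* emulate: ultradian pulsatility,
estrous-cycle modulation, assay noise autocorrelation, and
between-animal variance structure.  Tests passing against synthetic
targets therefore demonstrate the pipeline's internal correctness and
the model's qualitative behaviour, not agreement with any particular
animal dataset.

## Regulatory subspace sampling

Homeostatic regulatory variability is explored over the triple
(`K_p1`, `K_p2`, `k_p3`) inside a log-uniform box
(`default_sampling_box()`: K_p1 ∈ [0.015, 0.6], K_p2 ∈ [0.15, 1.6],
k_p3 ∈ [0.5, 2.2]) chosen once to contain the calibrated subspaces of
the nominal condition and of both chronic-stress conditions.  Chronic
stress is a persistent elevation of the CRH drive `k_p1` (2× and 4× for
the intermediate and high conditions).  Candidates are drawn by a
seeded Latin hypercube (no Sobol generator is available in the
dependency set; the spatial stratification serves the same purpose),
simulated to the entrained cycle, cosinor-fitted and accept/reject
tested.  A screening shortcut rejects candidates whose first
post-transient cycle deviates by more than six target SDs — by then the
dominant transient has decayed below one percent, so band-adjacent
candidates are never lost; on audit seeds the accepted set is identical
with and without the shortcut.  Acceptance rates are of order 0.5–1.5%,
reflecting that the calibrated set is a thin 2-manifold in the box.

**Surface area.**  The accepted triples approximate a surface
`k_p3 = f(K_p1, K_p2)`.  Its area is computed by Delaunay-triangulating
the accepted points in the (K_p1, K_p2) plane (a Bowyer–Watson
implementation with incircle-determinant predicates; no triangulation
library ships in the dependency set), restricting to the alpha complex
(circumradius ≤ 2× the median nearest-neighbour spacing, so concave
regions are not bridged), lifting each triangle through its `k_p3` and
summing 3D areas.  Two normalization choices matter and are deliberate:

* the triangulation and alpha test run in per-axis standardized
  coordinates, because the accepted regions are strongly anisotropic
  and raw-coordinate circumradii would discard every triangle of a
  thin region;
* for an `accepted_subspace` the area is measured in box-normalized
  coordinates (each axis divided by its box width) and reported in
  arbitrary units, because the three axes carry different units and a
  raw mixed-unit Euclidean area is not meaningful;
* the condition-comparison summary is by default the *projected*
  footprint of the accepted region in the normalized feedback plane
  (`lift = "projected"`).  The accepted set has a finite
  acceptance-band thickness; at the point densities the sampling
  achieves, sample-to-sample k_p3 jitter within that thickness enters a
  3D-lifted area as spurious steep triangles and dominates the estimate
  for the narrow stressed ribbons (measured spread across seeds: more
  than an order of magnitude), while the footprint is stable.  The
  fully lifted 3D area remains available (`lift = "k_p3"`), and on
  plain coordinate data (`surface_area(data.frame(...))`) the raw 3D
  lifted area is returned.

## Protocols

* **Acute stress** — a transient multiplicative pulse on `k_p1`
  (default 1 h at 5-fold; the source description fixes neither
  magnitude nor duration).  The response is ΔAUC of CORT over exactly
  4 h from onset between matched stressed/unstressed runs started from
  the identical converged state.  The "middle of the inactive phase"
  onset is anchored 7 h before the entrained CORT acrophase (see
  above).  Pooled responses are z-scored and
  partitioned into five equiprobable symbols at the standard-normal
  quintiles (±0.8416, ±0.2533); empirical quantiles are available by
  argument.
* **Shift work** — a 96 h inversion of the light/dark cycle, starting
  at a lights-on transition (the source leaves the anchor unstated);
  the statistic is the maximal circular difference between the daily
  CORT peak times of perturbed and control runs.
* **Jet lag** — a permanent 10 h delay of lights-on (to 17:00) with
  photoperiod preserved; re-entrainment is the first day from which
  the consecutive-peak spacing stays within 3 min of 24 h for three
  consecutive cycles (the persistence requirement suppresses transient
  false positives around the criterion's knife edge).

## Entrainment and stability

`is_entrained()` rescales the schedule to an arbitrary entrainer period
(photoperiod fraction preserved) and scales the square-wave amplitude
by the entrainer strength; 1:1 locking is declared when the
stroboscopic CORT-peak phase drifts less than 0.05 h per cycle over the
final 15 of 20 observation cycles after a 40-cycle burn-in.  Only 1:1
locking is classified.  The detector's logic is validated against the
Adler phase equation, whose locking boundary |Δω| ≤ K is known in
closed form.  `arnold_tongue()` maps the grid and records the intrinsic
period τ and amplitude A0 for axis normalization; `tongue_area()`
integrates the entrained cells.

Floquet analysis integrates the 14×14 variational system (analytic
Jacobian, compiled) along one period of the converged orbit and takes
the eigenvalues of the monodromy matrix.  Under forcing the period is
the entrainer's and all multipliers describe stability; in constant
darkness the Newton-refined free-running period is used and the
neutral multiplier is excluded from the leading exponent.  Exponents
are `log(multiplier)/period` in h⁻¹; more negative real parts mean
faster amplitude relaxation (a more rigid oscillator).  The
entrainment-range analyses and the multiple linear regression of the
leading exponent on (K_p1, K_p2, k_p3) (ordinary least squares) use the
*intrinsic* exponent — the constant-darkness orbit's leading
non-trivial exponent — because the weak/strong-oscillator theory
relating relaxation rate to entrainment range concerns the unforced
oscillator's amplitude dynamics; on the representative nominal triples
the intrinsic |exponent| falls as the entrainment domain widens
(Spearman ≈ −0.8) while the forced-orbit exponent does not track the
tongue at all.

## Study sizes and determinism

`run_study()` wires the full pipeline: synthetic target → three
subspaces → subspace comparison → acute responses with symbolization →
photoperiod protocols → Arnold tongues for representative triples →
Floquet exponents and regression.  All randomness derives from the
single `seed` argument; identical configurations reproduce identical
outputs bit-for-bit.  The default study sizes used by the shipped
analysis script are 1800 candidates per condition, an 8 × 4 tongue
grid, and 6–9 representative triples per surface; the package's test
suite runs the trend checks at the same scale with five independent
seeds and the parameter-recovery check at 2000 candidates across 20
seeds.  These sizes were chosen as the smallest at which the accepted
sets are large enough (roughly 10–30 triples per condition) to support
the geometric summaries.

## Known limitations

* The entrained acrophase phasing discussed above.
* Under this calibration, chronic-stress habituation does **not**
  sensitize the acute stress response: at matched adrenal sensitivity
  the high-stress ΔAUC lies below nominal at the mid-inactive onset and
  at every onset of a whole-day sweep, because habituation to the 4×
  drive demands roughly ten-fold stronger hypothalamic feedback, which
  damps the response to a CRH-drive pulse more than the elevated drive
  amplifies it.  The corresponding trend check in the test suite fails
  by design rather than being weakened.
* At matched adrenal sensitivity the intermediate-stress condition has
  the narrowest entrainment domain (its free-running period is the most
  detuned from 24 h), so the entrainment domain does not decrease
  monotonically across all three stress levels; the nominal condition's
  domain exceeds both stressed conditions'.
* No ultradian (pulsatile) secretion, no stochastic dynamics, no
  mechanistic SCN or peripheral clock, no diurnal-species variant.
* CRH and ACTH dynamic ranges are not separately calibrated; only the
  CORT observable is matched, so their absolute excursions should not
  be interpreted quantitatively.
* Acceptance rates make the accepted-set geometry noisy at the default
  sizes; area comparisons are stable at the median-over-seeds level,
  individual-seed areas fluctuate by tens of percent.
* The subspace surface areas are reported in box-normalized arbitrary
  units and are comparable within this package's conventions only.
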