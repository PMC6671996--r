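# hpaclock

Light-entrained limit-cycle modelling of circadian
hypothalamic–pituitary–adrenal (HPA) axis glucocorticoid rhythms, and
the analysis of how chronic stress reshapes its regulation.

## The scientific problem

The HPA axis secretes glucocorticoids (corticosterone, CORT, in
rodents) with a pronounced circadian rhythm entrained by light, and it
is also the body's main acute stress-response system.  Habituation to a
chronic stressor can leave the CORT rhythm looking normal while the
underlying regulation has silently shifted — a change with consequences
for stress reactivity, entrainability, and tolerance of shift work and
jet lag.  `hpaclock` is for computational physiologists and
chronobiologists who want to study these trade-offs in a mechanistic
model: it identifies *all* regulatory configurations compatible with a
homeostatic CORT rhythm, not a single best fit, and then asks how that
ensemble's functional properties change when the central stress drive
is chronically elevated.

## The model

A Goodwin-type oscillator for the hormonal cascade, closed by
glucocorticoid-receptor (GR) pharmacodynamics and forced by light
(14 h light : 10 h dark, lights on 07:00–21:00):

* CRH: zero-order synthesis `k_p1` inhibited by the nuclear
  receptor–hormone complex, `K_p1/(K_p1 + DR(N))`; Michaelis–Menten
  degradation enhanced up to two-fold by the delayed photic signal
  (`1 + light_effect/(1 + light_effect)`).
* ACTH: first-order synthesis from CRH inhibited with constant `K_p2`;
  Michaelis–Menten degradation.
* CORT: synthesis `k_p3 · ACTH` (adrenal sensitivity); Michaelis–Menten
  degradation.
* GR module: GR mRNA (repressed by DR(N)), free GR, cytosolic complex
  DR, nuclear complex DR(N), with partial receptor recycling.
* Photic pathway: two 3-compartment transfer chains (light onset and
  offset) feeding an ultrasensitive Hill nonlinearity, giving the
  ~1.5 h photic lag.

Three parameters carry the studied regulatory variability: the
hypothalamic feedback constant `K_p1`, the pituitary feedback constant
`K_p2`, and the adrenal sensitivity `k_p3`.  Chronic stress is a
persistent elevation of `k_p1`.  The analyses built on the model:
cosinor rhythmometry with a ±1 SD calibration box; accept–reject
sampling of the calibrated (K_p1, K_p2, k_p3) subspace under nominal,
2× and 4× drive; acute-stress ΔAUC scoring with five-symbol
equiprobable partitioning; 96 h light-inversion (shift work) and
permanent 10 h delay (jet lag) protocols; Arnold tongues (domains of
1:1 entrainment over entrainer period × strength); and Floquet
stability of the limit cycle (entrained and free-running), with a
multiple linear regression of the intrinsic leading exponent on the
regulatory triple.

A synthetic-data generator produces the calibration target from the
model itself, so the entire study runs with no external data.

## Worked example

```r
library(hpaclock)

p <- default_parameters()

# entrained limit cycle under 14L:10D
cyc <- integrate_to_limit_cycle(p, light_schedule())
fit_cosinor(cyc$times, cyc$states[, "CORT"])
#> Cosinor fit (period 24 h): mesor 1.653, amplitude 2.65, acrophase 11.48 h

free_running_period(p)      # constant darkness
#> [1] 24.31341

floquet_exponents(p, light_schedule())
#> Floquet result (period 24.0000 h): leading exponent -0.029626 1/h
#>   |multipliers|: 0.4911, 0.4911, 0.02838, 0.000132, 1.78e-17 ...
```

The cosinor mesor/amplitude/acrophase summarize the steady-state CORT
rhythm; the free-running period shows the oscillator is intrinsically
circadian (τ ≈ 24.3 h ≠ 24 h, so the 24 h rhythm under the schedule is
genuine entrainment); the negative leading Floquet exponent
(−0.030 h⁻¹) says amplitude perturbations relax back to the orbit with
a ~34 h time constant.

A scaled-down end-to-end study:

```r
res <- run_study(seed = 1, n_samples = 1800)
res$comparison
#>      condition k_p1 n_accepted mean_K_p1 mean_K_p2 mean_k_p3      area
#> 1      nominal    3         11   0.22888    0.8663     1.355 1.439e-02
#> 2 intermediate    6         10   0.05563    0.5861     1.593 1.861e-03
#> 3         high   12         14   0.02254    0.3846     1.594 5.419e-05
#> Trends: K_p1_decreases: yes; k_p3_increases: yes; area_decreases: yes
```

The qualitative signature of allostatic adaptation: with rising chronic
drive the hypothalamic feedback strengthens (mean `K_p1` drops from
0.23 to 0.02, an order of magnitude), adrenal sensitivity rises (mean
`k_p3` 1.36 → 1.59), and the footprint of the calibrated regulatory
surface shrinks (area 1.4e-2 → 5.4e-5 box units) — the system keeps its
rhythm but loses regulatory flexibility.  One departure from the
sensitization picture is documented in the methods vignette: in this
calibration the chronically stressed systems respond *less* strongly to
an acute CRH-drive pulse at matched adrenal sensitivity, because
habituation demands much stronger hypothalamic feedback.

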