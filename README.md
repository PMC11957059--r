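# kaishuffle

Stochastic modelling and inference of ATPase-driven subunit shuffling in
KaiC-CI hexamers.

KaiC, the hexameric AAA+ ATPase at the core of the cyanobacterial circadian
clock, exchanges monomers between hexamers on a timescale of hours, and this
shuffling is thought to synchronise the clock ensemble.  The package is for
quantitative biologists who study subunit exchange with tag-ladder mixing
experiments: native and 2xFLAG-tagged homo-hexamers are mixed 1:1, and
ion-exchange chromatography resolves hexamers with k = 0..6 tagged subunits
into seven peaks whose areas give the tag-count distribution p_k(t).

At its core are:

* a per-monomer nucleotide cycle — hydrolysis T→D at rate k_h and exchange
  D→T at rate k_e (h⁻¹), giving the ATPase activity
  `k_cat = k_h k_e / (k_h + k_e)` and the steady competent-state (CS,
  ≥ 2 ADP) hexamer fraction `f_cs = 1 − (1 + 6x)/(1 + x)⁶` with
  `x = k_h/k_e`;
* stochastic simulators (fast-equilibrium and explicit event-driven) that
  couple this cycle to disassembly/reassembly of CS hexamers and track the
  tag-count distribution of the population;
* the distribution distance `L = Σ_{k=1..5} |p_k − q_mix · C(6,k)/2⁶|`,
  which discriminates sequential, cooperative and stochastic dissociation
  modes along the mixing trajectory;
* chromatogram rendering and constrained seven-peak deconvolution;
* estimators: the one-phase exponential shuffling rate
  `p_het(t) = p_∞ (1 − e^{−k_s t})`, and inference of (k_h, k_e) from
  (k_cat, k_s) by contour intersection or from (k_cat, f_cs) in closed
  form.

## Worked example

Simulate the wild-type CI mixing experiment (measured activity
0.43 h⁻¹, ATP-buffer exchange rate 25.5 h⁻¹) and fit its shuffling rate:

```r
library(kaishuffle)

wt  <- rate_params(kh = invert_kcat(0.43, 25.5), ke = 25.5)
sim <- simulate_shuffling(wt, n_hexamers = 2000, t_grid = seq(0, 36, 2), seed = 7)
sim
#> Shuffling simulation (fast_eq method), 2000 hexamers, 19 time points
#>   kh = 0.4374 /h, ke = 25.5 /h (kcat = 0.43 /h)
#>   hetero fraction: 0.0000 -> 0.9670 over 36 h

fit_ks(sim$series, seed = 7)
#> One-phase exponential shuffling fit: ks = 0.1695 /h  (95% CI 0.1669-0.1716)
#>   amplitude p_inf = 0.9654, SSE = 0.000262, 19 points
```

The hetero-hexamer fraction rises from zero toward its 1:1 saturation
(62/64), and the fitted `ks` is the shuffling rate in h⁻¹.  Inference for a
construct whose hetero ladder cannot be resolved directly works from its
activity and CS fraction instead — here the phospho-mimic KaiC-EE
(2.0 ATP/day/monomer, f_cs ≈ 0.95):

```r
ee <- estimate_from_kcat_fcs(kcat_target = 0.08, fcs_target = 0.95)
ee
#> Inferred kinetic rates
#>   kh = 0.1913 /h, ke = 0.1375 /h
#>   constraints: kcat = 0.08 /h, fcs = 0.95 (closed form, x = kh/ke = 1.391)
#>   residuals: kcat 1.39e-17, fcs 1.85e-14

steady_state(kh = ee$kh, ke = ee$ke)
#> Per-monomer ADP occupancy: 0.5818
#> ADP-count distribution per hexamer (0..6):
#>     d0     d1     d2     d3     d4     d5     d6
#> 0.0053 0.0447 0.1553 0.2881 0.3006 0.1673 0.0388
#> CS-hexamer fraction (>= 2 ADP): 0.9500
```

`simulate_mode()` / `classify_mode()` discriminate dissociation patterns,
`generate_trace()` / `deconvolve()` handle the chromatography layer, and
`preset_scenarios()` + `build_experiment()` produce complete synthetic
mixing experiments with known ground truth.  The methods vignette
(`vignettes/shuffling-model.Rmd`) documents the model, its assumptions and
the numerical choices.

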