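---
title: "An ATPase-coupled model of subunit shuffling in KaiC-CI hexamers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An ATPase-coupled model of subunit shuffling in KaiC-CI hexamers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kaishuffle)
```

## The system and the observable

KaiC, the central hub of the cyanobacterial circadian clock, is a hexameric
AAA+ ATPase.  Its N-terminal CI domain forms stable hexamers on its own, yet
monomers swap between hexamers on the timescale of hours.  The standard way
to observe this is a mixing experiment: two pools of homo-hexamers -- one
native, one carrying a charged 2xFLAG tag on every subunit -- are mixed 1:1,
and samples taken over time are run on an ion-exchange column.  Because the
tag adds negative charge, hexamers with $k = 0..6$ tagged subunits elute as
a ladder of seven peaks, and the areas of those peaks estimate the
tag-count distribution $p_k(t)$.  The package's central observable is this
seven-component distribution; the hetero-hexamer fraction
$p_\mathrm{het} = \sum_{k=1}^{5} p_k$ rises from 0 toward its 1:1
saturation value $62/64$ as subunits randomise, and the rate constant
$k_s$ of a one-phase exponential fit
$p_\mathrm{het}(t) = p_\infty (1 - e^{-k_s t})$ is the shuffling rate.

## The kinetic model

Each monomer carries one nucleotide: ATP (T), ADP (D) or, in analogue
experiments, AMP-PNP (N).  Two irreversible per-monomer reactions drive the
cycle: hydrolysis T $\to$ D at rate $k_h$ and nucleotide exchange
D $\to$ T at rate $k_e$ (both in h$^{-1}$; reverse reactions are
neglected).  The steady ATPase activity per monomer is then the cycle flux

$$k_\mathrm{cat} = \frac{k_h k_e}{k_h + k_e},$$

and per-monomer ADP occupancy is $p_D = k_h / (k_h + k_e)$, so a hexamer's
ADP count is Binomial$(6, p_D)$ at steady state (`steady_state()`).

ADP at a subunit interface destabilises it.  A hexamer with two or more
ADP-bound monomers has two weakened interfaces and can fall apart into two
oligomers: we call it a competent-state (CS) hexamer, in contrast to
ground-state (GS) hexamers with fewer than two ADP.  The steady CS fraction
follows in closed form,

$$f_\mathrm{cs} = 1 - \frac{1 + 6x}{(1+x)^6}, \qquad x = k_h / k_e,$$

which is the Binomial$(6, p_D)$ tail probability of at least two ADP
(`fcs()`; implemented through `pbinom` to avoid cancellation at small
$x$).

Subunit exchange happens only through the CS pool: CS hexamers dissociate
into two contiguous arcs (dissociation rate $k_{dcs}$, default
3600 h$^{-1}$ $\approx$ 1 s$^{-1}$) and complementary-size free oligomers
re-associate (rate $k_{rcs}$ per complementary pair).  Because
$k_{dcs} \gg k_h, k_e$, the dissociation/re-association chain relaxes to
its stationary distribution between nucleotide events.  The package
therefore offers two couplings in `simulate_shuffling()`:

* **fast-equilibrium** (default): at synchronisation intervals
  $\Delta t_\mathrm{mix} = 0.1 / (6 (k_h + k_e))$, all subunits of all
  current CS hexamers are pooled and repartitioned uniformly at random.
  Per-monomer reactions are advanced by tau-leaping with the same step,
  which is two orders of magnitude below the per-hexamer reaction time, so
  leap errors are negligible against Monte-Carlo noise.
* **explicit**: full Gillespie dynamics with finite $k_{dcs}$ and
  $k_{rcs}$, free oligomers that keep their nucleotide and tag states and
  continue per-monomer kinetics, and either uniformly chosen cut-site pairs
  (default) or cuts restricted to ADP-weakened interfaces
  (`cut_rule = "weakened"`).

The explicit method is the finite-rate oracle for the fast-equilibrium
approximation: the two agree on hetero-fraction trajectories within
Monte-Carlo error once $k_{dcs} / \max(k_h, k_e) \gtrsim 100$, *provided*
the free-oligomer pool holds more than a handful of fragments at a time.
If re-association is made very fast relative to the supply of newly
dissociated hexamers, a fragment pair mostly re-binds itself and exchange
stalls -- an implementation trap rather than physics, since the fast limit
is taken with the pool population held at its quasi-steady value.  The
default $k_{rcs} = k_{dcs}/2$ keeps the steady free-subunit fraction below
a few percent for wild-type-like rates while leaving the pool populated;
the equivalence test in the suite pins this behaviour.

Because shuffling permutes monomers without creating or destroying them,
total subunits, tagged subunits and (in ATP-only runs) each hexamer's
nucleotide kinetics are conserved or unaffected; `conservation_check()`
verifies the tallies on every recorded trajectory, and a
shuffling-disabled run reproduces the closed-form binomial ADP histogram
and $f_\mathrm{cs}$.

## Dissociation modes and the L statistic

How a hexamer breaks is a fingerprint of its hydrolysis pattern.
`simulate_mode()` implements three kinematic limits with no nucleotide
bookkeeping: *sequential* hydrolysis leaves two adjacent weak interfaces
(monomer + pentamer), *cooperative* hydrolysis shatters the ring into six
monomers, and *stochastic* hydrolysis produces two loose interfaces at a
uniformly random pair of the fifteen interface pairs, which yields every
fragment size 1-5 with equal expected frequency.  Fragments re-assemble at
random from a common pool; the breakup rate only rescales time, so mode
signatures are read against the mixing stage rather than the clock.

The discriminating statistic compares the observed distribution with the
random binomial ladder $p^S_k = \binom{6}{k}/2^6$ scaled to the same
mixing stage $q_\mathrm{mix} = p_\mathrm{het} / (62/64)$:

$$L = \sum_{k=1}^{5} \left| p_k - q_\mathrm{mix}\, p^S_k \right|.$$

Cooperative break-up randomises in one event, so its $L$ stays at zero;
sequential exchange moves single monomers and maximises $L$; stochastic
break-up lies in between.  `classify_mode()` assigns an observed
$L$-versus-$q_\mathrm{mix}$ trajectory to the mode with the smallest mean
absolute deviation from seed-averaged reference curves
(`mode_reference_curves()`; curves are averaged over replicate seeds and
their spread is reported, since a single run's curve wobbles near the ends
of the mixing range).

## Chromatograms and deconvolution

`generate_trace()` renders a distribution as
$\mathrm{baseline} + \mathrm{scale}\sum_k p_k\,\phi(v; c_k, w)$ on an
elution-volume grid, with unit-area peaks so that peak area is
proportional to molar fraction (absorbance per hexamer is assumed
tag-independent).  The default geometry places the native homo-hexamer at
17.5 ml and the fully tagged one at 20.5 ml with intermediate centres
0.5 ml apart; peaks are Gaussian ($w = 0.15$ ml) by default, with an
exponentially modified Gaussian available for tailed columns.

`deconvolve()` fits seven non-negative areas, one shared width, per-peak
centre shifts bounded within $\pm 0.15$ ml of the calibration centres, and
a constant baseline, by bounded Levenberg-Marquardt with three jittered
restarts.  The shared width and tight centre windows prevent the
amplitude/width degeneracy between overlapping neighbours; fractions are
the fitted areas normalised to one.  At 1% noise the round trip recovers
every fraction within $\pm 0.02$ (and in practice within a few $10^{-3}$);
a trace with no signal is rejected as degenerate rather than silently
fitted to zeros.

## Estimation

* `fit_ks()` fits the one-phase exponential with the amplitude free in
  $(0, 62/64]$ -- real mixing experiments plateau slightly below the
  theoretical saturation, so pinning the amplitude would bias $k_s$ -- and
  reports a 200-replicate residual-resampling bootstrap interval.  A
  fixed-amplitude variant is available for comparison.  An all-zero series
  returns $k_s = 0$ with an interval covering zero rather than an
  arbitrary unidentifiable number.
* `estimate_from_kcat_ks()` intersects the measured-activity contour
  $k_\mathrm{cat}(k_h, k_e)$ with the shuffling-rate contour: along the
  activity contour (parameterised by $k_e$) the simulated $k_s$ decreases
  monotonically, so bisection on $\log k_e$ with seed-averaged simulated
  rates and common random numbers converges in about ten evaluations; the
  match tolerance (5% relative) reflects the Monte-Carlo noise floor of
  the objective.  Infeasible targets report the attainable range instead
  of a spurious root.
* `estimate_from_kcat_fcs()` is closed-form up to one 1-D root:
  $f_\mathrm{cs}(x)$ is strictly increasing, so $x = k_h/k_e$ comes from
  `uniroot` and the scale from the activity.  This is the route to
  full-length KaiC phospho-mimics, whose CS fraction is observable while
  their hetero-hexamer ladder is not.

## The synthetic-data generator

`preset_scenarios()` encodes the study conditions as data: the CI point
mutants with measured activities 0.09, 0.29, 0.43 and 0.73 h$^{-1}$
(exchange rate 25.5 h$^{-1}$ for the wild type in ATP buffer, 10 h$^{-1}$
for the point mutants), a catalytically dead control, ATP:AMP-PNP
titrations (1 mM analogue against 0-1 mM ATP, affinity ratio default
$K_A = 15$, the geometric midpoint of the reported 7.4-23.8 range, and
analogue-buffer exchange rate 12 h$^{-1}$), and the phospho-mimics: KaiC-EE
from activity 0.08 h$^{-1}$ plus CS fraction 0.95 via the closed-form
inversion, and KaiC-AA from activity 0.79 h$^{-1}$ with an exchange rate
of order $10^3$ h$^{-1}$.  For KaiC-AA we deliberately parameterise by the
reported exchange-rate scale rather than by inverting a nominal CS
fraction of 0.01: "almost no CS hexamers" at that activity corresponds to
$k_e \sim 10^3$ h$^{-1}$ ($f_\mathrm{cs} \approx 10^{-5}$), and at
$f_\mathrm{cs} = 0.01$ ($k_e \approx 29$ h$^{-1}$) the simulated shuffling
rate is far above the sub-0.05 h$^{-1}$ regime the construct actually
shows, so that operationalisation would misrepresent the biology.

`build_experiment()` composes simulation and rendering into a full
in-silico experiment (trajectory, per-time chromatograms, manifest) with
1% peak-maximum noise by default.  The generator emulates peak geometry,
counting noise and detector noise; it does not emulate baseline drift,
injection artifacts, column aging, or the non-hexamer oligomer species
that an association-limited construct can accumulate -- so passing
round-trip tests demonstrates the pipeline's statistical consistency, not
robustness to every instrumental pathology of real chromatograms.

## Numerical choices and problem sizes

Simulations in the test suite use 300-5000 hexamers and horizons of 3-96 h
chosen to cover about four shuffling times; seed-averaged quantities use
2-8 replicates.  The acceptance script runs the headline conditions at
5000 hexamers and five seeds, which puts replicate standard deviations of
$k_s$ near 1-2% of the estimate.  Tag-count distributions are validated to
sum to one within $10^{-9}$; the adaptive horizon for rate prediction uses
the slow eigenvalue of the ADP-count chain $0 \to 1 \to 2$ as an a-priori
scale for $k_s$, which is exact in the limit where every first passage
into the CS state fully randomises a hexamer.

## Known limitations

* The fast-equilibrium coupling randomises the whole CS pool at every
  synchronisation step.  This is the strongest defensible reading of
  "dissociation is fast"; mechanisms in which a CS passage exchanges only
  part of a hexamer's subunits (for example, cuts pinned to ADP positions
  whose arcs persist until the ADP turns over) mix up to about twofold
  more slowly at high $k_e$.  Measured shuffling rates for some constructs
  sit between these two limits, so the absolute $k_s$ scale carries a
  model-structure uncertainty of that order even though all relative
  trends (activity dependence, mode discrimination, monotonicity in
  $k_e$) are robust.  The `cut_rule = "weakened"` option exposes the
  slower variant for sensitivity analysis.
* Phosphorylation chemistry of the CII domain is outside the model;
  full-length constructs enter only through their $(k_h, k_e)$
  re-parameterisation.
* The deconvolution assumes exactly seven ladder peaks; species eluting
  outside the ladder (free oligomers) are not modelled and bias the
  recovered fractions if abundant.
* KaiA/KaiB binding and full clock oscillations are out of scope.
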