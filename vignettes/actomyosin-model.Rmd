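---
title: "The cortexsim model: agents, mechanics, and measurement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The cortexsim model: agents, mechanics, and measurement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

cortexsim simulates a thin patch of cell cortex as a two-dimensional network
of rigid, polar actin filaments remodelled by two-headed myosin motors. The
package exists to study one emergent phenomenon: the self-organisation of a
disordered filament field into *asters* — radial arrays whose plus-ends pack
into a dense core that traps motors — and the conditions that build, block,
or dissolve them.

## The model

**Filaments** are rigid rods of fixed length $L$ (default 1 µm) with a
centre of mass $(x_i, y_i)$ and an orientation $\theta_i$; the plus
(barbed) end sits at $+L/2$ along the orientation vector. Flexibility,
steric interactions and explicit (de)polymerisation are all omitted: at
these lengths an actin filament's persistence length far exceeds $L$, and
polymer kinetics are condensed into a single whole-filament *turnover* rate
$p_2$ — a turned-over filament is deleted and re-inserted at a
uniform-random position and orientation, severing everything bound to it.
Treadmilling is quantifiably negligible at this timestep
(`treadmilling_displacement()`: about $10^{-5}$ µm per 0.01 s step) and is
not applied.

**Motors** are bipolar myosin mini-filaments reduced to a zero-rest-length
Hookean spring (stiffness $k$, default 3 pN/µm) with two independent heads.
A head bound to filament $i$ at signed coordinate $\ell$ sits at

$$a = x_i + \ell\cos\theta_i,\qquad b = y_i + \ell\sin\theta_i,$$

and walks toward the plus-end at constant speed $v$ ($\ell \leftarrow \ell +
v\,dt$). A motor exerts force only when both heads are load-bearing; each
filament then receives $F = k\,(\text{opposite head} - \text{this head})$
at its attachment point. A single length $r$ (default 0.3 µm) bounds both
the binding search and the stretch at which a motor is forced off; the
maximum motor force is therefore $k r = 0.9$ pN. Heads also detach
stochastically at rate $p_0$ and on reaching the plus-end.

**Mechanics.** Motion is overdamped: summed forces are rotated into the
filament frame, and the centre and angle advance against slender-rod drag

$$\Gamma_\perp = \frac{4\pi\eta L}{\ln p + 0.84},\quad
  \Gamma_\parallel = \frac{2\pi\eta L}{\ln p + 0.114},\quad
  \Gamma_{rot} = \frac{\pi\eta L^3/3}{\ln p - 0.662},\qquad p = L/d,$$

with natural logarithms (the end-correction constants are defined for
$\ln$) and torque $\sum_j \ell_j F_{\perp,j}$. The domain is an open regular
hexagon; agents that leave are re-inserted uniformly at random (bound heads
are severed first, so no spring is ever teleported).

**Cross-linkers** are passive two-point springs modelling CH-domain
bundlers: they bind only filament pairs co-oriented within $\pi/8$
(polarity-aware — anti-parallel pairs never qualify) and no more than 40 nm
apart, at the mutually closest points of the closest eligible pair, and
never walk. Motors pass through bound cross-linkers freely.

## The per-step schedule

Each step applies, in fixed order: (1) free-motor diffusion, (2) motor
search/bind, (3) cross-linker search/bind, (4) walking, (5) release checks
(plus-end, stochastic, over-stretch), (6) force accumulation, (7) the
overdamped filament update, (8) turnover, (9) boundary enforcement,
(10) scheduled parameter switches, (11) recording. Force computation
precedes motion within a step; the rest of the ordering is this package's
choice, and it is pinned by an oracle test: on configurations whose event
probabilities are all 0 or 1 a compiled-engine step agrees with an
independent straight-line R implementation (`reference_step()`) to machine
precision.

Randomness comes from R's global RNG, so a `seed` makes whole trajectories
bit-reproducible. Per-step event probabilities are `rate * dt` clipped to 1
(at the standard rates `rate * dt <= 0.1`, within 0.5% of
`1 - exp(-rate*dt)`); a uniform draw is consumed only when the probability
is strictly between 0 and 1, which is what lets deterministic
configurations run draw-free.

## Design choices in the binding rules

Three rules were genuinely open, and the package's defaults were chosen
because they are the readings under which the model's emergent behaviour
(aster formation under turnover, the force phenomenology, the sparse
ensemble statistics) actually reproduces; every alternative remains
available as a configuration switch:

* **Free-motor capture is deterministic on discovery**
  (`deterministic_free_capture`). A diffusing motor that finds a filament
  within its search radius grabs it immediately; only the pair-forming
  second attachment is gated by the attachment rate $p_1$. With fully
  stochastic capture the motor population spends most of its time diffusing
  instead of trafficking along filaments, the search–capture–traffic
  feedback starves, and turnover at the standard $p_2 = 0.7\,/s$ outruns
  polarity sorting: no aster ever forms at any domain size.
* **A searching head binds a uniform-random candidate at its contact
  point** (`binding_site = "random"`). The shortest-distance rule is stated
  only for cross-linkers (which keep it); applying it to motors produces
  near-zero binding extensions everywhere, which collapses both the sparse
  ensemble force (to ~0.03–0.06 pN) and the force ordering between
  disordered and aster states. Random-candidate binding keeps extensions in
  disordered, high-turnover networks broad while aster-core rebinding stays
  slack — reproducing both the ensemble mean and the ordering.
* **The dangling head of a one-bound motor is carried with its walking
  partner** (`free_head_follows`): a zero-rest-length spring is taut, so
  the free head searches around the bound head's position.
* **The free leg of a spatially tethered motor dwells at the plus-end**
  (`tethered_tip_hold`) instead of being shed there, so printed-motor bands
  reel filaments in plus-end first. The supplementary material defining the
  tether mechanics is not available; this reconstruction produces the
  documented motor and plus-end enrichment over the tethered band. Even
  so, a dominant free aster is not out-competed by the band within ~80 s of
  model time — the band first depletes its surroundings (an effect the
  original study also reports) and the free aster then settles at the
  centroid of the remaining mobile network, away from the band. The
  corresponding acceptance check is left failing rather than weakened.

## The domain size

The hexagon's size is the one structural parameter with no published value.
It was calibrated once against the sparse-ensemble statistic (the mean over
100 replicates of the final-step mean motor force, target 0.09 pN ± 36%)
and frozen at a circumradius of 2.2 µm. Two independent observations
support this scale: the calibrated mean (0.067 pN) lies inside the target
band, and at this size — about four filament lengths across — the dense
standard network forms exactly one central aster, as the reference figures
show, whereas at twice the size it fragments into many small asters with an
inter-aster spacing of roughly 2 µm set by the filament length and motor
reach. The free-motor diffusion step (0.05 µm per step, direction
isotropic) is likewise unspecified upstream; it lets a free motor explore
its own 0.3 µm search scale within about a second.

## Measurement

* `divergence_map()` bins filament plus-ends into boxes of side $L/8$, sums
  unit orientation vectors per box, and takes central differences (one-sided
  at the boundary). Aster cores are deeply negative with a positive
  surround. `detect_asters()` Gaussian-smooths the field (σ = 1 box) and
  thresholds at 3 times the field's 2nd-percentile depth — a robust scale a
  deep core cannot inflate — then merges nearby cores and requires the
  positive surround. The $L/8$ box scale is tuned to the default filament
  length; a single aster spanning the whole domain built from 2 µm
  filaments can evade it (visible by eye in rendered frames), so sweeps
  over extreme lengths should adapt `box_size` or the smoothing.
* `render_frame()` emulates additive fluorescence: one count per filament
  per crossed pixel (dominant-axis stepping, so a segment lights
  `max(|dx|,|dy|)/px + 1` pixels), one count per motor. Pixel size defaults
  to 0.05 µm — 20 px per standard filament; the raster resolution of the
  reference images was never stated.
* `roi_mean_intensity()`, `kymograph()` and `coarse_hexagon_segmentation()`
  reproduce the live-imaging toolkit: ROI traces normalised by the frame
  mean, position–time stacks, and the 1.7-fold hexagon highlighting with
  adjacency merging.
* `plus_end_connectedness()` is a *reconstruction*: the quantity it mirrors
  was plotted but never defined upstream. Here it is the fraction of
  plus-ends in the largest single-linkage cluster at a linking radius of
  $2r$.
* `energy_accounting()` tracks the elastic energy
  $\sum \frac{1}{2}k\,\mathrm{ext}^2$ of all connectors and the viscous
  dissipation implied by realized displacements,
  $\sum (\Gamma_\parallel \Delta x_\parallel^2 + \Gamma_\perp
  \Delta x_\perp^2 + \Gamma_{rot}\Delta\theta^2)/dt$; in overdamped
  dynamics the work done by the applied forces leaves as drag loss, so the
  realized-displacement form stands in for the unavailable closed-form
  bookkeeping of the source analysis.

## What the synthetic experiments do and do not show

All inputs are generated by the package itself (`init_random()`,
`init_aligned()`, `init_bar()`, `tether_motors()`, `fix_filaments()`); there
is no external data. The generator's defaults are the study conditions:
50 filaments / 250 motors (sparse) or 1000 / 5000 (dense) for 1000 steps of
0.01 s. Passing tests therefore demonstrate the *model's* internal
phenomenology — polarity sorting, aster emergence and annihilation,
cross-linker interference — not fidelity to any particular cell: real
cortical networks have polydisperse, semiflexible, sterically interacting
filaments, motors with load-dependent kinetics, and signalling-driven
parameter fields, none of which are represented.

Problem sizes used by the test-suite: the replicate ensembles use 100 sparse
runs; phase-diagram claims use 10 dense seeds for the standard cell and 3
seeds per perturbed cell; switch and cross-linker experiments use 3 seeds
with majority readouts; the tethered runs use 3000 steps. These counts are
the package's chosen trade-off between the stochastic-majority statements
made by the claims and ensemble redundancy.

## Known limitations

* Criterion-level: tethered-motor runs do not relocate the dominant aster
  onto the tethered band (see above); the corresponding check fails by
  design rather than being weakened.
* No steric or nematic filament interactions: density can grow without
  bound at an aster core.
* The binding-rule defaults above are reconstructions of an incompletely
  specified kinetic scheme; all are switchable, and the package reports
  which rules a run used via its stored configuration.
* Aster detection is scale-tuned to $L/8$ boxes (see above).
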