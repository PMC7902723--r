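---
title: "Methods: pH-dependent gLV communities under temporal fluctuations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pH-dependent gLV communities under temporal fluctuations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

phglv simulates communities of bacterial strains — modelled on
aerobically culturable nasal isolates (*Staphylococcus* and
*Corynebacterium* species) — whose growth depends on environmental pH and
on each other.  Each strain $i$ follows a generalized Lotka–Volterra
(gLV) equation with continuous dilution:

$$\frac{dS_i}{dt} \;=\; r_i(p)\Bigl[1 - \frac{S_i - \gamma_i}{K_i(p)}\Bigr]S_i - \delta S_i,
\qquad \gamma_i = \sum_{j \ne i} c_{ij}\,S_j .$$

$S_i$ is density in OD units, $r_i(p)$ and $K_i(p)$ are the pH-dependent
growth rate (1/h) and carrying capacity (OD), tabulated on a pH grid
(5.1–7.5 at 0.3 steps) and linearly interpolated, and $\delta$ is the
dilution rate mimicking mucosal turnover.  The interaction coefficient
$c_{ij}$ (effect of $j$ on $i$) is $-1$ on the diagonal (complete niche
overlap), in $(-1, 0)$ for partial overlap, below $-1$ for inhibition
beyond resource competition, and positive for facilitation.

Coefficients are inferred from cell-free supernatant assays: growing $i$
in spent medium of $j$ reaches capacity $K_{ij} = K_i + c_{ij} K_j$, so
$c_{ij} = (K_{ij} - K_i)/K_j$ (`infer_interaction()`, with delta-method
propagation of the capacities' empirical SDs; the propagation method is
this package's choice, as only the SDs themselves are standard).  A pair
with $c_{ij} > 0$, $c_{ji} > 0$ and $c_{ij} c_{ji} > 1$ (strong mutual
facilitation) makes the model diverge; `screen_instability()` flags such
pairs, and the synthetic generator never produces them.  The condition is
implemented as mutual positivity plus product $> 1$ and verified against
a numerical divergence oracle in the test suite.

## Parameters

| name | meaning | default | unit |
|------|---------|---------|------|
| `delta` | dilution rate | 0.1 (quoted range 0.03–0.3) | 1/h |
| `n_c` | strains per initial assemblage | 20 | — |
| `n_s` | assembly instances at full scale | 10000 | — |
| `n_gen` | generations simulated | 100 | — |
| `n_ext` | extinction density | 1e-6 | OD |
| `s0` | initial density per strain | 1e-4 | OD |
| `f_p` | strain-level parameter variation | 0.20 | proportion |
| `ph_range` | characterized pH range | 5.1–7.5 | — |
| `f_ph` | sinusoid frequency | 1 (sweeps use 0.2) | 1/h |
| `dph` | sinusoid amplitude | 0.5 | pH |

Two choices the source leaves open:

* **Generation time.**  Under continuous dilution a surviving population
  must double every $\ln 2/\delta$ hours just to hold its density, so one
  generation is defined as $\ln 2/\delta$ h and `n_gen` generations fix
  the simulated horizon ($\approx 693$ h at $\delta = 0.1$/h).
* **Center pH.**  The sinusoid's center is never printed; we default to
  6.3, the midpoint of the characterized range.  The parameter table's
  $f_{pH} = 1$/h is kept as the configuration default while the sweep
  functions default to the 0.2/h used in the headline figures.

## Synthetic strain panels

The measured nasal strain panel is distributed through an external code
repository rather than in print, so `generate_base_panel()` creates
statistically faithful stand-ins: 6 species; smooth unimodal pH-response
curves (Gaussian bumps with optima inside the grid, clipped to $r \in
[0,1]$/h and $K \in [0.05,1]$ OD — typical plate-reader scales for these
organisms); an interaction matrix with diagonal $-1$, exactly 3 of the 30
off-diagonals positive and small ($\le 0.3$), roughly a fifth of the
negative entries below $-1.2$ (strong inhibition), and no mutual or
cyclic facilitation.  Everything is a deterministic function of the seed.

In silico strains are made by `modulate_strain()`: one multiplier
$u \sim \mathrm{Uniform}(1-f_p,\,1+f_p)$ for the whole $r$ curve and an
independent one for the whole $K$ curve.  Curve-level (not per-grid-point)
multipliers preserve the measured response shape; "up to 20%" is read as
a hard bound, hence uniform rather than Gaussian noise.  Per-point
modulation is available behind a flag.  Strain pairs of the same species
interact at $-1$ before modulation (complete niche overlap between
near-identical strains; the source does not state intra-species
coefficients).

**What a green test establishes.**  The generator matches the
*structure* of the measured panel, not its numbers.  Tests and sweeps on
synthetic panels establish that the pipeline reproduces the qualitative
shapes (amplitude monotonicity, interior frequency maximum, facilitation
effects); they cannot certify measured-panel percentages, which belong to the
experimentally characterized parameters.  The file-input path (`load_panel()`)
accepts an externally obtained measured panel in plain CSV.

## Numerics

Integration uses an adaptive Dormand–Prince 5(4) embedded Runge–Kutta
pair written in C++ (no ODE-solver package is assumed), with mixed
error control (`rel_tol` 1e-7, `abs_tol` 1e-10 by default; halving the
tolerances moves a 5-strain benchmark composition by $<10^{-6}$
Bray–Curtis).  Strains at exactly zero have zero derivative, so
extinction is permanent; undershoots from truncation error are clipped
at zero.  The extinction rule ($S_i <$ `n_ext` $\Rightarrow S_i = 0$) is
applied at generation boundaries, keeping the ODE smooth between
checkpoints.  pH drivers are clamped to the characterized grid range, and
responses are clamped to end values outside it: nothing was measured
beyond the grid.  Telegraph drivers switch between $p_0 \pm \Delta pH$
with exponential holding times of mean $1/f_{pH}$ (the switching law is
unspecified in the source; exponential holding makes the characteristic
frequency comparable to a sinusoid's), with switch times treated as
integration breakpoints.  A sinusoid with $\Delta pH = 0$ takes exactly
the same solver path as a constant driver, so zero-amplitude controls
are exactly zero, not merely small.

## The deviation metric

`fluctuation_response()` simulates a stable community under a fluctuating
driver and under a constant driver at the same center pH for the same
horizon of `n_gen` generations, then reports the Bray–Curtis
dissimilarity between the two cycle-averaged relative-abundance vectors,
averaged over the final fluctuation period ($\min(1/f, \text{horizon})$).
A final-instant variant is available (`metric = "final"`).

The horizon is *never* extended to accommodate slow drivers.  This is
deliberate and load-bearing: within a fixed observation window a very
slow fluctuation barely moves the pH, which is what suppresses the
deviation at the low-frequency end; cycle averaging suppresses it at the
high-frequency end (fast fluctuations average out, and the community sees
the mean pH).  Between the two lies the interior maximum in the frequency
sweep.  Extending the horizon at low $f$ (an alternative we tried and
rejected) flattens the low-frequency end and destroys that shape.

## Analytic limits as oracles

**Slow (quasi-static).**  When fluctuations are much slower than
community dynamics, the community equilibrates to each instantaneous pH:
$[C]\,\bar S = \bar b$ with $b_i = [\delta - r_i(p)]\,K_i(p)/r_i(p)$
(`quasi_static_composition()`).  The raw linear solve ignores both
positivity and stability, so consumers need two refinements, both this
package's design choices:

* a negative component means "this strain leaves the community at this
  pH"; the most negative strain is removed and the reduced system
  re-solved;
* a feasible point can still be a saddle — near-degenerate same-species
  strain twins produce $2\times2$ blocks with $c_{ij}c_{ji} \approx 1$
  and negative determinant — so the Jacobian
  $\mathrm{diag}(S_i r_i/K_i)\,[C]$ is checked and the weakest strain
  dropped until the equilibrium is locally stable.

The approximation's domain of validity is checked, not assumed: tracking
error scales like the ratio of the driver's angular rate $2\pi f$ to the
slowest community relaxation rate $\lambda$ (`relaxation_rate()`, the
least-negative Jacobian eigenvalue).  Requiring error $\lesssim 10^{-2}$
means $\lambda \ge 100 \cdot 2\pi f$.  Near-degenerate strain twins push
$\lambda$ toward zero, taking a community outside the quasi-static domain
at any fixed frequency; the acceptance test therefore draws communities
until 20 satisfy the separation condition, and all of them must track the
oracle within Bray–Curtis 0.01.

**Fast (WKB).**  For rapidly oscillating growth,
$r(t) = r_0 + r_d \sin(2\pi f t)$, the first-order envelope is
$E(t) \propto \exp[-(r_d/2\pi f)\cos(2\pi f t)]$: the log-density
oscillation amplitude falls as $1/f$.  `verify_limits()` checks this with
a single-species reduction whose growth rate is linear in pH (so the pH
sinusoid maps exactly onto the WKB setting) and asserts a log–log slope
of $-1 \pm 0.1$ across two decades.  With dilution the exact linearized
amplitude is $(\delta/r_0)\, r_d/\sqrt{\lambda^2 + \omega^2}$, which has
the same $1/f$ tail; only the slope is asserted.

## Experiment designs

* **Competitive vs cooperative groups.**  Realized strain-level
  facilitation fractions of exactly 0.5 essentially never arise under
  random assembly (same-species pairs are negative), so the groups are
  built by construction, mirroring the prevalence manipulation: matched
  panels with no facilitation versus the same pH responses with
  prevalence raised to 50% (every unordered pair positive in one
  direction — the maximum without mutual facilitation).  Twins share
  assemblage seeds.  Communities must have at least 2 members: the
  facilitation fraction "among members" is undefined for singletons,
  which are trivially unresponsive and would otherwise dilute the
  competitive group.  Medians of the two dissimilarity samples are
  nearly equal (true of the measured-panel comparison as well) and the
  effect lives in the mean/upper tail, so the Mann–Whitney test needs several hundred
  communities per group for power; the acceptance test uses 800.
* **Niche overlap and prevalence sweeps.**  `set_niche_overlap()` sets
  all off-diagonals to a fixed negative value;
  `set_facilitation_prevalence()` raises the positive fraction without
  ever creating mutual facilitation.  Expected shapes: dissimilarity
  rises with overlap until diversity collapses toward richness 1 (where
  near-monocultures become insensitive again); prevalence raises richness
  and lowers dissimilarity.
* **Assembly under fluctuation.**  Matched assemblages (same seeds) are
  enriched under constant versus fluctuating pH;
  `richness_under_fluctuating_assembly()` reports the richness-change
  distribution and tallies of the species most often gained or lost.

## Limitations

Deterministic, well-mixed, phenomenological: no demographic noise, no
spatial structure, no explicit resources or mediators, and the community
does not feed back on pH.  Interaction coefficients are pH-independent by
default (a linear-in-pH extension with slopes is provided).  The gLV form
itself is a first-order abstraction of microbial interactions.  Synthetic
panels reproduce structure, not measured values, so quantitative
statistics (e.g. the fraction of cases under 0.2 dissimilarity) are
panel-dependent.
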