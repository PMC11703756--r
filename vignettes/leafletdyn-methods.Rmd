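---
title: "Methods: flip-flop detection, transport quantification and fate logic in leafletdyn"
author: "leafletdyn maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flip-flop detection, transport quantification and fate logic in leafletdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafletdyn)
```

# The scientific setting

Synthetic cells built from giant unilamellar vesicles (GUVs) can be
"differentiated" by sequentially adding metal-selective ionophores: each
ionophore carries its cognate ion (Ni²⁺, Cu²⁺ or Ca²⁺) across the membrane
and switches on a dormant apo-metalloenzyme inside the vesicle. The order of
additions matters because ionophores embedded in the same bilayer inhibit
each other: the first one acts at full strength, the second only weakly, and
a third has no effect. Mechanistically this cross-inhibition is visible in
the ionophores' membrane dynamics — their interleaflet flip-flop (the
transfer of the molecule from one lipid leaflet to the other, required for
carrier-type transport) is strongly suppressed when an unlike ionophore is
present, and the suppressed molecule is shifted towards the membrane
periphery.

`leafletdyn` packages the complete quantitative chain behind that picture:

1. a **Langevin bilayer-mimetic generator** producing ground-truthed solute
   trajectories and fluorescence/area traces;
2. **trajectory I/O** (GRO, DCD, PDB, and a TSV z-trace dialect);
3. **leaflet dynamics**: hysteresis flip-flop detection, leaflet
   assignment, height distributions (including the intensity-sensitive
   folded representation), orientation profiles;
4. **pair statistics**: radial distribution functions and cutoff
   clustering;
5. **transport quantification**: every fluorescence/area formula used to
   score transport, leakage and lysis;
6. **fate logic**: the pluripotent → multipotent → terminal differentiation
   state machine;
7. a **pipeline** driving all of it from a YAML config.

# The generator model

Atomistic simulation of ionophore flip-flop needs microseconds of bilayer
MD; this package instead ships a phenomenological stand-in whose
*statistics* (not forces) mimic the membrane system, so that every analysis
operation can be exercised against known ground truth.

Each solute moves by overdamped (Euler–Maruyama) Langevin dynamics. Along
the membrane normal it feels a quartic double well

$$U(z) = \Delta E\,\left[(z/z_0)^2 - 1\right]^2,$$

whose minima $\pm z_0$ are the two leaflet resting positions and whose
central barrier $\Delta E$ (kT) sets the flip-flop rate in the Kramers
sense: waiting times grow roughly as $e^{\Delta E}$. Laterally the solute
diffuses in a periodic box. Units are fixed throughout: nm, ns, kT.

Pairs of solutes within lateral range interact through three terms sharing
a lateral weight $w_r(r) = \exp(-r^2/2\sigma_r^2)$ (minimum-image lateral
distance, truncated at $3\sigma_r$):

* a **mid-membrane penalty** $\varepsilon\, w_r(r)\, e^{-z^2/2\sigma_z^2}$
  acting on each partner's own $z$ — when the pair is in contact this adds
  up to $\varepsilon$ kT to the interleaflet barrier, suppressing flip-flop;
* a **peripheral bias**, an outward force $\kappa\, w_r(r)\,\mathrm{sign}(z)$
  pushing paired molecules towards the head groups — the positional shift
  seen for a suppressed ionophore;
* a **lateral attraction** $-\varepsilon\, w_r(r)$, whose gradient drives
  the partners together and produces transient clusters.

The single coupling strength $\varepsilon$ intentionally drives both
clustering and barrier raising: cross-inhibition in the membrane is a
contact effect, so the same parameter that keeps molecules together should
make their passage harder. This is an emulation target, not a claim about
the real ionophore–ionophore potential of mean force, for which no
quantitative model is available.

## Default conditions

* `well_position_z0 = 1` nm, `barrier_height = 8` kT, `box_xy = 6.3` nm —
  two solutes in a 6.3 nm box reproduce the two-dimensional density of
  ~0.05 molecules/nm² of the membrane system being emulated.
* Diffusion coefficients default to 0.1 nm²/ns (both lateral and normal).
  No measured value exists for these solutes; this choice puts flip-flop
  waiting times at a 4 kT barrier in the hundreds of nanoseconds, the same
  order as the slow ionophore's statistics over a 2 µs trajectory.
* `timestep = 0.01` ns and `n_steps = 200000` give a 2 µs run, the length
  of the trajectories the generator stands in for. Construction rejects
  any timestep whose RMS single-step normal displacement exceeds
  $z_0/5$.
* Two static "phosphate" sheets are emitted at ±1.9 nm so that the analysis
  layer's membrane-centre computation (mass-weighted COM of the P
  particles, recomputed every frame) is genuinely exercised rather than
  assumed.
* Interaction experiments in the tests and acceptance checks run at
  $\Delta E = 4$ kT with $\varepsilon = 6$ kT, $\sigma_r = 0.6$ nm,
  $\sigma_z = 0.35$ nm, $\kappa = 2$ kT/nm: the 4 kT barrier gives the
  unpaired control enough events (≈12 per 2 µs) for tight confidence
  intervals, and a 6 kT contact penalty is strong coupling on that scale.

Ground truth (transition times, leaflet occupancy, contact fractions) is
recorded at full step resolution, *before* any frame-stride downsampling,
using exactly the confirmed-transition criterion of the analysis layer — so
`detect_transitions()` run on a full-resolution trace must reproduce it
event for event, which is a standing test.

What the generator does **not** emulate: molecular structure and
orientation (solutes are points; orientation profiling is exercised on
constructed multi-atom fixtures), membrane undulations, solvent, realistic
lipid packing, or any chemistry. Passing tests therefore demonstrate the
correctness of the *analysis* operations and the qualitative phenomenology
(suppression, peripheral shift, clustering), not quantitative agreement
with any atomistic system.

# Flip-flop detection

A molecule is only counted as having flipped when the transfer is complete:
before and after the event its membrane-normal COM position must reach a
species-specific distance $d$ from the membrane centre, once with each
sign. Equivalently: take the subsequence of samples with $|z| \ge d$ and
count sign changes — a confirmed-leaflet automaton with dead zone
$(-d, d)$. Defaults are $d = 0.7$ nm for species A and $d = 0.6$ nm for
species B, close to each molecule's typical resting distance; other species
must be configured explicitly.

Decisions the criterion itself does not fix:

* **Event timestamp** — the first confirming sample in the new leaflet.
* **Stride** — analyses run at stored frame resolution. Downsampling can
  only lose events (a property test); counts at a coarser stride are a
  lower bound.
* **Replica averaging** — the mean of per-replica counts, which may be
  fractional (replicas with 1 and 0 events average to 0.5). Rates are
  per-replica, then averaged, with a warning when observation windows
  differ.

`detect_transitions()` is verified exactly against an independently coded
brute-force oracle on tens of thousands of random traces, and obeys
negation, time-reversal, sub-threshold-insertion and downsampling
invariants.

# Height distributions

Two representations are provided. `full_z` is the plain normalized
histogram of $z$ (default bin width 0.05 nm, edges aligned so 0 is an
edge). The `intensity_sensitive` representation handles
leaflet-asymmetric statistics: find whether the higher histogram peak lies
at positive or negative $z$, keep only samples from that half, and
re-histogram them as a function of $|z|$. Exact peak ties go to the
positive half (the criterion does not specify; the choice is documented and
tested). `same_leaflet` conditioning keeps only frames where molecule and
partner occupy the same leaflet; the instantaneous sign is the default
criterion (a confirmed-leaflet option exists) because the conditioning is
a per-frame statement about co-residence, not about completed transitions.

`histogram_peak(h, refine = TRUE)` refines the mode position below the bin
width by a three-point parabolic interpolation through the maximum bin and
its neighbours. This matters for the peripheral-shift analysis: the
coupling-induced outward shift of the distribution mode is of order
0.05 nm, i.e. about one default bin, and the raw argmax bin centre
quantizes it; the parabolic vertex resolves it stably.

# Pair statistics

The RDF normalizes minimum-image pair-distance histograms by the ideal-gas
expectation with the finite-N correction (eligible ordered pairs, i.e.
$N-1$ partners per reference particle), so a uniform system gives
$g(r) = 1$ — a calibration that is tested directly on Poisson
configurations. Both a `full_3d` metric (default — interleaflet contacts
such as edge-to-edge pairs with one partner in each leaflet have a genuine
z-component) and a `lateral_2d` metric (in-leaflet analyses) are provided,
with leaflet conditioning (`same_leaflet` / `opposite_leaflet`); the
normalization then uses the eligible-pair count after filtering so the
uniform baseline remains 1. `r_max` may not exceed half the smallest box
edge of the chosen metric.

Clustering is cutoff-based: connected components of the graph joining
particles within the cutoff (default 1.0 nm, where ionophore RDFs deviate
strongly from unity), computed with `igraph` and verified against a
hand-coded union-find oracle.

# Transport, leakage and lysis quantification

All formulas operate on per-GUV or per-well intensity series:

* quench transport (Ni²⁺/Cu²⁺ entering a Ca²⁺–Rhod2-loaded GUV):
  $(I_{initial} - I_{final})/I_{mean} \times 100$, with $I_{mean}$ the
  initial mean over all analysed GUVs in the sample;
* relative Ca²⁺ transport: $(I_{final} - I_{initial})$ over the mean
  reference-condition change, which defines 100 %;
* plate-reader series: $(I_{initial} - I_x)/(I_{initial} - I_{min})$
  (quench) and $(I_x - I_{initial})/(I_{max} - I_{initial})$ (gain),
  per timepoint;
* dye retention: $I_t/I_0 \times 100$ at 20/40/60 min, baseline 100 % at
  $t = 0$;
* lysis: median-smoothed area falling below half the initial area and
  staying there; onset is the first such time.

$I_{initial}$ and $I_{final}$ are means over configurable windows
(default 3 samples) rather than single snapshots, purely to reduce noise —
window 1 restores snapshot behaviour. Negative percentages are reported,
not clipped (quench can undershoot under noise); QC flags mark values
outside $[-5, 105]$. All identities are tested to machine precision on
noise-free traces; with 2 % Gaussian noise the quench estimator recovers
known transport fractions with RMSE well under 5 percentage points.

# Fate logic

The state machine encodes sequence-dependent differentiation: the first
ionophore sets the primary fate (A: pH rise via urease; B: H₂O₂ via
galactose oxidase; C: PLA₂ activation and lysis, absorbing), the second
gives the dampened fates A-b, A-c, B-a, B-c, and any third input only locks
the state. Enumerating all six orderings yields exactly five distinct
terminal fates, with both C-first orders collapsing to lysis.

The readout classifier maps end-point sensor values (urease fold, GaoA
fold, leakage, lysis flag) to fate labels with configurable thresholds
(defaults 2×, 2×, 20 %; no numeric cutoffs are published, so the defaults
encode the qualitative contrasts). Because the B-a/B-c readouts genuinely
overlap near the leakage threshold, the classifier keeps an explicit
`unclassified` category instead of forcing calls, and flags the
contradictory combination of a lysis flag with intact-GUV sensor responses.

# Numerical choices and degenerate inputs

* Euler–Maruyama integration; accuracy is validated by the
  stationary-distribution invariant (the sampled z-histogram at
  $\varepsilon = 0$ passes a KS test against $e^{-U(z)}$ using
  decorrelated subsamples, one per 50 ns).
* Interaction truncation at $3\sigma_r$ under the minimum-image
  convention; construction requires the half-box to exceed the truncation
  range.
* z is never wrapped; lateral coordinates are wrapped to the primary box.
* Histogram edge conventions: left-closed bins with the rightmost edge
  closed; 0 is always a bin edge for height histograms.
* Empty selections, missing thresholds, degenerate normalizers, truncated
  files and inconsistent atom counts all raise immediate, named errors —
  nothing loads or computes silently.

# Problem sizes used in the shipped checks

Unit tests run the generator at 50 k steps (0.5 µs); the acceptance-style
checks use 20 replicas of 2 µs runs per condition, 10⁴ random traces for
the detector–oracle equivalence, 400-frame Poisson configurations for RDF
calibration, and 50 GUVs for transport recovery. These sizes give the
comparisons their stated statistical resolution (non-overlapping 95 %
confidence intervals for the suppression contrasts) while keeping a full
run on one CPU in minutes.

# Known limitations

* The generator's interaction model is phenomenological; $\varepsilon$,
  $\sigma_r$, $\sigma_z$, $\kappa$ are emulation dials with no mapping to a
  measured potential of mean force.
* Orientation profiles require multi-atom molecules and are therefore only
  exercised on constructed trajectories, not generator output.
* XTC input is not supported; DCD (plus GRO topology or the JSON sidecar)
  is the binary-trajectory route, and the TSV z-trace dialect is the
  recommended interchange format.
* The readout classifier's thresholds are heuristic by necessity; with
  different enzyme loadings they should be recalibrated via the exposed
  `thresholds` argument.
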