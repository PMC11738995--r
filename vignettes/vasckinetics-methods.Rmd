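---
title: "Models and methods behind vasckinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vasckinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vasckinetics)
```

This vignette documents the statistical models, the synthetic-data
generators, and the numerical and design choices in `vasckinetics`, in the
spirit of a methods supplement: enough detail to judge what the package's
validation does and does not demonstrate.

## The dual-pulse cell-cycle model

### Assumptions

The estimators treat the scored population as an *asynchronous steady-state*
population: every cycling cell progresses at a constant rate around a cycle
of fixed length `T_C` containing one contiguous S-phase window of length
`T_S`, and cycle positions are uniformly distributed across cells at any
instant. A fraction `GF` (the growth fraction) of cells cycles; the rest
never enter S-phase and are KI67-negative. Under these assumptions, for an
analogue-availability window of length `T_i` followed by a short second
pulse:

* cells in S at harvest are double-positive: `E[S]/P = GF · T_S / T_C`;
* cells that left S during the interval are EdU-only:
  `E[L]/P = GF · T_i / T_C`.

Taking ratios removes the unknown `GF · P / T_C`:

* `T_S = T_i / (L/S)`,
* `T_C = T_S / (S / (P·GF))` with `GF = KI67⁺/P`.

Both are ratio estimators; they are exactly scale-invariant in the counts
(multiplying `P, S, L, KI67⁺` by any positive integer changes nothing), and
`T_S` inverts the `L/S` ratio by construction. A subtlety worth recording:
once Eq. 1's `T_S` is substituted into Eq. 2, `S` cancels —
`T_C = T_i · P · GF / L` — so the composed estimate depends on the data
only through `P`, `GF` and `L`. The monotonicity of `T_C` in `S` holds for
Eq. 2 at fixed `T_S`, and that is how the package's tests state it.

### Validity regime and re-entry bias

The derivation requires that no cell exits S-phase and re-enters it within
the experiment, i.e. the gap `T_C − T_S` must exceed the schedule horizon
(the time from first analogue to harvest; 8 h for the default schedule).
When it does not, some cells that would be scored `L` re-enter S while the
second analogue is available and become `S` instead: `L` is deflated and
both `T_S` and `T_C` are inflated. The simulator models this faithfully
with a wrapping (modulo-`T_C`) overlap test and emits a classed warning
(`vasckinetics_warning_reentry_regime`) instead of refusing, because the
biased regime is itself scientifically interesting: the test suite
demonstrates the positive bias on a `T_C = 12 h, T_S = 8 h` population,
where the closed-form expectation under the default schedule gives a
three-fold overestimate.

### The labeling schedule

The default `pulse_schedule()` encodes the experimental design the package
targets: repeated first-analogue injections keeping EdU available over
0–6 h, a BrdU pulse at 6 h, harvest at 8 h, and `T_i = 6 h`. The protocol's
"6 h" is anchored at the *first* EdU injection here; the schedule is fully
configurable (the acceptance script, for instance, uses a proportionally
shortened 2 h + 0.5 h schedule so that fast cycles near 8 h remain in the
valid regime, since with the default schedule a `T_C ≈ 8 h` population
violates `T_C − T_S >` horizon for any plausible `T_S`).

### Division-by-zero policy and the bootstrap

Degenerate counts raise typed errors, never silent `NaN`: `S = 0` (no
double positives), `L = 0` (interval too short or population saturated),
`GF = 0` (no cycling cells) each have a distinct condition class.

`bootstrap_estimates()` resamples *cells* with replacement and recomputes
all three quantities per replicate, reporting percentile 2.5/97.5
intervals. Because the estimators see the data only through the counts of
the eight `(EdU, BrdU, KI67)` flag combinations, the resample is drawn as a
single multinomial over those strata — distributionally identical to
resampling rows, order-independent, and `O(n_boot)` rather than
`O(n_boot · n)`. Replicates with `S = 0`, `L = 0` or no KI67⁺ cells are
recorded as failed; more than 20% failures aborts with advice to score
more cells. A per-embryo (block) resampling scheme would be the natural
extension when section-level provenance is available; the cell-level
bootstrap is the package's default and its coverage is checked by
simulation (95% intervals cover the generating `T_C` in ≥ 90 of 100
independent 20,000-cell simulations).

## The cycling-population simulator

`simulate_pulse_labeling()` draws, per cell, a Bernoulli(`GF`) cycling flag
and a uniform cycle position at `t = 0`, then marks each analogue positive
iff the cell's S window — the half-open interval `[s_phase_start,
s_phase_start + T_S)` of cycle position, wrapped modulo `T_C` — intersects
the analogue's availability window. A cell entering S exactly at harvest
counts as labeled (it is in S at harvest). The S-window position within the
cycle is a free parameter because the steady-state assumption makes all
counts independent of it; the default centers S in the cycle, and the test
suite verifies the invariance empirically across positions.

What the simulator deliberately does **not** model: analogue
pharmacokinetics (availability windows are sharp), detection noise or
partial-nucleus staining (flags are exact), cell death, division-coupled
label dilution, and growth-fraction changes over the experiment. Passing
recovery tests therefore demonstrates correctness of the *estimators under
their own assumptions*, not robustness to biological or staining artifacts.
A `KI67` mis-scoring rate could be layered on top by flipping flags in the
returned cell table; the estimators themselves are agnostic to how the
table was produced.

## The vessel-scene generator

`generate_vessel_scene()` builds a voxel volume (default 50 × 180 × 180
voxels at 2 × 0.5 × 0.5 µm, i.e. 100 × 90 × 90 µm — the anisotropy matches
a typical confocal/light-sheet z-step) containing an analytic straight
tube (default radius 14 µm) and spherical nuclei (radius 3 µm) each with a
spherical Golgi (radius 1.5 µm) whose centroid is offset 6 µm in the x–y
plane along a direction drawn from von Mises(`mu_deg`, `kappa`). Angles
live on the body-axis compass: 0° = +y ("dorsal"), 90° = +x ("lateral").

Placement is rejection sampling with three constraints, each named in the
error on failure: both spheres inside the volume; the nucleus centroid
within the tube (inside cells) or clearly outside it (outside cells), with
a one-voxel safety band so that voxel-lookup classification reproduces the
generated compartments exactly; and a minimum nucleus separation of
`2·(golgi_offset + golgi_radius) + 2 µm`, which guarantees that every
Golgi is strictly nearer (border-to-border) to its own nucleus than to any
other — making the ground-truth pairing the unique nearest-neighbor
solution, so the pairing stage can be tested for exact recovery. The
default cell counts (5 inside, 9 outside) keep placement reliable in the
default volume; larger scenes scale all three dials together.

Spheres are rasterized by a voxel-center distance test in physical µm, so
anisotropic spacing is respected everywhere. Discretization moves a
rasterized centroid by at most half a voxel, which bounds the angle error
of the round-trip at `atan(spacing_xy / golgi_offset)` (≈ 4.8° at
defaults); the observed errors are well inside that. No point-spread
function, noise, or intensity model is simulated — inputs to the real
pipeline are label masks by contract, so photorealism would add nothing to
what the tests can show.

### von Mises sampling

No circular-statistics distribution was available among the package's
dependencies, so the sampler implements the Best–Fisher (1979)
wrapped-Cauchy rejection algorithm directly, with two exact limits:
`kappa = 0` falls through to uniform sampling, and `kappa ≥ 1e6`
(including `Inf`) is treated as a point mass at `mu`. The sampler is
validated against a naive accept–reject oracle (uniform proposals accepted
with probability `exp(κ(cos(θ−µ)−1))`) on mean direction, resultant
length and quartiles.

## The polarity pipeline

`extract_geometry()` computes per-label centroids as unweighted means of
voxel centers (voxel `(i)` center at `(i − 0.5) · spacing`) and boundaries
as foreground voxels with a background 6-neighbor (volume-edge voxels
included). `pair_nuclei_golgi()` computes all nucleus × Golgi minimum
border-to-border distances in 3D µm and resolves conflicts greedily by
ascending distance; the exhaustive-search `"optimal"` assignment (total
distance minimized) is available for small scenes and agrees with greedy on
well-separated ones. Excluded pairs (> 5 µm by default) are *not*
re-matched to the next-nearest Golgi: the exclusion marks the pair as
unreliable, and silently re-pairing would bias the retained angles.

`compute_polarity_angles()` implements θ = arccos(A·B) on the x–y
projection and resolves the sign ambiguity of the inverse cosine with the
2D cross product of the reference axis B and the pair vector A: the
rose diagram spans 360°, so a signed convention is implied, and the
package takes "lateral" as the −90° rotation of dorsal in a right-handed
x–y frame (i.e. +x when dorsal is +y), configurable by supplying a
different reference axis (for the contralateral body side, negate the
x-component convention by reflecting the reference frame). Equivalence
with a rotation-matrix-plus-`atan2` formulation holds to 10⁻⁹ degrees, and
angles are equivariant under joint in-plane rotation of the scene and
reference to 10⁻⁶ degrees.

`summarize_angles()` uses right-open equal-width bins (so 360k/n falls in
bin k+1, never out of range), the circular mean via `atan2` of the mean
resultant vector, and the Rayleigh uniformity test with the standard
series approximation `p = exp(−nR²)(1 + (2nR² − (nR²)²)/(4n))`, clamped to
[0, 1]. The approximation is accurate for the n in the hundreds–thousands
this pipeline sees; for small samples a Monte Carlo null (resampling R
under uniformity) is available and agrees with the approximation where
both apply. Calibration is checked at scale: at `kappa = 0`, the 5%-level
test rejects in ≤ 10 of 100 seeded 2,000-cell replicates; at `kappa = 2`
it rejects in ≥ 99 with circular means within 5° of the generating
direction.

## Morphometry

`classify_compartment()` operationalizes "inside the vessel" as
centroid-in-mask, with an optional distance tolerance: a cell whose
centroid lies within `tolerance_um` of the nearest vessel voxel center
(anisotropic µm) also counts as inside — equivalently, signed surface
distance ≤ tolerance with interior negative. The tolerance default is 0
because the segmentation-software cutoff the readout emulates is not a
fixed community standard; it is an explicit parameter. For points outside
the mask, the nearest foreground voxel center is always a 6-connected
boundary voxel, so distances are computed against the (much smaller)
boundary set; equality with an all-voxel brute-force search is asserted in
the tests. Out-of-bounds centroids are `"unassigned"` and reported
separately — never folded into either compartment.

`fold_change()` reports the ratio of stage means (never the mean of
per-replicate ratios, which is biased for small counts) with the replicate
standard deviations propagated by the delta method. Fold changes compose
exactly across stages. `compare_groups()` is a thin wrapper over
`stats::t.test` (Student, unpaired, two-tailed) and `stats::aov`, with the
zero-variance degeneracies made explicit (equal means → t = 0, p = 1;
different means → t = ±∞, p capped at the smallest positive double)
because image-derived counts occasionally produce them.

## Determinism and problem sizes

Every stochastic operation takes one integer seed and scopes it (the
caller's RNG stream is saved and restored), so fixed inputs give identical
outputs; `run_pipeline()` derives per-stage seeds from one master seed and
stamps its JSON report with a configuration hash, and re-running a
configuration reproduces the report byte-for-byte. Floating-point
comparisons in the tests use the tolerances stated above (10⁻⁹/10⁻⁶ for
the angle oracles).

The validation suites use 50,000-cell populations for single-point
estimator recovery (sampling error of `T_C` ≈ 1%, comfortably inside the
5% recovery criterion), 20,000 cells × 100 simulations for bootstrap
coverage, 2,000 angles × 100 replicates for Rayleigh calibration, and
8–14-cell scenes for the voxel-level round trips, where exactness rather
than sampling error is what is being tested. These sizes are the package's
validation design: large enough that Monte-Carlo noise cannot mask an
estimator defect at the stated tolerances, small enough to run routinely.

## Known limitations

* The cell-cycle model assumes steady-state exponential-phase kinetics;
  populations with synchronized or stage-dependent cycles violate the
  uniform-phase assumption in ways the simulator does not emulate.
* Pairing is nearest-neighbor-based; in dense tissue where a Golgi sits
  between two nuclei closer than the exclusion threshold, the greedy
  policy's choice is reasonable but not ground truth.
* The distance used for classification is to vessel *voxel centers*, so
  sub-voxel surface geometry is quantized at the voxel scale; tolerance
  semantics inherit that quantization (the dilation-consistency test
  quantifies it).
* The vessel model is a straight tube; curvature, branching and lumen
  irregularity affect only the synthetic scenes, not the classification
  code, but recovery tests say nothing about segmentation quality of real
  vessels.
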