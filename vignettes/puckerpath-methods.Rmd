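---
title: "Models and methods behind puckerpath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind puckerpath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`puckerpath` re-creates, at desk scale, the analysis chain used to
characterise a polysaccharide-lyase β-elimination mechanism: ring-puckering
coordinates and conformer assignment, reaction collective variables,
well-tempered metadynamics and umbrella sampling on model landscapes, WHAM,
and minimum free-energy-path analysis. This vignette documents the models,
their assumptions, the tunable parameters, and the design decisions taken
where several constructions were possible.

## Ring puckering

**Construction.** For a six-membered ring the Cremer–Pople description places
the origin at the geometric centre, defines the mean plane through the two
fixed trigonometric position sums `R' = Σ r_j sin(2πj/6)` and
`R'' = Σ r_j cos(2πj/6)` (normal `n = R'×R''/|·|`), and decomposes the
out-of-plane displacements `z_j = r_j·n` into the m = 2 mode (amplitude `q2`,
phase `φ2`) and the m = 3 mode (`q3`). We report `Q = √(q2²+q3²)` in Å and
the spherical angles `θ = atan2(q2, q3)` and `φ = φ2` in degrees; the result
is invariant under rigid motion of the input by construction.

**Conventions.** Ring atoms are taken cyclically as O5, C1, C2, C3, C4, C5
with O5 as atom 1; `reorder_ring()` restores this order from arbitrary input.
Under this convention `4C1` maps to θ = 0 and `1C4` to θ = 180°. The φ origin
follows the same Fourier convention as the displacement formula; published
Mercator plots differ between laboratories by a phase in φ, so the packaged
conformer table is the single authority for positions in this package, and no
attempt is made to match any specific figure's φ origin.

**Amplitude floor.** Below `Q = 0.05 Å` the angles are noise-dominated and
`cremer_pople()` raises a planar-ring error rather than returning meaningless
angles.

**Canonical table.** The 38 canonical conformers (2 chairs, 6 boats, 6
skew-boats, 12 envelopes, 12 half-chairs) are *generated*, not transcribed:
each conformer is written as its ideal displacement pattern (which atoms lie
above/below the plane) and projected through the same Fourier formulas,
yielding the class latitudes 0, 50.8, 54.7, 90, 125.3, 129.2 and 180 degrees
and the standard 30°-spaced meridians. A plain-text copy ships in
`inst/extdata/` and a test asserts generator/file agreement. Classification
is nearest-neighbour by great-circle distance with ties broken by table
order.

**Product pathway.** The unsaturated product of a lyase keeps C3–C4–C5–O5
coplanar; the compatible canonical conformers lie on
`θ = 90 + 39·cos(φ − 270°)`. `distance_to_pl_path()` minimises the
great-circle distance to this curve numerically (coarse grid then a
squared-distance Brent refinement, which is smooth at an on-curve minimum
where the plain distance has a |·| kink). All eight listed product conformers
fall within 3° of the curve under the packaged table, which is verified in
the tests.

## Collective variables

`CV1 = d1 − d2` and `CV2 = d2 − d3 + d4` with `d1 = d(H5–C5)`,
`d2 = d(H5–N)`, `d3 = d(H5–O4)` and `d4 = d(C4–O4)`, all in Å. Distances are
computed without periodic wrapping — these are intramolecular, active-site
distances and the fixtures carry no box metadata. Angular pucker CVs are
handled in radians internally (hill widths for them are quoted in radians)
and serialised in degrees in report tables.

## The Langevin surrogate sampler

QM/MM force evaluation is out of scope; sampling runs on analytic model
potentials over CV space (kcal/mol). The integrator is BAOAB with
`kB = 0.0019872041 kcal/(mol·K)`, default `T = 300 K`, `dt = 1 fs` and
friction `1 ps⁻¹`; mass is expressed in `kcal·mol⁻¹·ps²` per squared CV unit
with default 1, which puts well oscillation periods near 0.1–1 ps, far above
the time step. Runs are bitwise reproducible for a fixed seed (the C++ core
draws from R's RNG). Where a task needs fast configurational decorrelation
rather than realistic inertia — umbrella-window sampling, long recovery
runs — a higher friction (5–10 ps⁻¹, overdamped) is passed explicitly; the
relevant tests state their settings.

## Well-tempered metadynamics

The "well-tempered parameter" is carried in energy units (ΔT, kcal/mol)
because that is how hill schedules quote it; the equivalent bias factor
`γ = (T + ΔT/kB)/T` is reported in logs. Hills of height
`h0·exp(−V_bias/ΔT)` are deposited every `stride` steps (default 100). Two
bias bookkeeping modes exist: exact summation over all hills (default for
short runs, and always used by `bias_energy()` and the FES reconstruction)
and a gridded accumulator with multilinear interpolation (spacing σ/4) that
makes the per-step cost independent of the hill count; the two agree to
within interpolation error and a test asserts early-trajectory agreement.

The free energy is estimated as `F(s) = −(T+ΔT)/ΔT · V_bias(s)` anchored to
zero. With the large bias factors used here the bias oscillates as the
walker shuttles between basins; `reconstruct_fes(average_fraction = a)`
therefore averages the estimate over *every* intermediate hill count in the
final fraction `a` of the deposition (a closed-form weighted sum over
hills), which suppresses both the deposition ripple and the basin-to-basin
oscillation.

Hill bookkeeping (`n_hills × stride × dt`) is logged for every run; with
the conformational schedule (854 hills, stride 100, 1 fs) this reproduces
85.4 ps exactly. The reaction schedule's published hill count corresponds to
its quoted total time only for a sub-femtosecond time step, so the engine
always reports its own explicit dt alongside the identity.

## Surrogate landscapes

The generators define the study conditions; their stationary points are the
published MC/TS/IC/PC layout and are **exact by construction**:

- **Reaction landscape** (2D over CV1, CV2): a valley-tube potential
  `V = P − (P − f(s))·exp(−d⊥²/2σ⊥²)` where `s, d⊥` are the arclength and
  perpendicular distance to a smooth spline path through MC (−1.0, 1.1),
  TS (0.7, 0.3), IC (1.8, 1.7) and PC (1.8, 3.4), and `f` is a
  piecewise-cosine profile with values 0, 19, −1, −5 kcal/mol at those
  anchors plus a 0.5 kcal/mol knot between IC and PC that makes the
  intermediate a genuine basin (1.5 kcal/mol escape barrier toward the
  product). Because every profile knot has zero slope and sits on the path,
  each anchor is an exact stationary point with the correct Hessian
  signature. An earlier design from sums of ≤8 anisotropic Gaussians was
  abandoned: with the TS far off the straight MC–IC corridor, Gaussian
  wells-plus-channels either created spurious passes or left the saddle
  ~0.2 Å from its target under every calibration scheme tried; the tube
  construction needs no calibration at all. The plateau is 45 kcal/mol —
  off-pathway CV space around an enzyme active site is effectively
  inaccessible, and a high plateau keeps the metadynamics walker shuttling
  inside the valley instead of diffusing over irrelevant territory —
  with quadratic walls bounding the box. σ⊥ = 0.35 Å sets the valley width
  (well resolved by 0.15 Å hills). The gradient is analytic; the projection
  onto the discretised path (321 points) makes it exact except on the
  measure-zero medial set of the polyline, and a finite-difference audit of
  positions, energies, gradients and Hessian signatures runs every time the
  landscape is built.
- **Umbrella profile** (1D over CV1): a piecewise-cosine profile with a
  reactant minimum at −0.75 Å (F = 0), the barrier maximum at 0.7 Å with
  F = 17.7 kcal/mol (the refined activation free energy) and a product
  minimum at 1.9 Å with F = −5.
- **Conformational landscape** (2D over φ, θ in radians, φ periodic): three
  Gaussian wells on a 5 kcal/mol plateau — a polar trench along θ = π
  (the 1C4 pole is a single physical state, so a φ-degenerate trench is the
  correct chart representation), the 5S1 well at (π/2, π/2) 0.5 kcal/mol
  above it and the OS2 well at (11π/6, π/2) 2.0 kcal/mol above it. The wells
  are far apart, so a three-iteration tail compensation fixes the depths
  exactly; walls confine θ to [1.0, π].

**What the generators emulate and what they do not.** They reproduce the
*layout* of the published landscapes — positions and energies of stationary
points, basin topology, CV definitions, stage-anchored bond distances
(C5–C6: 1.54 → 1.45 → 1.54 Å; C4–C5: 1.50 → 1.37 Å interpolated by monotone
cubics with 0.01 Å noise) — not the microscopic physics: there is no
electronic structure, no protein environment, no coupling between pucker and
reaction coordinates, and the valley shape between anchors is a smooth
invention. Passing recovery tests therefore demonstrates that the *analysis
machinery* (sampling, bias bookkeeping, reconstruction, path extraction,
WHAM) is correct and internally consistent, not that the chemistry of any
real enzyme has been re-derived.

## Umbrella sampling and WHAM

Windows follow the nine-window protocol (−0.75 → 1.25 Å, step 0.25 Å) with
the first third of each run discarded, mirroring a 7.5 ps window of which
the last 5 ps are kept. The default force constant follows the design rule
`k = kBT/(spacing/2)²`; for the steep 17.7 kcal/mol profile the recovery
study uses `k = 200 kcal/mol/Å²` — on a flank with |dF/ds| ≈ 19 kcal/mol/Å a
soft spring lets window means slide ~0.5 Å apart and adjacent histograms
lose contact, while 200 keeps the worst-case mean gap within ~5 biased
standard deviations — together with friction 10 ps⁻¹ for fast decorrelation
and 250 000 steps per window. WHAM uses 201 bins over the pooled sample
range, direct iteration to 1e−8 kcal/mol on the window constants (cap 1e5
iterations), an adjacent-overlap floor of 1e−4 (violations name the gap),
and is gauge-invariant in the initial constants. The barrier is read from
the PMF after excluding sparsely-populated bins (≥200 counts) and averaging
over a ±6-bin neighbourhood: `−kT·log` of a small histogram mass is biased
upward, so raw extrema over 201 noisy bins would systematically overestimate
a barrier. Error bars, when needed, come from `window_block_se()` (simple
block standard errors); autocorrelation-corrected estimators are out of
scope.

## Free-energy-surface analysis

Minima are grid-local strict minima filtered by persistence: the depth of a
minimum relative to the level at which its basin merges into a deeper one,
computed by a union-find sweep in ascending energy order. The MFEP is the
minimax (lowest-maximum) path on the 8-connected grid graph — the bottleneck
level from the same union-find sweep, then a deterministic Dijkstra
(cumulative energy, ties by cell index) inside the sublevel set — followed by
steepest-descent smoothing of the two legs from the saddle; the saddle is
the path maximum. The minimax level is invariant under monotone transforms
of F and is tested against exhaustive path enumeration on 5×5 grids.
Intermediates along a path are contiguous segments whose minimum lies at
least 0.5 kcal/mol (configurable) below both flanking path maxima — the
published "flat region" carries no quantitative threshold, so this value is
a documented choice, not an inference. Default grids are 101×101 over the
sampled range; sub-cell agreement with two-decimal published coordinates is
not claimed, and a test verifies that doubling the grid changes extracted
barriers by < 0.2 kcal/mol on the smooth surrogate.

## Recovery studies

Run lengths are convergence-based choices for the surrogates (which differ
from the real system in depth, area and diffusivity), made by watching the
estimator variance across seeds: the reaction study deposits 20 000 hills
per seed (schedule 0.15 Å × 0.15 Å × 1.0 kcal/mol, ΔT = 30) and averages
the FES over the final 60% before MFEP extraction, three seeds; the
conformational study deposits 60 000 hills (0.1 rad × 0.1 rad × 0.5
kcal/mol, ΔT = 15), averages over the final 80%, five seeds, and reads the
1C4 reference as the φ-average along the polar trench (a single physical
state) and the well values as small-disc averages at the canonical
positions; the umbrella study is described above. The remaining systematic
effects — minimax paths preferentially crossing noise dips, slow
trench-to-well equilibration — are visible in the per-seed spreads returned
by the `recover_*()` functions.

## Numerical conventions and edge cases

Energies kcal/mol, distances Å, puckering angles degrees in all tables and
files, radians internally for angular CVs; frame numbering is 1-based.
Writers emit `%.17g` so read–write round trips preserve values exactly.
Degenerate rings (coincident or collinear atoms) and planar rings raise
errors; empty hill logs, ragged rows and missing atoms are reported with
line/frame context; overlapping basin definitions and non-overlapping
windows are rejected rather than silently accepted. Tie-breaks everywhere
(classification, Dijkstra, `which.min`) are first-index deterministic.

## Known limitations

No real force fields or QM engines; no multiple walkers or
transition-tempered variants; no MBAR or 2D WHAM; no committor analysis or
continuous-space string methods; rings of size ≠ 6 and furanose nomenclature
are out of scope. The tube potential's gradient has measure-zero kinks on
the medial set of its discretised path (invisible to the samplers but worth
knowing when differentiating it elsewhere). The conformational surrogate's
trench-versus-well free-energy differences converge slowly under
metadynamics — the dominant uncertainty in the conformational recovery — and
the per-seed spreads quantify it.
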