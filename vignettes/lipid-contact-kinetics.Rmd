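---
title: "Methods: dual-cutoff lipid contact kinetics and domain dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-cutoff lipid contact kinetics and domain dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidkin)
```

This vignette is the package's own account of the science it implements: the
models, their assumptions, the tunable parameters and why their defaults are
what they are, what the synthetic generators do and do not emulate, and the
numerical decisions a maintainer would want written down.

## The contact model

A lipid "contact" is not a well-defined physical object: any single distance
cutoff turns thermal rattling at the boundary into a stream of spurious
on/off events, which wrecks duration statistics. The standard remedy — used
by lipid-interaction fingerprinting tools for coarse-grained GPCR
simulations — is a *dual cutoff* with hysteresis:

* a contact is **initiated** when the minimum distance between any selected
  headgroup particle of a lipid and the target drops strictly below `d_on`;
* it **persists** while that distance stays at or below `d_off`;
* it **ends** at the first frame the distance exceeds `d_off`; the event's
  last frame is the preceding one.

Defaults are resolution presets: `d_on = 0.55`, `d_off = 1.0` nm for
coarse-grained beads and `0.35 / 0.55` nm for atomistic contacts. These are
the conventional values for MARTINI-scale beads and heavy-atom contacts
respectively; both are exposed in `contact_spec()` and can be overridden.
Distances use the minimum-image convention on orthorhombic boxes only —
triclinic input is rejected rather than silently mishandled, since the
membrane-patch systems this targets are cuboid (15 × 15 × 17 nm³ is the
default synthetic box).

The "target" is a grouping choice, exposed as a parameter rather than fixed:
per **residue** (distance = minimum over the residue's particles), per
user-declared **site** (a named set of residues), or the **whole protein**.
The protein surface means *all* particles of the protein selection by
default; users wanting backbone-only contact definitions can restrict the
selection.

**Event accounting.** Durations count inclusive frames times the frame
spacing: a contact visible for a single frame has duration `dt`, not zero.
Events still active at the trajectory end (or already active in frame 0) are
closed at the boundary and flagged `censored`. They are *included* in
occupancy and in survival curves: dropping them would systematically bias the
long-residence tail downward, which is exactly the part of the distribution
the analysis cares about. The flag is carried so users can study sensitivity.

## From durations to k_off

Pooled durations (across lipids, and across replicates when a config lists
several trajectories) give the empirical survival function
`σ(t) = mean(duration ≥ t)` on a uniform grid from 0 to `max_lag`
(default: the maximum observed duration, 200 points). The fitted model is the
bi-exponential

σ̂(t) = A·exp(−k_fast·t) + (1 − A)·exp(−k_slow·t)

with `A ∈ [0, 1]` and `k_fast ≥ k_slow > 0`. `k_off` is defined as the slow
rate and the residence time as `1/k_off`: the fast component absorbs
cutoff-boundary rattling and brief encounters, while the slow component
describes the stable bound state. A mono-exponential never fits real contact
data well precisely because those two populations coexist.

One ambiguity is worth recording: descriptions of this procedure in the
literature ("curve fitting of interaction durations as a function of time")
do not distinguish between fitting the duration *survival function* and
fitting a normalized interaction *time-correlation function*. This package
fits the survival function — it is the direct empirical object, requires no
windowing choices, and belongs to the same functional family either way. The
choice is a package definition, not a claim about any particular historical
implementation.

**Numerics.** The constraints are built into the parameterization
(`A = plogis(a)`, `k_slow = exp(b)`, `k_fast = k_slow·(1 + exp(c))`), so the
optimizer is unconstrained: Nelder-Mead from `A = 0.8`,
`k_fast = 10/mean(duration)`, `k_slow = 1/mean(duration)`, followed by a BFGS
polish. Two degenerate regimes are handled explicitly:

* if the fitted slow amplitude `1 − A` falls below 0.01, `k_slow` is
  unidentified (the decay is carried entirely by the "fast" term); the fast
  rate is then reported as `k_off`;
* if the optimizer fails, a mono-exponential fallback (log-linear regression
  on `σ > 0`) is reported with `converged = FALSE` — never an exception,
  because per-residue profiling must survive residues with pathological
  event sets. Residues with fewer than 10 events skip fitting entirely and
  report their mean duration, flagged `fitted = FALSE`.

## Occupancy and lateral RDF

Site occupancy counts headgroup *particles* (not molecules) within the site
cutoff per frame, matching the "maximal number of headgroup atoms within
6 Å" convention of normalized occupancy plots; the default cutoff is
0.6 nm in both resolutions. Normalization is `raw / max(raw)` with all-zero
series left at zero — it is scale-free (duplicating frames changes nothing).

The radial distribution of a lipid species around the protein is computed
*laterally* (xy only, distance from the per-frame center of geometry of the
reference selection), because lipids live in a quasi-2D leaflet: a 3D RDF
would convolve in-plane enrichment with bilayer geometry. Counts are
normalized by annulus area `2πr·Δr`, frame count, and the species' mean
lateral number density, so a uniform species gives `g ≈ 1` at large r. No
published normalization exists for the result this mirrors; the
flat-at-uniform contract is this package's definition. Leaflets are
separated by an explicit z-window (`z_range`), never guessed from lipid
orientation, since an extracellular ganglioside and an intracellular
phosphoinositide must not be pooled.

## Domain geometry

The inter-domain angle is the angle between *oriented* plane normals: each
domain's plane is spanned by an ordered residue triplet `(P1, P2, P3)`
(backbone bead or Cα, per resolution), with normal
`(P2−P1) × (P3−P1)` normalized, and the angle is
`acos(clamp(n₁·n₂))` in degrees on the full [0, 180]° range. Folding to
[0, 90]° would be wrong here: reported receptor hinge angles exceed 120°,
which is only meaningful with oriented normals, and orientation is pinned by
the order in which the residues are listed. Reversing one triplet maps
θ → 180° − θ; that ambiguity is inherent to the convention and documented
rather than hidden — absolute angles from other implementations may differ by
exactly this reflection. Collinear triplets (cross-product norm < 1e-9 nm²)
exclude the frame with a warning instead of poisoning the series.

Superposition is the closed-form least-squares fit (SVD with a determinant
correction so only proper rotations are returned). Domain RMSD superposes
every frame on frame 0 using the fit selection (e.g. the transmembrane
domain) and measures RMSD over a different selection (e.g. the extracellular
domain, residues 27–132 in the canonical receptor usage) — the fit removes
rigid-body motion so the RMSD isolates inter-domain rearrangement.

PCA operates on the fitted coordinates of the analysis selection, flattened
to 3N vectors: eigen-decomposition of their covariance about the time mean,
implemented through SVD of the centered data matrix for stability (this also
makes the eigenvalue-sum-equals-total-variance identity exact to floating
point). The reference is frame 0 of each replicate, and PCA is per-replicate
by default, because first-eigenvalue fractions are reported per replicate
(they vary widely — tens of percent — between replicates, and pooling hides
that). The warning threshold `n_frames > 3 × particles` flags
rank-deficient covariances.

## The synthetic generators: what a green test establishes

`make_binding_trajectory()` encodes precisely the statistical structure the
kinetics analysis assumes, and nothing else:

* binding is a discrete-time Markov chain with *exact* exponential step
  probabilities (`1 − exp(−k·dt)`), so dwell times are geometric with mean
  `dt / (1 − exp(−k_off·dt))` — within `k_off·dt ≤ 0.2` (enforced) this
  matches the continuous `1/k_off` to a few percent and keeps recovery tests
  unbiased at finite `dt`;
* bound headgroups are placed < 0.45 nm from their site's residues, unbound
  ones ≥ 1.2 nm from every protein bead — strictly inside/outside the
  0.55/1.0 nm band, so dual-cutoff detection must recover the chain's state
  *frame-for-frame*, and a lipid released in one step sits out at least one
  frame before rebinding so truth intervals can never merge;
* one lipid binds one site at a time; unbound lipids perform a reflected 2D
  random walk at fixed z. Steps that would enter the protein exclusion disk
  are rejected (the walker stays put), which leaves the uniform distribution
  on the accessible leaflet exactly invariant — the property the
  RDF-flatness test relies on. The default step (1.5 nm per frame) is
  deliberately unphysical: it is chosen so the walk decorrelates within tens
  of frames, because the generator's job is statistical, not dynamical.

What a green test therefore establishes: the detection automaton, the
survival/fit machinery, occupancy, and the RDF normalization are correct
*given their own model assumptions*. What it does not establish: anything
about force fields, membrane undulations, leaflet asymmetry, lipid shape
(headgroups here are single beads), multi-site competition, or non-Markovian
binding — real trajectories violate all of these to some degree, and the
package makes no claim that the bi-exponential is the true duration law of
any particular system.

`make_hinge_trajectory()` inverts the angle measurement by construction:
domain B is pre-aligned so its triplet normal coincides with domain A's, then
rigidly rotated per frame about a fixed axis perpendicular to that normal —
so the measured angle equals the prescribed series to machine precision, on
the closed interval [0, 180]°, including both degenerate endpoints.

## Configuration and reporting choices

The run configuration is one JSON file (read with `jsonlite`); JSON was
chosen over YAML because it is equally human-readable at this schema size and
requires no additional parser. CLI flags override config values. Replicates
are first-class: durations pool across the trajectory list by default (the
convention for multi-replicate fingerprinting), with per-replicate fits
available for convergence diagnostics. The manifest records inputs,
parameters, package version and seed even for deterministic runs, and reruns
are bit-identical.

Trajectory formats: GRO and multi-MODEL PDB (text) and DCD (binary) are read
and written natively. XTC and TRR are declined with a structured error — XTC
compression would require the xdrfile algorithm, and no reader is available
in the dependency-free environment this package targets; converting to DCD
is lossless at float32 precision. Angle summaries report the plain
(circular-naive) mean ± SD on [0, 180]°, matching how such distributions are
conventionally quoted; for strongly bimodal series the full per-frame CSV is
the authoritative output.

## Known limitations

* No neighbor-list acceleration: distances are exact minimum-image over all
  selected pairs, vectorized per lipid. Fine up to ~10⁴ frames × ~10² lipids
  × ~10² targets; beyond that, expect minutes.
* Event attribution is per (lipid, target) pair; a lipid simultaneously
  within `d_on` of two residues yields two independent events, and no
  clustering of residues into data-driven sites is attempted (sites are
  user-declared).
* Occupancy counts particles; molecule-level occupancy must be emulated by
  selecting one particle per molecule.
* The left-censoring flag treats frame-0 contacts as censored; with very
  short trajectories this can mark a substantial fraction of events.
* PCA extreme conformations are linear extrapolations along component 1;
  they are visual aids, not physical conformations.
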