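# lipidkin

Lipid–protein contact kinetics and domain dynamics from membrane molecular
dynamics trajectories, in R.

Membrane proteins — G-protein-coupled receptors in particular — are
surrounded by a shell of lipids whose headgroups bind and unbind at specific
sites on the protein surface. Quantifying those interactions from MD
trajectories (coarse-grained or atomistic) is a standard fingerprinting task:
which residues does a species such as a ganglioside (GM3) or PIP₂ contact,
for how long, and with what dissociation rate? `lipidkin` implements the
full analysis chain for this, plus the companion geometry analyses used to
relate lipid binding to large-scale domain motion (e.g. the extracellular
domain of a class B1 receptor swinging about its hinge relative to the
transmembrane bundle).

## What it computes

**Contact kinetics (the core).** A contact between a lipid headgroup particle
and a target (residue, user-declared site, or whole protein) is detected with
a *dual-cutoff* (hysteresis) rule: the contact starts when the minimum
periodic distance drops below *d_on* and ends only when it exceeds *d_off*,
which suppresses rattling at a single boundary. Presets: 0.55/1.0 nm for
coarse-grained and 0.35/0.55 nm for atomistic systems. Pooled contact
durations give the empirical survival function

    σ(t) = (1/N) Σᵢ 1[Dᵢ ≥ t]

which is fitted by nonlinear least squares with the bi-exponential

    σ̂(t) = A·exp(−k_fast·t) + (1−A)·exp(−k_slow·t),
    A ∈ [0,1],  k_fast ≥ k_slow > 0.

The slow rate is reported as the dissociation rate, k_off = k_slow, and the
residence time is τ = 1/k_off; the fast component absorbs boundary rattling.
Per-residue profiles (residence time, occupancy, event count) can be painted
onto a structure through the PDB B-factor column.

**Site occupancy and localization.** Per-frame counts of headgroup particles
within a cutoff (default 0.6 nm = 6 Å) of a declared site, normalized by the
maximal count; and a lateral (2D, minimum-image) radial distribution function
g(r) of a species around the transmembrane domain, normalized so a uniform
species gives g ≈ 1.

**Domain conformation.** The inter-domain angle between two planes defined by
ordered residue triplets (oriented normals — angles live on [0, 180]°, no
folding), per-frame RMSD of one domain after least-squares (Kabsch)
superposition on another, and PCA of the fitted trajectory with the
first-eigenvalue fraction λ₁/Σλ.

**Synthetic ground truth.** Every analysis is testable without MD:
`make_binding_trajectory()` evolves lipids by a discrete-time Markov chain
with exact exponential transition probabilities and places them strictly
inside/outside the dual-cutoff band, so detection must recover the true bound
intervals frame-for-frame; `make_hinge_trajectory()` constructs a two-domain
system whose plane angle equals a prescribed series exactly;
`sample_durations()` draws from the bi-exponential mixture itself.

## Worked example

Two binding sites with tenfold different dissociation rates, recovered from
a generated trajectory:

```r
library(lipidkin)

sim <- make_binding_trajectory(
  n_lipids = 30,
  sites = list(list(residue_ids = 1:3,  k_on = 0.05, k_off = 0.5),
               list(residue_ids = 11:13, k_on = 0.05, k_off = 0.05)),
  dt = 0.1, n_frames = 10000, seed = 42)

ds  <- min_distance_series(sim$frames, sim$meta, "species GM3",
                           grouping = "site",
                           sites = list(`site 1` = 1:3, `site 2` = 11:13))
ev  <- detect_contacts(ds, contact_spec(resolution = "cg", grouping = "site"))
head(ev, 3)
#>    lipid target start_frame end_frame duration_ns censored
#> 1 L/1001 site 1         638       652         1.5    FALSE
#> 2 L/1001 site 1         768       892        12.5    FALSE
#> 3 L/1001 site 1        1026      1030         0.5    FALSE

fit_koff(survival_curve(ev$duration_ns[ev$target == "site 2"]))
#> KineticFit: k_off = 0.04956 /ns (residence 20.18 ns), k_fast = 0.1071 /ns,
#>             A = 0.114, 737 events
```

The fitted k_off of 0.0496 /ns recovers the generating rate (0.05 /ns) to
about 1%; the residence time of ~20 ns is the quantity mapped per residue in
interaction-profile figures.

The same analyses run from one JSON config over many replicates:

```sh
Rscript inst/cli/lipidkin run --config config.json --stages contacts,kinetics
Rscript inst/cli/lipidkin synth --out toy --n-lipids 20 --n-frames 2000
```

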