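---
title: "duplexflip: models, conventions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{duplexflip: models, conventions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(duplexflip)
```

This vignette is the package's own account of its science: the forward
model and its inverse, the statistics behind the free-energy machinery,
what the synthetic generator does and does not emulate, and where open
design choices were settled.

## 1. The forward model and the helical-parameter convention

A duplex is described by twelve rigid-body coordinates: six per base pair
(shear, stretch, stagger in Angstrom; buckle, propeller, opening in
degrees) and six per base step (shift, slide, rise; tilt, roll, twist).
`duplexflip` adopts a 3DNA-style mid-frame convention. Every base carries
an orthonormal frame fitted to its ring atoms; the strand-II frame is
flipped about its x-axis so both frames of a pair are near-parallel. The
relative rotation between two frames is factored as

$$ R = R_z(\omega/2-\phi)\, R_y(\gamma)\, R_z(\omega/2+\phi), $$

with twist-like coordinate $\omega$, bend magnitude $\gamma$ and phase
$\phi$; tilt-like and roll-like coordinates are $\gamma\sin\phi$ and
$\gamma\cos\phi$, and translations are expressed in the mid-frame (the
half-way rotation). The same factorization is used for pairs (buckle,
propeller, opening) and steps (tilt, roll, twist), and it is exactly
invertible: `build_duplex()` composes frames from parameters,
`measure_all()` decomposes fitted frames back, and the round trip is
exact to ~1e-13 (property-tested over hundreds of random states in the
B-DNA range). Self-consistency — not agreement with any particular
external program, which would use its own curvilinear conventions — is
the contract. Twist angles beyond ±180 degrees are outside the
decomposition's principal branch; B-DNA never approaches this.

Parameter signs are fixed by the package's template frames. One visible
consequence: a positive opening rotation moves the O6/N4 edge of a C:G
pair *together* and the N2/O2 edge apart. Sign semantics therefore differ
from curvilinear-axis tools; all analyses in the package (and the
two-state defaults) are internally consistent with this convention.

## 2. Idealized nucleotide templates

Template geometry lives in `inst/extdata/base_templates.tsv` and is
derived (script in `data-raw/`) from the ideal residue geometries of the
Chemical Component Dictionary: bases planarized, one common
sugar-phosphate unit grafted onto all four bases through the glycosidic
frame, backbone torsions set so the phosphate sits at the fibre-B-DNA
radial position (9.4 Å from the axis). The base-pair frame is constructed,
rather than copied from a published table, by placing each base with its
C1' on a fixed line and its glycosidic bond at a shared angle λ to the
C1'–C1' vector, then optimizing (d(C1'–C1'), λ) per Watson–Crick pair so
the canonical heavy-atom donor–acceptor distances hit crystal-survey
targets (2.82–2.90 Å). This guarantees three detectable bonds for C:G and
two for T:A under the 3.0 Å / 135° criterion, and makes λ₁ = λ₂ exact by
construction for an ideal pair. Polar base hydrogens are retained (the
H-bond criterion needs them); sugar hydrogens are not. 5'-terminal
residues carry no phosphate.

A canonical 17-mer built with twist 36°, rise 3.38 Å measures 59.1 Å
along the fitted helix axis and 20.4 Å across — the textbook B-form
dimensions of such an oligomer.

## 3. The synthetic world

`generate_trajectory()` emulates the *statistical structure* that the
analyses assume, not molecular mechanics:

* independent Gaussian fluctuations of each helical parameter around a
  mean state. Defaults (`fluctuation_state()`: 0.08–0.3 Å, 2.5–5°) are of
  the order seen in room-temperature B-DNA simulations; tests that need
  hydrogen bonds slaved to the hidden state use `scale = 0.2` ("small
  fluctuations"), because at full scale the 0.1–0.15 Å margin between the
  ideal bond distances and the 3.0 Å cutoff is crossed a few percent of
  the time — exactly as real Watson–Crick occupancies fall below 100 %.
* a hidden two-state Markov chain on one parameter of one pair
  (`two_state_spec()`), emulating wobble-pair opening: closed at −1°,
  open at 45°, stationary open fraction p₍co₎/(p₍co₎+p₍oc₎). Within-state
  widths default to 3°: beyond an opening of roughly 53° the rigidly
  attached backbones of the target pair would overlap, so the open basin
  must stay inside the forward model's validity domain. Rejection: a
  clashing frame (< 0.5 Å between any two atoms) is redrawn — including
  the state-conditional value, keeping the hidden label — up to 100
  times; at the default widths the truncated tail is < 1e-3.
* deterministic sweeps of the flip coordinate (`flip_sweep`), the
  stand-in for biased runs. The flipping nucleotide is rotated rigidly
  about the axis through the two sugar centres of mass, which changes the
  pseudo-dihedral by exactly the rotation applied; it is excluded from
  the clash scan, since driving a base from 10° to 180° necessarily
  grazes its neighbours.

What a green test on this world establishes: the estimators (PMF,
occupancy, SASA profile, ABF) recover known inputs at their stated
tolerances. What it does not establish: force-field realism, solvent
effects, correlated parameter fluctuations, backbone relaxation during
opening, or the actual energetics of any real mispair.

## 4. The flip coordinate

The flip angle is the dihedral of four mass-weighted centres: the
flipping base's heavy atoms; its sugar; the neighbouring nucleotide's
sugar; and the neighbour's base plus the base paired to the neighbour
(`group_preset = "figure1"`), optionally plus that partner's sugar
(`"methods_text"`). Both presets are implemented because the textual and
graphical definitions in the literature differ; neither is canonical. In
this geometry they differ by a systematic ~7°. The neighbour defaults to
the 3' side: with that choice the canonical flipped-in conformation
measures ≈ 29–45° across the central pairs — the 35–50° phenomenology of
flipped-in bases — whereas the 5' neighbour yields 7–16°. Angles are
reported in [0, 360) with a sign convention chosen so the angle grows
toward 180° as the base leaves the stack; degenerate (collinear) centre
configurations raise an error rather than returning an arbitrary value.

The lambda angle is measured at C1', between C1'→N1/N9 and
C1'→partner-C1' (the field's convention, ≈ 52° for the ideal pair built
here).

## 5. Free-energy machinery

`pmf_from_series()` bins a series with edges anchored at integer
multiples of the bin width (2° for angles, 0.2 Å for translations), so
−1° and 45° are bin centres; takes the modal bin as reference (ties go to
the lowest index, with a message); and reports
ΔG᷊ᵢ = −k_B T ln(nᵢ/n_ref) with k_B = 0.0019872041 kcal/(mol·K), T = 300 K
by default. Empty bins stay `NA` — never ±∞, never interpolated.
`average_profiles()` evaluates each run separately and then averages:
per-bin mean, standard error over runs and a Student-t 99 % confidence
interval (the interval construction is a package choice; both SE and CI
are emitted so either error convention can be read off). Bins absent in
any run are dropped. `profile_difference()` evaluates ΔG between two
coordinate values per run, which is reference-independent, and applies
the same t statistics. `convergence_windows()` recomputes the averaged
profile from the leading 2/3, 5/6 and all of every run and scores the
maximal |ΔΔG| between successive windows.

## 6. The reduced ABF model

The full-coordinate ABF of an all-atom duplex is out of scope; the
sampler runs on a closed-form 1-D potential over the 10–180° window
(reflecting boundaries, since only the major-groove path is modelled).
Potentials are sums of a quadratic, a quartic wall and Gaussian wells —
enough to express the presets while keeping the force evaluable in
compiled code; the analytic derivative is verified against a finite
difference at construction. The double-well preset places local minima at
42.25° and 66.75° separated by a 1.01 kcal/mol barrier with the second
minimum 0.3 kcal/mol above the first, and rises by ~5.5 kcal/mol toward
180° — the shape reported for wobble-pair flipping.

Dynamics are overdamped Langevin in reduced time units: dt = 0.5,
friction 1, so the RMS free-diffusion step (≈ 0.8°) resolves the 2° bins
yet traverses the window in well under 10⁶ steps. The instantaneous force
−dU/dθ is accrued into the current bin every step; the applied bias is
the negative running mean force, ramped linearly from zero to full
between 0 and `n_min = 2000` samples (the threshold protocol; the ramp is
common ABF practice). `pmf_from_forces()` integrates the mean force by
the trapezoid rule over bin centres and anchors the minimum at zero.
Reconstruction accuracy on the presets: minima within a bin, barrier
within 0.2 kcal/mol, at ~10⁶ steps per run averaged over five seeds. With
`n_min = Inf` the sampler reduces to plain Langevin and its histogram PMF
matches U within sampling error — the bias-off control used in the tests.

## 7. Hydrogen bonds and surface areas

A donor–hydrogen/acceptor triple is a bond iff the donor–acceptor
distance is ≤ 3.0 Å **and** the acceptor–hydrogen–donor angle is ≥ 135°,
both inclusive (the boundary semantics are fixed by decision; the
three-point angle is symmetric in its end atoms, so the written atom
order is immaterial). Occupancy is the fraction of analyzed frames
(burn-in excluded) with the bond formed, per run, then mean ± SE over
runs; one run reports no SE. The donor/acceptor table covers all four
bases and water (the data model accepts explicit waters; the generator
produces none).

SASA is Shrake–Rupley with a deterministic golden-spiral lattice of 960
points per atom, Bondi radii, and a 1.4 Å probe: a surface point is
accessible when the probe centred there penetrates no other expanded
sphere. Isolated atoms reproduce 4π(r+1.4)² essentially exactly;
two-sphere overlaps match the spherical-cap closed form within 2 %, which
is the accuracy contract against analytic methods.

## 8. Statistical choices worth knowing

* The open fraction of a two-state chain has variance inflated by
  autocorrelation, factor (1+ρ)/(1−ρ) with ρ = 1 − p₍co₎ − p₍oc₎; all
  chain tests use this corrected SE.
* Occupancy of a flat-landscape ABF run is only loosely uniform: the
  sampler is a correlated walk, so bin counts fluctuate far beyond
  multinomial noise. The property tested is "no empty bins, max/min < 3
  at 10⁶ steps".
* The ring-only base-frame fit under 0.05 Å coordinate noise has a mean
  angular error of ~1.2° (nine purine ring atoms); tests bound the mean
  at 1.5°.
* PDB files round-trip coordinates at 10⁻³ Å, which propagates to a few
  hundredths of a degree in the angular parameters.

## 9. Known limitations

Rigid nucleotides (no sugar repuckering, no backbone torsion model —
adequate for centre-of-mass, λ, H-bond and SASA analyses, by design);
independent Gaussian parameter fluctuations (no sequence-dependent
stiffness, no cross-correlations); opening angles beyond ≈ 53° are
geometrically unreachable, so the wobble "open" caricature lives at the
edge of the model's validity; the ABF model is 1-D and uncoupled from the
duplex; no solvent, ions or force-field energetics anywhere.
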