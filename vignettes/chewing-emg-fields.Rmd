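---
title: "Modeling chewing-muscle EMG propagation to the cerebral cortex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling chewing-muscle EMG propagation to the cerebral cortex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question and the method

The masticatory muscles (temporalis, masseter, pterygoids) lie millimeters
from the cranial cavity and produce, during chewing, broadband EMG that is
orders of magnitude stronger than cortical potentials. Whether this
extracranial activity drives electric fields (EF) inside the skull large
enough to modulate ongoing cortical activity — the usual reference value from
transcranial stimulation work is about 0.2 V/m — cannot be measured directly
in healthy people. `chewEF` implements the indirect route:

1. **Measure** chewing-related (ChR) bursts simultaneously on the scalp (EEG)
   and on the cortical surface (ECoG, in implanted patients).
2. **Calibrate** the strength of equivalent current dipoles in the chewing
   muscles so that a volume-conductor model of the *implanted* head (with
   craniotomy defects and the insulating silicone grid; "HM1") reproduces the
   measured intracranial burst amplitudes.
3. **Predict** the cortical EF those dipoles produce in an *intact* head
   model ("HM3", no defects, no grid) — the situation of a healthy person.
4. **Scale** the per-event fields to chewing of different intensity using
   noninvasive scalp EMG amplitudes from food conditions of graded hardness,
   and report the fraction of chewing events whose peak cortical EF exceeds
   0.2 V/m.

Because no clinical recordings are distributable, the package ships a
synthetic-data layer (phantom + recording generator) that emulates the
statistical structure of every input, so the whole pipeline is testable from
scratch.

## The head phantom

`phantomSpec()` / `buildPhantom()` produce a concentric-sphere head (white
26, gray 32, CSF 36, skull 42, scalp 48 mm by default; 2-mm isotropic voxels)
with:

* a **muscle compartment**: the sector of the extracranial soft-tissue shell
  within 45 degrees of the +x axis, which hosts the temporalis-belly analogue
  (equator), a superior extension (toward the burr holes), and a
  pterygoid-like region near the skull base;
* **craniotomy defects** (HM1 only): CSF-filled burr-hole cylinders of 12 and
  16 mm diameter and a 4-mm saw-line slot through the skull shell;
* a **foramen channel**: a 5-mm cylinder through the basal skull filled at
  0.38 S/m (the average of blood and white matter), the high-conductance
  tunnel next to the pterygoid source;
* an **insulating grid patch** (HM1, HM2): a sheet of `grid_insulator`
  voxels, three voxels thick, draped column-by-column over the +x gray
  surface within a 26-mm footprint. A constructive sealing pass
  (`sealCheck()` plus face-connector insertion) guarantees the sheet has no
  edge- or corner-only contacts, which would otherwise leak current in the
  FEM discretization.

The three variants differ *only* at defect and grid voxels, so differences
between their forward solutions isolate the defect-shunt and grid-shield
mechanisms. Spatial scale, layer thicknesses and defect positions are a desk-
scale idealization, not patient anatomy: the phantom preserves mechanisms
(skull barrier, CSF shunts, foramen tunnel, insulating sheet), not geometry,
so all cross-variant *magnitudes* are phantom-specific and only directions
and calibrated/linear quantities transfer.

Subdural contacts form the 4 x 4, 10-mm-pitch lattice of the grid, placed
half a voxel *below* the gray/CSF interface so they sample the cortex facing
the contact rather than the insulator above it. Scalp electrodes are a
Fibonacci lattice on the outer sphere (19 by default).

## The synthetic recordings

`generateRecording()` synthesizes 1024-Hz recordings (1–344 Hz acquisition
band) with chewing bursts at 0.8–1.8 Hz repetition: band-limited 30–500 Hz
Gaussian noise under an asymmetric envelope with a 10-ms linear rise and an
exponential decay (time constant one third of the burst duration, so the
envelope ends near 5 % of its peak). Each burst is normalized so that a
channel with gain g µV yields a ChR amplitude statistic of exactly g µV under
the default analysis parameters; per-trial strength varies lognormally.
Scalp channels receive the burst at the configured scalp amplitude with
distance-weighted mixing from the muscle; subdural channels receive it
attenuated by the configured factor (default 5.5) with a **zero-mean**
spatial pattern, because the intracranial analysis is CAR-referenced and a
common-mode pattern would otherwise be removed by the reference. All
channels get independent 1/f background noise, scaled in the same
statistic units (optionally per electrode kind).

What the generator does *not* emulate: nonstationary chewing rhythms, jaw
artifacts, electrode drift, line noise, volume-conducted cortical activity,
or realistic scalp EMG topographies (the distance-weighted mixing is a
stand-in; no per-channel EMG topography is published). Tests passing on this
generator therefore validate the *pipeline arithmetic and statistics*, not
robustness to clinical artifacts.

`detectChewingEvents()` recovers annotations from the data (rectified,
smoothed 30–500 Hz envelope; onset at a threshold on the sharp rise; burst
end by log-linear extrapolation of the exponential tail, because the
5 %-of-peak crossing itself is noise-limited). Onsets are recovered to about
the envelope rise time; end times are intrinsically an order of magnitude
less precise.

## Event-related analysis

* **Re-referencing**: common average reference for the subdural set, single
  reference (e.g. Cz) for scalp data.
* **Relative spectra**: sliding rectangular-window FFT, 256 samples (250 ms)
  window, 25 samples (24.41 ms) step, on –2…+2 s excerpts; power divided by a
  baseline and log10-scaled. The baseline definition is *median across
  baseline time bins within trial, then mean across trials*
  (`spectralParams(baselineOrder=)` exposes the mean-then-median
  alternative). The window function is rectangular by default — the analysis
  operates on broadband power ratios, where leakage largely cancels. One
  estimator property worth knowing: per-bin power is strongly right-skewed
  (χ²-like), and overlapping windows inside a short baseline excerpt contain
  only a couple of *independent* bins, so the median-across-bins baseline
  drifts toward the distribution mean and null log ratios acquire a small
  negative offset (about −0.1 for a 0.5-s excerpt of white noise, −0.02 for
  a 2-s excerpt). The sign test against zero is therefore anticonservative
  under very short baselines; give the baseline excerpt a couple of seconds
  where the recording permits.
* **Statistics**: per time–frequency bin, an exact two-tailed binomial sign
  test of zero median across trials (zeros dropped, smaller tail doubled,
  capped at 1). Multiple testing uses Benjamini–Yekutieli at q = 0.001 — the
  FDR variant that is valid under arbitrary dependence, which is the
  appropriate choice for strongly correlated neighboring bins.
* **ChR amplitude**: zero-phase 4th-order Butterworth high-pass (default
  100 Hz; the 55-Hz variant is a parameter), then the difference between the
  10th and 90th percentile (linear interpolation between order statistics) in
  a 100-ms window around the event center; peak-to-peak and window lengths of
  50–300 ms as variants. For a sinusoid of amplitude A the statistic is
  2 A sin(0.4 π) ≈ 1.902 A, which the tests verify against brute-force
  sampling. Both the per-trial channel-median and channel-max reductions are
  computed; downstream calibration uses the median by default.

## The FEM forward solver

The quasi-static problem ∇·(σ∇V) = −∇·jₛ is discretized on *regular*
(axis-aligned, non-geometry-adapted) trilinear hexahedra, one element per
labeled voxel. For cube elements the element stiffness is σ·h·K_ref with a
single reference matrix, so assembly is a sparse triplet accumulation.
Conductivities (S/m): white 0.14, gray 0.33, CSF 1.54, blood 0.63, skull
0.0063, muscle 0.11, soft tissue 0.17, internal air 0.002, foramen fill
0.38, defect fill = CSF. The grid insulator uses 1e−12 S/m: at the solver
tolerance this is indistinguishable from a perfect insulator while keeping
the stiffness matrix invertible in floating point.

Dipoles use a St. Venant-style monopole distribution: the minimum-norm load
set on the nodes of the containing element and its vertex neighbors whose
zeroth moment vanishes and whose first moment equals the dipole moment — the
constraints are enforced exactly (KKT solution), so moment accuracy is at
machine precision. The singular, consistent system (constant null space) is
solved by Jacobi-preconditioned conjugate gradients to a relative residual
of 1e−9; the solution is reported zero-mean over nodes. Electrode potentials
are trilinear interpolations at contact centers (metal contacts are not
modeled); E = −∇V is evaluated from trilinear gradients at element
centroids and reported for gray-matter elements; the peak is the maximum
vector magnitude over gray elements, with no spatial smoothing.

**Verification** is against an independently implemented analytic oracle:
the Legendre-series potential of a dipole in a concentric multilayer sphere
with insulating exterior (`analyticSphere()`), with per-degree layer
coefficients from interface continuity conditions, all radial factors scaled
to remain bounded, and truncation at 1e−12 relative. RDM (topography) and
lnMAG (magnitude) metrics compare the two solutions after common-average
referencing over the sample points, since the two solutions carry different
potential references. On the 4-layer sphere (radii 78/80/86/92 mm, gray/
CSF/skull/scalp conductivities, eccentric dipole at 60 % radius, 2-mm mesh)
the agreement is RDM ≈ 0.02 and |lnMAG| ≈ 0.07 for both orientations.

## Grid reconstruction

The six-step reconstruction of a subdural grid molded onto the cortex:

1. `shrinkwrap()`: a subdivided icosphere is shrunk radially onto the
   directional maxima of the input surface with Laplacian smoothing of the
   radial field each step, then clamped to enclose the input. This is an
   explicit algorithm chosen for the star-shaped geometry of brain hulls; it
   bridges sulci/gyri rather than following them.
2.–3. `extractPatch()`: corners snap to hull vertices; the patch boundary is
   the concatenation of Dijkstra shortest paths between consecutive corners;
   the interior is flood-filled from the corner-centroid direction.
4. `embedPatch2D()`: classical MDS of graph-geodesic distances (the isomap
   construction). The edge graph is augmented with chords between all vertex
   pairs within a fixed 10-mm radius (the contact-pitch scale): pure
   edge-graph Dijkstra on lattice-like triangulations overestimates
   geodesics by up to tens of percent through direction quantization, an
   error that does *not* vanish with refinement at fixed connectivity,
   whereas within a fixed physical radius refinement adds directions and the
   error decreases monotonically. On developable test surfaces geodesic
   errors stay under 2 % (0.3 % at typical resolutions). Exactly planar
   patches short-circuit to their orthogonal projection (the exact
   isometry). The embedding is defined up to rigid motion and reflection.
5.–6. `placeAndTriangulate()`: a rigid rows x cols lattice at 10-mm pitch,
   anchored at the first corner and advancing toward the second (an elastic
   fit would be the alternative; the rigid lattice matches the physical
   inflexibility of the silicone sheet). The reflection ambiguity is
   resolved by matching the 2-D corner winding to the 3-D patch orientation.
   Each center links to its three nearest embedded vertices (ties broken by
   vertex index) and back-projects through their barycentric coordinates;
   near-collinear triples fall back to inverse-distance weights.

`sealCheck()` finally verifies that a rasterized grid has only face-to-face
contacts, and `rasterizeSurface()` inserts the reconstructed sheet into a
labeled volume with automatic sealing.

## Calibration and exceedance

With linearity of the forward problem, one solve per head model and source
model gives the two constants of `unitForward()`: the CAR-referenced
sub-grid amplitude measure per unit dipole moment in HM1 (channel-median of
absolute contact potentials), and the peak gray-matter EF per unit moment in
HM3. Then per trial i:

* strength: qᵢ = Aᵢ / (2 · gridMeasure) — the factor 2 models the potential
  reversal contained in a two-sided amplitude statistic and is applied
  exactly once, to the simulated measure;
* healthy-head field: EFᵢ = qᵢ · peakEF (vector magnitude; the peak location
  consistently falls in the gray matter facing the muscle);
* condition scaling: EFᵢ,c = EFᵢ · S_c / Mᵢ with S_c the condition mean over
  participants (not per-participant values) and Mᵢ the trial's scalp
  channel-median amplitude;
* exceedance: the percentage of trials with EFᵢ,c strictly above 0.2 V/m,
  reported over the full sweep high-pass {55, 100} Hz x window 50–300 ms x
  statistic x source model.

Source models: SM1 — one dipole central in the temporalis belly; SM2 — seven
belly dipoles plus one superior dipole, equal moments, one shared scale;
SM3 — one medial-pterygoid dipole on the foramen axis. Belly/superior
dipoles are oriented along the muscle long axis (phantom z), the pterygoid
dipole along the foramen channel; orientations are configurable since no
anatomical orientations are published.

`recoverySimulation()` closes the loop: true strengths qᵢ are drawn
lognormally around a level that places the gum-condition scaled field near
0.15 V/m (astride the threshold, so the exceedance estimate is maximally
sensitive); subdural channels carry the burst scaled by 2 · uₙ · qᵢ (the HM1
contact pattern), scalp channels carry a constant designed amplitude, and
background noise sits at SNR 10 per kind. Scalp trial strengths are held
constant *independently* of the intracranial drive: if both shared one
drive, the scaled field would be constant across trials and the exceedance
degenerate — the variability of the recovered distribution then reflects
the strength distribution, as intended. With n = 500 trials, calibrated
strengths show a median relative error of about 2 % and recovered
exceedance fractions fall inside the binomial 95 % interval of the design.

## Numerical choices and problem sizes

* Solver tolerance 1e−9 (relative residual), iteration cap 30 000; Jacobi
  preconditioning suffices because regular hexahedra give a well-structured
  stiffness even at the 244-fold CSF/skull contrast.
* Series truncation 1e−12 relative, three consecutive sub-threshold terms.
* Percentiles: type-7 (linear interpolation); ties in nearest-neighbor
  searches break by index order; exceedance uses strict inequality (ties are
  measure-zero in floating point).
* Default problem sizes were chosen so the full suite and the acceptance
  script run comfortably on one CPU: 49³ voxel phantoms (≈ 58 000 elements),
  the 2-mm four-layer oracle sphere (≈ 420 000 elements, ≈ 20 s per solve),
  recovery at 500 trials, null simulations at 2000 bins / 300 replicates.
  All sizes are parameters.
* Every stochastic routine takes an explicit seed; nothing depends on global
  RNG state.

## Limitations

* The phantom is spherical and desk-scale: magnitudes (shielding ratios,
  attenuation factors, absolute field strengths) are not anatomical
  predictions; only directions, calibrated linear relations and statistical
  properties are.
* Regular hexahedra carry staircase error at curved interfaces;
  geometry-adapted (node-shifted) meshes are out of scope.
* Conductivities are isotropic and frequency-independent; skull anisotropy
  and the metal of the contacts are not modeled.
* The patient-specific exceedance percentages of the original clinical data
  depend on undeposited recordings and anatomy; the package reproduces the
  procedure and its recoverable properties, not those numbers.
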