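---
title: "Methods: membrane footprint and lipid fingerprint analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: membrane footprint and lipid fingerprint analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memfoot)
```

# Scope and model

memfoot quantifies two things about a membrane-deforming protein in a
coarse-grained bilayer simulation: the geometry of the membrane
deformation (the *footprint*: dome depth and leaflet height maps) and
the protein's lipid fingerprint (2D densities, per-residue contact
profiles, the preferential binding coefficient δ_L, and
cholesterol-recognition motifs in the sequence). All analyses operate
on *headgroup beads* — one polar bead per lipid (the phosphate bead of
phospholipids, the hydroxyl bead of cholesterol) — because the
headgroup surface is what defines leaflets, dome depth and contact
shells in CG models. Coordinates are in nm throughout (PDB input is
converted on read).

# Leaflet assignment

Leaflets are found by a branching-network flood fill: starting from the
headgroup bead with maximal z (a deterministic, reproducible seed), any
headgroup bead within `leaflet_cutoff_nm` (default 2.0 nm) of a member
joins the set, until closure. The complement is the other leaflet; a
confirmation pass seeded at the highest bead of the complement must
reproduce it exactly. The method needs the cutoff to sit between the
in-plane neighbour spacing and the inter-leaflet separation; if the
fill absorbs every bead the leaflets are fused at that cutoff and the
function stops rather than guessing.

Distances for leaflet assignment use the minimum-image convention in x
and y only. A bilayer is periodic in the membrane plane, but applying
the z image as well could connect a deep dome to the opposite leaflet's
periodic image through the solvent gap; contact analysis, by contrast,
wraps all three dimensions (a solvated box is periodic in z for real
bead pairs). Both conventions are fixed, documented behaviour.

Beads reachable from neither seed are typically lipids caught mid-flip
between leaflets. Simulation protocols remove such lipids by hand, so
the default here is an error listing the stray beads; an opt-in
`assign_strays_by_z` attaches them to the leaflet with the nearer mean
z. Assignment is recomputed per frame (with a `static` option to reuse
frame 1), and the per-frame series reports a flip diagnostic: any bead
whose label changed between consecutive frames.

The neighbour search runs on a cell list with a brute-force
`O(N^2)` backend kept as a reference; the test suite checks the two
against each other and against an independent graph-components oracle.

# Dome depth

For one leaflet and frame,

`depth = surface − bottom`

where the *surface level* is the mean z over headgroup beads with z at
or above the `surface_percentile` (default 90th) percentile of that
leaflet's z values, and the *bottom* is the single lowest headgroup z.
Averaging the top decile damps thermal fluctuation of the flat far
field; the bottom needs no averaging because it sits against the
protein, which is also the fitting reference. The percentile threshold
is inclusive (z ≥ P90, linearly interpolated): an exclusive threshold
returns an empty set on a perfectly flat (all-tied) leaflet, and on
noisy data the difference is negligible. Depth analysis expects a
trajectory fitted to the whole-protein reference; an equilibration
window (`depth_exclusion_ns`, default 1000 ns) is dropped first.
Summaries pool per-frame depths across runs and report mean ± SEM
(sd/√N), with an optional block-averaged SEM for autocorrelated data.

Two properties matter for interpreting tests against synthetic ground
truth with Gaussian z-jitter of scale σ:

- the surface level is a conditional tail mean, biased upward by
  ≈ 1.755·σ (the mean of a Gaussian's top decile), and the bottom is a
  minimum statistic, biased downward — so the estimator recovers a
  planted depth D with a small, noise-derived positive offset
  (≈ 0.2 nm at σ = 0.1 nm), well inside the ±0.3 nm band the suite
  asserts;
- being part tail-mean, part extremum, the per-frame depth distribution
  is right-skewed, so mean comparisons at 3·SEM are asserted on samples
  of ≥ 100 frames, against the *expected* depth under noise computed by
  an independent Monte-Carlo oracle (the 5-line sort/slice/mean/min
  statistic applied to the generator's noise-free coordinates plus
  fresh jitter). A naive 3·SEM band around D itself would fail for any
  sample size, not because recovery is poor but because SEM shrinks
  while the tail-mean offset does not.

# Height and density maps

Height maps bin headgroup beads of one leaflet on a `heightmap_bins`²
grid (default 75×75) spanning the reference frame's box; each frame
contributes its per-bin mean z, and frames are averaged per bin,
ignoring bins empty in that frame — zero-filling would drag averages
toward z = 0. Bins empty in every frame are `NA`. Beads drifting
outside the grid are clipped into the edge bins and counted.
`angular_minima()` summarises lobedness: occupied bins are assigned to
angular sectors about the grid centre, each sector contributes its
minimum height, and local minima of the (circularly smoothed,
plateau-merged) profile are counted; a three-bladed footprint gives 3.

Density maps histogram selected beads (one species' headgroups, or all
protein beads) per frame, sum over frames and divide by
`n_molecules × n_frames`. With one counted bead per molecule and no
clipping, the normalized map sums to exactly 1, which the tests assert.
Protein density uses the same per-molecule convention with the trimer
counted as three molecules. Density and contact analyses fit the
trajectory to the pore region (residues 2105–2547 by default, the
C-terminal trimeric core), whereas depth and height maps fit to the
whole protein; `analysis_config(fit_selection=)` selects the reference.

# Contacts and the preferential binding coefficient

A contact is a (protein bead, lipid headgroup bead) pair at
minimum-image distance strictly below `contact_cutoff_nm` (default
0.55 nm). Pair counting (rather than a binary per residue–lipid flag)
is the default because the per-molecule, per-frame normalization then
yields the continuous per-residue profiles the field plots; the strict
inequality at the boundary is a measure-zero choice, made explicit in
the tests with an exactly representable cutoff. Per-residue counts are
summed over frames and over chains at equal residue number (the trimer
is symmetric; chains with mismatching residue sets are an error), then
normalized by `n_lipid_molecules × n_frames`. Summation happens before
normalization; for equal-length chains the two orders differ only by a
constant. Residues at or above `significance_fraction` of the profile
maximum (0.6 for sterols, 0.7 for PIP₂ by convention) are flagged
significant. Contact-based analyses drop `contact_exclusion_ns`
(default 1500 ns) of equilibration, versus 1000 ns for depth — the two
windows reflect the slower convergence of PIP₂ contacts.

The preferential binding coefficient uses whole-protein contact data:
per retained frame, `δ_L = N_L − N_A·(n_L/n_A)` per species, then the
ensemble mean ± SEM over frames. Σ_L δ_L = 0 holds per frame by
algebra, and the suite asserts it on every synthetic run. The ensemble
unit is the frame; block averaging is available through the depth
aggregator's pattern if autocorrelation is a concern.

# Motif scanning

CRAC `(L/V)-X(1–5)-Y-X(1–5)-(R/K)` and CARC
`(R/K)-X(1–5)-(Y/F)-X(1–5)-(L/V)` are scanned N→C. The CARC central
anchor admits Y or F (the common definition); a Y-restricted variant is
selectable, and under it CARC is exactly the mirror of CRAC, a symmetry
the tests exploit. Because the consensus is loose, counting conventions
matter: the default is leftmost-shortest non-overlapping (smallest
start; ties broken by smallest end, then smallest centre; scanning
resumes past the hit), and `all_matches` enumerates every distinct
anchor triple. Published counts for the 2547-residue mouse Piezo1
sequence (19 CRAC, 40 CARC) are the calibration point for the
convention; the acceptance test asserts them against the UniProt E2JF22
sequence when it has been placed under `inst/extdata/` (see the
README), and the convention is deliberately left configurable rather
than hard-coded. Positions are 1-based inclusive, matching standard
residue numbering.

# The synthetic generator

`make_dome_trajectory()` builds two headgroup lattices (spacing
0.8 nm, i.e. safely under the 2 nm leaflet cutoff) separated
vertically by 4 nm, both displaced by the dome field

`f(r, θ) = −D · exp(−r²/2σ²) · (1 + a·cos kθ)/(1 + a)`, with
`f(0) ≡ −D` to remove the angular singularity at the centre. θ is
measured about the lattice centre, and the lattice is phased so the
centre is a bead — the noiseless dome minimum is then exactly −D.
Species are sampled per leaflet from an asymmetric composition whose
defaults mirror a plasma-membrane design qualitatively: sphingomyelin
only in the upper (extracellular) leaflet, PIP₂ (10%) only in the
lower (cytosolic) leaflet, 20% cholesterol in both. An optional
annulus overrides the composition near the centre (used to plant lipid
enrichment around the protein stub), and an optional planted
translocation moves one lipid across leaflets mid-trajectory to
exercise the flip diagnostic. Protein stubs come in two arrangements:
a central three-chain column (fitting reference, depth systems) and
three-chain rings at both leaflet planes (a contact-rich stub for
binding-preference systems). Per-frame Gaussian jitter (σ_xy, σ_z) is
the only dynamics. All randomness flows from one seed; the same spec
and seed reproduce trajectories bit-for-bit, and with jitter off the
geometry is seed-independent (only species labels change).

Generation checks the leaflet-separability precondition it promises:
no cross-leaflet headgroup pair within the cutoff plus a 6σ jitter
margin, else it errors. Steep domes (large D/σ or strong lobes at
small radius) legitimately violate this — the dome walls bring the
leaflets closer than their vertical separation — which bounds the
parameter combinations the tests use.

What the generator deliberately does **not** emulate: membrane
elasticity (the dome is imposed, not emergent), lipid diffusion and
exchange (species are static; frames differ only by jitter), tails and
solvent (single-bead lipids by default, an optional 2-bead tail only to
exercise headgroup selection), and protein conformational dynamics.
Passing tests therefore demonstrate that the *analyses* are correct
against known ground truth — exact leaflet recovery, exact planted
contact profiles, unbiased depth recovery up to the characterised noise
offset — not that the generator reproduces bilayer physics.
`make_planted_contact_system()` places lipids at 0.4 nm from scheduled
residues (all other protein–lipid distances > 1 nm), making the
expected contact profile exact bookkeeping;
`make_motif_sequence()` draws background residues from an alphabet
without motif anchors and enforces a ≥ 7-residue gap between planted
motifs, so no anchor triple can span two motifs and the expected hit
list is exact.

# Problem sizes and numerical choices

The test suite and acceptance script run on lattices of roughly
400–3 200 headgroup beads, 1–30 frames and 5–20 seeds per condition —
sizes chosen so that stochastic recovery checks have the sample sizes
their 3·SEM bands assume while the whole suite stays quick on one CPU.
Depth-recovery conditions use D ∈ {2, 4, 6, 8} nm with σ_z = 0.1 nm
and a dome width scaled as max(2.5, 0.8·D) nm, keeping wall slopes
inside the separability bound. Other fixed choices: unweighted
(mass-free) rigid fits, no periodic-image reassembly before fitting
(molecules are assumed whole), box-fixed grid extents with edge
clipping, and ties in leaflet mean z (impossible on real bilayers)
treated as errors.

# Known limitations

- XTC/TRR trajectories are not read; multi-frame GRO is the trajectory
  dialect (convert with standard tools first). Frame times are taken
  from a `t=` title token, interpreted in ns.
- GRO carries no chain identifiers, so protein chains are inferred from
  residue-number restarts; PDB chain ids are honoured when present.
- The default headgroup-bead table (PO4; PO4/P1/P2 for PIP₂; ROH for
  cholesterol) matches common Martini naming but is a convention, not a
  standard — override `category_rules` to match your topology.
- Leaflet detection assumes a (possibly strongly deformed) planar
  bilayer; vesicles and micelles are out of scope, as are
  curvature-aware local-normal methods.
- δ_L SEM treats frames as independent; for long correlated
  trajectories, block averaging is advisable.
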