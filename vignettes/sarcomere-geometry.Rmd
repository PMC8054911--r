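---
title: "Geometric models behind sarcotomo: lattice, helix, cross-bridges, Z-disc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric models behind sarcotomo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sarcotomo)
```

# Scope and conventions

`sarcotomo` analyses three-dimensional coordinate models of striated-muscle
sarcomeres of the kind produced by cryo-electron tomography after filament
annotation and subtomogram averaging: filament axis polylines, actin subunit
positions, myosin head placements, and alpha-actinin cross-links. Because
raw tomographic data are far beyond desk scale, the package pairs every
analysis with a synthetic ground-truth generator that emulates the
statistical structure those analyses assume. Every analysis stage is
therefore testable end to end: the generator writes the truth, the analysis
recovers it.

Conventions used throughout:

* the filament axis is **+Y**; tomogram-style slices are XY planes stacked
  along Z; cross-sections are XZ planes;
* **internal lengths are Angstrom**, all reported statistics are nm.
  Parameters follow the field's habits: lattice and rod lengths in nm,
  helical rise in Angstrom;
* azimuths are degrees in [0, 360), counter-clockwise from +X in the plane
  normal to the axis (for a +Y filament, `atan2(z, x)`); angular
  *differences* are wrapped to (-180, 180]. `estimateHelicalParams()`
  exposes a `flip` argument for data using the opposite handedness
  convention, which simply negates the recovered twist.

# The A-band lattice

In the vertebrate A band, thick filaments form a triangular (hexagonal)
lattice; `LatticeSpec` defaults to the measured 45-nm thick-thick spacing.
Thin filaments occupy the two trigonal interstices per unit cell, each
equidistant from three thick filaments at $a/\sqrt{3} \approx 25.98$ nm --
the "~26 nm" thin-to-thick spacing. `buildLattice()` constructs exactly
this geometry, applies optional isotropic in-plane Gaussian jitter
(`jitterSd`, nm) as rigid whole-filament displacements, and records each
thin filament's three nearest thick neighbours with stable labels
`R`, `G`, `B` assigned in ascending bearing order. An I-band variant
(`band = "I"`) omits the thick filaments; with jitter it reproduces the
loss of hexagonal bond-orientational order that distinguishes I-band from
A-band cross-sections.

# Actin helical arithmetic

The thin filament is modelled with the genetic helix: twist
$\varphi = -166.6^\circ$ and rise $r = 27.9$ Å per subunit, the symmetry
used for the in-situ reconstructions. Subunit $k$ sits at axial offset
$k r$ and azimuth $\theta_0 + k\varphi$; strand parity is $k \bmod 2$.
Two derived constants recur in the analyses:

* subunits per half-helical (crossover) repeat,
  $180 / (180 - |\varphi|) = 13.43$, i.e. "~13 subunits";
* crossover repeat length $13.43 \times 27.9\,\text{Å} = 37.5$ nm, the
  familiar ~37-nm target-zone period.

`estimateHelicalParams()` inverts this: the axis is the principal
component of the subunit coordinates, rise the mean consecutive axial
spacing, and twist the *circular* mean of consecutive azimuth increments
(an arithmetic mean would be corrupted by wrap-around at +/-180).
On noiseless generated coordinates the round trip recovers
(-166.6, 27.9) to three decimals; with two subunits the estimate
degenerates, by construction, to the single interval along the
connecting line.

# Orientation-gated myosin binding

The cross-bridge model follows the observation that myosin heads bind
actin subunits oriented toward the thick filament the head originates
from, with bound-subunit orientations confined to a ~120 degree range.
`BindingSpec` therefore gates eligibility at
`gateHalfwidth = 60` degrees around the bearing toward the candidate
thick filament.

Head budgeting is crown-based: 6 heads (3 two-headed myosin molecules)
per 14.3-nm axial crown, `crowns = floor(length / 14.3 nm)`; a 49-crown
filament carries the textbook 294 heads. At the lattice boundary a thick
filament faces fewer than its six interstitial thin neighbours, so its
budget is scaled by the fraction modelled ($n/6$); this mirrors a census
restricted to an annotated region and keeps occupancy interpretable on
finite lattices.

`pAttach` is defined as the **per-head attachment probability**, so the
expected occupancy (attached / theoretical heads) equals `pAttach`; the
rigor default is 0.825, the occupancy recomputed from the printed counts
2,734 / 3,315. Internally molecules (not heads) are drawn, with
molecule-level class probabilities chosen so the *head-level* fractions
match the requested `fracSingle` (default 0.083) and `fracSplit`
(default 0.006): with $f_s$ the single and $f_{sp}$ the split head
fraction,

$$q_\text{single} = \frac{2 f_s}{1 + f_s},\qquad
  q_\text{split} = \frac{f_{sp}}{1 + f_s},\qquad
  p_\text{molecule} = p_\text{attach}\,(1 + f_s),$$

which gives $E[\text{heads}] = 2\,p_\text{attach}$ per molecule slot.
Double heads occupy same-strand adjacent subunits ($k$, $k+2$; 55.8 Å
apart); split heads occupy subunits on two different thin filaments
within a 60-Å axial window; a molecule whose preferred sites are
exhausted falls back to a single head (counted in
`metadata$binding$single_fallbacks`) rather than silently disappearing,
so occupancy tracks `pAttach` with only a small (<1 point) deficit.
The crown's axial capture range (`reach`, default 120 Å) reflects the
S2 flexibility that lets a head reach subunits away from its crown; the
default was chosen once as a round, physically plausible value giving
high placement success, and the rendered head centre sits 30 Å outside
its subunit along the subunit azimuth.

Because all thin filaments are grown in helical register with a common
phase and finite length, bound-orientation spans measured on synthetic
models sit slightly below the 120-degree gate: the azimuth values
available on a 200-nm filament form a discrete subset of the 0.2-degree
grid generated by the twist, and the extreme orientations near the gate
edges are not always represented. Spans of ~115 degrees on the default
30-filament A-band are the expected finite-size behaviour, not a defect.

# The binding-profile alphabet and alignment

For the footprint analysis each thin filament is split into its two
long-pitch strands and encoded over `{R, G, B, E}`: the neighbour label
of the binding head's thick filament, or `E` for myosin-free subunits.
Only strand 1 is aligned; strand 2 is carried through strand 1's gap
pattern, because consecutive genetic-helix subunits differ by 166.6
degrees in orientation and interleaving them destroys alignment signal.

The aligner is a Needleman-Wunsch global alignment with affine gaps over
a symmetric 4x4 substitution table, merged progressively by a
centre-star strategy (centre = maximal summed pairwise score, ties by
input order; "once a gap, always a gap"). The default weights reward
conserved hotspot colour and tolerate the abundant `E` background:
match +3, `E`-`E` +1, colour-colour mismatch -2, colour-`E` -1, gap open
-5, gap extend -1 (the first gap position costs the open penalty). These
defaults are declared package choices -- the weighting matrix used for
the original analysis was not published -- and are overridable through
`profileWeights()`. The pairwise core is verified in the test suite
against an exhaustive alignment enumerator and against an independent
aligner; the progressive merge preserves each row's optimal pairwise
alignment with the centre exactly.

One unit subtlety: the azimuthal eligibility pattern repeats every
$360 / (2(180 - |\varphi|)) = 13.4$ *strand positions*, which is ~75 nm
of one strand; the ~37-nm hotspot period emerges at the filament level
where the two interleaved strands alternate. Footprint autocorrelation
on synthetic profiles is therefore tested at 13-14 strand positions.

# Distance statistics

The bound/free thin-to-thick distance comparison uses the
three-measurements-per-subunit rule: a myosin-free subunit contributes
three free measurements (one per neighbour thick filament); a bound
subunit contributes one bound measurement (to the binder's filament) and
two free ones. Bookkeeping is exact: 3 x subunit count measurements,
always. `distanceSummary()` reports per-population mean, SD, and sample
skewness with a normal-reference z test (skewness / SE), and the
difference of means with a 95% CI -- Welch's normal approximation by
default, a seeded percentile bootstrap (10,000 reps) as an option; the
original report does not state its CI method, so both are provided.

# Z-disc geometry

`buildZdisc()` interdigitates two antiparallel thin-filament arrays
(barbed ends inside the disc, pointed tangents facing away) and places
alpha-actinin cross-links between laterally adjacent opposite-polarity
pairs. The generator takes the *link* geometry as primary -- rod length
33 nm (centre-to-centre distance minus the 6-nm actin diameter) and the
obtuse angle to the pointed end (~128 degrees in the thin disc form,
~158 in the thick) -- and derives the lateral spacing as
$(L + d)\sin\theta$, so more obtuse discs are laterally more compact, as
observed. Cross-link endpoints are placed exactly on the filament axes,
making `crosslinkGeometry()` a lossless round trip and the identity
`length + diameter = centre distance` exact to machine precision.

Anchors repeat at the 37.5-nm crossover pitch inside the overlap
(default `overlapLength` 75 nm = two pitches, giving three anchor rows);
each link spawns, with probability `doubletProb`, a partner on the
longitudinally adjacent same-strand subunit (axial offset
$2r = 5.58$ nm -- the 6-nm doublet). Ladder pairs are disjoint
(filaments 1-2, 3-4, ...), so each filament carries a single anchor
grid and the consecutive-spacing histogram shows interpretable peaks:
~5.6 nm within doublets and ~25 / ~31 / ~37.5 nm between them,
binned at 3 nm from zero. The doublet window is [3, 9) nm so the ideal
5.6-nm spacing is counted even though measured peaks are reported as
"6-9 nm"; the original binning origin is not stated, and this choice is
the package's.

Disc thickness is the axial extent of all cross-link binding sites
(where alpha-actinins bind the two antiparallel arrays), measured along
the filament axis -- a slice-based measurement of a tilted disc would
differ slightly, and a projected-angle mode is provided for
comparability. With fixed rod length, thickness grows strictly with the
hinge angle ($\Delta y = (L + d)\,|\cos\theta|$ per rung), which is the
parallel-hinge signature: across models, thickness and mean angle
correlate positively. Absolute thickness depends on `overlapLength`
(~99 nm at 128 degrees, ~111 at 158 for the default); the observed
80-100 nm range is matched in ordering, which is what the analysis
claims, not in absolute value.

# Tropomyosin states

Tropomyosin azimuthal state is abstracted to one angular offset per
subunit: the M (myosin-bound) state mean on the A-band side of the
boundary, the C (calcium-induced) state mean 21 degrees away on the
I-band side, plus Gaussian noise. The analysis mirrors the 37-nm
sectioning procedure: sections anchor at the A/I boundary and grow into
the I band (section 1 = last A-band section, section 2 = first I-band
section); each section's circular-mean offset is classified as the
nearer reference when within a 5-degree margin, otherwise
"intermediate". The margin is a package default standing in for a visual
classification of averaged maps. `locateTransition()` returns the first
non-M section; on sharp synthetic boundaries at most one intermediate
section appears, reproducing the observed M, intermediate, C, C pattern
with the transition completing within about one section. Note the
analysis operates on the angular abstraction, not on averaged densities:
passing it says the sectioning and classification logic is correct, not
that densities were averaged.

# Volumes, tracing, and their limits

`rasterizeVolume()` renders filaments as Gaussian tubes (SD =
`filamentRadius`), heads and cross-links as Gaussian blobs, with
amplitudes normalised so tubes peak at ~1 and rods at ~0.6; optional
white noise is added at a peak-SNR, and a hard angular missing-wedge
mask (tilt axis X, beam Z) can be applied in Fourier space. No CTF and
no realistic noise spectrum are modelled -- the renders exist to give the
tracing stage a volume whose ground truth is known exactly.

Tracing reimplements the picking cascade in-package: a 60-Å low-pass
(optional), an equatorial Fourier mask per XY slice that keeps
components with axial frequency $|f_y| \le$ `keepHalfwidth` (suppressing
axially periodic cross-bridge signal while preserving the DC term and
tube ridges; the filter is a projection, hence idempotent; the band
width used originally is unstated, so it is a config value), then
Laplacian-of-Gaussian blob detection per XZ plane with sub-voxel
quadratic refinement, then greedy plane-to-plane linking (step bound,
kink bound, ties by minimal direction change then lower x, gaps of up to
two planes bridged, minimum-length filter). A neural-network detector
was used originally; any detector satisfying the recovery oracle is
acceptable, and the LoG choice is deterministic. On noiseless renders
the cascade recovers all filaments with sub-voxel axis error;
`measureLattice()` then reproduces the 45-nm thick-thick and ~26-nm
thin-thick modes and a 6-fold bond-orientational order score of 1 for
perfect lattices.

What passing these tests shows -- and does not: the synthetic volumes
have isotropic Gaussian noise, straight filaments, and exact lattice
geometry. Real tomograms add CTF modulation, curvilinear filaments,
crowding, and anisotropic missing-wedge artefacts; recovery rates there
will be lower, and the package's defaults (detection threshold, kink and
step bounds) are starting points, not guarantees.

# Problem sizes and determinism

All shipped tests and the acceptance script run on one CPU in well under
two minutes combined: lattices up to 5 x 5 unit cells (30 thin
filaments, ~21,000 subunits), volumes up to ~10^6 voxels, alignments of
up to ~10 sequences of ~100 letters. These sizes were chosen as the
smallest at which the law-of-large-numbers checks are comfortably inside
their standard-error bounds. Every stochastic routine takes an integer
seed, stores it in its output, and is bitwise reproducible; the pipeline
derives per-stage seeds from the run seed by fixed offsets.

# Known limitations

* No mechanics: the hinge is geometric; no forces, elasticity, or
  dynamics.
* The generator's binding ignores inter-filament distance, so the small
  bound-vs-free distance preference is studied on explicitly simulated
  Gaussian populations at the printed parameters, not re-derived from
  lattice geometry.
* M-band, myosin-binding protein C, titin/nebulin, and troponin
  structure are out of scope.
* MRC support is mode-2 (float32) volumes only; STAR import reads
  coordinate loops and ignores Euler angles.
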