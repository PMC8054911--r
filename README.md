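# sarcotomo

Geometric and statistical analysis of striated-muscle sarcomere
architecture from 3D coordinate models — the kind produced by
cryo-electron tomography after filament annotation and subtomogram
averaging. The package is aimed at structural biologists who have (or
want to prototype against) coordinate-level sarcomere models: filament
axis traces, actin subunit positions, myosin head placements, and
α-actinin cross-links.

Because tomographic raw data are not desk-scale, every analysis is
paired with a synthetic ground-truth generator, so the whole pipeline is
verifiable without any data download.

## What it computes

**Actin helix arithmetic.** The thin filament is the genetic helix with
twist φ = −166.6° and rise r = 27.9 Å per subunit. Subunit k sits at
azimuth θ₀ + kφ (mod 360°); the crossover (half-helical) repeat holds
180/(180 − |φ|) ≈ 13.4 subunits ≈ 37.5 nm — the period of the
cross-bridge "target zones". `estimateHelicalParams()` recovers (φ, r)
from coordinates by a principal-axis fit and circular-mean twist.

**A-band census.** Thick filaments on a 45-nm hexagonal lattice, thin
filaments at the trigonal interstices (a/√3 ≈ 26 nm from three thick
neighbours). Myosin heads are budgeted at 6 per 14.3-nm crown and
assigned to actin subunits; occupancy = assigned / theoretical heads
(e.g. 2,734 / 3,315 = 82.5 %). Head topology is classified as
double-head (two heads, one filament), split-head (two heads, two
filaments), or single. Binding preference is quantified by the
orientation of bound subunits relative to the originating thick filament
(gated at ±60°, hence ~120° spans), by R/G/B/E binding-profile sequences
aligned with an affine-gap Needleman–Wunsch + centre-star multiple
alignment, and by bound-vs-free thin-to-thick distance statistics under
the three-measurements-per-subunit rule.

**Z-disc geometry.** Antiparallel thin filaments cross-linked by
α-actinin rods: length = centre distance − 6 nm actin diameter (≈33 nm),
obtuse angle to the pointed end (~128° thin form, ~158° thick form),
6-nm spacing doublets on longitudinally adjacent subunits, 3-nm-binned
spacing histograms, and the thickness–angle correlation that signals the
parallel-hinge behaviour of the disc.

**Tropomyosin states.** Per-subunit azimuthal offsets (M vs C state,
~21° apart) sectioned in 37-nm windows from the A/I boundary; the
transition localises to the first I-band section.

**Tracing.** Equatorial Fourier filtering of XY slices,
Laplacian-of-Gaussian cross-section detection in XZ planes with
sub-voxel refinement, and greedy linking into 3D traces; lattice
statistics (neighbour distances, 6-fold bond-orientational order) from
traces. MRC2014 volumes and STAR particle tables are supported for
interoperability.

## Worked example

```r
library(sarcotomo)

model <- buildLattice(LatticeSpec(nRows = 5, nCols = 5,
                                  axisLength = 200), seed = 1)
model <- simulateBinding(model, BindingSpec(), seed = 2)
model
#> SarcomereModel (A band)
#>   filaments : 30 thin, 25 thick
#>   subunits  : 2160 (975 myosin-bound)
#>   heads     : 975
#>   crosslinks: 0
#>   helix     : -166.6 deg / 27.9 A
#>   seed      : 2

b <- model@metadata$binding
occupancyCensus(nrow(myosinHeads(model)), b$theoretical_heads)$occupancyPct
#> [1] 83.04941

topo <- classifyHeadTopology(myosinHeads(model), b$theoretical_heads)
c(topo$pctSingleOfAttached, topo$pctSplitOfAttached)
#> [1] 8.5128205 0.2051282

ori <- boundOrientations(model)
angularDistribution(ori$orientation, ori$label)
#>   group   n circularMeanDeg spanDeg
#> 1     B 354       0.9435018   113.6
#> 2     G 305      -1.0364574   113.6
#> 3     R 316       1.7556937   119.4
```

Reading the numbers: the generator attached 975 of a 1,174-head budget
(83.0 % occupancy, matching the 0.825 per-head attachment probability),
8.5 % of attached heads are unpaired singles and 0.2 % sit in split
pairs; the bound-subunit orientations of each thick-filament group span
~114–119°, the finite-size realisation of the ±60° orientation gate.

The same vocabulary applies to Z-discs:

```r
zm  <- buildZdisc(ZdiscSpec(actininAngle = 128, doubletProb = 1), seed = 3)
geo <- crosslinkGeometry(zm)
range(geo$length_nm)        # 33 33  (centre distance minus 6 nm)
spacingAndDoublets(geo)$nDoublets
```

and `runPipeline(config)` drives simulate → (rasterize + trace) →
analyses from a YAML or list config, writing model tables and one
aggregated `report.json` deterministically per seed.

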