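#' @import methods
NULL

#' Actin helical symmetry parameters
#'
#' Per-subunit twist (degrees) and rise (Angstrom) of the actin genetic
#' helix, plus the azimuthal phase of subunit 0. Defaults are the helical
#' symmetry of the skeletal-muscle thin filament (-166.6 degrees, 27.9 A).
#'
#' @slot twist numeric, degrees per subunit, stored in (-180, 180].
#' @slot rise numeric, Angstrom per subunit, > 0.
#' @slot theta0 numeric, azimuth of subunit 0 in degrees.
#' @export
setClass("HelixSpec",
  representation(twist = "numeric", rise = "numeric", theta0 = "numeric"),
  prototype(twist = -166.6, rise = 27.9, theta0 = 0))

setValidity("HelixSpec", function(object) {
  msg <- character()
  if (length(object@rise) != 1L || !is.finite(object@rise) || object@rise <= 0)
    msg <- c(msg, "rise must be a single positive number (Angstrom)")
  if (length(object@twist) != 1L || !is.finite(object@twist) ||
      object@twist <= -180 || object@twist > 180)
    msg <- c(msg, "twist must lie in (-180, 180] degrees")
  if (length(object@theta0) != 1L || !is.finite(object@theta0))
    msg <- c(msg, "theta0 must be a single finite number")
  if (length(msg)) msg else TRUE
})

#' @param twist degrees per subunit in (-180, 180].
#' @param rise Angstrom per subunit, > 0.
#' @param theta0 azimuth of subunit 0, degrees.
#' @return A \code{HelixSpec} object.
#' @rdname HelixSpec-class
#' @examples
#' HelixSpec()               # thin-filament defaults
#' HelixSpec(twist = 120, rise = 30)
#' @export
HelixSpec <- function(twist = -166.6, rise = 27.9, theta0 = 0) {
  new("HelixSpec", twist = wrapTo180(twist), rise = rise, theta0 = theta0)
}

#' Filament lattice specification
#'
#' Geometry of a myofibril cross-section lattice. In the A band, thick
#' filaments sit on a triangular (hexagonal) lattice with spacing
#' \code{thickSpacing} (default 45 nm) and thin filaments occupy the two
#' trigonal interstices per unit cell, a/sqrt(3) ~ 26 nm from their three
#' nearest thick filaments.
#'
#' @slot thickSpacing numeric, nm, > 0.
#' @slot nRows,nCols integer counts of thick-filament lattice rows/columns.
#' @slot jitterSd numeric, nm, isotropic in-plane Gaussian displacement SD.
#' @slot band character, one of "A", "I", "Z".
#' @slot axisLength numeric, filament length along the axis, nm.
#' @export
setClass("LatticeSpec",
  representation(thickSpacing = "numeric", nRows = "integer",
                 nCols = "integer", jitterSd = "numeric",
                 band = "character", axisLength = "numeric"),
  prototype(thickSpacing = 45, nRows = 4L, nCols = 4L, jitterSd = 0,
            band = "A", axisLength = 200))

setValidity("LatticeSpec", function(object) {
  msg <- character()
  if (object@thickSpacing <= 0) msg <- c(msg, "thickSpacing must be > 0")
  if (object@jitterSd < 0) msg <- c(msg, "jitterSd must be >= 0")
  if (object@nRows < 1L || object@nCols < 1L)
    msg <- c(msg, "nRows and nCols must be >= 1")
  if (!object@band %in% c("A", "I", "Z"))
    msg <- c(msg, "band must be one of 'A', 'I', 'Z'")
  if (object@axisLength <= 0) msg <- c(msg, "axisLength must be > 0")
  if (length(msg)) msg else TRUE
})

#' @param thickSpacing nm, thick-thick lattice constant.
#' @param nRows,nCols lattice extent.
#' @param jitterSd nm, in-plane Gaussian jitter SD.
#' @param band sarcomere zone ("A", "I" or "Z").
#' @param axisLength nm, filament length.
#' @return A \code{LatticeSpec} object.
#' @rdname LatticeSpec-class
#' @export
LatticeSpec <- function(thickSpacing = 45, nRows = 4, nCols = 4,
                        jitterSd = 0, band = "A", axisLength = 200) {
  new("LatticeSpec", thickSpacing = thickSpacing,
      nRows = as.integer(nRows), nCols = as.integer(nCols),
      jitterSd = jitterSd, band = band, axisLength = axisLength)
}

#' Orientation-gated myosin binding specification
#'
#' Parameters of the stochastic cross-bridge model. A subunit is eligible
#' for heads from a neighbouring thick filament when its azimuth lies
#' within \code{gateHalfwidth} of the bearing toward that filament (the
#' observed confinement of bound-subunit orientations to a ~120 degree
#' range corresponds to the default half-width of 60 degrees).
#' \code{pAttach} is the per-head attachment probability, so the expected
#' head occupancy (attached / theoretical heads) equals \code{pAttach};
#' the rigor-state default is 0.825. \code{fracSingle} and
#' \code{fracSplit} are the target fractions of attached heads that are
#' unpaired singles (default 0.083) and members of split pairs bridging
#' two thin filaments (default 0.006).
#'
#' @slot gateHalfwidth degrees in (0, 180].
#' @slot pAttach,fracSingle,fracSplit probabilities.
#' @slot minPairGap integer, subunit-index gap of a double-head pair
#'   (2 = adjacent subunits on the same long-pitch strand).
#' @export
setClass("BindingSpec",
  representation(gateHalfwidth = "numeric", pAttach = "numeric",
                 fracSingle = "numeric", fracSplit = "numeric",
                 minPairGap = "integer"),
  prototype(gateHalfwidth = 60, pAttach = 0.825, fracSingle = 0.083,
            fracSplit = 0.006, minPairGap = 2L))

setValidity("BindingSpec", function(object) {
  msg <- character()
  p <- c(object@pAttach, object@fracSingle, object@fracSplit)
  if (any(p < 0 | p > 1))
    msg <- c(msg, "pAttach, fracSingle, fracSplit must lie in [0, 1]")
  if (object@fracSingle + object@fracSplit > 1)
    msg <- c(msg, "fracSingle + fracSplit must not exceed 1")
  if (object@gateHalfwidth <= 0 || object@gateHalfwidth > 180)
    msg <- c(msg, "gateHalfwidth must lie in (0, 180]")
  if (object@minPairGap < 1L) msg <- c(msg, "minPairGap must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @param gateHalfwidth degrees, orientation gate half-width.
#' @param pAttach per-head attachment probability.
#' @param fracSingle target single-head fraction of attached heads.
#' @param fracSplit target split-head fraction of attached heads.
#' @param minPairGap subunit gap for double-head pairing.
#' @return A \code{BindingSpec} object.
#' @rdname BindingSpec-class
#' @export
BindingSpec <- function(gateHalfwidth = 60, pAttach = 0.825,
                        fracSingle = 0.083, fracSplit = 0.006,
                        minPairGap = 2) {
  new("BindingSpec", gateHalfwidth = gateHalfwidth, pAttach = pAttach,
      fracSingle = fracSingle, fracSplit = fracSplit,
      minPairGap = as.integer(minPairGap))
}

#' Z-disc cross-link specification
#'
#' Geometry of alpha-actinin cross-links between antiparallel thin
#' filaments. \code{actininLength} is the rod length (default 33 nm,
#' centre-to-centre distance minus the 6-nm actin diameter);
#' \code{actininAngle} the obtuse angle between the cross-link axis and
#' the filament tangent toward the pointed end (observed range roughly
#' 125-160 degrees; default 128, the thin Z-disc form).
#' \code{doubletProb} is the probability that a cross-link is accompanied
#' by a partner on the longitudinally adjacent same-strand subunit
#' (axial offset 2 x rise ~ 5.6 nm). \code{overlapLength} is the axial
#' interdigitation of the two antiparallel arrays.
#'
#' @slot actininLength nm, > actinDiameter... rod length.
#' @slot actininAngle degrees, in (90, 180).
#' @slot doubletProb probability.
#' @slot actinDiameter nm (default 6).
#' @slot overlapLength nm.
#' @export
setClass("ZdiscSpec",
  representation(actininLength = "numeric", actininAngle = "numeric",
                 doubletProb = "numeric", actinDiameter = "numeric",
                 overlapLength = "numeric"),
  prototype(actininLength = 33, actininAngle = 128, doubletProb = 0.5,
            actinDiameter = 6, overlapLength = 74))

setValidity("ZdiscSpec", function(object) {
  msg <- character()
  if (object@actininAngle <= 90 || object@actininAngle >= 180)
    msg <- c(msg, "actininAngle must lie in (90, 180) degrees")
  if (object@actininLength <= object@actinDiameter)
    msg <- c(msg, "actininLength must exceed actinDiameter")
  if (object@doubletProb < 0 || object@doubletProb > 1)
    msg <- c(msg, "doubletProb must lie in [0, 1]")
  if (object@overlapLength <= 0) msg <- c(msg, "overlapLength must be > 0")
  if (length(msg)) msg else TRUE
})

#' @param actininLength nm.
#' @param actininAngle degrees, obtuse.
#' @param doubletProb probability of a 6-nm doublet partner.
#' @param actinDiameter nm.
#' @param overlapLength nm, antiparallel interdigitation.
#' @return A \code{ZdiscSpec} object.
#' @rdname ZdiscSpec-class
#' @export
ZdiscSpec <- function(actininLength = 33, actininAngle = 128,
                      doubletProb = 0.5, actinDiameter = 6,
                      overlapLength = 74) {
  new("ZdiscSpec", actininLength = actininLength,
      actininAngle = actininAngle, doubletProb = doubletProb,
      actinDiameter = actinDiameter, overlapLength = overlapLength)
}

## empty-table prototypes keep column schemas in one place
## (defined before the class so the prototype can evaluate them)
emptyFilaments <- function()
  data.frame(id = integer(), kind = character(), polarity = character(),
             x = numeric(), z = numeric(), y0 = numeric(), y1 = numeric())
emptyPoints <- function()
  data.frame(filament_id = integer(), point_index = integer(),
             x = numeric(), y = numeric(), z = numeric())
emptySubunits <- function()
  data.frame(filament_id = integer(), k = integer(), x = numeric(),
             y = numeric(), z = numeric(), azimuth = numeric(),
             strand = integer(), bound = logical(),
             tpm_offset = numeric())
emptyHeads <- function()
  data.frame(myosin_id = integer(), head_slot = character(),
             origin_thick_id = integer(), filament_id = integer(),
             subunit_k = integer(), class = character(),
             x = numeric(), y = numeric(), z = numeric())
emptyCrosslinks <- function()
  data.frame(id = integer(), fil_a = integer(), fil_b = integer(),
             ya = numeric(), yb = numeric(), cx = numeric(),
             cy = numeric(), cz = numeric(),
             center_distance_nm = numeric(), length_nm = numeric(),
             angle_deg = numeric(), doublet_of = integer())
emptyNeighbors <- function()
  data.frame(thin_id = integer(), thick_id = integer(),
             label = character(), bearing_deg = numeric())

#' Sarcomere coordinate model
#'
#' Container for one ground-truth or analysed sarcomere coordinate model:
#' filament axes, actin subunits, myosin heads, alpha-actinin cross-links,
#' thin-to-thick neighbour assignments, and the generating specifications.
#' All coordinates are Angstrom; the filament axis is +Y.
#'
#' @slot filaments data.frame: id, kind ("thin"/"thick"), polarity,
#'   x, z (axis position, A), y0, y1 (axial extent, A).
#' @slot points data.frame: filament_id, point_index, x, y, z (A) --
#'   ordered axis polylines.
#' @slot subunits data.frame: filament_id, k, x, y, z (A), azimuth (deg),
#'   strand (0/1), bound (logical), tpm_offset (deg, NA until assigned).
#' @slot heads data.frame: myosin_id, head_slot ("a"/"b"),
#'   origin_thick_id, filament_id, subunit_k, class
#'   ("double"/"single"/"split"), x, y, z (A).
#' @slot crosslinks data.frame: id, fil_a, fil_b, ya, yb (binding-site
#'   axial coords, A), cx, cy, cz (centre, A), center_distance_nm,
#'   length_nm, angle_deg, doublet_of (id of partner or NA).
#' @slot neighbors data.frame: thin_id, thick_id, label ("R"/"G"/"B"),
#'   bearing_deg.
#' @slot helix a \code{HelixSpec}.
#' @slot lattice a \code{LatticeSpec}.
#' @slot zdisc a \code{ZdiscSpec} (Z-band models).
#' @slot seed integer RNG seed the model was generated from (NA if none).
#' @slot metadata list of free-form provenance entries.
#' @export
setClass("SarcomereModel",
  representation(filaments = "data.frame", points = "data.frame",
                 subunits = "data.frame", heads = "data.frame",
                 crosslinks = "data.frame", neighbors = "data.frame",
                 helix = "HelixSpec", lattice = "LatticeSpec",
                 zdisc = "ZdiscSpec", seed = "integer",
                 metadata = "list"),
  prototype(filaments = emptyFilaments(), points = emptyPoints(),
            subunits = emptySubunits(), heads = emptyHeads(),
            crosslinks = emptyCrosslinks(), neighbors = emptyNeighbors(),
            seed = NA_integer_, metadata = list()))

setValidity("SarcomereModel", function(object) {
  msg <- character()
  fil <- object@filaments
  if (nrow(object@subunits) &&
      !all(object@subunits$filament_id %in% fil$id))
    msg <- c(msg, "subunits reference unknown filaments")
  h <- object@heads
  if (nrow(h)) {
    if (!all(h$origin_thick_id %in% fil$id[fil$kind == "thick"]))
      msg <- c(msg, "heads reference unknown thick filaments")
    key <- paste(h$filament_id, h$subunit_k)
    if (anyDuplicated(key))
      msg <- c(msg, "more than one head bound to a single subunit")
    tab <- table(h$myosin_id)
    if (any(tab > 2))
      msg <- c(msg, "a myosin molecule has more than two heads")
    skey <- paste(object@subunits$filament_id, object@subunits$k)
    if (!all(key %in% skey))
      msg <- c(msg, "heads reference unknown subunits")
  }
  cl <- object@crosslinks
  if (nrow(cl) && !all(c(cl$fil_a, cl$fil_b) %in% fil$id))
    msg <- c(msg, "crosslinks reference unknown filaments")
  if (length(msg)) msg else TRUE
})

#' Accessors for SarcomereModel
#'
#' @param object,x a \code{SarcomereModel}.
#' @return The corresponding component table (a data.frame), spec object,
#'   or seed.
#' @name SarcomereModel-accessors
#' @aliases filaments subunits myosinHeads crossLinks thinNeighbors
#'   modelSeed
NULL

#' @rdname SarcomereModel-accessors
#' @export
setGeneric("filaments", function(object) standardGeneric("filaments"))
#' @rdname SarcomereModel-accessors
#' @export
setMethod("filaments", "SarcomereModel", function(object) object@filaments)

#' @rdname SarcomereModel-accessors
#' @export
setGeneric("subunits", function(object) standardGeneric("subunits"))
#' @rdname SarcomereModel-accessors
#' @export
setMethod("subunits", "SarcomereModel", function(object) object@subunits)

#' @rdname SarcomereModel-accessors
#' @export
setGeneric("myosinHeads", function(object) standardGeneric("myosinHeads"))
#' @rdname SarcomereModel-accessors
#' @export
setMethod("myosinHeads", "SarcomereModel", function(object) object@heads)

#' @rdname SarcomereModel-accessors
#' @export
setGeneric("crossLinks", function(object) standardGeneric("crossLinks"))
#' @rdname SarcomereModel-accessors
#' @export
setMethod("crossLinks", "SarcomereModel", function(object) object@crosslinks)

#' @rdname SarcomereModel-accessors
#' @export
setGeneric("thinNeighbors", function(object) standardGeneric("thinNeighbors"))
#' @rdname SarcomereModel-accessors
#' @export
setMethod("thinNeighbors", "SarcomereModel", function(object) object@neighbors)

#' @rdname SarcomereModel-accessors
#' @export
setGeneric("modelSeed", function(object) standardGeneric("modelSeed"))
#' @rdname SarcomereModel-accessors
#' @export
setMethod("modelSeed", "SarcomereModel", function(object) object@seed)

setMethod("show", "SarcomereModel", function(object) {
  fil <- object@filaments
  cat(sprintf("SarcomereModel (%s band)\n",
              if (nrow(fil) && any(fil$kind == "thick")) object@lattice@band
              else object@lattice@band))
  cat(sprintf("  filaments : %d thin, %d thick\n",
              sum(fil$kind == "thin"), sum(fil$kind == "thick")))
  cat(sprintf("  subunits  : %d (%d myosin-bound)\n",
              nrow(object@subunits), sum(object@subunits$bound)))
  cat(sprintf("  heads     : %d\n", nrow(object@heads)))
  cat(sprintf("  crosslinks: %d\n", nrow(object@crosslinks)))
  cat(sprintf("  helix     : %.1f deg / %.1f A\n",
              object@helix@twist, object@helix@rise))
  cat(sprintf("  seed      : %s\n", as.character(object@seed)))
  invisible(NULL)
})

setMethod("show", "HelixSpec", function(object) {
  cat(sprintf("HelixSpec: twist %.2f deg, rise %.2f A, theta0 %.2f deg\n",
              object@twist, object@rise, object@theta0))
})

#' Rasterised tomogram-like volume
#'
#' A dense 3D grid of densities with voxel size (Angstrom) and origin.
#' Array dimensions are (x, y, z); the filament axis of models rendered
#' by \code{\link{rasterizeVolume}} is +Y, and tomogram-style XY slices
#' are \code{vol[, , iz]}.
#'
#' @slot data 3D numeric array.
#' @slot voxelSize numeric, A per voxel (isotropic).
#' @slot origin numeric length-3, A coordinate of voxel (1,1,1) centre.
#' @export
setClass("TomoVolume",
  representation(data = "array", voxelSize = "numeric",
                 origin = "numeric"),
  prototype(data = array(0, c(1, 1, 1)), voxelSize = 1,
            origin = c(0, 0, 0)))

setValidity("TomoVolume", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3) msg <- c(msg, "data must be 3D")
  if (object@voxelSize <= 0) msg <- c(msg, "voxelSize must be > 0")
  if (length(object@origin) != 3) msg <- c(msg, "origin must be length 3")
  if (length(msg)) msg else TRUE
})

#' @param data 3D array.
#' @param voxelSize A per voxel.
#' @param origin A, coordinate of the first voxel centre.
#' @return A \code{TomoVolume}.
#' @rdname TomoVolume-class
#' @export
TomoVolume <- function(data, voxelSize = 1, origin = c(0, 0, 0)) {
  new("TomoVolume", data = data, voxelSize = voxelSize, origin = origin)
}

setMethod("show", "TomoVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("TomoVolume: %d x %d x %d voxels @ %.2f A\n",
              d[1], d[2], d[3], object@voxelSize))
})

#' @rdname TomoVolume-class
#' @param object a \code{TomoVolume}.
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))
#' @rdname TomoVolume-class
#' @export
setMethod("voxelSize", "TomoVolume", function(object) object@voxelSize)
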