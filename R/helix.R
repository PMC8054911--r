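#' Angle wrapping utilities
#'
#' \code{wrapTo360} wraps angles to [0, 360); \code{wrapTo180} wraps to
#' (-180, 180]. Used throughout: azimuths are reported in [0, 360),
#' angular differences in (-180, 180].
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector of wrapped angles.
#' @examples
#' wrapTo360(-166.6)  # 193.4
#' wrapTo180(190)     # -170
#' @export
wrapTo360 <- function(x) {
  y <- x %% 360
  ## guard the floating edge cases: %% of a tiny negative returns 360
  y[y < 0] <- y[y < 0] + 360
  y[y >= 360] <- y[y >= 360] - 360
  y
}

#' @rdname wrapTo360
#' @export
wrapTo180 <- function(x) {
  y <- wrapTo360(x)
  y[y > 180] <- y[y > 180] - 360
  y
}

#' Azimuth of the k-th subunit of an actin helix
#'
#' The genetic helix places subunit k at azimuth theta0 + k * twist,
#' wrapped to [0, 360).
#'
#' @param k integer subunit index (>= 0), vectorised.
#' @param theta0 azimuth of subunit 0, degrees.
#' @param helix a \code{\link{HelixSpec}}.
#' @return azimuths in degrees, [0, 360).
#' @examples
#' subunitAzimuth(1)   # 193.4 for the default -166.6 deg twist
#' subunitAzimuth(2)   # 26.8
#' @export
subunitAzimuth <- function(k, theta0 = helix@theta0, helix = HelixSpec()) {
  stopifnot(all(k >= 0), all(k == floor(k)))
  wrapTo360(theta0 + k * helix@twist)
}

#' Crossover (half-helical) repeat of an actin filament
#'
#' Two long-pitch strands cross over every 180/(180 - |twist|) subunits;
#' for the thin-filament symmetry (-166.6 deg, 27.9 A) this is ~13.4
#' subunits, a repeat length of ~37.5 nm -- the familiar "~37 nm / ~13
#' subunit" target-zone period.
#'
#' @param helix a \code{\link{HelixSpec}}.
#' @return list with \code{subunitsPerHalfRepeat} and
#'   \code{repeatLengthNm}.
#' @examples
#' crossoverRepeat()  # 13.43 subunits, 37.5 nm
#' @export
crossoverRepeat <- function(helix = HelixSpec()) {
  if (abs(abs(helix@twist) - 180) < 1e-9)
    stop("crossover repeat undefined for twist = +/-180 degrees")
  n <- 180 / (180 - abs(helix@twist))
  list(subunitsPerHalfRepeat = n,
       repeatLengthNm = n * helix@rise / 10)
}

#' In-plane bearing from one axis point toward another
#'
#' The bearing is the azimuthal direction, in the plane normal to the
#' filament axis, from \code{from} toward \code{to}: degrees in
#' [0, 360), counter-clockwise from +X (for the +Y axis convention this
#' is \code{atan2(dz, dx)}).
#'
#' @param from,to numeric length-3 points (A) or n x 3 matrices.
#' @param axis filament axis unit vector (default +Y).
#' @return bearings in degrees, [0, 360).
#' @export
bearingAngle <- function(from, to, axis = c(0, 1, 0)) {
  from <- rbind(from); to <- rbind(to)
  d <- to - from
  a <- axis / sqrt(sum(axis^2))
  ## project out the axial component, express in the (e1, e2) frame
  ## with e2 = e1 x axis (so that for axis = +Y, bearing = atan2(dz, dx))
  ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 0, 1)
  e1 <- ref - sum(ref * a) * a
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(e1[2] * a[3] - e1[3] * a[2],
          e1[3] * a[1] - e1[1] * a[3],
          e1[1] * a[2] - e1[2] * a[1])
  u <- d %*% e1
  v <- d %*% e2
  if (any(abs(u) < 1e-12 & abs(v) < 1e-12))
    stop("coincident axes: bearing undefined")
  wrapTo360(atan2(v, u) * 180 / pi)
}

#' Orientation of a subunit relative to a neighbouring thick filament
#'
#' Wrapped difference between the subunit azimuth and the bearing from
#' the thin-filament axis to the thick-filament axis, in (-180, 180].
#' A value of 0 means the subunit faces the thick filament exactly.
#'
#' @param azimuth subunit azimuth(s), degrees.
#' @param bearing bearing(s) toward the thick filament, degrees (see
#'   \code{\link{bearingAngle}}).
#' @return degrees in (-180, 180].
#' @examples
#' relativeOrientation(10, 10)    # 0
#' relativeOrientation(200, 10)   # -170
#' @export
relativeOrientation <- function(azimuth, bearing) {
  wrapTo180(azimuth - bearing)
}

#' Estimate helical parameters from ordered subunit coordinates
#'
#' Least-squares style recovery of twist and rise from one filament's
#' subunit positions: the axis is the principal direction of the
#' coordinates (or +/-Y by default orientation), rise is the mean
#' consecutive axial spacing, and twist is the circular mean of
#' consecutive azimuth increments with sign preserved. Azimuths are
#' measured in the (e1, e2 = e1 x axis) frame so that a filament grown
#' with \code{\link{growFilament}} round-trips exactly; \code{flip}
#' selects the opposite handedness convention.
#'
#' @param coords n x 3 matrix of subunit coordinates (A), in subunit
#'   order.
#' @param flip logical; negate the azimuth frame handedness.
#' @return list with \code{twist} (deg, (-180, 180]) and \code{rise} (A).
#' @export
estimateHelicalParams <- function(coords, flip = FALSE) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 2) stop("need at least 2 subunits")
  if (anyDuplicated(coords)) stop("duplicated subunit coordinates")
  ctr <- colMeans(coords)
  cc <- sweep(coords, 2, ctr)
  a <- prcomp(cc)$rotation[, 1]
  ## orient the axis along increasing subunit order
  if (sum((coords[nrow(coords), ] - coords[1, ]) * a) < 0) a <- -a
  axial <- drop(cc %*% a)
  if (is.unsorted(axial, strictly = FALSE) && is.unsorted(rev(axial)))
    stop("subunits are not ordered along the axis")
  ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 0, 1)
  e1 <- ref - sum(ref * a) * a
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(e1[2] * a[3] - e1[3] * a[2],
          e1[3] * a[1] - e1[1] * a[3],
          e1[1] * a[2] - e1[2] * a[1])
  if (flip) e2 <- -e2
  az <- atan2(drop(cc %*% e2), drop(cc %*% e1)) * 180 / pi
  dAz <- wrapTo180(diff(az))
  twist <- atan2(mean(sin(dAz * pi / 180)),
                 mean(cos(dAz * pi / 180))) * 180 / pi
  list(twist = wrapTo180(twist), rise = mean(diff(axial)))
}

#' Circular mean of angles
#'
#' @param x angles in degrees.
#' @param wrap "360" for [0, 360) or "180" for (-180, 180].
#' @return circular mean in degrees.
#' @export
circularMean <- function(x, wrap = c("360", "180")) {
  wrap <- match.arg(wrap)
  m <- atan2(mean(sin(x * pi / 180)), mean(cos(x * pi / 180))) * 180 / pi
  if (wrap == "360") wrapTo360(m) else wrapTo180(m)
}
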