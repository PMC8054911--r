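## Filament tracing from tomogram-like volumes: equatorial Fourier
## filtering of XY slices, Laplacian-of-Gaussian cross-section detection
## in XZ planes, and greedy plane-to-plane linking into 3D traces.

#' Equatorial Fourier filter of XY slices
#'
#' For each XY slice of the volume (filament axis +Y), Fourier
#' components whose axial frequency |f_y| exceeds \code{keepHalfwidth}
#' (cycles per voxel) are zeroed, retaining the equatorial band that
#' carries the filament lattice signal and suppressing axially periodic
#' features such as cross-bridges. The DC component is always kept;
#' \code{keepHalfwidth = 0.5} is the identity. The filter is a
#' projection, hence idempotent.
#'
#' @param vol a \code{\link{TomoVolume}}.
#' @param keepHalfwidth band half-width as a spatial-frequency fraction,
#'   in (0, 0.5].
#' @return a filtered \code{TomoVolume} of the same shape.
#' @export
equatorFilter <- function(vol, keepHalfwidth = 0.1) {
  if (keepHalfwidth <= 0 || keepHalfwidth > 0.5)
    stop("keepHalfwidth must lie in (0, 0.5]")
  d <- dim(vol@data)
  fy <- .fftFreq(d[2])
  keep <- abs(fy) <= keepHalfwidth + 1e-12
  out <- vol@data
  for (iz in seq_len(d[3])) {
    ft <- stats::fft(out[, , iz])
    ft[, !keep] <- 0
    out[, , iz] <- Re(stats::fft(ft, inverse = TRUE)) / (d[1] * d[2])
  }
  TomoVolume(out, voxelSize = vol@voxelSize, origin = vol@origin)
}

#' Low-pass filter a volume
#'
#' Hard spherical low-pass in Fourier space at a given resolution
#' (default 60 A), the usual pre-processing before filament picking.
#'
#' @param vol a \code{\link{TomoVolume}}.
#' @param resolution cutoff resolution (A).
#' @return filtered \code{TomoVolume}.
#' @export
lowpassVolume <- function(vol, resolution = 60) {
  d <- dim(vol@data)
  fx <- .fftFreq(d[1]) / vol@voxelSize
  fy <- .fftFreq(d[2]) / vol@voxelSize
  fz <- .fftFreq(d[3]) / vol@voxelSize
  r2 <- outer(outer(fx^2, fy^2, "+"), fz^2, "+")
  ft <- stats::fft(vol@data)
  ft[r2 > (1 / resolution)^2] <- 0
  TomoVolume(Re(stats::fft(ft, inverse = TRUE)) / prod(d),
             voxelSize = vol@voxelSize, origin = vol@origin)
}

#' Detect filament cross-sections in XZ planes
#'
#' Per XZ plane (fixed Y index), convolves with a Laplacian-of-Gaussian
#' kernel of scale \code{blobSigma} and returns local maxima above
#' \code{threshold} (relative to the plane's maximum response when
#' \code{relative = TRUE}) with sub-voxel quadratic refinement.
#'
#' @param vol a \code{\link{TomoVolume}} (ideally equator-filtered).
#' @param blobSigma blob scale (A); must be at least the voxel size.
#' @param threshold detection threshold; with \code{relative = TRUE} a
#'   fraction of the per-volume maximum response.
#' @param relative logical, interpret threshold as a fraction.
#' @param planeStride use every \code{planeStride}-th XZ plane.
#' @return data.frame of detections: plane_index, x, y, z (A), response.
#' @export
detectCrossSections <- function(vol, blobSigma = 50, threshold = 0.3,
                                relative = TRUE, planeStride = 1L) {
  if (blobSigma < vol@voxelSize)
    stop("blobSigma must be >= the voxel size")
  d <- dim(vol@data)
  if (d[1] < 4 || d[3] < 4) stop("volume too small in X/Z")
  n1 <- d[1]; n3 <- d[3]
  sig <- blobSigma / vol@voxelSize
  kx <- .fftFreq(n1) * n1
  kz <- .fftFreq(n3) * n3
  r2 <- outer(kx^2, kz^2, "+")
  g <- exp(-r2 / (2 * sig^2))
  ker <- -(r2 - 2 * sig^2) / sig^4 * g
  ker <- ker - mean(ker)
  fker <- stats::fft(ker)
  planes <- seq(1L, d[2], by = as.integer(planeStride))
  resp <- array(NA_real_, c(n1, length(planes), n3))
  for (j in seq_along(planes)) {
    img <- vol@data[, planes[j], ]
    resp[, j, ] <- Re(stats::fft(stats::fft(img) * fker,
                                 inverse = TRUE)) / (n1 * n3)
  }
  thr <- if (relative) threshold * max(resp) else threshold
  out <- list()
  for (j in seq_along(planes)) {
    r <- resp[, j, ]
    ## 8-neighbour local maxima, excluding the one-voxel border
    ctr <- r[2:(n1 - 1), 2:(n3 - 1)]
    ismax <- ctr > thr &
      ctr >= r[1:(n1 - 2), 2:(n3 - 1)] & ctr >= r[3:n1, 2:(n3 - 1)] &
      ctr >= r[2:(n1 - 1), 1:(n3 - 2)] & ctr >= r[2:(n1 - 1), 3:n3] &
      ctr >= r[1:(n1 - 2), 1:(n3 - 2)] & ctr >= r[3:n1, 3:n3] &
      ctr >= r[1:(n1 - 2), 3:n3] & ctr >= r[3:n1, 1:(n3 - 2)]
    idx <- which(ismax, arr.ind = TRUE)
    if (!nrow(idx)) next
    ix <- idx[, 1] + 1L; iz <- idx[, 2] + 1L
    ## sub-voxel quadratic refinement, axis by axis
    dx <- (r[cbind(ix - 1L, iz)] - r[cbind(ix + 1L, iz)]) /
      (2 * (r[cbind(ix - 1L, iz)] - 2 * r[cbind(ix, iz)] +
              r[cbind(ix + 1L, iz)]))
    dz <- (r[cbind(ix, iz - 1L)] - r[cbind(ix, iz + 1L)]) /
      (2 * (r[cbind(ix, iz - 1L)] - 2 * r[cbind(ix, iz)] +
              r[cbind(ix, iz + 1L)]))
    dx[!is.finite(dx)] <- 0; dz[!is.finite(dz)] <- 0
    dx <- pmin(pmax(dx, -0.5), 0.5); dz <- pmin(pmax(dz, -0.5), 0.5)
    out[[length(out) + 1L]] <- data.frame(
      plane_index = planes[j],
      x = vol@origin[1] + (ix - 1 + dx) * vol@voxelSize,
      y = vol@origin[2] + (planes[j] - 1) * vol@voxelSize,
      z = vol@origin[3] + (iz - 1 + dz) * vol@voxelSize,
      response = r[cbind(ix, iz)])
  }
  if (!length(out))
    return(data.frame(plane_index = integer(), x = numeric(),
                      y = numeric(), z = numeric(),
                      response = numeric()))
  res <- do.call(rbind, out)
  res[order(res$plane_index, res$x, res$z), , drop = FALSE]
}

#' Link per-plane detections into filament traces
#'
#' Greedy nearest-neighbour linking of detections from successive XZ
#' planes into 3D polylines. A detection extends a trace when its
#' in-plane displacement from the trace's predicted position is at most
#' \code{maxStep} (per plane of gap) and the direction change is at most
#' \code{maxKink}. Ties are broken by minimal direction change, then by
#' lower x. Gaps of up to \code{maxGap} missing planes are bridged.
#' Traces shorter than \code{minLength} along Y are discarded.
#'
#' @param detections data.frame from \code{\link{detectCrossSections}}.
#' @param maxStep maximum in-plane step between consecutive planes (A).
#' @param maxKink maximum direction change (degrees).
#' @param minLength minimum trace extent along Y (A).
#' @param maxGap maximum number of bridged missing planes.
#' @return data.frame of trace points: trace_id, point_index, x, y, z.
#' @export
linkDetections <- function(detections, maxStep = 60, maxKink = 20,
                           minLength = 500, maxGap = 2L) {
  if (!nrow(detections)) return(data.frame(trace_id = integer(),
                                           point_index = integer(),
                                           x = numeric(), y = numeric(),
                                           z = numeric()))
  planes <- sort(unique(detections$y))
  ## plane pitch inferred from the detection grid: gaps are measured in
  ## multiples of it, so planes with no detections still count as gaps
  pitch <- if (length(planes) > 1) min(diff(planes)) else 1
  traces <- list()   # each: list(pts = matrix(x,y,z), open = TRUE)
  for (p in planes) {
    det <- detections[detections$y == p, , drop = FALSE]
    det <- det[order(det$x, det$z), , drop = FALSE]
    used <- rep(FALSE, nrow(det))
    openIdx <- which(vapply(traces, function(tr) tr$open, TRUE))
    ## most recently extended traces first (deterministic order)
    for (ti in openIdx) {
      tr <- traces[[ti]]
      last <- tr$pts[nrow(tr$pts), ]
      gap <- p - last[2]
      nskip <- max(0L, round(gap / pitch) - 1L)
      if (nskip > maxGap) { traces[[ti]]$open <- FALSE; next }
      lim <- maxStep * (nskip + 1)
      cand <- which(!used)
      if (!length(cand)) next
      dd <- sqrt((det$x[cand] - last[1])^2 + (det$z[cand] - last[3])^2)
      ok <- dd <= lim
      if (!any(ok)) next
      cand <- cand[ok]; dd <- dd[ok]
      ## direction change relative to the previous step
      kink <- rep(0, length(cand))
      if (nrow(tr$pts) >= 2) {
        prev <- tr$pts[nrow(tr$pts) - 1, ]
        v0 <- last - prev
        for (q in seq_along(cand)) {
          v1 <- c(det$x[cand[q]], p, det$z[cand[q]]) - last
          cosang <- sum(v0 * v1) /
            (sqrt(sum(v0^2)) * sqrt(sum(v1^2)))
          kink[q] <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
        }
        keep <- kink <= maxKink
        if (!any(keep)) next
        cand <- cand[keep]; dd <- dd[keep]; kink <- kink[keep]
      }
      o <- order(round(kink, 6), det$x[cand])
      pick <- cand[o[1]]
      traces[[ti]]$pts <- rbind(tr$pts,
                                c(det$x[pick], p, det$z[pick]))
      used[pick] <- TRUE
    }
    for (q in which(!used))
      traces[[length(traces) + 1L]] <-
        list(pts = matrix(c(det$x[q], p, det$z[q]), 1, 3), open = TRUE)
  }
  traces <- Filter(function(tr)
    nrow(tr$pts) >= 2 &&
      (max(tr$pts[, 2]) - min(tr$pts[, 2])) >= minLength, traces)
  if (!length(traces)) return(data.frame(trace_id = integer(),
                                         point_index = integer(),
                                         x = numeric(), y = numeric(),
                                         z = numeric()))
  do.call(rbind, lapply(seq_along(traces), function(i) {
    m <- traces[[i]]$pts
    data.frame(trace_id = i, point_index = seq_len(nrow(m)) - 1L,
               x = m[, 1], y = m[, 2], z = m[, 3])
  }))
}

.traceAt <- function(tracePts, y) {
  ## linear interpolation of each trace at axial position y
  out <- lapply(split(tracePts, tracePts$trace_id), function(tp) {
    if (y < min(tp$y) || y > max(tp$y)) return(NULL)
    data.frame(trace_id = tp$trace_id[1],
               kind = if ("kind" %in% names(tp)) tp$kind[1] else "unknown",
               x = stats::approx(tp$y, tp$x, y, ties = mean)$y,
               z = stats::approx(tp$y, tp$z, y, ties = mean)$y)
  })
  do.call(rbind, out)
}

#' Lattice statistics of traced filaments at a cross-section
#'
#' Interpolates each trace at \code{planePosition}, computes
#' nearest-neighbour distance distributions (thick-thick and
#' thin-to-thick when kinds are available, otherwise all-to-all), and a
#' 6-fold bond-orientational (hexagonal) order score: the mean over
#' points of the resultant length of exp(6 i theta) over each point's
#' neighbours within 1.3 x the median nearest-neighbour distance.
#'
#' @param tracePts data.frame with trace_id, x, y, z and optionally kind
#'   ("thin"/"thick").
#' @param planePosition axial position of the cross-section (A).
#' @return list with \code{thickThickNm}, \code{thinThickNm} (numeric
#'   vectors of nearest-neighbour distances, nm) and
#'   \code{hexOrder}.
#' @export
measureLattice <- function(tracePts, planePosition) {
  sec <- .traceAt(tracePts, planePosition)
  if (is.null(sec) || nrow(sec) < 3)
    stop("need at least 3 traces crossing the plane")
  xy <- cbind(sec$x, sec$z)
  dmat <- as.matrix(stats::dist(xy))
  diag(dmat) <- Inf
  kinds <- sec$kind
  thick <- which(kinds == "thick")
  thin <- which(kinds == "thin")
  tt <- if (length(thick) >= 2)
    apply(dmat[thick, thick, drop = FALSE], 1, min) / NM else numeric()
  tn <- if (length(thin) >= 1 && length(thick) >= 1)
    apply(dmat[thin, thick, drop = FALSE], 1, min) / NM else numeric()
  allNN <- apply(dmat, 1, min)
  ## psi-6 over the thick sub-lattice when present, else all points
  pts <- if (length(thick) >= 3) thick else seq_len(nrow(sec))
  dsub <- dmat[pts, pts, drop = FALSE]
  cutoff <- 1.3 * stats::median(apply(dsub, 1, min))
  psi <- vapply(seq_along(pts), function(i) {
    nbr <- which(dsub[i, ] <= cutoff)
    if (!length(nbr)) return(NA_real_)
    th <- atan2(xy[pts[nbr], 2] - xy[pts[i], 2],
                xy[pts[nbr], 1] - xy[pts[i], 1])
    Mod(mean(exp(6i * th)))
  }, numeric(1))
  list(thickThickNm = unname(tt), thinThickNm = unname(tn),
       allNearestNm = unname(allNN) / NM,
       hexOrder = mean(psi, na.rm = TRUE))
}

#' Trace filaments in a volume (detection + linking)
#'
#' Convenience wrapper: optional 60-A low-pass, equatorial filtering,
#' cross-section detection and linking with consistent defaults.
#'
#' @param vol a \code{\link{TomoVolume}}.
#' @param keepHalfwidth equatorial band half-width (fraction).
#' @param blobSigma detector scale (A).
#' @param threshold relative detection threshold.
#' @param maxStep,maxKink,minLength,maxGap linking parameters.
#' @param lowpass optional low-pass resolution (A) applied first, or
#'   NULL.
#' @return data.frame of trace points (see
#'   \code{\link{linkDetections}}).
#' @export
traceFilaments <- function(vol, keepHalfwidth = 0.1, blobSigma = 50,
                           threshold = 0.3, maxStep = 60, maxKink = 20,
                           minLength = 500, maxGap = 2L,
                           lowpass = NULL) {
  if (!is.null(lowpass)) vol <- lowpassVolume(vol, lowpass)
  filt <- equatorFilter(vol, keepHalfwidth)
  det <- detectCrossSections(filt, blobSigma = blobSigma,
                             threshold = threshold)
  linkDetections(det, maxStep = maxStep, maxKink = maxKink,
                 minLength = minLength, maxGap = maxGap)
}
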