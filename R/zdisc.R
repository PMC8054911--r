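## Z-disc geometry: alpha-actinin cross-link detection between
## antiparallel thin filaments, link length and pointed-end angle,
## spacing histograms with 6-nm doublet detection, disc thickness and
## the thickness-angle ("parallel hinge") correlation.

#' Detect alpha-actinin cross-link candidates
#'
#' In coordinates mode (no volume), candidate cross-links are taken
#' from the model table after validating that each connects an
#' opposite-polarity filament pair. With a volume, candidate midpoints
#' sampled along each opposite-polarity neighbour pair's overlap are
#' scored by local mean intensity and thresholded.
#'
#' @param model a Z-disc \code{\link{SarcomereModel}}.
#' @param vol optional \code{\link{TomoVolume}} rasterised from a
#'   compatible model.
#' @param maxLateralNm maximum lateral pair spacing to consider (nm).
#' @param threshold relative intensity threshold (volume mode).
#' @param stepNm axial sampling step along the overlap (volume mode).
#' @return data.frame of cross-link candidates (columns as the model's
#'   crosslinks table; volume-mode candidates carry fil_a, fil_b, ya,
#'   yb, cx, cy, cz and score).
#' @export
detectCrosslinks <- function(model, vol = NULL, maxLateralNm = 45,
                             threshold = 0.5, stepNm = 1) {
  fil <- model@filaments
  pairs <- NULL
  if (nrow(fil) >= 2) {
    cmb <- utils::combn(fil$id, 2)
    for (c0 in seq_len(ncol(cmb))) {
      i <- match(cmb[1, c0], fil$id); j <- match(cmb[2, c0], fil$id)
      if (fil$polarity[i] == fil$polarity[j]) next
      dlat <- sqrt((fil$x[i] - fil$x[j])^2 + (fil$z[i] - fil$z[j])^2)
      if (dlat > maxLateralNm * NM) next
      lo <- max(fil$y0[i], fil$y0[j]); hi <- min(fil$y1[i], fil$y1[j])
      if (hi <= lo) next
      pairs <- rbind(pairs, data.frame(a = fil$id[i], b = fil$id[j],
                                       lo = lo, hi = hi, dlat = dlat))
    }
  }
  if (is.null(pairs)) {
    warning("no overlapping antiparallel filament pairs found")
    return(emptyCrosslinks())
  }
  if (is.null(vol)) {
    cl <- model@crosslinks
    pk <- c(paste(pairs$a, pairs$b), paste(pairs$b, pairs$a))
    ok <- paste(cl$fil_a, cl$fil_b) %in% pk
    if (any(!ok)) warning(sum(!ok),
                          " cross-links rejected: not antiparallel")
    return(cl[ok, , drop = FALSE])
  }
  ## volume mode: score sampled midpoints by local intensity
  d <- dim(vol@data)
  peak <- max(vol@data)
  out <- NULL
  for (p in seq_len(nrow(pairs))) {
    i <- match(pairs$a[p], fil$id); j <- match(pairs$b[p], fil$id)
    ## tilted links reach past the strict overlap window by up to one
    ## link length, so sample a 40-nm margin on both sides
    ys <- seq(pairs$lo[p] - 40 * NM, pairs$hi[p] + 40 * NM,
              by = stepNm * NM)
    mx <- (fil$x[i] + fil$x[j]) / 2
    mz <- (fil$z[i] + fil$z[j]) / 2
    iv <- function(x, y, z) {
      ix <- round((x - vol@origin[1]) / vol@voxelSize) + 1
      iy <- round((y - vol@origin[2]) / vol@voxelSize) + 1
      iz <- round((z - vol@origin[3]) / vol@voxelSize) + 1
      if (ix < 1 || iy < 1 || iz < 1 || ix > d[1] || iy > d[2] ||
          iz > d[3]) return(0)
      vol@data[ix, iy, iz]
    }
    sc <- vapply(ys, function(y) iv(mx, y, mz), numeric(1))
    hit <- sc > threshold * peak
    if (!any(hit)) next
    ## collapse runs of consecutive hits to their best sample
    runs <- split(which(hit), cumsum(c(1, diff(which(hit)) > 1)))
    for (rn in runs) {
      best <- rn[which.max(sc[rn])]
      out <- rbind(out, data.frame(
        fil_a = pairs$a[p], fil_b = pairs$b[p],
        ya = ys[best], yb = ys[best],
        cx = mx, cy = ys[best], cz = mz, score = sc[best]))
    }
  }
  if (is.null(out)) {
    warning("no cross-link candidates above threshold")
    return(data.frame())
  }
  cbind(id = seq_len(nrow(out)), out)
}

#' Geometry of alpha-actinin cross-links
#'
#' Recomputes, per link, the centre-to-centre distance between the two
#' filament axes along the link axis, the rod length (centre distance
#' minus the actin diameter), and the angle between the link axis and
#' the filament tangent oriented toward the pointed end (obtuse by
#' definition; exact 90-degree links are flagged). By default the angle
#' is measured in 3D; \code{projected = TRUE} measures it in the
#' projection onto the plane containing the filament axis and the
#' lateral offset (slice-like measurement).
#'
#' @param model a Z-disc \code{\link{SarcomereModel}} (for filament
#'   axes and polarities).
#' @param links data.frame of cross-links (default: the model's table).
#' @param actinDiameterNm actin filament diameter subtracted from the
#'   centre distance (nm).
#' @param projected logical; 2D projected angle instead of 3D.
#' @return the links table with recomputed center_distance_nm,
#'   length_nm, angle_deg and a logical \code{perpendicular} flag.
#' @export
crosslinkGeometry <- function(model, links = crossLinks(model),
                              actinDiameterNm = 6, projected = FALSE) {
  fil <- model@filaments
  if (!nrow(links)) return(links)
  ia <- match(links$fil_a, fil$id); ib <- match(links$fil_b, fil$id)
  if (anyNA(ia) || anyNA(ib)) stop("links reference unknown filaments")
  pa <- cbind(fil$x[ia], links$ya, fil$z[ia])
  pb <- cbind(fil$x[ib], links$yb, fil$z[ib])
  v <- pb - pa
  cd <- sqrt(rowSums(v^2))
  if (any(cd < 1e-9)) stop("degenerate zero-length cross-link axis")
  ## tangent of filament a toward its pointed end:
  ## "plus" polarity = barbed toward +Y, so pointed tangent is -Y
  tp <- ifelse(fil$polarity[ia] %in% c("plus", "plus_toward_z_disc"),
               -1, 1)
  if (projected) {
    ## project the link into the (lateral, axial) plane of filament a
    lat <- sqrt(v[, 1]^2 + v[, 3]^2)
    ang <- atan2(lat, v[, 2] * tp) * 180 / pi
  } else {
    cosang <- (v[, 2] * tp) / cd
    ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  }
  links$center_distance_nm <- cd / NM
  links$length_nm <- cd / NM - actinDiameterNm
  links$angle_deg <- ang
  links$perpendicular <- abs(ang - 90) < 1e-6
  if (any(links$length_nm < 0))
    warning("some links shorter than the actin diameter")
  links
}

#' Cross-link spacing histogram and doublet census
#'
#' Per filament, collects consecutive axial spacings between cross-link
#' binding sites (both ends of every link contribute to the filament
#' they touch), histograms them in 3-nm bins, and counts doublets --
#' spacings in the [3, 9) nm window, which captures the ideal
#' longitudinally-adjacent-subunit spacing of 2 x rise ~ 5.6 nm.
#' Also reports doublet pairs per 37-nm window of crosslinked filament
#' span.
#'
#' @param links cross-links table (from the model or
#'   \code{\link{detectCrosslinks}}).
#' @param binWidthNm histogram bin width (nm).
#' @param doubletWindowNm numeric length-2, spacing window counted as a
#'   doublet (nm).
#' @return list: \code{spacingsNm}, \code{histogram} (counts),
#'   \code{breaksNm}, \code{nDoublets}, \code{doubletsPer37nm}.
#' @export
spacingAndDoublets <- function(links, binWidthNm = 3,
                               doubletWindowNm = c(3, 9)) {
  sites <- rbind(data.frame(fil = links$fil_a, y = links$ya),
                 data.frame(fil = links$fil_b, y = links$yb))
  sp <- unlist(lapply(split(sites$y, sites$fil), function(y) {
    if (length(y) < 2) return(numeric())
    diff(sort(y)) / NM
  }), use.names = FALSE)
  if (!length(sp))
    return(list(spacingsNm = numeric(), histogram = integer(),
                breaksNm = numeric(), nDoublets = 0L,
                doubletsPer37nm = NA_real_))
  breaks <- seq(0, ceiling(max(sp) / binWidthNm) * binWidthNm,
                by = binWidthNm)
  h <- graphics::hist(sp, breaks = breaks, plot = FALSE,
                      right = FALSE)
  nD <- sum(sp >= doubletWindowNm[1] & sp < doubletWindowNm[2])
  span <- sum(vapply(split(sites$y, sites$fil), function(y)
    if (length(y) < 2) 0 else diff(range(y)), numeric(1))) / NM
  list(spacingsNm = sp, histogram = h$counts, breaksNm = h$breaks,
       nDoublets = nD,
       doubletsPer37nm = if (span > 0) nD / (span / 37) else NA_real_)
}

#' Z-disc thickness
#'
#' Axial extent of the cross-linked zone: the distance along the
#' filament axis between the outermost cross-link binding sites on the
#' two antiparallel arrays (where alpha-actinins bind the filaments).
#'
#' @param model a Z-disc \code{\link{SarcomereModel}}.
#' @param links cross-links table (default the model's).
#' @return thickness in nm.
#' @export
zdiscThickness <- function(model, links = crossLinks(model)) {
  if (!nrow(links)) return(NA_real_)
  ys <- c(links$ya, links$yb)
  (max(ys) - min(ys)) / NM
}

#' Thickness vs alpha-actinin angle across Z-disc models
#'
#' For each model, measures the disc thickness and the mean cross-link
#' angle to the pointed end, then correlates thickness against angle
#' across models (Pearson and Spearman). A positive correlation is the
#' signature of the parallel-hinge behaviour: more obtuse angles open
#' the linkage and thicken the disc.
#'
#' @param models list of Z-disc \code{\link{SarcomereModel}}s.
#' @return list: \code{perModel} data.frame (thicknessNm, meanAngleDeg),
#'   \code{pearson}, \code{spearman} (NA with a message when undefined).
#' @export
thicknessAndHinge <- function(models) {
  pm <- do.call(rbind, lapply(models, function(m) {
    geo <- crosslinkGeometry(m)
    data.frame(thicknessNm = zdiscThickness(m),
               meanAngleDeg = mean(geo$angle_deg))
  }))
  out <- list(perModel = pm, pearson = NA_real_, spearman = NA_real_)
  if (nrow(pm) < 2) {
    message("fewer than 2 models: correlation skipped")
    return(out)
  }
  if (stats::sd(pm$thicknessNm) == 0 || stats::sd(pm$meanAngleDeg) == 0) {
    message("zero variance across models: correlation undefined")
    return(out)
  }
  out$pearson <- stats::cor(pm$thicknessNm, pm$meanAngleDeg)
  out$spearman <- stats::cor(pm$thicknessNm, pm$meanAngleDeg,
                             method = "spearman")
  out
}
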