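## Synthetic sarcomere generator: ground-truth coordinate models with the
## statistical structure the downstream analyses assume. Internal unit is
## Angstrom; user-facing lattice/length parameters are nm. Filament axis
## is +Y; cross-sections are XZ planes.

NM <- 10  # Angstrom per nm

.orthoFrame <- function(axis) {
  a <- axis / sqrt(sum(axis^2))
  ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 0, 1)
  e1 <- ref - sum(ref * a) * a
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(e1[2] * a[3] - e1[3] * a[2],
          e1[3] * a[1] - e1[1] * a[3],
          e1[1] * a[2] - e1[2] * a[1])
  list(a = a, e1 = e1, e2 = e2)
}

#' Grow an actin filament as a table of subunits
#'
#' Places subunit k at axial offset k * rise along \code{axis} from
#' \code{origin}, at azimuth theta0 + k * twist (wrapped to [0, 360)),
#' displaced radially by \code{radius} so that coordinates encode the
#' helix. Strand parity is k mod 2 (the two long-pitch strands).
#'
#' @param origin length-3 axis point of subunit 0 (A).
#' @param axis filament axis direction (need not be unit length).
#' @param nSubunits number of subunits (>= 1).
#' @param helix a \code{\link{HelixSpec}}.
#' @param theta0 azimuth of subunit 0 (deg); defaults to the helix phase.
#' @param radius radial offset of subunit centres from the axis (A).
#' @return data.frame with k, x, y, z, azimuth, strand.
#' @examples
#' su <- growFilament(c(0, 0, 0), c(0, 1, 0), 14)
#' diff(su$y)[1]  # 27.9 A rise
#' @export
growFilament <- function(origin, axis, nSubunits, helix = HelixSpec(),
                         theta0 = helix@theta0, radius = 25) {
  if (sqrt(sum(axis^2)) < 1e-12) stop("axis vector must be non-zero")
  if (nSubunits < 1) stop("nSubunits must be >= 1")
  fr <- .orthoFrame(axis)
  k <- seq_len(nSubunits) - 1L
  az <- wrapTo360(theta0 + k * helix@twist)
  axial <- k * helix@rise
  pos <- outer(axial, fr$a) +
    radius * (outer(cos(az * pi / 180), fr$e1) +
              outer(sin(az * pi / 180), fr$e2))
  pos <- sweep(pos, 2, origin, "+")
  data.frame(k = k, x = pos[, 1], y = pos[, 2], z = pos[, 3],
             azimuth = az, strand = as.integer(k %% 2L))
}

.axisPoints <- function(id, x, z, y0, y1, stepA = 100) {
  n <- max(2L, as.integer(ceiling((y1 - y0) / stepA)) + 1L)
  y <- seq(y0, y1, length.out = n)
  data.frame(filament_id = id, point_index = seq_len(n) - 1L,
             x = x, y = y, z = z)
}

#' Build a filament lattice model
#'
#' Constructs an A-band (or I-band) cross-section lattice: thick
#' filaments on a triangular lattice with spacing
#' \code{lattice@thickSpacing}, thin filaments at the two trigonal
#' interstitial positions of each unit cell (distance a/sqrt(3) from the
#' three surrounding thick filaments; ~26 nm for a 45-nm lattice).
#' In-plane Gaussian jitter displaces whole filaments. Each thin
#' filament records its three nearest thick neighbours with stable
#' "R"/"G"/"B" labels (ascending bearing). Thin filaments carry actin
#' subunits grown in helical register (common phase); in the I band
#' no thick filaments are emitted.
#'
#' @param lattice a \code{\link{LatticeSpec}}.
#' @param helix a \code{\link{HelixSpec}}.
#' @param seed integer RNG seed (stored in the model).
#' @param subunitRadius radial offset of subunit centres (A).
#' @return A \code{\link{SarcomereModel}}.
#' @examples
#' m <- buildLattice(LatticeSpec(nRows = 3, nCols = 3))
#' table(filaments(m)$kind)
#' @export
buildLattice <- function(lattice = LatticeSpec(), helix = HelixSpec(),
                         seed = NULL, subunitRadius = 25) {
  validObject(lattice)
  if (!is.null(seed)) set.seed(seed)
  a <- lattice@thickSpacing * NM
  h <- a * sqrt(3) / 2
  rows <- seq_len(lattice@nRows) - 1L
  cols <- seq_len(lattice@nCols) - 1L
  thick <- do.call(rbind, lapply(rows, function(i) {
    data.frame(x = cols * a + (i %% 2) * a / 2, z = i * h)
  }))
  key <- function(x, z) sprintf("%.2f_%.2f", x, z)
  tset <- key(thick$x, thick$z)
  ## interstitial (trigonal) sites: centroids of up and down triangles
  thin <- NULL
  for (r in seq_len(nrow(thick))) {
    x <- thick$x[r]; z <- thick$z[r]
    if (all(key(c(x + a, x + a / 2), c(z, z + h)) %in% tset))
      thin <- rbind(thin, data.frame(x = x + a / 2, z = z + h / 3))
    if (all(key(c(x + a, x + a / 2, x + 3 * a / 2),
                c(z, z + h, z + h)) %in% tset))
      thin <- rbind(thin, data.frame(x = x + a, z = z + 2 * h / 3))
  }
  if (is.null(thin)) thin <- data.frame(x = numeric(), z = numeric())
  nThick <- if (lattice@band == "I") 0L else nrow(thick)
  nThin <- nrow(thin)
  if (nThin == 0L)
    stop("lattice too small to contain interstitial thin filaments; ",
         "increase nRows/nCols")
  jit <- function(n) if (lattice@jitterSd > 0)
    matrix(stats::rnorm(2 * n, 0, lattice@jitterSd * NM), ncol = 2)
  else matrix(0, n, 2)
  lenA <- lattice@axisLength * NM
  fil <- data.frame(
    id = seq_len(nThick + nThin),
    kind = c(rep("thick", nThick), rep("thin", nThin)),
    polarity = "plus_toward_z_disc",
    x = c(if (nThick) thick$x, thin$x),
    z = c(if (nThick) thick$z, thin$z),
    y0 = 0, y1 = lenA)
  jm <- jit(nrow(fil))
  fil$x <- fil$x + jm[, 1]
  fil$z <- fil$z + jm[, 2]
  pts <- do.call(rbind, lapply(seq_len(nrow(fil)), function(i)
    .axisPoints(fil$id[i], fil$x[i], fil$z[i], fil$y0[i], fil$y1[i])))
  nSub <- as.integer(floor(lenA / helix@rise)) + 1L
  thinIds <- fil$id[fil$kind == "thin"]
  sub <- do.call(rbind, lapply(thinIds, function(id) {
    g <- growFilament(c(fil$x[fil$id == id], 0, fil$z[fil$id == id]),
                      c(0, 1, 0), nSub, helix, radius = subunitRadius)
    cbind(data.frame(filament_id = id), g)
  }))
  sub$bound <- FALSE
  sub$tpm_offset <- NA_real_
  ## three nearest thick neighbours of each thin filament
  nb <- NULL
  if (nThick >= 3L) {
    tf <- fil[fil$kind == "thick", ]
    for (id in thinIds) {
      px <- fil$x[fil$id == id]; pz <- fil$z[fil$id == id]
      d <- sqrt((tf$x - px)^2 + (tf$z - pz)^2)
      o <- order(d)[1:3]
      br <- wrapTo360(atan2(tf$z[o] - pz, tf$x[o] - px) * 180 / pi)
      ord <- order(br)
      nb <- rbind(nb, data.frame(thin_id = id, thick_id = tf$id[o][ord],
                                 label = c("R", "G", "B"),
                                 bearing_deg = br[ord]))
    }
  }
  if (is.null(nb)) nb <- emptyNeighbors()
  new("SarcomereModel", filaments = fil, points = pts, subunits = sub,
      heads = emptyHeads(), crosslinks = emptyCrosslinks(),
      neighbors = nb, helix = helix, lattice = lattice,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      metadata = list(generator = "buildLattice"))
}

#' Simulate orientation-gated myosin binding
#'
#' Draws myosin molecules head by head from each thick filament's crown
#' budget (6 heads / 3 molecules per 14.3 nm crown) and attaches them to
#' actin subunits of neighbouring thin filaments. A subunit is eligible
#' for a given thick filament when its azimuth is within
#' \code{spec@gateHalfwidth} of the bearing toward that filament and it
#' is not already occupied. Molecules attach with probability
#' pAttach * (1 + fracSingle) and are classed single / split / double
#' with probabilities chosen so the head-level single and split
#' fractions equal \code{fracSingle} and \code{fracSplit} (see the
#' methods vignette); expected head occupancy equals \code{pAttach}.
#' Double heads occupy same-strand adjacent subunits (k, k + 2); split
#' heads occupy subunits on two different thin filaments.
#'
#' @param model an A-band \code{\link{SarcomereModel}} from
#'   \code{\link{buildLattice}}.
#' @param spec a \code{\link{BindingSpec}}.
#' @param seed integer RNG seed.
#' @param reach axial capture range of a crown (A).
#' @param headOffset radial offset of the rendered head centre from its
#'   subunit, along the subunit azimuth (A).
#' @return the model with a populated heads table, subunit bound flags,
#'   and census metadata (theoretical head count, unplaced molecules).
#' @export
simulateBinding <- function(model, spec = BindingSpec(), seed = NULL,
                            reach = 120, headOffset = 30) {
  validObject(spec)
  fil <- model@filaments
  if (sum(fil$kind == "thin") < 1 || sum(fil$kind == "thick") < 3)
    stop("need an A-band model with >= 1 thin and >= 3 thick filaments")
  if (!is.null(seed)) set.seed(seed)
  sub <- model@subunits
  nb <- model@neighbors
  gate <- spec@gateHalfwidth
  gap <- spec@minPairGap
  fs <- spec@fracSingle; fsp <- spec@fracSplit
  qS <- 2 * fs / (1 + fs)          # molecule-level class probabilities
  qP <- fsp / (1 + fs)
  pMol <- min(1, spec@pAttach * (1 + fs))

  ## eligibility lists per (thin, thick) pair, subunit rows sorted by y
  elig <- list()
  for (r in seq_len(nrow(nb))) {
    rows <- which(sub$filament_id == nb$thin_id[r])
    keep <- abs(wrapTo180(sub$azimuth[rows] - nb$bearing_deg[r])) <= gate
    rows <- rows[keep]
    elig[[paste(nb$thin_id[r], nb$thick_id[r])]] <-
      rows[order(sub$y[rows])]
  }
  occupied <- rep(FALSE, nrow(sub))
  subK <- sub$k; subY <- sub$y; subFil <- sub$filament_id

  thickIds <- fil$id[fil$kind == "thick"]
  crownA <- 143  # 14.3 nm crown spacing
  nNbr <- table(factor(nb$thick_id, levels = thickIds))
  mol <- NULL
  for (tid in thickIds) {
    len <- fil$y1[fil$id == tid] - fil$y0[fil$id == tid]
    nCrown <- floor(len / crownA)
    if (nCrown < 1) next
    ## full budget is 3 molecules (6 heads) per crown; at the lattice
    ## boundary only the fraction facing modelled thin filaments
    ## (nNbr of 6 interstitial neighbours) is budgeted, mirroring a
    ## census restricted to the annotated region
    nMol <- round(3 * nCrown * nNbr[[as.character(tid)]] / 6)
    if (nMol < 1) next
    yC <- fil$y0[fil$id == tid] + (seq_len(nCrown) - 0.5) * crownA
    mol <- rbind(mol, data.frame(thick = tid,
                                 y = rep_len(yC, nMol)))
  }
  if (is.null(mol) || !nrow(mol))
    stop("no myosin crowns fit the thick filament length")
  nTheo <- 2L * nrow(mol)
  mol <- mol[sample.int(nrow(mol)), , drop = FALSE]
  thinOf <- split(nb$thin_id, nb$thick_id)

  heads <- vector("list", nrow(mol))
  nHeads <- 0L; myoId <- 0L; unplaced <- 0L; fallbacks <- 0L
  freeRows <- function(tid, fid, y) {
    rows <- elig[[paste(fid, tid)]]
    if (is.null(rows)) return(integer())
    rows <- rows[abs(subY[rows] - y) <= reach]
    rows[!occupied[rows]]
  }
  for (i in seq_len(nrow(mol))) {
    if (stats::runif(1) >= pMol) next
    u <- stats::runif(1)
    cls <- if (u < qS) "single" else if (u < qS + qP) "split" else "double"
    tid <- mol$thick[i]; yC <- mol$y[i]
    fils <- thinOf[[as.character(tid)]]
    if (is.null(fils)) { unplaced <- unplaced + 1L; next }
    fils <- sample(fils)
    placed <- FALSE
    fellBack <- FALSE
    myoId <- myoId + 1L
    if (cls == "double") {
      for (fid in fils) {
        rows <- freeRows(tid, fid, yC)
        if (length(rows) < 2) next
        kk <- subK[rows]
        j <- match(kk + gap, kk)         # partner at k + gap, same strand
        cand <- which(!is.na(j))
        if (!length(cand)) next
        pick <- cand[sample.int(length(cand), 1)]
        r1 <- rows[pick]; r2 <- rows[j[pick]]
        heads[[myoId]] <- data.frame(
          myosin_id = myoId, head_slot = c("a", "b"),
          origin_thick_id = tid, filament_id = fid,
          subunit_k = subK[c(r1, r2)], class = "double")
        occupied[c(r1, r2)] <- TRUE
        placed <- TRUE; break
      }
    } else if (cls == "split") {
      if (length(fils) >= 2) {
        prs <- utils::combn(fils, 2, simplify = FALSE)
        for (pr in prs[sample.int(length(prs))]) {
          ra <- freeRows(tid, pr[1], yC); rb <- freeRows(tid, pr[2], yC)
          if (!length(ra) || !length(rb)) next
          r1 <- ra[sample.int(length(ra), 1)]
          db <- abs(subY[rb] - subY[r1])
          rb <- rb[db <= 60]              # the two heads stay within reach
          if (!length(rb)) next
          r2 <- rb[sample.int(length(rb), 1)]
          heads[[myoId]] <- data.frame(
            myosin_id = myoId, head_slot = c("a", "b"),
            origin_thick_id = tid,
            filament_id = c(subFil[r1], subFil[r2]),
            subunit_k = subK[c(r1, r2)], class = "split")
          occupied[c(r1, r2)] <- TRUE
          placed <- TRUE; break
        }
      }
    }
    if (!placed && cls != "single") { cls <- "single"; fellBack <- TRUE }
    if (!placed && cls == "single") {
      for (fid in fils) {
        rows <- freeRows(tid, fid, yC)
        if (!length(rows)) next
        r1 <- rows[sample.int(length(rows), 1)]
        heads[[myoId]] <- data.frame(
          myosin_id = myoId, head_slot = "a", origin_thick_id = tid,
          filament_id = fid, subunit_k = subK[r1], class = "single")
        occupied[r1] <- TRUE
        placed <- TRUE; break
      }
      if (placed && fellBack) fallbacks <- fallbacks + 1L
    }
    if (!placed) { unplaced <- unplaced + 1L; myoId <- myoId - 1L }
  }
  hd <- do.call(rbind, heads[!vapply(heads, is.null, TRUE)])
  if (is.null(hd)) hd <- emptyHeads() else {
    idx <- match(paste(hd$filament_id, hd$subunit_k),
                 paste(subFil, subK))
    azr <- sub$azimuth[idx] * pi / 180
    hd$x <- sub$x[idx] + headOffset * cos(azr)
    hd$y <- sub$y[idx]
    hd$z <- sub$z[idx] + headOffset * sin(azr)
    hd <- hd[order(hd$myosin_id, hd$head_slot), ]
    rownames(hd) <- NULL
  }
  sub$bound <- occupied
  model@subunits <- sub
  model@heads <- hd
  model@metadata$binding <- list(
    theoretical_heads = nTheo, attached_heads = nrow(hd),
    unplaced_molecules = unplaced, single_fallbacks = fallbacks,
    spec = spec)
  if (!is.null(seed)) model@seed <- as.integer(seed)
  validObject(model)
  model
}

#' Build a Z-disc model of antiparallel cross-linked filaments
#'
#' Two interdigitated antiparallel thin-filament arrays (alternating
#' along X within each row) connected by alpha-actinin cross-links of
#' length \code{spec@actininLength} at the obtuse angle
#' \code{spec@actininAngle} to the pointed end. The lateral filament
#' spacing is derived from the link geometry,
#' (length + actin diameter) * sin(angle), so more obtuse (thicker-form)
#' discs are laterally more compact. Cross-links are anchored at the
#' crossover-repeat pitch (~37 nm) within the overlap; with probability
#' \code{spec@doubletProb} a doublet partner is added on the
#' longitudinally adjacent same-strand subunit (axial offset 2 x rise,
#' ~5.6 nm). Endpoint coordinates lie on the filament axes, so link
#' geometry is exact by construction and recoverable by
#' \code{\link{crosslinkGeometry}}.
#'
#' @param spec a \code{\link{ZdiscSpec}}.
#' @param lattice a \code{\link{LatticeSpec}} (nRows rows of
#'   2 x nCols alternating-polarity filaments; jitterSd applied in-plane).
#' @param helix a \code{\link{HelixSpec}}.
#' @param seed integer RNG seed.
#' @return A \code{\link{SarcomereModel}} with band "Z".
#' @export
buildZdisc <- function(spec = ZdiscSpec(),
                       lattice = LatticeSpec(nRows = 2, nCols = 3,
                                             band = "Z"),
                       helix = HelixSpec(), seed = NULL) {
  validObject(spec)
  if (!is.null(seed)) set.seed(seed)
  th <- spec@actininAngle * pi / 180
  D <- (spec@actininLength + spec@actinDiameter) * NM  # centre distance
  u <- D * sin(th)                # lateral spacing (A)
  delta <- -D * cos(th)           # axial link offset (A), > 0 (obtuse)
  O <- spec@overlapLength * NM
  ext <- 500
  nPerRow <- 2L * lattice@nCols
  fil <- NULL
  for (i in seq_len(lattice@nRows) - 1L) {
    for (m in seq_len(nPerRow) - 1L) {
      left <- m %% 2L == 0L        # TRUE: barbed +Y (sarcomere below)
      fil <- rbind(fil, data.frame(
        kind = "thin", polarity = if (left) "plus" else "minus",
        x = m * u, z = i * 1.5 * u,
        y0 = if (left) -O / 2 - ext else -O / 2,
        y1 = if (left) O / 2 else O / 2 + ext))
    }
  }
  fil <- cbind(data.frame(id = seq_len(nrow(fil))), fil)
  if (lattice@jitterSd > 0) {
    jm <- matrix(stats::rnorm(2 * nrow(fil), 0, lattice@jitterSd * NM),
                 ncol = 2)
    fil$x <- fil$x + jm[, 1]; fil$z <- fil$z + jm[, 2]
  }
  pts <- do.call(rbind, lapply(seq_len(nrow(fil)), function(i)
    .axisPoints(fil$id[i], fil$x[i], fil$z[i], fil$y0[i], fil$y1[i])))
  nSub <- as.integer(floor((O + ext) / helix@rise)) + 1L
  sub <- do.call(rbind, lapply(seq_len(nrow(fil)), function(i) {
    up <- fil$polarity[i] == "plus"   # k grows toward the barbed end
    g <- growFilament(c(fil$x[i], if (up) fil$y0[i] else fil$y1[i],
                        fil$z[i]),
                      c(0, if (up) 1 else -1, 0), nSub, helix,
                      theta0 = stats::runif(1, 0, 360))
    cbind(data.frame(filament_id = fil$id[i]), g)
  }))
  sub$bound <- FALSE
  sub$tpm_offset <- NA_real_
  ## cross-links between laterally adjacent opposite-polarity filaments;
  ## disjoint ladder pairs (1-2, 3-4, ...) so each filament carries a
  ## single 37-nm anchor grid and spacing peaks stay interpretable
  pitch <- crossoverRepeat(helix)$repeatLengthNm * NM
  dblOff <- 2 * helix@rise
  links <- NULL; lid <- 0L
  for (i in seq_len(lattice@nRows) - 1L) {
    base <- i * nPerRow
    for (m in seq(1L, nPerRow - 1L, by = 2L)) {
      aIdx <- base + m; bIdx <- base + m + 1L
      if (fil$polarity[aIdx] == fil$polarity[bIdx]) next
      ## anchor on the "plus" (barbed-up) member so delta points +Y
      if (fil$polarity[aIdx] != "plus") { tmp <- aIdx; aIdx <- bIdx; bIdx <- tmp }
      yA <- O / 2 - (0:floor(O / pitch)) * pitch
      yA <- yA[yA >= -O / 2 & yA + delta <= fil$y1[bIdx]]
      for (y in yA) {
        lid <- lid + 1L
        links <- rbind(links, data.frame(
          id = lid, fil_a = fil$id[aIdx], fil_b = fil$id[bIdx],
          ya = y, yb = y + delta, doublet_of = NA_integer_))
        if (stats::runif(1) < spec@doubletProb) {
          sgn <- if (stats::runif(1) < 0.5) -1 else 1
          y2 <- y + sgn * dblOff
          if (y2 >= -O / 2 && y2 <= O / 2) {
            links <- rbind(links, data.frame(
              id = lid + 1L, fil_a = fil$id[aIdx], fil_b = fil$id[bIdx],
              ya = y2, yb = y2 + delta, doublet_of = lid))
            lid <- lid + 1L
          }
        }
      }
    }
  }
  if (is.null(links)) cl <- emptyCrosslinks() else {
    ax <- fil$x[links$fil_a]; az <- fil$z[links$fil_a]
    bx <- fil$x[links$fil_b]; bz <- fil$z[links$fil_b]
    cd <- sqrt((bx - ax)^2 + (bz - az)^2 + (links$yb - links$ya)^2)
    cl <- data.frame(
      id = links$id, fil_a = links$fil_a, fil_b = links$fil_b,
      ya = links$ya, yb = links$yb,
      cx = (ax + bx) / 2, cy = (links$ya + links$yb) / 2,
      cz = (az + bz) / 2,
      center_distance_nm = cd / NM,
      length_nm = cd / NM - spec@actinDiameter,
      angle_deg = spec@actininAngle, doublet_of = links$doublet_of)
  }
  lattice@band <- "Z"
  new("SarcomereModel", filaments = fil, points = pts, subunits = sub,
      heads = emptyHeads(), crosslinks = cl, neighbors = emptyNeighbors(),
      helix = helix, lattice = lattice, zdisc = spec,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      metadata = list(generator = "buildZdisc"))
}

#' Assign tropomyosin azimuthal states along thin filaments
#'
#' Subunits on the A-band side of \code{boundary} (lower Y; the barbed
#' end faces the Z-disc at +Y) receive the myosin-bound M-state mean
#' offset \code{refM}; subunits on the I-band side receive the
#' Ca2+-induced C-state mean \code{refM + stateOffset} (the two states
#' differ by an azimuthal rotation of ~21 degrees). Gaussian angular
#' noise of SD \code{noiseSd} is added.
#'
#' @param model a \code{\link{SarcomereModel}} with thin-filament
#'   subunits.
#' @param boundary axial position of the A/I boundary (nm).
#' @param stateOffset M-to-C azimuthal rotation (deg, default 21).
#' @param noiseSd angular noise SD (deg).
#' @param refM M-state mean offset (deg).
#' @param seed integer RNG seed.
#' @return the model with subunit \code{tpm_offset} filled in and the
#'   boundary recorded in metadata.
#' @export
assignTropomyosin <- function(model, boundary, stateOffset = 21,
                              noiseSd = 0, refM = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sub <- model@subunits
  if (!nrow(sub)) stop("model has no subunits")
  bA <- boundary * NM
  mean_off <- ifelse(sub$y < bA, refM, refM + stateOffset)
  noise <- if (noiseSd > 0) stats::rnorm(nrow(sub), 0, noiseSd) else 0
  sub$tpm_offset <- mean_off + noise
  model@subunits <- sub
  model@metadata$tpm <- list(boundary_nm = boundary,
                             state_offset = stateOffset,
                             ref_M = refM, noise_sd = noiseSd)
  model
}

.splatBlob <- function(vol, d, cx, cy, cz, sigma, vs, org, amp = 1) {
  ## separable Gaussian blob added over a +/- 3 sigma window
  w <- 3 * sigma
  rng <- function(c0, dim, o) {
    lo <- max(1, floor((c0 - w - o) / vs) + 1)
    hi <- min(dim, ceiling((c0 + w - o) / vs) + 1)
    if (lo > hi) integer() else lo:hi
  }
  ix <- rng(cx, d[1], org[1])
  iy <- rng(cy, d[2], org[2])
  iz <- rng(cz, d[3], org[3])
  if (!length(ix) || !length(iy) || !length(iz)) return(vol)
  gx <- exp(-((org[1] + (ix - 1) * vs - cx)^2) / (2 * sigma^2))
  gy <- exp(-((org[2] + (iy - 1) * vs - cy)^2) / (2 * sigma^2))
  gz <- exp(-((org[3] + (iz - 1) * vs - cz)^2) / (2 * sigma^2))
  vol[ix, iy, iz] <- vol[ix, iy, iz] + amp * outer(outer(gx, gy), gz)
  vol
}

#' Rasterise a sarcomere model into a tomogram-like volume
#'
#' Renders filaments as Gaussian tubes (SD \code{filamentRadius}),
#' myosin heads and alpha-actinin cross-links as Gaussian blobs, adds
#' white Gaussian noise at a given peak-signal-to-noise ratio, and
#' optionally applies a hard missing-wedge mask in Fourier space
#' (zeroing components within \code{missingWedgeHalfangle} of the beam
#' (Z) frequency axis in the ky-kz plane; the tilt axis is X).
#'
#' @param model a \code{\link{SarcomereModel}}.
#' @param voxelSize A per voxel.
#' @param filamentRadius Gaussian tube SD (A).
#' @param snr peak signal / noise SD; \code{Inf} for noiseless.
#' @param missingWedgeHalfangle degrees, or NULL for none.
#' @param seed integer RNG seed (noise).
#' @param pad bounding-box padding (A).
#' @param headRadius blob SD for heads and cross-links (A).
#' @param includeHeads,includeCrosslinks logicals.
#' @return A \code{\link{TomoVolume}}.
#' @export
rasterizeVolume <- function(model, voxelSize = 20, filamentRadius = 40,
                            snr = Inf, missingWedgeHalfangle = NULL,
                            seed = NULL, pad = 150, headRadius = 30,
                            includeHeads = TRUE,
                            includeCrosslinks = TRUE) {
  if (voxelSize <= 0) stop("voxelSize must be > 0")
  if (voxelSize > filamentRadius)
    warning("voxel size exceeds filament radius; tubes undersampled")
  if (!is.null(seed)) set.seed(seed)
  pts <- model@points
  if (!nrow(pts)) stop("model has no filament points")
  org <- c(min(pts$x), min(pts$y), min(pts$z)) - pad
  hi <- c(max(pts$x), max(pts$y), max(pts$z)) + pad
  d <- pmax(2L, as.integer(ceiling((hi - org) / voxelSize)) + 1L)
  vol <- array(0, d)
  vs <- voxelSize
  xg <- org[1] + (seq_len(d[1]) - 1) * vs
  yg <- org[2] + (seq_len(d[2]) - 1) * vs
  zg <- org[3] + (seq_len(d[3]) - 1) * vs
  fil <- model@filaments
  for (fid in fil$id) {
    pp <- pts[pts$filament_id == fid, ]
    vertical <- all(abs(diff(pp$x)) < 1e-9) && all(abs(diff(pp$z)) < 1e-9)
    if (vertical) {
      gx <- exp(-((xg - pp$x[1])^2) / (2 * filamentRadius^2))
      gz <- exp(-((zg - pp$z[1])^2) / (2 * filamentRadius^2))
      g <- outer(gx, gz)
      iy <- which(yg >= min(pp$y) & yg <= max(pp$y))
      if (length(iy))
        vol[, iy, ] <- vol[, iy, ] +
          aperm(array(g, c(d[1], d[3], length(iy))), c(1, 3, 2))
    } else {
      seg <- cbind(pp$x, pp$y, pp$z)
      for (s in seq_len(nrow(seg) - 1)) {
        L <- sqrt(sum((seg[s + 1, ] - seg[s, ])^2))
        tt <- seq(0, 1, length.out = max(2, ceiling(L / (vs / 2)) + 1))
        step <- L * (tt[2] - tt[1])
        ## normalised so a line of blobs peaks at ~1 like the tube path
        amp <- step / (filamentRadius * sqrt(2 * pi))
        for (t in tt) {
          p <- seg[s, ] + t * (seg[s + 1, ] - seg[s, ])
          vol <- .splatBlob(vol, d, p[1], p[2], p[3],
                            filamentRadius, vs, org, amp = amp)
        }
      }
    }
  }
  if (includeHeads && nrow(model@heads))
    for (r in seq_len(nrow(model@heads)))
      vol <- .splatBlob(vol, d, model@heads$x[r], model@heads$y[r],
                        model@heads$z[r], headRadius, vs, org)
  if (includeCrosslinks && nrow(model@crosslinks)) {
    cl <- model@crosslinks
    for (r in seq_len(nrow(cl))) {
      pa <- c(fil$x[fil$id == cl$fil_a[r]], cl$ya[r],
              fil$z[fil$id == cl$fil_a[r]])
      pb <- c(fil$x[fil$id == cl$fil_b[r]], cl$yb[r],
              fil$z[fil$id == cl$fil_b[r]])
      L <- sqrt(sum((pb - pa)^2))
      tt <- seq(0, 1, length.out = max(2, ceiling(L / (vs / 2)) + 1))
      step <- L * (tt[2] - tt[1])
      amp <- 0.6 * step / (headRadius * sqrt(2 * pi))  # rods dimmer
      for (t in tt)
        vol <- .splatBlob(vol, d, pa[1] + t * (pb[1] - pa[1]),
                          pa[2] + t * (pb[2] - pa[2]),
                          pa[3] + t * (pb[3] - pa[3]),
                          headRadius, vs, org, amp = amp)
    }
  }
  if (is.finite(snr)) {
    peak <- max(vol)
    sd <- if (peak > 0) peak / snr else 1
    vol <- vol + array(stats::rnorm(length(vol), 0, sd), d)
  }
  if (!is.null(missingWedgeHalfangle)) {
    fy <- .fftFreq(d[2]); fz <- .fftFreq(d[3])
    ang <- atan2(abs(rep(fy, times = d[3])),
                 abs(rep(fz, each = d[2]))) * 180 / pi
    mask <- matrix(ang >= missingWedgeHalfangle |
                     (rep(fy, times = d[3]) == 0 &
                      rep(fz, each = d[2]) == 0),
                   d[2], d[3])
    ft <- apply(vol, 1, function(sl) stats::fft(sl))  # per-x 2D FFTs
    ft <- array(ft, c(d[2], d[3], d[1]))
    for (i in seq_len(d[1]))
      ft[, , i] <- ft[, , i] * mask
    back <- apply(ft, 3, function(sl)
      Re(stats::fft(sl, inverse = TRUE)) / (d[2] * d[3]))
    vol <- aperm(array(back, c(d[2], d[3], d[1])), c(3, 1, 2))
  }
  TomoVolume(vol, voxelSize = vs, origin = org)
}

.fftFreq <- function(n) {
  neg <- if (floor(n / 2) >= 1) seq(-floor(n / 2), -1) else numeric()
  c(seq(0, floor((n - 1) / 2)), neg) / n
}
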