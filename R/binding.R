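## A-band cross-bridge census and myosin binding-preference analyses:
## head-to-subunit assignment, head topology, R/G/B/E binding-profile
## encoding, custom-matrix pairwise and progressive multiple alignment,
## grouped angular distributions and bound/free distance statistics.

#' Theoretical myosin head budget of a thick filament
#'
#' Six heads (three myosin molecules) per 14.3-nm crown;
#' crowns = floor(length / 14.3 nm).
#'
#' @param lengthNm thick-filament length (nm), vectorised.
#' @param crownSpacingNm crown repeat (nm).
#' @param headsPerCrown heads per crown.
#' @return integer head counts.
#' @export
theoreticalHeadCount <- function(lengthNm, crownSpacingNm = 14.3,
                                 headsPerCrown = 6) {
  as.integer(headsPerCrown * floor(lengthNm / crownSpacingNm))
}

#' Cross-bridge occupancy census
#'
#' Occupancy is the fraction of the theoretical head budget found bound
#' to thin filaments: e.g. 2,734 fitted of 3,315 theoretical heads gives
#' 82.5 percent.
#'
#' @param nAssigned number of heads assigned to subunits.
#' @param nTheoretical theoretical head budget.
#' @return list with counts and \code{occupancyPct}.
#' @examples
#' occupancyCensus(2734, 3315)$occupancyPct  # 82.5
#' @export
occupancyCensus <- function(nAssigned, nTheoretical) {
  if (nTheoretical <= 0) stop("nTheoretical must be positive")
  list(nAssigned = nAssigned, nTheoretical = nTheoretical,
       occupancyPct = 100 * nAssigned / nTheoretical)
}

#' Assign myosin head positions to actin subunits
#'
#' Each head is assigned to the nearest subunit centre within
#' \code{captureRadiusNm} (default 5.5 nm, one subunit diameter).
#' Unassigned heads are flagged and counted, never dropped. The summary
#' reports occupancy against the model's theoretical head budget and
#' the bound-subunit fraction.
#'
#' @param headPositions data.frame with x, y, z (A) and optionally
#'   myosin_id, head_slot, origin_thick_id.
#' @param model a \code{\link{SarcomereModel}}.
#' @param captureRadiusNm capture radius (nm).
#' @return list: \code{heads} (the input plus filament_id, subunit_k,
#'   assigned) and \code{summary} (census list).
#' @export
assignHeads <- function(headPositions, model, captureRadiusNm = 5.5) {
  sub <- model@subunits
  if (!nrow(sub)) stop("model has no subunits")
  hp <- as.data.frame(headPositions)
  rad <- captureRadiusNm * NM
  n <- nrow(hp)
  filId <- rep(NA_integer_, n); subK <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    cand <- which(abs(sub$y - hp$y[i]) <= rad)
    if (!length(cand)) next
    dd <- sqrt((sub$x[cand] - hp$x[i])^2 + (sub$y[cand] - hp$y[i])^2 +
                 (sub$z[cand] - hp$z[i])^2)
    j <- which.min(dd)
    if (dd[j] <= rad) {
      filId[i] <- sub$filament_id[cand[j]]
      subK[i] <- sub$k[cand[j]]
    }
  }
  hp$filament_id <- filId
  hp$subunit_k <- subK
  hp$assigned <- !is.na(filId)
  fil <- model@filaments
  nTheo <- sum(theoreticalHeadCount(
    (fil$y1[fil$kind == "thick"] - fil$y0[fil$kind == "thick"]) / NM))
  if (!is.null(model@metadata$binding))
    nTheo <- model@metadata$binding$theoretical_heads
  cen <- occupancyCensus(sum(hp$assigned), max(nTheo, 1L))
  cen$nUnassigned <- sum(!hp$assigned)
  cen$boundSubunitFraction <-
    length(unique(paste(filId, subK)[hp$assigned])) / nrow(sub)
  list(heads = hp, summary = cen)
}

#' Classify myosin head topology
#'
#' Heads sharing a myosin_id form one molecule: two heads on the same
#' thin filament are a double-head, two heads on different thin
#' filaments a split-head, an unpaired head a single. Fractions are
#' reported against both the attached and (when given) the theoretical
#' head counts; e.g. 10 split pairs among 3,315 theoretical heads is
#' 0.6 percent of all heads.
#'
#' @param heads data.frame with myosin_id, filament_id (and subunit_k).
#' @param nTheoretical optional theoretical head budget.
#' @return list of counts and percentage fractions.
#' @examples
#' h <- data.frame(myosin_id = rep(1:2, each = 2),
#'                 filament_id = c(1, 1, 1, 2), subunit_k = c(1, 3, 5, 2))
#' classifyHeadTopology(h)$nSplitPairs  # 1
#' @export
classifyHeadTopology <- function(heads, nTheoretical = NULL) {
  if (!nrow(heads)) {
    z <- list(nHeads = 0L, nDoublePairs = 0L, nSplitPairs = 0L,
              nSingle = 0L, pctSingleOfAttached = NA_real_,
              pctSplitOfAttached = NA_real_)
    return(z)
  }
  grp <- split(heads, heads$myosin_id)
  sizes <- vapply(grp, nrow, 1L)
  if (any(sizes > 2)) stop("a myosin_id has more than two heads")
  classes <- vapply(grp, function(g) {
    if (nrow(g) == 1) "single"
    else if (length(unique(g$filament_id)) == 1) "double" else "split"
  }, character(1))
  nH <- nrow(heads)
  nD <- sum(classes == "double"); nSp <- sum(classes == "split")
  nS <- sum(classes == "single")
  out <- list(nHeads = nH, nDoublePairs = nD, nSplitPairs = nSp,
              nSingle = nS,
              pctSingleOfAttached = 100 * nS / nH,
              pctSplitOfAttached = 100 * 2 * nSp / nH,
              pctDoubleOfAttached = 100 * 2 * nD / nH)
  if (!is.null(nTheoretical)) {
    out$pctSingleOfTheoretical <- 100 * nS / nTheoretical
    out$pctSplitOfTheoretical <- 100 * 2 * nSp / nTheoretical
  }
  out
}

#' Encode a thin filament's myosin-binding profile
#'
#' Each thin filament is treated as its two long-pitch strands; per
#' strand, subunit positions (ordered by k) are encoded as the letter of
#' the neighbouring thick filament whose head binds there ("R", "G" or
#' "B", stable labels from the model's neighbour table) or "E" for
#' myosin-free subunits.
#'
#' @param model a \code{\link{SarcomereModel}} after
#'   \code{\link{simulateBinding}} (or with an assigned heads table).
#' @param filamentId thin-filament id.
#' @return list with character vectors \code{strand1} (k even) and
#'   \code{strand2} (k odd).
#' @export
encodeProfiles <- function(model, filamentId) {
  sub <- model@subunits[model@subunits$filament_id == filamentId, ]
  if (!nrow(sub)) stop("unknown filament id: ", filamentId)
  nb <- model@neighbors[model@neighbors$thin_id == filamentId, ]
  if (nrow(nb) != 3)
    warning("filament ", filamentId, " has ", nrow(nb),
            " labelled thick neighbours (expected 3); reduced alphabet")
  hd <- model@heads[model@heads$filament_id == filamentId, ]
  letter <- rep("E", nrow(sub))
  if (nrow(hd)) {
    m <- match(sub$k, hd$subunit_k)
    hit <- !is.na(m)
    lab <- nb$label[match(hd$origin_thick_id[m[hit]], nb$thick_id)]
    lab[is.na(lab)] <- "E"
    letter[hit] <- lab
  }
  o <- order(sub$k)
  letter <- letter[o]; kk <- sub$k[o]
  list(strand1 = letter[kk %% 2 == 0], strand2 = letter[kk %% 2 == 1])
}

#' Default binding-profile substitution weights
#'
#' Symmetric 4x4 score table over \{R, G, B, E\} with affine gap
#' penalties: same-colour match +3, E-E +1, colour-colour mismatch -2,
#' colour-E -1; opening a gap costs \code{gapOpen} for its first
#' position and \code{gapExtend} for each further position.
#'
#' @param match,ee,mismatch,colorE scores.
#' @param gapOpen,gapExtend gap penalties (negative).
#' @return list with \code{matrix}, \code{gapOpen}, \code{gapExtend}.
#' @export
profileWeights <- function(match = 3, ee = 1, mismatch = -2,
                           colorE = -1, gapOpen = -5, gapExtend = -1) {
  ab <- c("R", "G", "B", "E")
  m <- matrix(mismatch, 4, 4, dimnames = list(ab, ab))
  diag(m) <- match
  m["E", "E"] <- ee
  m["E", c("R", "G", "B")] <- colorE
  m[c("R", "G", "B"), "E"] <- colorE
  list(matrix = m, gapOpen = gapOpen, gapExtend = gapExtend)
}

.checkAlphabet <- function(s, weights) {
  if (!all(s %in% rownames(weights$matrix)))
    stop("sequence contains letters outside the profile alphabet")
}

#' Global pairwise alignment of binding profiles (affine gaps)
#'
#' Needleman-Wunsch with affine gap penalties over the R/G/B/E alphabet.
#' The first position of a gap run costs \code{gapOpen}, each further
#' position \code{gapExtend}.
#'
#' @param s1,s2 character vectors over the profile alphabet.
#' @param weights a \code{\link{profileWeights}} list.
#' @return list with \code{score} and gapped character vectors
#'   \code{aligned1}, \code{aligned2} ("-" for gaps).
#' @export
pairwiseAlignProfiles <- function(s1, s2, weights = profileWeights()) {
  .checkAlphabet(s1, weights); .checkAlphabet(s2, weights)
  W <- weights$matrix; go <- weights$gapOpen; ge <- weights$gapExtend
  n <- length(s1); m <- length(s2)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)  # s1 aligned to gap in s2
  Iy <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  if (n) Ix[2:(n + 1), 1] <- go + (0:(n - 1)) * ge
  if (m) Iy[1, 2:(m + 1)] <- go + (0:(m - 1)) * ge
  ptrM <- matrix(0L, n + 1, m + 1)
  ptrX <- matrix(0L, n + 1, m + 1)
  ptrY <- matrix(0L, n + 1, m + 1)
  for (i in seq_len(n)) {
    wrow <- W[s1[i], ]
    for (j in seq_len(m)) {
      prev <- c(M[i, j], Ix[i, j], Iy[i, j])
      b <- which.max(prev)
      M[i + 1, j + 1] <- prev[b] + wrow[s2[j]]
      ptrM[i + 1, j + 1] <- b
      vx <- c(M[i, j + 1] + go, Ix[i, j + 1] + ge, Iy[i, j + 1] + go)
      b <- which.max(vx)
      Ix[i + 1, j + 1] <- vx[b]; ptrX[i + 1, j + 1] <- b
      vy <- c(M[i + 1, j] + go, Ix[i + 1, j] + go, Iy[i + 1, j] + ge)
      b <- which.max(vy)
      Iy[i + 1, j + 1] <- vy[b]; ptrY[i + 1, j + 1] <- b
    }
  }
  fin <- c(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
  state <- which.max(fin)
  score <- fin[state]
  a1 <- character(); a2 <- character()
  i <- n; j <- m
  while (i > 0 || j > 0) {
    if (state == 1) {
      a1 <- c(s1[i], a1); a2 <- c(s2[j], a2)
      state <- ptrM[i + 1, j + 1]; i <- i - 1; j <- j - 1
      if (state == 0) state <- 1
    } else if (state == 2) {
      a1 <- c(s1[i], a1); a2 <- c("-", a2)
      ns <- ptrX[i + 1, j + 1]; i <- i - 1
      state <- if (ns == 0) 2 else ns
    } else {
      a1 <- c("-", a1); a2 <- c(s2[j], a2)
      ns <- ptrY[i + 1, j + 1]; j <- j - 1
      state <- if (ns == 0) 3 else ns
    }
  }
  list(score = unname(score), aligned1 = a1, aligned2 = a2)
}

## merge a new pairwise view of the centre sequence into the master
## alignment ("once a gap, always a gap")
.mergeIntoMaster <- function(masterRows, centerGapped, newGapped) {
  ## masterRows[[1]] and centerGapped are two gapped versions of the same
  ## ungapped centre sequence; walk both, keeping every gap ever made
  mc <- masterRows[[1]]
  nm <- length(mc); np <- length(centerGapped)
  sel <- integer(0)       # source column in master; 0 = new all-gap col
  newRow <- character(0)
  i <- 1; j <- 1
  while (i <= nm || j <= np) {
    if (i <= nm && mc[i] == "-") {
      sel <- c(sel, i); newRow <- c(newRow, "-"); i <- i + 1
    } else if (j <= np && centerGapped[j] == "-") {
      sel <- c(sel, 0L); newRow <- c(newRow, newGapped[j]); j <- j + 1
    } else if (i <= nm && j <= np) {   # same ungapped centre letter
      sel <- c(sel, i); newRow <- c(newRow, newGapped[j])
      i <- i + 1; j <- j + 1
    } else stop("internal error merging alignments")
  }
  out <- lapply(masterRows, function(r)
    ifelse(sel == 0L, "-", r[pmax(sel, 1L)]))
  out[[length(out) + 1L]] <- newRow
  out
}

#' Progressive multiple alignment of binding profiles (centre star)
#'
#' Aligns two or more strand-1 binding-profile sequences: all pairwise
#' scores are computed with \code{\link{pairwiseAlignProfiles}}, the
#' centre sequence (maximal summed pairwise score; ties by input order)
#' is chosen, every other sequence is aligned to it, and the pairwise
#' alignments are merged with the "once a gap, always a gap" rule.
#' Column-wise letter occurrence counts give the binding footprint.
#' Strand-2 sequences can be carried through the strand-1 alignment
#' with \code{\link{mapStrandTwo}}.
#'
#' @param profiles list of character vectors over \{R,G,B,E\}.
#' @param weights a \code{\link{profileWeights}} list.
#' @return list: \code{alignment} (character matrix, rows in input
#'   order), \code{counts} (4 x width occurrence matrix),
#'   \code{center} (index of the centre sequence),
#'   \code{pairwiseScores}.
#' @export
alignProfiles <- function(profiles, weights = profileWeights()) {
  np <- length(profiles)
  if (np < 2) stop("need at least two profiles")
  lapply(profiles, .checkAlphabet, weights = weights)
  S <- matrix(0, np, np)
  for (i in seq_len(np - 1)) for (j in (i + 1):np) {
    sc <- pairwiseAlignProfiles(profiles[[i]], profiles[[j]],
                                weights)$score
    S[i, j] <- sc; S[j, i] <- sc
  }
  center <- which.max(rowSums(S))
  masterRows <- list(profiles[[center]])
  rowOrder <- center
  for (q in setdiff(seq_len(np), center)) {
    pa <- pairwiseAlignProfiles(profiles[[center]], profiles[[q]],
                                weights)
    masterRows <- .mergeIntoMaster(masterRows, pa$aligned1, pa$aligned2)
    rowOrder <- c(rowOrder, q)
  }
  width <- length(masterRows[[1]])
  aln <- matrix("-", np, width)
  for (r in seq_along(masterRows)) aln[rowOrder[r], ] <- masterRows[[r]]
  ab <- rownames(weights$matrix)
  counts <- t(vapply(ab, function(L) colSums(aln == L),
                     numeric(width)))
  rownames(counts) <- ab
  list(alignment = aln, counts = counts, center = center,
       pairwiseScores = S)
}

#' Map strand-2 sequences through a strand-1 alignment
#'
#' Applies each row's gap pattern from a strand-1 multiple alignment to
#' the corresponding strand-2 sequence (strand 2 of each filament is
#' aligned using the same alignment as strand 1).
#'
#' @param alignment character matrix from \code{\link{alignProfiles}}.
#' @param strand2 list of ungapped strand-2 character vectors, one per
#'   alignment row.
#' @return character matrix of gapped strand-2 sequences.
#' @export
mapStrandTwo <- function(alignment, strand2) {
  if (length(strand2) != nrow(alignment))
    stop("need one strand-2 sequence per alignment row")
  out <- matrix("-", nrow(alignment), ncol(alignment))
  for (r in seq_len(nrow(alignment))) {
    pos <- which(alignment[r, ] != "-")
    s <- strand2[[r]]
    n <- min(length(pos), length(s))
    out[r, pos[seq_len(n)]] <- s[seq_len(n)]
  }
  out
}

#' Minimal circular arc containing a fraction of angles
#'
#' @param angles degrees.
#' @param mass fraction of points the arc must contain (default 1).
#' @return arc width in degrees.
#' @export
minimalArc <- function(angles, mass = 1) {
  a <- sort(wrapTo360(angles))
  n <- length(a)
  if (n <= 1) return(0)
  if (mass >= 1) {
    gaps <- diff(c(a, a[1] + 360))
    return(360 - max(gaps))
  }
  k <- max(2L, ceiling(mass * n))
  ext <- c(a, a + 360)
  min(ext[seq_len(n) + k - 1] - a)
}

#' Grouped circular distribution of bound-subunit orientations
#'
#' Per-group circular histogram, circular mean and minimal arc
#' containing \code{mass} of the observations. With the default
#' orientation gate the per-group span is ~120 degrees, the observed
#' confinement of myosin-bound actin orientations.
#'
#' @param angles relative orientations (deg).
#' @param groups group labels (e.g. originating thick filament).
#' @param binWidth histogram bin width (deg).
#' @param mass arc mass fraction.
#' @return data.frame with group, n, circularMeanDeg, spanDeg; histogram
#'   matrices in \code{attr(, "histogram")}.
#' @export
angularDistribution <- function(angles, groups, binWidth = 10,
                                mass = 1) {
  stopifnot(length(angles) == length(groups))
  sp <- split(wrapTo180(angles), groups)
  keep <- vapply(sp, length, 1L) > 0
  if (any(!keep)) warning("empty groups skipped: ",
                          paste(names(sp)[!keep], collapse = ", "))
  sp <- sp[keep]
  breaks <- seq(-180, 180, by = binWidth)
  hists <- lapply(sp, function(x)
    graphics::hist(x, breaks = breaks, plot = FALSE)$counts)
  out <- data.frame(
    group = names(sp),
    n = vapply(sp, length, 1L),
    circularMeanDeg = vapply(sp, circularMean, numeric(1),
                             wrap = "180"),
    spanDeg = vapply(sp, minimalArc, numeric(1), mass = mass))
  rownames(out) <- NULL
  attr(out, "histogram") <- do.call(rbind, hists)
  out
}

.skewness <- function(x) {
  n <- length(x)
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  g1 <- mean((x - m)^3) / s^3
  se <- sqrt(6 * n * (n - 1) / ((n - 2) * (n + 1) * (n + 3)))
  z <- g1 / se
  list(skewness = g1, se = se, z = z,
       p = 2 * stats::pnorm(-abs(z)))
}

#' Bound vs free thin-to-thick distance statistics
#'
#' Summarises the two distance populations (myosin-bound and
#' myosin-free measurements), reporting per-population mean, SD and
#' sample skewness with a normal-reference significance, and the
#' difference of means (free - bound) with a 95 percent confidence
#' interval (Welch normal approximation by default, seeded percentile
#' bootstrap as an option).
#'
#' @param bound,free numeric vectors (nm).
#' @param conf confidence level.
#' @param ciMethod "welch" or "bootstrap".
#' @param nBoot bootstrap replicates.
#' @param seed RNG seed for the bootstrap.
#' @return list of summaries; \code{differenceNm} is mean(free) -
#'   mean(bound).
#' @export
distanceSummary <- function(bound, free, conf = 0.95,
                            ciMethod = c("welch", "bootstrap"),
                            nBoot = 10000, seed = NULL) {
  ciMethod <- match.arg(ciMethod)
  if (length(bound) < 2 || length(free) < 2)
    stop("need at least 2 measurements in each population")
  n1 <- length(bound); n2 <- length(free)
  m1 <- mean(bound); m2 <- mean(free)
  s1 <- stats::sd(bound); s2 <- stats::sd(free)
  diffm <- m2 - m1
  if (ciMethod == "welch") {
    se <- sqrt(s1^2 / n1 + s2^2 / n2)
    df <- se^4 / ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
    q <- stats::qt(1 - (1 - conf) / 2, df)
    ci <- c(diffm - q * se, diffm + q * se)
  } else {
    if (!is.null(seed)) set.seed(seed)
    bs <- replicate(nBoot,
                    mean(sample(free, n2, replace = TRUE)) -
                      mean(sample(bound, n1, replace = TRUE)))
    ci <- unname(stats::quantile(bs, c((1 - conf) / 2,
                                       1 - (1 - conf) / 2)))
  }
  list(bound = list(n = n1, meanNm = m1, sdNm = s1,
                    skew = .skewness(bound)),
       free = list(n = n2, meanNm = m2, sdNm = s2,
                   skew = .skewness(free)),
       differenceNm = diffm, ci = ci, conf = conf, method = ciMethod)
}

#' Thin-to-thick distance measurements from a model
#'
#' Implements the three-measurements-per-subunit rule: a myosin-free
#' subunit contributes three free measurements (to its three neighbour
#' thick filaments); a myosin-bound subunit contributes one bound
#' measurement (to the binder's thick filament) and two free
#' measurements. Distances are centre-to-centre between filament axes
#' at the subunit's axial position, in nm.
#'
#' @param model a \code{\link{SarcomereModel}} with heads.
#' @return list with numeric vectors \code{bound}, \code{free} and the
#'   exact bookkeeping count \code{nMeasurements} (3 x subunits).
#' @export
filamentDistances <- function(model) {
  sub <- model@subunits
  nb <- model@neighbors
  fil <- model@filaments
  if (!nrow(nb)) stop("model has no thin-to-thick neighbour table")
  hd <- model@heads
  binder <- rep(NA_integer_, nrow(sub))
  if (nrow(hd)) {
    m <- match(paste(sub$filament_id, sub$k),
               paste(hd$filament_id, hd$subunit_k))
    binder <- hd$origin_thick_id[m]
  }
  fx <- fil$x[match(nb$thick_id, fil$id)]
  fz <- fil$z[match(nb$thick_id, fil$id)]
  tx <- fil$x[match(nb$thin_id, fil$id)]
  tz <- fil$z[match(nb$thin_id, fil$id)]
  nb$dist_nm <- sqrt((fx - tx)^2 + (fz - tz)^2) / NM
  bound <- numeric(); free <- numeric()
  for (tid in unique(sub$filament_id)) {
    nbi <- nb[nb$thin_id == tid, ]
    if (!nrow(nbi)) next
    rows <- which(sub$filament_id == tid)
    for (r in rows) {
      b <- binder[r]
      if (!is.na(b) && b %in% nbi$thick_id) {
        bound <- c(bound, nbi$dist_nm[nbi$thick_id == b])
        free <- c(free, nbi$dist_nm[nbi$thick_id != b])
      } else {
        free <- c(free, nbi$dist_nm)
      }
    }
  }
  list(bound = bound, free = free,
       nMeasurements = length(bound) + length(free))
}

#' Relative orientations of bound subunits per thick-filament group
#'
#' For every bound subunit, the orientation relative to the thick
#' filament its head originates from, grouped by the neighbour label
#' ("R"/"G"/"B").
#'
#' @param model a \code{\link{SarcomereModel}} after binding.
#' @return data.frame with filament_id, k, label, orientation (deg).
#' @export
boundOrientations <- function(model) {
  hd <- model@heads
  if (!nrow(hd)) return(data.frame(filament_id = integer(),
                                   k = integer(), label = character(),
                                   orientation = numeric()))
  nb <- model@neighbors
  sub <- model@subunits
  m <- match(paste(hd$filament_id, hd$subunit_k),
             paste(sub$filament_id, sub$k))
  nbm <- match(paste(hd$filament_id, hd$origin_thick_id),
               paste(nb$thin_id, nb$thick_id))
  ok <- !is.na(m) & !is.na(nbm)
  data.frame(filament_id = hd$filament_id[ok], k = hd$subunit_k[ok],
             label = nb$label[nbm[ok]],
             orientation = relativeOrientation(sub$azimuth[m[ok]],
                                               nb$bearing_deg[nbm[ok]]))
}
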