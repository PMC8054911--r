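test_that("the occupancy census reproduces the worked example", {
  cen <- occupancyCensus(2734, 3315)
  expect_equal(round(cen$occupancyPct, 1), 82.5)
  expect_equal(occupancyCensus(0, 3315)$occupancyPct, 0)
  expect_error(occupancyCensus(10, 0), "positive")
  expect_equal(theoreticalHeadCount(14.3), 6L)
  expect_equal(theoreticalHeadCount(14.3 * 49), 294L)  # per filament
})

test_that("head positions are assigned back to their true subunits", {
  m <- smallBoundModel()
  hd <- myosinHeads(m)
  res <- assignHeads(hd[, c("x", "y", "z")], m)
  expect_true(all(res$heads$assigned))
  expect_equal(res$heads$filament_id, hd$filament_id)
  expect_equal(res$heads$subunit_k, hd$subunit_k)
  expect_equal(res$summary$nAssigned, nrow(hd))
  # a far-away head is flagged unassigned, not dropped
  far <- rbind(hd[1, c("x", "y", "z")] + 5000)
  res2 <- assignHeads(rbind(hd[, c("x", "y", "z")], far), m)
  expect_equal(res2$summary$nUnassigned, 1)
  expect_equal(nrow(res2$heads), nrow(hd) + 1)
})

test_that("head topology fractions reproduce the split worked example", {
  # 10 split pairs among 3,315 theoretical heads -> 0.6% of all heads
  hd <- data.frame(
    myosin_id = rep(1:10, each = 2), head_slot = c("a", "b"),
    filament_id = rep(c(1, 2), 10), subunit_k = seq_len(20))
  topo <- classifyHeadTopology(hd, nTheoretical = 3315)
  expect_equal(topo$nSplitPairs, 10)
  expect_equal(round(topo$pctSplitOfTheoretical, 1), 0.6)
  # all unpaired -> single fraction 100%
  hs <- data.frame(myosin_id = 1:5, filament_id = 1, subunit_k = 1:5)
  expect_equal(classifyHeadTopology(hs)$pctSingleOfAttached, 100)
  # more than two heads per molecule is an input error
  bad <- data.frame(myosin_id = c(1, 1, 1), filament_id = 1,
                    subunit_k = 1:3)
  expect_error(classifyHeadTopology(bad), "more than two")
})

test_that("binding profiles encode heads by neighbour label", {
  m0 <- buildLattice(LatticeSpec(nRows = 4, nCols = 4,
                                 axisLength = 100))
  tid <- thinNeighbors(m0)$thin_id[1]
  pr0 <- encodeProfiles(m0, tid)
  expect_true(all(pr0$strand1 == "E"))  # no heads -> all-E
  expect_true(all(pr0$strand2 == "E"))
  m <- smallBoundModel()
  nb <- thinNeighbors(m)
  tid <- nb$thin_id[1]
  pr <- encodeProfiles(m, tid)
  sub <- subunits(m)
  nSub <- sum(sub$filament_id == tid)
  expect_equal(length(pr$strand1) + length(pr$strand2), nSub)
  # oracle: rebuild the letters from the tables directly
  hd <- myosinHeads(m)
  hd <- hd[hd$filament_id == tid, ]
  nbt <- nb[nb$thin_id == tid, ]
  for (r in seq_len(nrow(hd))) {
    k <- hd$subunit_k[r]
    lab <- nbt$label[nbt$thick_id == hd$origin_thick_id[r]]
    strand <- if (k %% 2 == 0) pr$strand1 else pr$strand2
    expect_equal(strand[floor(k / 2) + 1], lab)
  }
  expect_equal(sum(c(pr$strand1, pr$strand2) != "E"), nrow(hd))
  expect_error(encodeProfiles(m, 99999), "unknown filament")
})

test_that("pairwise alignment matches the exhaustive oracle", {
  w <- profileWeights()
  set.seed(31)
  ab <- c("R", "G", "B", "E")
  for (rep in 1:40) {
    s1 <- sample(ab, sample(1:6, 1), replace = TRUE)
    s2 <- sample(ab, sample(1:6, 1), replace = TRUE)
    pa <- pairwiseAlignProfiles(s1, s2, w)
    expect_equal(pa$score, bruteForceAlignScore(s1, s2, w),
                 info = paste(paste(s1, collapse = ""),
                              paste(s2, collapse = "")))
    # the reported alignment scores to the reported score
    expect_equal(scoreAlignedPair(pa$aligned1, pa$aligned2, w),
                 pa$score)
    # gap-stripped rows reproduce the inputs
    expect_equal(pa$aligned1[pa$aligned1 != "-"], s1)
    expect_equal(pa$aligned2[pa$aligned2 != "-"], s2)
  }
})

test_that("pairwise alignment agrees with an independent aligner", {
  w <- profileWeights()
  # Biostrings costs gaps as opening + extension per position; ours
  # costs gapOpen for the first position and gapExtend after, so
  # opening = -(gapOpen - gapExtend), extension = -gapExtend
  set.seed(32)
  ab <- c("R", "G", "B", "E")
  for (rep in 1:10) {
    s1 <- sample(ab, sample(3:9, 1), replace = TRUE)
    s2 <- sample(ab, sample(3:9, 1), replace = TRUE)
    ref <- Biostrings::pairwiseAlignment(
      paste(s1, collapse = ""), paste(s2, collapse = ""),
      substitutionMatrix = w$matrix, type = "global",
      gapOpening = -(w$gapOpen - w$gapExtend),
      gapExtension = -w$gapExtend, scoreOnly = TRUE)
    expect_equal(pairwiseAlignProfiles(s1, s2, w)$score, ref)
  }
})

test_that("identical sequences align gap-free at the diagonal score", {
  w <- profileWeights()
  s <- c("R", "G", "E", "E", "B", "E")
  pa <- pairwiseAlignProfiles(s, s, w)
  expect_equal(pa$score, sum(diag(w$matrix)[match(s, rownames(w$matrix))]))
  expect_false(any(pa$aligned1 == "-") || any(pa$aligned2 == "-"))
  al <- alignProfiles(list(s, s, s), w)
  expect_false(any(al$alignment == "-"))
  expect_equal(unname(al$counts["R", 1]), 3)
  expect_error(pairwiseAlignProfiles(c("R", "Q"), s, w), "alphabet")
})

test_that("the centre-star merge preserves optimal centre alignments", {
  w <- profileWeights()
  set.seed(33)
  ab <- c("R", "G", "B", "E")
  profs <- lapply(1:4, function(i) sample(ab, sample(5:8, 1), TRUE))
  al <- alignProfiles(profs, w)
  expect_equal(dim(al$alignment)[1], 4)
  # every row strips back to its input
  for (i in 1:4)
    expect_equal(al$alignment[i, ][al$alignment[i, ] != "-"],
                 profs[[i]])
  # induced centre-row pairwise scores equal the pairwise optima
  c0 <- al$center
  for (i in setdiff(1:4, c0)) {
    ind <- scoreAlignedPair(al$alignment[c0, ], al$alignment[i, ], w)
    expect_equal(ind, al$pairwiseScores[c0, i])
  }
  # column counts add up to the number of letters
  expect_equal(sum(al$counts), sum(lengths(profs)))
  # deterministic
  al2 <- alignProfiles(profs, w)
  expect_identical(al$alignment, al2$alignment)
})

test_that("strand 2 is carried through the strand-1 alignment", {
  aln <- rbind(c("R", "-", "E", "G"), c("R", "B", "E", "-"))
  s2 <- list(c("E", "E", "R"), c("G", "E", "E"))
  m <- mapStrandTwo(aln, s2)
  expect_equal(m[1, ], c("E", "-", "E", "R"))
  expect_equal(m[2, ], c("G", "E", "E", "-"))
  expect_error(mapStrandTwo(aln, s2[1]), "one strand-2")
})

test_that("binding footprints repeat at the crossover period", {
  m <- simulateBinding(buildLattice(LatticeSpec(nRows = 4, nCols = 4,
                                                axisLength = 200)),
                       seed = 17)
  thinIds <- unique(thinNeighbors(m)$thin_id)
  profs <- lapply(thinIds, function(id) encodeProfiles(m, id)$strand1)
  # filaments are in helical register, so columns align position-wise;
  # the non-E occupancy track should autocorrelate at the strand-level
  # period 360 / (2 * (180 - |twist|)) ~ 13.4 strand positions
  occ <- Reduce("+", lapply(profs, function(p) as.numeric(p != "E")))
  occ <- occ - mean(occ)
  ac <- stats::acf(occ, lag.max = 20, plot = FALSE)$acf[-1]
  period <- 360 / (2 * (180 - 166.6))
  expect_equal(which.max(ac[8:20]) + 7, round(period), tolerance = 1)
})

test_that("angular distributions recover gate spans and group means", {
  m <- smallBoundModel()
  ori <- boundOrientations(m)
  ad <- angularDistribution(ori$orientation, ori$label)
  expect_setequal(ad$group, c("R", "G", "B"))
  expect_true(all(ad$spanDeg <= 120 + 1e-9))
  expect_true(all(ad$spanDeg > 90))
  # absolute azimuths of the three groups sit ~120 degrees apart
  sub <- subunits(m)
  hd <- myosinHeads(m)
  nb <- thinNeighbors(m)
  az <- sub$azimuth[match(paste(hd$filament_id, hd$subunit_k),
                          paste(sub$filament_id, sub$k))]
  lab <- nb$label[match(paste(hd$filament_id, hd$origin_thick_id),
                        paste(nb$thin_id, nb$thick_id))]
  # restrict to one thin filament (groups share bearings only within
  # a filament)
  keep <- hd$filament_id == hd$filament_id[1]
  mns <- vapply(split(az[keep], lab[keep]), circularMean, numeric(1))
  expect_true(all(abs(wrapTo180(diff(sort(mns)) - 120)) < 25))
  # single observation: zero span, mean equal to the angle
  one <- angularDistribution(33, "only")
  expect_equal(one$spanDeg, 0)
  expect_equal(one$circularMeanDeg, 33)
  expect_warning(angularDistribution(numeric(0), factor(levels = "x")),
                 "empty")
})

test_that("distance summaries detect differences and skewness", {
  set.seed(41)
  b <- rnorm(500, 25.9, 2.7)
  f <- rnorm(1500, 26.3, 2.7)
  ds <- distanceSummary(b, f)
  expect_equal(ds$differenceNm, mean(f) - mean(b))
  expect_lt(ds$ci[1], ds$differenceNm)
  expect_gt(ds$ci[2], ds$differenceNm)
  # identical populations: CI straddles zero
  x <- rnorm(800, 26, 2.7)
  ds0 <- distanceSummary(x, x)
  expect_lt(ds0$ci[1], 0 + 1e-9)
  expect_gte(ds0$ci[2], 0)
  # strongly log-normal input is flagged as skewed
  ln <- exp(rnorm(2000, 0, 0.8))
  dsl <- distanceSummary(ln, rnorm(2000, 26, 2.7))
  expect_lt(dsl$bound$skew$p, 0.01)
  expect_gt(abs(dsl$bound$skew$z), 2)
  expect_gt(dsl$free$skew$p, 0.001)
  expect_error(distanceSummary(1, c(1, 2)), "at least 2")
  # bootstrap CI is close to the Welch CI and seeded-reproducible
  db1 <- distanceSummary(b, f, ciMethod = "bootstrap", nBoot = 2000,
                         seed = 5)
  db2 <- distanceSummary(b, f, ciMethod = "bootstrap", nBoot = 2000,
                         seed = 5)
  expect_identical(db1$ci, db2$ci)
  expect_equal(db1$ci, ds$ci, tolerance = 0.15)
})

test_that("the three-measurement rule books every subunit thrice", {
  m <- smallBoundModel()
  d <- filamentDistances(m)
  expect_equal(d$nMeasurements, 3 * nrow(subunits(m)))
  expect_equal(length(d$bound), nrow(myosinHeads(m)))
  expect_equal(length(d$free),
               3 * nrow(subunits(m)) - nrow(myosinHeads(m)))
  # jitter-free lattice: all distances are the interstitial 26 nm
  expect_equal(unique(round(c(d$bound, d$free), 2)), 25.98)
})

test_that("the orientation rose plot renders without error", {
  m <- smallBoundModel()
  ori <- boundOrientations(m)
  ad <- angularDistribution(ori$orientation, ori$label)
  pdf(NULL)
  on.exit(dev.off())
  expect_no_error(plotAngularDistribution(ad))
})
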