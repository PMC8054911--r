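test_that("jitter-free lattice reproduces closed-form distances", {
  m <- buildLattice(LatticeSpec(nRows = 4, nCols = 4,
                                axisLength = 100))
  fil <- filaments(m)
  nb <- thinNeighbors(m)
  # every thin filament's three thick-neighbour distances equal a/sqrt(3)
  d <- sqrt((fil$x[match(nb$thick_id, fil$id)] -
               fil$x[match(nb$thin_id, fil$id)])^2 +
            (fil$z[match(nb$thick_id, fil$id)] -
               fil$z[match(nb$thin_id, fil$id)])^2) / 10
  expect_equal(d, rep(45 / sqrt(3), nrow(nb)), tolerance = 1e-9)
  expect_equal(round(unique(round(d, 6))), 26)  # the ~26 nm spacing
  # nearest thick-thick distance is exactly the lattice constant
  th <- fil[fil$kind == "thick", ]
  dm <- as.matrix(dist(cbind(th$x, th$z))) / 10
  diag(dm) <- Inf
  expect_equal(min(dm), 45, tolerance = 1e-9)
  expect_equal(unname(apply(dm, 1, min)), rep(45, nrow(th)),
               tolerance = 1e-9)
})

test_that("lattice construction validates its spec", {
  expect_error(LatticeSpec(thickSpacing = -45), "thickSpacing")
  expect_error(LatticeSpec(jitterSd = -1), "jitterSd")
  expect_error(LatticeSpec(nRows = 0), "nRows")
  expect_error(buildLattice(LatticeSpec(nRows = 1, nCols = 1)),
               "too small")
})

test_that("grown filaments respect rise, strand parity and azimuth", {
  g <- growFilament(c(0, 0, 0), c(0, 1, 0), 20)
  expect_equal(g$y[g$k == 13], 13 * 27.9)          # 362.7 A
  expect_equal(diff(g$y[g$strand == 0])[1], 55.8)  # same-strand spacing
  expect_equal(g$azimuth[g$k == 2], 26.8)
  expect_equal(g$strand, as.integer(g$k %% 2))
})

test_that("same seed and specs give bitwise-identical models", {
  spec <- LatticeSpec(nRows = 4, nCols = 4, jitterSd = 1,
                      axisLength = 100)
  m1 <- simulateBinding(buildLattice(spec, seed = 7), seed = 8)
  m2 <- simulateBinding(buildLattice(spec, seed = 7), seed = 8)
  expect_identical(filaments(m1), filaments(m2))
  expect_identical(subunits(m1), subunits(m2))
  expect_identical(myosinHeads(m1), myosinHeads(m2))
  z1 <- buildZdisc(seed = 5)
  z2 <- buildZdisc(seed = 5)
  expect_identical(crossLinks(z1), crossLinks(z2))
})

test_that("binding respects conservation invariants", {
  m <- smallBoundModel()
  hd <- myosinHeads(m)
  expect_gt(nrow(hd), 0)
  # each subunit binds at most one head
  expect_false(anyDuplicated(paste(hd$filament_id, hd$subunit_k)) > 0)
  # each myosin contributes at most two heads
  expect_lte(max(table(hd$myosin_id)), 2)
  # class totals account for every attached head
  topo <- classifyHeadTopology(hd)
  expect_equal(2 * topo$nDoublePairs + 2 * topo$nSplitPairs +
                 topo$nSingle, nrow(hd))
  # bound flags agree with the heads table
  sub <- subunits(m)
  expect_equal(sum(sub$bound), nrow(hd))
})

test_that("bound subunits always satisfy the orientation gate", {
  m <- smallBoundModel()
  ori <- boundOrientations(m)
  expect_gt(nrow(ori), 0)
  expect_true(all(abs(ori$orientation) <= 60 + 1e-9))
})

test_that("a vanishing gate attaches no heads", {
  m0 <- buildLattice(LatticeSpec(nRows = 4, nCols = 4, jitterSd = 0.5,
                                 axisLength = 100), seed = 3)
  mb <- simulateBinding(m0, BindingSpec(gateHalfwidth = 1e-4),
                        seed = 4)
  expect_equal(nrow(myosinHeads(mb)), 0)
})

test_that("binding statistics converge to the spec parameters", {
  occ <- numeric(); sng <- numeric(); spl <- numeric(); nH <- 0
  for (s in 1:2) {
    m <- simulateBinding(buildLattice(LatticeSpec(nRows = 5, nCols = 5,
                                                  axisLength = 200)),
                         seed = s)
    b <- m@metadata$binding
    t <- classifyHeadTopology(myosinHeads(m), b$theoretical_heads)
    occ <- c(occ, 100 * t$nHeads / b$theoretical_heads)
    sng <- c(sng, t$pctSingleOfAttached)
    spl <- c(spl, t$pctSplitOfAttached)
    nH <- nH + t$nHeads
  }
  # law-of-large-numbers checks at generous multiples of the binomial SE
  expect_lt(abs(mean(occ) - 82.5), 3)
  seS <- 100 * sqrt(0.083 * 0.917 / nH)
  expect_lt(abs(mean(sng) - 8.3), 3 * seS + 1)   # + fallback allowance
  seP <- 100 * sqrt(0.006 * 0.994 / nH)
  expect_lt(abs(mean(spl) - 0.6), 4 * seP)
})

test_that("binding spec validation rejects impossible fractions", {
  expect_error(BindingSpec(fracSingle = 0.7, fracSplit = 0.5),
               "exceed 1")
  expect_error(BindingSpec(gateHalfwidth = 0), "gateHalfwidth")
  expect_error(BindingSpec(pAttach = 1.2), "lie in")
})

test_that("Z-disc generator places doublets at 2 x rise", {
  expect_equal(2 * 27.9 / 10, 5.58)  # ideal doublet spacing (nm)
  zm <- buildZdisc(ZdiscSpec(doubletProb = 1), seed = 11)
  cl <- crossLinks(zm)
  expect_gt(sum(!is.na(cl$doublet_of)), 0)
  prt <- cl[!is.na(cl$doublet_of), ]
  base <- cl[match(prt$doublet_of, cl$id), ]
  expect_equal(abs(prt$ya - base$ya), rep(55.8, nrow(prt)),
               tolerance = 1e-9)
})

test_that("Z-disc spec validation enforces the obtuse angle", {
  expect_error(ZdiscSpec(actininAngle = 80), "90, 180")
  expect_error(ZdiscSpec(actininAngle = 180), "90, 180")
  expect_error(ZdiscSpec(actininLength = 5, actinDiameter = 6),
               "exceed")
})

test_that("tropomyosin assignment splits states at the boundary", {
  m <- buildLattice(LatticeSpec(nRows = 4, nCols = 4,
                                axisLength = 100))
  m <- assignTropomyosin(m, boundary = 5, noiseSd = 0)
  sub <- subunits(m)
  expect_equal(unique(sub$tpm_offset[sub$y < 50]), 0)
  expect_equal(unique(sub$tpm_offset[sub$y >= 50]), 21)
  # boundary at the filament midpoint -> equal halves (even count)
  n <- length(unique(sub$k))
  mid <- (n - 1) * 27.9 / 2
  m2 <- assignTropomyosin(m, boundary = mid / 10 + 1e-9, noiseSd = 0)
  s2 <- subunits(m2)
  if (n %% 2 == 0)
    expect_equal(sum(s2$tpm_offset == 0), sum(s2$tpm_offset == 21))
})

test_that("rasterised volumes put peak density on a filament axis", {
  m <- buildLattice(LatticeSpec(nRows = 3, nCols = 3,
                                axisLength = 60))
  vol <- rasterizeVolume(m, voxelSize = 20, includeHeads = FALSE)
  idx <- arrayInd(which.max(vol@data), dim(vol@data))
  px <- vol@origin[1] + (idx[1] - 1) * vol@voxelSize
  pz <- vol@origin[3] + (idx[3] - 1) * vol@voxelSize
  fil <- filaments(m)
  expect_lt(min(sqrt((fil$x - px)^2 + (fil$z - pz)^2)),
            vol@voxelSize)
})

test_that("volume noise is zero-mean at the requested level", {
  m <- buildLattice(LatticeSpec(nRows = 3, nCols = 3,
                                axisLength = 60))
  v1 <- rasterizeVolume(m, voxelSize = 20, includeHeads = FALSE)
  v2 <- rasterizeVolume(m, voxelSize = 20, includeHeads = FALSE,
                        snr = 2, seed = 9)
  noise <- v2@data - v1@data
  expect_lt(abs(mean(noise)), 3 * sd(noise) / sqrt(length(noise)))
  expect_equal(sd(noise), max(v1@data) / 2, tolerance = 0.05)
})

test_that("rendered A-band cross-sections repeat at the lattice spacing", {
  m <- buildLattice(LatticeSpec(nRows = 3, nCols = 4,
                                axisLength = 60))
  vol <- rasterizeVolume(m, voxelSize = 15, includeHeads = FALSE)
  # line profile along X through the z = 0 row of thick filaments
  iy <- round(dim(vol@data)[2] / 2)
  iz <- round((0 - vol@origin[3]) / vol@voxelSize) + 1
  prof <- vol@data[, iy, iz]
  pk <- which(diff(sign(diff(prof))) == -2) + 1
  pk <- pk[prof[pk] > 0.5 * max(prof)]
  expect_equal(diff(pk) * vol@voxelSize, rep(450, length(pk) - 1),
               tolerance = 0.05)
})

test_that("the missing wedge removes energy but preserves the mean", {
  m <- buildLattice(LatticeSpec(nRows = 3, nCols = 3,
                                axisLength = 60))
  v0 <- rasterizeVolume(m, voxelSize = 20, includeHeads = FALSE)
  vw <- rasterizeVolume(m, voxelSize = 20, includeHeads = FALSE,
                        missingWedgeHalfangle = 30)
  expect_equal(mean(vw@data), mean(v0@data), tolerance = 1e-8)
  expect_lt(sum(vw@data^2), sum(v0@data^2))
})

test_that("oversized voxels trigger the undersampling warning", {
  m <- buildLattice(LatticeSpec(nRows = 3, nCols = 3,
                                axisLength = 60))
  expect_warning(rasterizeVolume(m, voxelSize = 50,
                                 filamentRadius = 40,
                                 includeHeads = FALSE),
                 "undersampled")
})
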