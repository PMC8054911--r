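volFixture <- local({
  cache <- new.env()
  function(rows = 3, cols = 3, len = 80, heads = FALSE, vox = 20) {
    key <- paste(rows, cols, len, heads, vox)
    if (is.null(cache[[key]])) {
      m <- buildLattice(LatticeSpec(nRows = rows, nCols = cols,
                                    axisLength = len))
      if (heads) m <- simulateBinding(m, seed = 21)
      cache[[key]] <- list(model = m,
                           vol = rasterizeVolume(m, voxelSize = vox,
                                                 includeHeads = heads))
    }
    cache[[key]]
  }
})

test_that("the equatorial filter is the identity at full bandwidth", {
  vol <- volFixture()$vol
  out <- equatorFilter(vol, keepHalfwidth = 0.5)
  expect_equal(out@data, vol@data, tolerance = 1e-10)
})

test_that("the equatorial filter is an idempotent projection", {
  vol <- volFixture()$vol
  f1 <- equatorFilter(vol, keepHalfwidth = 0.08)
  f2 <- equatorFilter(f1, keepHalfwidth = 0.08)
  expect_equal(f2@data, f1@data, tolerance = 1e-10)
})

test_that("the equatorial filter preserves the DC component exactly", {
  vol <- volFixture()$vol
  f <- equatorFilter(vol, keepHalfwidth = 0.05)
  for (iz in c(1, 3)) # per-slice means are the slice DC terms
    expect_equal(mean(f@data[, , iz]), mean(vol@data[, , iz]),
                 tolerance = 1e-12)
  expect_error(equatorFilter(vol, 0), "keepHalfwidth")
  expect_error(equatorFilter(vol, 0.7), "keepHalfwidth")
})

test_that("equatorial filtering suppresses cross-bridges, not tubes", {
  fx <- volFixture(heads = TRUE)
  vol <- fx$vol
  filt <- equatorFilter(vol, keepHalfwidth = 0.05)
  at <- function(v, x, y, z) {
    i <- round((c(x, y, z) - v@origin) / v@voxelSize) + 1
    v@data[i[1], i[2], i[3]]
  }
  hd <- myosinHeads(fx$model)
  fil <- filaments(fx$model)
  # head blob centres, displaced off the thin-filament axis
  hGain <- vapply(seq_len(min(25, nrow(hd))), function(r) {
    at(filt, hd$x[r], hd$y[r], hd$z[r]) /
      at(vol, hd$x[r], hd$y[r], hd$z[r])
  }, numeric(1))
  th <- fil[fil$kind == "thick", ]
  tGain <- vapply(seq_len(nrow(th)), function(r) {
    at(filt, th$x[r], 400, th$z[r]) / at(vol, th$x[r], 400, th$z[r])
  }, numeric(1))
  expect_gt(mean(tGain), 0.9)   # tube ridge preserved within 10%
  expect_lt(mean(hGain), mean(tGain) - 0.15)  # bridges attenuated
})

test_that("a single filament yields one detection per plane on axis", {
  hx <- HelixSpec()
  fil <- data.frame(id = 1L, kind = "thin",
                    polarity = "plus_toward_z_disc",
                    x = 100, z = 60, y0 = 0, y1 = 600)
  pts <- data.frame(filament_id = 1L, point_index = 0:1,
                    x = 100, y = c(0, 600), z = 60)
  m <- new("SarcomereModel", filaments = fil, points = pts,
           helix = hx, lattice = LatticeSpec())
  vol <- rasterizeVolume(m, voxelSize = 20)
  det <- detectCrossSections(vol, blobSigma = 50, threshold = 0.5)
  perPlane <- table(det$plane_index)
  expect_true(all(perPlane == 1))
  expect_true(all(abs(det$x - 100) <= 10))  # within half a voxel
  expect_true(all(abs(det$z - 60) <= 10))
})

test_that("an empty volume yields no detections", {
  vol <- TomoVolume(array(0, c(16, 10, 16)), voxelSize = 20)
  det <- detectCrossSections(vol, blobSigma = 50, threshold = 1e-6,
                             relative = FALSE)
  expect_equal(nrow(det), 0)
})

test_that("detections per plane count the filaments crossing it", {
  fx <- volFixture()
  filt <- equatorFilter(fx$vol, keepHalfwidth = 0.1)
  det <- detectCrossSections(filt, blobSigma = 50, threshold = 0.3)
  nFil <- nrow(filaments(fx$model))
  # interior planes (filaments span the whole y range)
  counts <- table(det$plane_index)
  inner <- counts[seq(5, length(counts) - 5)]
  expect_true(all(inner == nFil))
})

test_that("linking recovers straight filaments end to end", {
  fx <- volFixture()
  tr <- traceFilaments(fx$vol, minLength = 400)
  fil <- filaments(fx$model)
  expect_equal(length(unique(tr$trace_id)), nrow(fil))
  for (tid in unique(tr$trace_id)) {
    tp <- tr[tr$trace_id == tid, ]
    d <- sqrt((fil$x - mean(tp$x))^2 + (fil$z - mean(tp$z))^2)
    expect_lt(min(d), 20)  # matches a true axis within one voxel
    expect_lt(max(abs(tp$x - fil$x[which.min(d)])), 20)
  }
})

test_that("filaments farther than maxStep are never merged", {
  det <- rbind(
    data.frame(plane_index = rep(1:10, 2), x = rep(c(0, 500), each = 10),
               y = rep((1:10) * 20, 2), z = 0, response = 1))
  tr <- linkDetections(det, maxStep = 60, minLength = 100)
  expect_equal(length(unique(tr$trace_id)), 2)
  for (tid in unique(tr$trace_id))
    expect_equal(length(unique(tr$x[tr$trace_id == tid])), 1)
})

test_that("gaps of up to two planes are bridged", {
  keep <- setdiff(1:12, 6)  # one missing plane
  det <- data.frame(plane_index = keep, x = 100, y = keep * 20, z = 50,
                    response = 1)
  tr <- linkDetections(det, maxStep = 60, minLength = 100, maxGap = 2)
  expect_equal(length(unique(tr$trace_id)), 1)
  keep3 <- setdiff(1:12, 5:8)  # four missing planes: too wide
  det3 <- data.frame(plane_index = keep3, x = 100, y = keep3 * 20,
                     z = 50, response = 1)
  tr3 <- linkDetections(det3, maxStep = 60, minLength = 50, maxGap = 2)
  expect_equal(length(unique(tr3$trace_id)), 2)
})

test_that("short traces are discarded by minLength", {
  det <- data.frame(plane_index = 1:3, x = 0, y = (1:3) * 20, z = 0,
                    response = 1)
  expect_equal(nrow(linkDetections(det, maxStep = 60,
                                   minLength = 500)), 0)
  expect_gt(nrow(linkDetections(det, maxStep = 60, minLength = 30)), 0)
})

test_that("lattice statistics recover the 45 / 26 nm modes", {
  m <- buildLattice(LatticeSpec(nRows = 4, nCols = 4,
                                axisLength = 100))
  ml <- measureLattice(modelTraceTable(m), planePosition = 500)
  expect_equal(unique(round(ml$thickThickNm, 6)), 45)
  expect_equal(unique(round(ml$thinThickNm, 2)), 25.98)
  expect_equal(round(unique(round(ml$thinThickNm, 2))), 26)
  expect_equal(ml$hexOrder, 1, tolerance = 1e-9)
  expect_error(measureLattice(modelTraceTable(m)[1:2, ], 500),
               "at least 3")
})

test_that("jittered I-band lattices are less hexagonally ordered", {
  mA <- buildLattice(LatticeSpec(nRows = 4, nCols = 4,
                                 axisLength = 100))
  mI <- buildLattice(LatticeSpec(nRows = 4, nCols = 4, jitterSd = 3,
                                 band = "I", axisLength = 100),
                     seed = 13)
  oA <- measureLattice(modelTraceTable(mA), 500)$hexOrder
  oI <- measureLattice(modelTraceTable(mI), 500)$hexOrder
  expect_lt(oI, oA)
})

test_that("tracing recovers >= 95% of filaments with sub-voxel error", {
  fx <- volFixture(rows = 3, cols = 4, len = 100)
  tr <- traceFilaments(fx$vol, minLength = 500)
  fil <- filaments(fx$model)
  hits <- 0; errs <- numeric()
  for (i in seq_len(nrow(fil))) {
    best <- Inf
    for (tid in unique(tr$trace_id)) {
      tp <- tr[tr$trace_id == tid, ]
      d <- mean(sqrt((tp$x - fil$x[i])^2 + (tp$z - fil$z[i])^2))
      best <- min(best, d)
    }
    if (best < 20) { hits <- hits + 1; errs <- c(errs, best) }
  }
  expect_gte(hits / nrow(fil), 0.95)
  expect_lt(mean(errs), 20)  # mean axis error below one voxel
  # every reported point lies inside the volume bounding box
  d <- dim(fx$vol@data)
  expect_true(all(tr$x >= fx$vol@origin[1] &
                    tr$x <= fx$vol@origin[1] + (d[1] - 1) * 20))
  expect_true(all(tr$z >= fx$vol@origin[3] &
                    tr$z <= fx$vol@origin[3] + (d[3] - 1) * 20))
})
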