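# Shared fixtures and independent oracles for the test suite.

# Exhaustive global-alignment oracle with affine gaps: enumerates every
# alignment recursively (no dynamic programming shared with the
# implementation). First gap position of a run costs gapOpen, each
# further position gapExtend; runs are per sequence.
bruteForceAlignScore <- function(s1, s2, weights = profileWeights()) {
  W <- weights$matrix
  go <- weights$gapOpen
  ge <- weights$gapExtend
  rec <- function(i, j, state) {
    if (i > length(s1) && j > length(s2)) return(0)
    best <- -Inf
    if (i <= length(s1) && j <= length(s2))
      best <- max(best, W[s1[i], s2[j]] + rec(i + 1, j + 1, "M"))
    if (i <= length(s1))  # s1[i] against a gap in s2
      best <- max(best, (if (state == "X") ge else go) +
                    rec(i + 1, j, "X"))
    if (j <= length(s2))
      best <- max(best, (if (state == "Y") ge else go) +
                    rec(i, j + 1, "Y"))
    best
  }
  rec(1, 1, "M")
}

# Score an explicit pair of gapped rows under the same affine scheme
# (gap-gap columns are skipped).
scoreAlignedPair <- function(a1, a2, weights = profileWeights()) {
  W <- weights$matrix
  go <- weights$gapOpen
  ge <- weights$gapExtend
  keep <- !(a1 == "-" & a2 == "-")
  a1 <- a1[keep]; a2 <- a2[keep]
  sc <- 0
  state <- "M"
  for (c0 in seq_along(a1)) {
    if (a1[c0] == "-") {
      sc <- sc + if (state == "Y") ge else go
      state <- "Y"
    } else if (a2[c0] == "-") {
      sc <- sc + if (state == "X") ge else go
      state <- "X"
    } else {
      sc <- sc + W[a1[c0], a2[c0]]
      state <- "M"
    }
  }
  sc
}

# Small A-band model with simulated binding, reused across tests.
smallBoundModel <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulateBinding(
        buildLattice(LatticeSpec(nRows = 4, nCols = 4,
                                 axisLength = 150)),
        seed = 42)
    cache
  }
})

# Ground-truth trace table (trace_id, kind, x, y, z) from a model's
# axis polylines, for measureLattice and tracing oracles.
modelTraceTable <- function(model) {
  fil <- filaments(model)
  pts <- model@points
  pts$kind <- fil$kind[match(pts$filament_id, fil$id)]
  data.frame(trace_id = pts$filament_id, kind = pts$kind,
             x = pts$x, y = pts$y, z = pts$z)
}
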