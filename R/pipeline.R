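## End-to-end pipeline runner: simulate -> (optional rasterize + trace)
## -> binding / Z-disc / tropomyosin analyses, with one aggregated JSON
## report. Deterministic for a given seed: every stochastic stage draws
## its own seed derived from the run seed.

.cfgGet <- function(cfg, key, default = NULL) {
  v <- cfg[[key]]
  if (is.null(v)) default else v
}

#' Run the full synthetic-sarcomere analysis pipeline
#'
#' Builds an A-band model, simulates myosin binding, optionally
#' rasterises and re-traces it, optionally builds and analyses a Z-disc
#' model and tropomyosin sectioning, and writes the model tables plus a
#' single \code{report.json} aggregating all summary statistics.
#' Repeated runs with the same configuration and seed produce identical
#' reports.
#'
#' @param config a nested list, or the path of a YAML file holding one.
#'   Recognised blocks: \code{lattice}, \code{helix}, \code{binding},
#'   \code{zdisc}, \code{tpm}, \code{trace} -- each with the fields of
#'   the corresponding specification constructor (snake_case accepted)
#'   and an \code{enabled} flag for the analysis blocks -- plus
#'   top-level \code{seed} and \code{out_dir}.
#' @param outDir overrides \code{config$out_dir}.
#' @return invisibly, the report list (also written to
#'   \code{out_dir/report.json}).
#' @export
runPipeline <- function(config = list(), outDir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(.cfgGet(config, "seed", 1L))
  outDir <- if (!is.null(outDir)) outDir
            else .cfgGet(config, "out_dir", tempfile("sarcorun"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = seed)

  hx <- config$helix
  helix <- HelixSpec(twist = .cfgGet(hx, "twist", -166.6),
                     rise = .cfgGet(hx, "rise", 27.9),
                     theta0 = .cfgGet(hx, "theta0", 0))
  lt <- config$lattice
  lattice <- LatticeSpec(
    thickSpacing = .cfgGet(lt, "thick_spacing", 45),
    nRows = .cfgGet(lt, "n_rows", 4),
    nCols = .cfgGet(lt, "n_cols", 4),
    jitterSd = .cfgGet(lt, "jitter_sd", 0),
    band = .cfgGet(lt, "band", "A"),
    axisLength = .cfgGet(lt, "axis_length", 200))

  model <- buildLattice(lattice, helix, seed = seed)
  fil <- filaments(model)
  report$simulation <- list(
    n_thin = sum(fil$kind == "thin"),
    n_thick = sum(fil$kind == "thick"),
    n_subunits = nrow(subunits(model)))

  bc <- config$binding
  if (isTRUE(.cfgGet(bc, "enabled", TRUE)) &&
      sum(fil$kind == "thick") >= 3) {
    bspec <- BindingSpec(
      gateHalfwidth = .cfgGet(bc, "gate_halfwidth", 60),
      pAttach = .cfgGet(bc, "p_attach", 0.825),
      fracSingle = .cfgGet(bc, "frac_single", 0.083),
      fracSplit = .cfgGet(bc, "frac_split", 0.006))
    model <- simulateBinding(model, bspec, seed = seed + 1L)
    meta <- model@metadata$binding
    topo <- classifyHeadTopology(myosinHeads(model),
                                 meta$theoretical_heads)
    ori <- boundOrientations(model)
    ang <- angularDistribution(ori$orientation, ori$label)
    report$binding <- list(
      occupancy_pct = occupancyCensus(
        nrow(myosinHeads(model)), meta$theoretical_heads)$occupancyPct,
      topology = topo,
      mean_span_deg = mean(ang$spanDeg),
      groups = ang)
    dst <- filamentDistances(model)
    if (length(dst$bound) >= 2 && length(dst$free) >= 2) {
      ds <- distanceSummary(dst$bound, dst$free)
      report$binding$distance <- list(
        bound_mean_nm = ds$bound$meanNm, free_mean_nm = ds$free$meanNm,
        difference_nm = ds$differenceNm, ci = ds$ci)
    }
  }

  tc <- config$trace
  if (isTRUE(.cfgGet(tc, "enabled", FALSE))) {
    vol <- rasterizeVolume(model,
                           voxelSize = .cfgGet(tc, "voxel_size", 20),
                           snr = .cfgGet(tc, "snr", Inf),
                           seed = seed + 2L)
    tr <- traceFilaments(vol,
                         keepHalfwidth = .cfgGet(tc, "keep_halfwidth",
                                                 0.1),
                         blobSigma = .cfgGet(tc, "blob_sigma", 50),
                         threshold = .cfgGet(tc, "threshold", 0.3),
                         minLength = .cfgGet(tc, "min_length", 500))
    report$trace <- list(n_traces = length(unique(tr$trace_id)),
                         n_ground_truth = nrow(fil))
    writeMRC(vol, file.path(outDir, "volume.mrc"))
    utils::write.table(tr, file.path(outDir, "traces.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }

  zc <- config$zdisc
  if (isTRUE(.cfgGet(zc, "enabled", FALSE))) {
    zspec <- ZdiscSpec(
      actininLength = .cfgGet(zc, "actinin_length", 33),
      actininAngle = .cfgGet(zc, "actinin_angle", 128),
      doubletProb = .cfgGet(zc, "doublet_prob", 0.5),
      actinDiameter = .cfgGet(zc, "actin_diameter", 6),
      overlapLength = .cfgGet(zc, "overlap_length", 75))
    zm <- buildZdisc(zspec, seed = seed + 3L)
    geo <- crosslinkGeometry(zm)
    spd <- spacingAndDoublets(geo)
    report$zdisc <- list(
      n_crosslinks = nrow(geo),
      mean_length_nm = mean(geo$length_nm),
      mean_angle_deg = mean(geo$angle_deg),
      thickness_nm = zdiscThickness(zm),
      n_doublets = spd$nDoublets)
    writeModel(zm, file.path(outDir, "zdisc_model"))
  }

  pc <- config$tpm
  if (isTRUE(.cfgGet(pc, "enabled", FALSE))) {
    model <- assignTropomyosin(
      model,
      boundary = .cfgGet(pc, "boundary_nm", lattice@axisLength / 2),
      stateOffset = .cfgGet(pc, "state_offset", 21),
      noiseSd = .cfgGet(pc, "noise_sd", 3),
      seed = seed + 4L)
    sec <- sectionModel(model)
    tr <- locateTransition(sec)
    report$tpm <- list(sections = sec,
                       transition_index = tr$transitionIndex,
                       n_intermediate = tr$nIntermediate)
  }

  writeModel(model, file.path(outDir, "model"))
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(report)
}
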