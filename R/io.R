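## File interoperability: MRC2014 volumes, TSV+JSON model serialisation,
## and STAR particle-table import. Coordinates in files are Angstrom,
## axis order (x, y, z), 0-based voxel indices.

#' Read an MRC2014 volume
#'
#' Minimal MRC2014 reader: mode 2 (float32) volumes with the standard
#' 1024-byte header. Voxel size is taken as cell length / grid size;
#' the MRC2014 origin field is honoured.
#'
#' @param path file path.
#' @return a \code{\link{TomoVolume}}.
#' @export
readMRC <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 1024)
    stop("malformed MRC file (shorter than the 1024-byte header): ",
         path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdrInt <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- hdrInt[1]; ny <- hdrInt[2]; nz <- hdrInt[3]; mode <- hdrInt[4]
  mx <- hdrInt[8]; my <- hdrInt[9]; mz <- hdrInt[10]
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  invisible(readBin(con, "numeric", n = 3, size = 4, endian = "little"))
  mapcrs <- readBin(con, "integer", n = 3, size = 4, endian = "little")
  invisible(readBin(con, "numeric", n = 3, size = 4, endian = "little"))
  ispg <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  nsymbt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  invisible(readBin(con, "raw", n = 4 * 25))           # extra
  origin <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  map <- rawToChar(readBin(con, "raw", n = 4))
  if (nx <= 0 || ny <= 0 || nz <= 0)
    stop("malformed MRC header (non-positive dimensions) at offset 0")
  if (mode != 2)
    stop("unsupported MRC mode ", mode, " (only mode 2 float32)",
         " at header offset 12")
  if (!identical(map, "MAP "))
    warning("MRC header lacks the 'MAP ' magic at offset 208")
  need <- 1024 + nsymbt + 4 * as.numeric(nx) * ny * nz
  if (sz < need)
    stop(sprintf(
      "truncated MRC file: %d bytes, need %.0f (data from offset %d)",
      sz, need, 1024 + nsymbt))
  seek(con, 1024 + nsymbt)
  dat <- readBin(con, "numeric", n = nx * ny * nz, size = 4,
                 endian = "little")
  vox <- if (mx > 0) cella[1] / mx else 1
  TomoVolume(array(dat, c(nx, ny, nz)), voxelSize = vox,
             origin = origin)
}

#' Write an MRC2014 volume
#'
#' Writes mode 2 (float32), voxel size in the cell dimensions, origin
#' in the MRC2014 origin field.
#'
#' @param vol a \code{\link{TomoVolume}}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeMRC <- function(vol, path) {
  d <- dim(vol@data)
  con <- file(path, "wb")
  on.exit(close(con))
  wI <- function(x) writeBin(as.integer(x), con, size = 4,
                             endian = "little")
  wF <- function(x) writeBin(as.numeric(x), con, size = 4,
                             endian = "little")
  wI(d); wI(2)                       # nx ny nz, mode
  wI(c(0, 0, 0)); wI(d)              # nstart, m
  wF(d * vol@voxelSize)              # cella
  wF(c(90, 90, 90))                  # cellb
  wI(c(1, 2, 3))                     # mapc mapr maps
  dm <- range(vol@data)
  wF(c(dm[1], dm[2], mean(vol@data)))
  wI(1); wI(0)                       # ispg, nsymbt
  writeBin(raw(4 * 25), con)         # extra
  wF(vol@origin)                     # MRC2014 origin
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian
  wF(stats::sd(vol@data))            # rms
  wI(0)                              # nlabl
  writeBin(raw(800), con)            # labels
  writeBin(as.numeric(vol@data), con, size = 4, endian = "little")
  invisible(path)
}

.spec2list <- function(obj) {
  out <- lapply(methods::slotNames(obj), function(s)
    methods::slot(obj, s))
  names(out) <- methods::slotNames(obj)
  out
}

.list2spec <- function(cls, lst) {
  do.call(methods::new, c(list(cls), lst))
}

.modelTables <- c(filaments = "filaments.tsv", points = "points.tsv",
                  subunits = "subunits.tsv", heads = "heads.tsv",
                  crosslinks = "crosslinks.tsv",
                  neighbors = "neighbors.tsv")

#' Serialise a sarcomere model to a directory
#'
#' Writes one TSV per component table plus a JSON metadata file holding
#' the helix/lattice/Z-disc specifications, the seed and provenance.
#' Coordinates are Angstrom, indices 0-based.
#'
#' @param model a \code{\link{SarcomereModel}}.
#' @param dir output directory (created if needed).
#' @return invisibly, \code{dir}.
#' @export
writeModel <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (slot in names(.modelTables))
    utils::write.table(methods::slot(model, slot),
                       file.path(dir, .modelTables[[slot]]),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(helix = .spec2list(model@helix),
               lattice = .spec2list(model@lattice),
               zdisc = .spec2list(model@zdisc),
               seed = model@seed,
               generator = model@metadata$generator,
               tpm = model@metadata$tpm,
               binding = {
                 b <- model@metadata$binding
                 if (!is.null(b)) b$spec <- .spec2list(b$spec)
                 b
               })
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

.requireCols <- function(df, cols, file) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("schema error in ", file, ": missing column(s) ",
         paste(miss, collapse = ", "))
  df
}

#' Read a serialised sarcomere model
#'
#' Reads the TSV+JSON layout written by \code{\link{writeModel}},
#' validating schemas and referential integrity (subunits, heads and
#' cross-links must reference existing filaments/subunits).
#'
#' @param dir model directory.
#' @return a \code{\link{SarcomereModel}}.
#' @export
readModel <- function(dir) {
  rd <- function(f, proto) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("missing model table: ", f)
    df <- utils::read.table(p, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    if (!nrow(df)) return(proto)
    df <- .requireCols(df, names(proto), f)[, names(proto),
                                            drop = FALSE]
    for (nm in names(proto))   # all-NA columns read back as logical
      df[[nm]] <- methods::as(df[[nm]], class(proto[[nm]]))
    df
  }
  fil <- rd("filaments.tsv", emptyFilaments())
  pts <- rd("points.tsv", emptyPoints())
  sub <- rd("subunits.tsv", emptySubunits())
  hd <- rd("heads.tsv", emptyHeads())
  cl <- rd("crosslinks.tsv", emptyCrosslinks())
  nb <- rd("neighbors.tsv", emptyNeighbors())
  bad <- setdiff(sub$filament_id, fil$id)
  if (length(bad))
    stop("integrity error: subunits reference unknown filaments ",
         paste(unique(bad), collapse = ", "))
  if (nrow(hd)) {
    key <- paste(hd$filament_id, hd$subunit_k)
    skey <- paste(sub$filament_id, sub$k)
    if (!all(key %in% skey))
      stop("integrity error: heads reference unknown subunits (rows ",
           paste(which(!key %in% skey), collapse = ", "), ")")
  }
  bad <- setdiff(c(cl$fil_a, cl$fil_b), fil$id)
  if (length(bad))
    stop("integrity error: crosslinks reference unknown filaments ",
         paste(unique(bad), collapse = ", "))
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  m <- new("SarcomereModel", filaments = fil, points = pts,
           subunits = sub, heads = hd, crosslinks = cl, neighbors = nb,
           helix = .list2spec("HelixSpec", meta$helix),
           lattice = .list2spec("LatticeSpec",
                                within(meta$lattice, {
                                  nRows <- as.integer(nRows)
                                  nCols <- as.integer(nCols)
                                })),
           zdisc = .list2spec("ZdiscSpec", meta$zdisc),
           seed = if (is.null(meta$seed)) NA_integer_
                  else as.integer(meta$seed),
           metadata = list(generator = meta$generator,
                           tpm = meta$tpm))
  if (!is.null(meta$binding)) {
    b <- meta$binding
    b$spec <- .list2spec("BindingSpec",
                         within(b$spec,
                                minPairGap <- as.integer(minPairGap)))
    m@metadata$binding <- b
  }
  m
}

#' Import particle coordinates from a STAR file
#'
#' Minimal reader for RELION-style STAR particle tables: finds the
#' first \code{loop_} block containing \code{_rlnCoordinateX/Y/Z},
#' returns positions in Angstrom (coordinates multiplied by
#' \code{pixelSize}); Euler angles, if present, are ignored.
#'
#' @param path STAR file path.
#' @param pixelSize A per pixel used to scale coordinates.
#' @return data.frame with x, y, z (A) and any other columns as
#'   characters.
#' @examples
#' star <- system.file("extdata", "synthetic_particles.star",
#'                     package = "sarcotomo")
#' readStarParticles(star, pixelSize = 1.76)
#' @export
readStarParticles <- function(path, pixelSize = 1) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  li <- which(lines == "loop_")
  if (!length(li)) stop("no loop_ block in STAR file: ", path)
  for (start in li) {
    i <- start + 1
    cols <- character()
    while (i <= length(lines) && startsWith(lines[i], "_")) {
      cols <- c(cols, sub("\\s+#\\d+$", "", lines[i]))
      i <- i + 1
    }
    if (!all(c("_rlnCoordinateX", "_rlnCoordinateY",
               "_rlnCoordinateZ") %in% cols)) next
    rows <- list()
    while (i <= length(lines) && nzchar(lines[i]) &&
           !startsWith(lines[i], "data_") && lines[i] != "loop_") {
      rows[[length(rows) + 1L]] <- strsplit(lines[i], "\\s+")[[1]]
      i <- i + 1
    }
    if (!length(rows)) stop("empty STAR particle loop in ", path)
    mat <- do.call(rbind, rows)
    if (ncol(mat) != length(cols))
      stop("STAR loop row width does not match column count in ", path)
    df <- as.data.frame(mat, stringsAsFactors = FALSE)
    names(df) <- cols
    out <- data.frame(
      x = as.numeric(df[["_rlnCoordinateX"]]) * pixelSize,
      y = as.numeric(df[["_rlnCoordinateY"]]) * pixelSize,
      z = as.numeric(df[["_rlnCoordinateZ"]]) * pixelSize)
    extra <- setdiff(cols, c("_rlnCoordinateX", "_rlnCoordinateY",
                             "_rlnCoordinateZ"))
    for (e in extra) out[[e]] <- df[[e]]
    return(out)
  }
  stop("no particle loop with _rlnCoordinateX/Y/Z found in ", path)
}
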