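## Tropomyosin state localisation: 37-nm axial sectioning of thin
## filaments and classification of each section's circular-mean azimuth
## offset as M state, C state or intermediate.

#' Section a filament's tropomyosin offsets and classify states
#'
#' Sections of length \code{sectionLengthNm} are anchored at the A/I
#' boundary and grow into the I-band: section 1 is the last A-band
#' section, section 2 the first I-band section, and so on (sections
#' 0, -1, ... extend into the A-band). Each section's circular mean
#' offset is classified as the nearer of \code{refM} / \code{refC} when
#' within \code{marginDeg} of it, otherwise as "intermediate". Empty
#' sections are skipped. Classification is invariant under a common
#' rotation of offsets and references.
#'
#' @param y axial subunit positions (A).
#' @param tpmOffset per-subunit tropomyosin azimuth offsets (deg).
#' @param boundaryNm axial position of the A/I boundary (nm).
#' @param sectionLengthNm section length (nm, default 37).
#' @param refM,refC reference mean offsets of the M and C states (deg);
#'   they should differ by the ~21 degree azimuthal rotation.
#' @param marginDeg maximum circular distance to a reference for a hard
#'   state call.
#' @return data.frame: section_index, y_lo_nm, y_hi_nm, n_subunits,
#'   mean_offset, state.
#' @export
sectionAndClassify <- function(y, tpmOffset, boundaryNm,
                               sectionLengthNm = 37, refM = 0,
                               refC = 21, marginDeg = 5) {
  stopifnot(length(y) == length(tpmOffset))
  ok <- !is.na(tpmOffset)
  y <- y[ok]; tpmOffset <- tpmOffset[ok]
  if (!length(y)) stop("no tropomyosin offsets available")
  b <- boundaryNm * NM
  L <- sectionLengthNm * NM
  ## section index: 1 = [b - L, b), 2 = [b, b + L), 0 = [b - 2L, b - L)
  idx <- floor((y - b) / L) + 2L
  out <- NULL
  for (s in sort(unique(idx))) {
    rows <- idx == s
    mo <- circularMean(tpmOffset[rows], wrap = "180")
    dM <- abs(wrapTo180(mo - refM))
    dC <- abs(wrapTo180(mo - refC))
    state <- if (min(dM, dC) > marginDeg) "intermediate"
             else if (dM <= dC) "M" else "C"
    out <- rbind(out, data.frame(
      section_index = s,
      y_lo_nm = (b + (s - 2) * L) / NM,
      y_hi_nm = (b + (s - 1) * L) / NM,
      n_subunits = sum(rows), mean_offset = mo, state = state))
  }
  out
}

#' @rdname sectionAndClassify
#' @param model a \code{\link{SarcomereModel}} with tropomyosin offsets
#'   assigned (see \code{\link{assignTropomyosin}}).
#' @param filamentId thin filament to section (default: all pooled).
#' @param ... passed on to \code{sectionAndClassify}.
#' @export
sectionModel <- function(model, filamentId = NULL,
                         boundaryNm = model@metadata$tpm$boundary_nm,
                         ...) {
  sub <- model@subunits
  if (!is.null(filamentId)) sub <- sub[sub$filament_id %in% filamentId, ]
  if (is.null(boundaryNm)) stop("no boundary recorded or supplied")
  sectionAndClassify(sub$y, sub$tpm_offset, boundaryNm, ...)
}

#' Locate the M-to-C transition section
#'
#' Given sections ordered from the A-band into the I-band, returns the
#' index of the first section whose state is not "M" -- where the
#' tropomyosin transition occurs (observed as an intermediate section
#' immediately after the A/I boundary, with C-state sections beyond:
#' the transition completes mostly within one ~40-nm tropomyosin unit).
#'
#' @param sections data.frame from \code{\link{sectionAndClassify}}.
#' @return list: \code{transitionIndex} (section_index, or NA),
#'   \code{nIntermediate}, \code{states} in section order.
#' @export
locateTransition <- function(sections) {
  s <- sections[order(sections$section_index), ]
  nonM <- which(s$state != "M")
  if (!length(nonM))
    return(list(transitionIndex = NA_integer_, nIntermediate = 0L,
                states = s$state, message = "no-transition"))
  list(transitionIndex = s$section_index[nonM[1]],
       nIntermediate = sum(s$state == "intermediate"),
       states = s$state)
}
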