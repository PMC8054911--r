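## Lightweight base-graphics summaries of the two histogram-style
## analyses: grouped circular orientation distributions and cross-link
## spacing histograms.

#' Plot a grouped circular orientation distribution
#'
#' Rose-style plot of the per-group circular histograms produced by
#' \code{\link{angularDistribution}}: one radial polygon per group over
#' the (-180, 180] range, with the group's circular mean marked.
#'
#' @param ad result of \code{\link{angularDistribution}} (with its
#'   histogram attribute).
#' @param binWidth the bin width the distribution was computed with.
#' @param col colours, one per group.
#' @return invisibly, NULL.
#' @export
plotAngularDistribution <- function(ad, binWidth = 10,
                                    col = c("#D55E00", "#009E73",
                                            "#0072B2")) {
  h <- attr(ad, "histogram")
  if (is.null(h)) stop("no histogram attribute on the input")
  mids <- seq(-180 + binWidth / 2, 180 - binWidth / 2, by = binWidth)
  col <- rep_len(col, nrow(h))
  graphics::plot(NA, xlim = c(-1, 1), ylim = c(-1, 1), asp = 1,
                 axes = FALSE, xlab = "", ylab = "",
                 main = "Bound-subunit orientations by group")
  graphics::symbols(0, 0, circles = 1, inches = FALSE, add = TRUE,
                    fg = "grey70")
  for (g in seq_len(nrow(h))) {
    r <- h[g, ] / max(h)
    th <- mids * pi / 180
    graphics::polygon(c(0, r * cos(th), 0), c(0, r * sin(th), 0),
                      border = col[g], lwd = 2)
    mu <- ad$circularMeanDeg[g] * pi / 180
    graphics::arrows(0, 0, 1.05 * cos(mu), 1.05 * sin(mu),
                     length = 0.08, col = col[g])
  }
  graphics::legend("topright", bty = "n",
                   legend = sprintf("%s (span %.0f deg)", ad$group,
                                    ad$spanDeg),
                   col = col, lwd = 2)
  invisible(NULL)
}

#' Plot a cross-link spacing histogram
#'
#' Bar plot of the 3-nm-binned consecutive-spacing histogram from
#' \code{\link{spacingAndDoublets}}, with the doublet window shaded.
#'
#' @param sp result of \code{\link{spacingAndDoublets}}.
#' @param doubletWindowNm the doublet window to highlight (nm).
#' @return invisibly, NULL.
#' @export
plotSpacingHistogram <- function(sp, doubletWindowNm = c(3, 9)) {
  if (!length(sp$spacingsNm)) stop("no spacings to plot")
  mids <- sp$breaksNm[-1] - diff(sp$breaksNm) / 2
  cols <- ifelse(mids >= doubletWindowNm[1] &
                   mids < doubletWindowNm[2], "#D55E00", "grey60")
  graphics::barplot(sp$histogram, names.arg = sprintf("%.0f", mids),
                    col = cols, border = NA,
                    xlab = "consecutive cross-link spacing (nm)",
                    ylab = "count",
                    main = sprintf("%d doublet spacings", sp$nDoublets))
  invisible(NULL)
}
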