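## Zero-crossing analysis of differential spectra: band centres are
## positive-to-negative sign changes; band intensity is the peak-to-valley
## value of the two lobes flanking the crossing.

#' Locate band centres as zero crossings
#'
#' The spectrum is mildly smoothed (Savitzky-Golay; smoothing is applied to
#' the crossing search only, never to stored intensities), scanned for
#' positive-to-negative sign changes, and each crossing is localised by
#' linear interpolation between the bracketing bins. Crossings whose
#' flanking lobes both fail to exceed a robust noise floor (`noiseFloorK`
#' times the median absolute deviation of the smoothed spectrum) are
#' discarded. The noise level is estimated robustly as the MAD of the
#' high-frequency residual (raw minus smoothed intensity), so a noise-free
#' spectrum has a floor of zero and weak true bands are kept.
#'
#' @param wmr a [WMRSpectrum-class].
#' @param sgWindow Savitzky-Golay window length in bins (odd); default 9.
#' @param sgOrder Savitzky-Golay polynomial order; default 3.
#' @param flankWindow half-width (cm^-1) searched on each side of a crossing
#'   for its lobes; default 25.
#' @param noiseFloorK noise-floor multiplier on the MAD; default 3.
#' @return Numeric vector of crossing positions (cm^-1); possibly empty.
#' @export
findZeroCrossings <- function(wmr, sgWindow = 9, sgOrder = 3,
                              flankWindow = 25, noiseFloorK = 3) {
  ax <- spectralAxis(wmr)
  y0 <- intensityValues(wmr)
  y <- if (length(y0) > sgWindow) signal::sgolayfilt(y0, p = sgOrder,
                                                     n = sgWindow) else y0
  i <- which(y[-length(y)] > 0 & y[-1] < 0)
  if (!length(i)) return(numeric(0))
  x0 <- ax[i] + y[i] * (ax[i + 1] - ax[i]) / (y[i] - y[i + 1])
  floor <- noiseFloorK * stats::mad(y0 - y)
  keep <- vapply(x0, function(x) {
    lobeUp <- y[ax >= x - flankWindow & ax <= x]
    lobeDn <- y[ax >= x & ax <= x + flankWindow]
    length(lobeUp) > 0 && length(lobeDn) > 0 &&
      max(lobeUp) >= floor && -min(lobeDn) >= floor
  }, logical(1))
  x0[keep]
}

#' Match zero crossings to the reference catalogue
#'
#' Greedy nearest-distance assignment: candidate (reference, crossing) pairs
#' within the tolerance are assigned in order of increasing residual, each
#' crossing to at most one reference. Unmatched references are flagged, not
#' dropped.
#'
#' @param crossings numeric vector of crossing positions (cm^-1).
#' @param catalogue data.frame with a `position_cm1` column; default
#'   [referencePeaks()].
#' @param tol matching tolerance (cm^-1); default 8.
#' @return data.frame: `reference_cm1`, `observed_cm1` (NA if unmatched),
#'   `residual`, `matched`.
#' @export
matchToCatalogue <- function(crossings, catalogue = referencePeaks(),
                             tol = 8) {
  stopifnot(tol > 0)
  refs <- catalogue$position_cm1
  out <- data.frame(reference_cm1 = refs, observed_cm1 = NA_real_,
                    residual = NA_real_, matched = FALSE)
  if (length(crossings)) {
    cand <- expand.grid(r = seq_along(refs), c = seq_along(crossings))
    cand$d <- abs(refs[cand$r] - crossings[cand$c])
    cand <- cand[cand$d <= tol, , drop = FALSE]
    cand <- cand[order(cand$d), , drop = FALSE]
    usedC <- logical(length(crossings))
    for (k in seq_len(nrow(cand))) {
      r <- cand$r[k]; cc <- cand$c[k]
      if (out$matched[r] || usedC[cc]) next
      out$observed_cm1[r] <- crossings[cc]
      out$residual[r] <- crossings[cc] - refs[r]
      out$matched[r] <- TRUE
      usedC[cc] <- TRUE
    }
  }
  out
}

#' Peak-to-valley intensity around a band centre
#'
#' Difference between the maximum and minimum of the (unsmoothed)
#' differential intensity over a window around the crossing; for an exact
#' Lorentzian-derivative profile of amplitude A and half-width gamma this
#' equals \eqn{(9/(4\sqrt{3}))\,A/\gamma}.
#'
#' @param wmr a [WMRSpectrum-class].
#' @param center window centre (cm^-1).
#' @param window half-width (cm^-1); default 25.
#' @param lower,upper explicit window bounds (cm^-1); override `window`
#'   asymmetrically when supplied (used to clip windows at the midpoint to a
#'   neighbouring catalogue band).
#' @return Non-negative intensity difference.
#' @export
peakToValley <- function(wmr, center, window = 25,
                         lower = center - window, upper = center + window) {
  ax <- spectralAxis(wmr)
  if (lower < min(ax) || upper > max(ax))
    stop("peak-to-valley window outside the spectral axis")
  y <- intensityValues(wmr)[ax >= lower & ax <= upper]
  max(y) - min(y)
}

## per-reference window bounds, clipped at the midpoint to the nearest
## neighbouring catalogue band so close pairs (1040/1080, 1130/1150) never
## bridge
clippedWindows <- function(positions, window) {
  p <- sort(positions)
  lo <- p - window; hi <- p + window
  if (length(p) > 1) {
    mids <- (p[-length(p)] + p[-1]) / 2
    lo[-1] <- pmax(lo[-1], mids)
    hi[-length(p)] <- pmin(hi[-length(p)], mids)
  }
  data.frame(position_cm1 = p, lower = lo, upper = hi)
}

#' Quantify every catalogue band at every time point
#'
#' Per time point: locate zero crossings, match them to the catalogue, and
#' measure the peak-to-valley intensity in a window centred on the observed
#' crossing (clipped at midpoints between neighbouring catalogue bands and
#' at the axis limits). Unmatched bands are recorded as missing, never as a
#' spurious intensity.
#'
#' @param wmrList list of [WMRSpectrum-class], one per time point.
#' @param catalogue reference catalogue; default [referencePeaks()].
#' @param tol matching tolerance (cm^-1).
#' @param window peak-to-valley half-width (cm^-1) before clipping.
#' @param renormalize divide each band's series by its first non-missing
#'   value?
#' @param ... passed to [findZeroCrossings()].
#' @return data.frame: `reference_cm1`, `timestamp_h`, `observed_cm1`,
#'   `peak_to_valley`, `normalized` (NA where unmatched).
#' @export
quantifyRun <- function(wmrList, catalogue = referencePeaks(), tol = 8,
                        window = 25, renormalize = TRUE, ...) {
  stopifnot(length(wmrList) >= 1)
  wins <- clippedWindows(catalogue$position_cm1, window)
  rows <- lapply(wmrList, function(wmr) {
    m <- matchToCatalogue(findZeroCrossings(wmr, ...), catalogue, tol)
    ax <- spectralAxis(wmr)
    p2v <- rep(NA_real_, nrow(m))
    for (i in which(m$matched)) {
      w <- wins[match(m$reference_cm1[i], wins$position_cm1), ]
      shift <- m$observed_cm1[i] - m$reference_cm1[i]
      p2v[i] <- peakToValley(wmr, m$observed_cm1[i],
                             lower = max(w$lower + shift, min(ax)),
                             upper = min(w$upper + shift, max(ax)))
    }
    data.frame(reference_cm1 = m$reference_cm1,
               timestamp_h = timestampH(wmr),
               observed_cm1 = m$observed_cm1,
               peak_to_valley = p2v)
  })
  out <- do.call(rbind, rows)
  if (all(is.na(out$peak_to_valley)))
    stop("no catalogue band matched at any time point")
  out <- out[order(out$reference_cm1, out$timestamp_h), ]
  rownames(out) <- NULL
  out$normalized <- NA_real_
  if (renormalize) {
    for (p in unique(out$reference_cm1)) {
      i <- which(out$reference_cm1 == p & !is.na(out$peak_to_valley))
      if (length(i))
        out$normalized[i] <- out$peak_to_valley[i] / out$peak_to_valley[i[1]]
    }
  }
  out
}
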