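#' Extracted ion chromatograms and peak-shape similarity
#'
#' `extract_xic()` builds the chromatographic trace of a narrow m/z window
#' from one acquisition channel: one point per scan inside `rt_window`, with
#' intensity equal to the sum of centroid intensities within
#' `mz * (1 +/- tol_ppm * 1e-6)`; scans with no matching centroid contribute
#' zero.  Precursor traces should be extracted from the full-MS channel and
#' fragment traces from the AIF channel, where their intensity is highest.
#'
#' @param spectra a list of `aif_spectrum` objects (one acquisition channel,
#'   time-ordered), e.g. `run$ms1` or `run$aif`.
#' @param mz target m/z in Th.
#' @param tol_ppm extraction tolerance in ppm (> 0).
#' @param rt_window numeric length-2, retention-time window in minutes.
#' @param source_channel label stored on the trace (`"ms1"` or `"aif"`).
#' @return an object of class `xic`: list with `times` (min, strictly
#'   increasing), `intensities`, `target_mz`, `tol_ppm`, `source_channel`.
#' @export
extract_xic <- function(spectra, mz, tol_ppm, rt_window,
                        source_channel = NA_character_) {
  stopifnot(tol_ppm > 0, length(rt_window) == 2, rt_window[1] < rt_window[2])
  rts <- vapply(spectra, function(s) s$rt, numeric(1))
  sel <- which(rts >= rt_window[1] & rts <= rt_window[2])
  if (!length(sel)) stop("empty window: no scans in rt_window")
  lo <- mz * (1 - tol_ppm * 1e-6)
  hi <- mz * (1 + tol_ppm * 1e-6)
  ints <- vapply(sel, function(i) {
    s <- spectra[[i]]
    j <- which(s$mz >= lo & s$mz <= hi)
    if (length(j)) sum(s$intensity[j]) else 0
  }, numeric(1))
  structure(list(times = rts[sel], intensities = ints, target_mz = mz,
                 tol_ppm = tol_ppm, source_channel = source_channel),
            class = "xic")
}

#' @export
print.xic <- function(x, ...) {
  cat(sprintf("<xic> m/z %.4f (+/- %g ppm), %d points, rt %.3f-%.3f min, apex %.3g\n",
              x$target_mz, x$tol_ppm, length(x$times),
              min(x$times), max(x$times), max(x$intensities)))
  invisible(x)
}

#' Normalize an XIC to unit apex height
#'
#' Scales intensities so the maximum equals 1; times are unchanged.
#' Idempotent.  An all-zero trace cannot be normalized and raises an error.
#'
#' @param xic an `xic` object.
#' @return the normalized `xic`.
#' @export
normalize_xic <- function(xic) {
  m <- max(xic$intensities)
  if (m <= 0) stop("cannot normalize zero trace")
  xic$intensities <- xic$intensities / m
  xic
}

xic_apex <- function(xic) {
  i <- which.max(xic$intensities)
  list(rt = xic$times[i], intensity = xic$intensities[i])
}

#' Area between two normalized XICs
#'
#' The peak-shape similarity criterion: both traces are normalized to unit
#' apex height, linearly interpolated onto a shared uniform grid spanning
#' `rt_window` (MS1 and AIF scans are interleaved, so their time stamps never
#' coincide), and the mean absolute difference is integrated by the
#' trapezoid rule and divided by the window duration.  The result is
#' dimensionless in \[0, 2\]; a pair of identical shapes gives 0.  Values at
#' or below `threshold` pass the similarity filter.
#'
#' @param a,b `xic` objects overlapping `rt_window`; trace values outside a
#'   trace's sampled range are held at its boundary values.
#' @param rt_window numeric length-2 window in minutes.
#' @param threshold pass/fail threshold on the area (default 0.15).
#' @param grid_points number of uniform grid points (default 200).
#' @return an object of class `shape_comparison`: list with `area`,
#'   `threshold`, `passed`, `grid_points`.
#' @export
area_between <- function(a, b, rt_window, threshold = 0.15,
                         grid_points = 200L) {
  stopifnot(length(rt_window) == 2)
  T <- rt_window[2] - rt_window[1]
  if (T <= 0) stop("degenerate window")
  a <- normalize_xic(a)
  b <- normalize_xic(b)
  grid <- seq(rt_window[1], rt_window[2], length.out = grid_points)
  ya <- stats::approx(a$times, a$intensities, xout = grid, rule = 2)$y
  yb <- stats::approx(b$times, b$intensities, xout = grid, rule = 2)$y
  d <- abs(ya - yb)
  h <- diff(grid)
  area <- sum((d[-1] + d[-length(d)]) / 2 * h) / T
  structure(list(area = area, threshold = threshold,
                 passed = area <= threshold,
                 grid_points = as.integer(grid_points)),
            class = "shape_comparison")
}

#' @export
print.shape_comparison <- function(x, ...) {
  cat(sprintf("<shape_comparison> area %.4f vs threshold %.4f -> %s\n",
              x$area, x$threshold, if (x$passed) "pass" else "reject"))
  invisible(x)
}

#' Candidate fragment m/z values for a precursor
#'
#' Collects centroid m/z values from the AIF scan nearest the precursor's
#' chromatographic apex plus its two neighboring AIF scans, keeping peaks
#' with intensity at or above `min_fragment_intensity` and m/z not exceeding
#' the precursor m/z (within tolerance).  Values within `tol_ppm` of each
#' other are merged to their intensity-weighted mean.  Isotopologue
#' satellites (a centroid sitting one 13C spacing above a more intense
#' candidate) and the precursor's own residual peak are removed — they are
#' isotope peaks, not independent fragment masses.  The shape filter decides
#' later which survivors are true fragments.
#'
#' @param run an `aif_run`.
#' @param precursor_mz precursor m/z in Th.
#' @param precursor_rt precursor retention time in minutes.
#' @param config a [run_config()].
#' @return numeric vector of candidate m/z values, increasing.
#' @export
candidate_fragment_mzs <- function(run, precursor_mz, precursor_rt, config) {
  win <- precursor_rt + c(-1, 1) * config$rt_window
  rts <- vapply(run$aif, function(s) s$rt, numeric(1))
  sel <- which(rts >= win[1] & rts <= win[2])
  if (!length(sel)) stop("empty window: no AIF scans near precursor")
  # locate the precursor apex from its full-MS trace; fall back to the
  # nominal rt when the precursor is not seen in MS1
  apex_rt <- precursor_rt
  prec_xic <- tryCatch(
    extract_xic(run$ms1, precursor_mz, config$xic_tol_ppm, win, "ms1"),
    error = function(e) NULL)
  if (!is.null(prec_xic) && max(prec_xic$intensities) > 0)
    apex_rt <- xic_apex(prec_xic)$rt
  i0 <- sel[which.min(abs(rts[sel] - apex_rt))]
  take <- intersect(c(i0 - 1L, i0, i0 + 1L), sel)
  mzs <- numeric(0); ints <- numeric(0)
  for (i in take) {
    s <- run$aif[[i]]
    keep <- s$intensity >= config$min_fragment_intensity
    mzs <- c(mzs, s$mz[keep]); ints <- c(ints, s$intensity[keep])
  }
  if (!length(mzs)) return(numeric(0))
  o <- order(mzs); mzs <- mzs[o]; ints <- ints[o]
  # merge duplicates within tolerance to the intensity-weighted mean
  tol <- config$xic_tol_ppm * 1e-6
  grp <- cumsum(c(TRUE, diff(mzs) > mzs[-length(mzs)] * tol))
  mzm <- as.numeric(tapply(mzs * ints, grp, sum) / tapply(ints, grp, sum))
  im <- as.numeric(tapply(ints, grp, max))
  # de-isotope: drop centroids sitting one or two isotope spacings above a
  # stronger candidate.  The +1/+2 spacing intervals span 15N (0.9970)
  # through 13C (1.0034) and 34S (1.9958) through 13C2 (2.0067) but stop
  # short of the one- and two-hydrogen spacings (1.0078, 2.0157), so
  # fragment pairs differing by H or H2 are kept apart
  iso <- vapply(seq_along(mzm), function(i) {
    d <- mzm[i] - mzm
    j <- which((d >= 0.9960 & d <= 1.0055) | (d >= 1.9930 & d <= 2.0100))
    any(im[j] > im[i])
  }, logical(1))
  mzm <- mzm[!iso]; im <- im[!iso]
  keep <- mzm <= precursor_mz * (1 + config$xic_tol_ppm * 1e-6) &
    abs(mzm - precursor_mz) > precursor_mz * config$xic_tol_ppm * 1e-6
  sort(mzm[keep])
}
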