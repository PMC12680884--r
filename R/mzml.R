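#' In-memory containers for full MS/AIF acquisitions
#'
#' `new_spectrum()` builds one centroided scan; `acquisition_run()` bundles
#' the two channels of a full MS/AIF experiment: the unfragmented MS1 scans
#' and the all-ion-fragmentation (AIF) MS2 scans, each ordered by retention
#' time.  AIF scans carry no precursor isolation — every source ion is
#' fragmented — so any MS-level-2 scan belongs to the AIF channel.
#'
#' @param ms_level 1 (full MS) or 2 (AIF).
#' @param rt retention time in minutes.
#' @param mz numeric vector of centroid m/z values, strictly increasing.
#' @param intensity numeric vector of nonnegative intensities, same length.
#' @param collision_energies optional numeric vector of normalized collision
#'   energies (metadata only; stepped energies are pooled).
#' @return `new_spectrum()`: an object of class `aif_spectrum`.
#' @export
new_spectrum <- function(ms_level, rt, mz, intensity,
                         collision_energies = NULL) {
  ms_level <- as.integer(ms_level)
  if (!ms_level %in% c(1L, 2L)) stop("unknown MS level: ", ms_level)
  if (length(mz) != length(intensity))
    stop("mz and intensity lengths differ")
  if (length(mz) > 1 && any(diff(mz) <= 0))
    stop("mz must be strictly increasing")
  if (any(intensity < 0)) stop("negative intensity")
  structure(list(ms_level = ms_level, rt = as.numeric(rt),
                 mz = as.numeric(mz), intensity = as.numeric(intensity),
                 collision_energies = collision_energies),
            class = "aif_spectrum")
}

#' @param ms1,aif lists of `aif_spectrum` objects with MS level 1 / 2.
#' @param metadata list; recognized fields `source_file` and `polarity`
#'   (`"negative"` or `"positive"`, default negative).
#' @return `acquisition_run()`: an object of class `aif_run` with fields
#'   `ms1`, `aif`, `metadata`.
#' @rdname new_spectrum
#' @export
acquisition_run <- function(ms1, aif, metadata = list()) {
  chk <- function(ch, lvl) {
    for (s in ch) {
      stopifnot(inherits(s, "aif_spectrum"))
      if (s$ms_level != lvl) stop("wrong MS level in channel")
    }
    rts <- vapply(ch, function(s) s$rt, numeric(1))
    if (length(rts) > 1 && any(diff(rts) <= 0)) ch[order(rts)] else ch
  }
  if (is.null(metadata$polarity)) metadata$polarity <- "negative"
  structure(list(ms1 = chk(ms1, 1L), aif = chk(aif, 2L),
                 metadata = metadata), class = "aif_run")
}

#' @export
print.aif_run <- function(x, ...) {
  cat(sprintf("<aif_run> %d MS1 + %d AIF scans, polarity %s\n",
              length(x$ms1), length(x$aif), x$metadata$polarity))
  invisible(x)
}

run_rt_range <- function(run) {
  rts <- c(vapply(run$ms1, function(s) s$rt, numeric(1)),
           vapply(run$aif, function(s) s$rt, numeric(1)))
  range(rts)
}

#' Read a full MS/AIF run from an mzML file
#'
#' Parses a centroided mzML file (gzip accepted) via Bioconductor `mzR` and
#' splits the scans into the MS1 and AIF channels by MS level.  Retention
#' times are normalized to minutes.  Profile-mode spectra are rejected:
#' the shape and intensity semantics of the annotation pipeline are only
#' well-defined on centroided data.  Scans carrying an isolation window are
#' still treated as AIF (with a warning): the workflow assumes isolation-free
#' fragmentation.
#'
#' @param path path to an mzML file.
#' @param config a [run_config()]; supplies the default polarity when the
#'   file carries none.
#' @return an `aif_run`.
#' @export
read_run <- function(path, config = run_config()) {
  if (!file.exists(path)) stop("file not found: ", path)
  ms <- mzR::openMSfile(path)
  on.exit(mzR::close(ms), add = TRUE)
  hdr <- mzR::header(ms)
  if (nrow(hdr) == 0) stop("empty run")
  if (any(!is.na(hdr$centroided) & !hdr$centroided))
    stop("profile-mode spectra are not supported; centroid the data first")
  if (any(!hdr$msLevel %in% c(1L, 2L)))
    stop("unknown MS level in file")
  if (any(!is.na(hdr$isolationWindowTargetMZ) &
          hdr$isolationWindowTargetMZ > 0))
    warning("per-scan isolation windows present; treating all MS2 scans as AIF")
  pol <- unique(hdr$polarity[hdr$polarity %in% c(0L, 1L)])
  if (length(pol) > 1) stop("conflicting polarities across scans")
  polarity <- if (!length(pol)) config$polarity_default
              else if (pol == 1L) "positive" else "negative"
  pks <- mzR::peaks(ms)
  if (nrow(hdr) == 1) pks <- list(pks)
  specs <- lapply(seq_len(nrow(hdr)), function(i) {
    p <- pks[[i]]
    ce <- hdr$collisionEnergy[i]
    new_spectrum(hdr$msLevel[i], hdr$retentionTime[i] / 60,
                 p[, 1], p[, 2],
                 collision_energies = if (!is.na(ce) && ce > 0) ce else NULL)
  })
  acquisition_run(specs[hdr$msLevel == 1L], specs[hdr$msLevel == 2L],
                  metadata = list(source_file = basename(path),
                                  polarity = polarity))
}

#' Ionization polarity of a run
#'
#' @param run an `aif_run`.
#' @return `"negative"` or `"positive"`.
#' @export
polarity_of <- function(run) {
  pol <- run$metadata$polarity
  if (is.null(pol)) "negative" else pol
}

#' Write an acquisition run to an mzML file
#'
#' Serializes the MS1 and AIF channels, interleaved by retention time, as a
#' standard-conformant centroid mzML via `mzR`.  `read_run()` round-trips
#' the scan counts, MS levels, retention times and peak lists.
#'
#' @param run an `aif_run`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mzml <- function(run, path) {
  specs <- c(run$ms1, run$aif)
  if (!length(specs)) stop("empty run")
  rts <- vapply(specs, function(s) s$rt, numeric(1))
  specs <- specs[order(rts)]
  n <- length(specs)
  pol <- if (identical(polarity_of(run), "positive")) 1L else 0L
  pk <- lapply(specs, function(s) cbind(mz = s$mz, intensity = s$intensity))
  safe_max <- function(x) if (length(x)) max(x) else 0
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n),
    msLevel = vapply(specs, function(s) s$ms_level, integer(1)),
    polarity = pol,
    peaksCount = vapply(pk, nrow, integer(1)),
    totIonCurrent = vapply(specs, function(s) sum(s$intensity), numeric(1)),
    retentionTime = vapply(specs, function(s) s$rt * 60, numeric(1)),
    basePeakMZ = vapply(specs, function(s)
      if (length(s$mz)) s$mz[which.max(s$intensity)] else 0, numeric(1)),
    basePeakIntensity = vapply(specs, function(s)
      safe_max(s$intensity), numeric(1)),
    collisionEnergy = vapply(specs, function(s)
      if (is.null(s$collision_energies)) 0 else mean(s$collision_energies),
      numeric(1)),
    ionisationEnergy = 0,
    lowMZ = vapply(specs, function(s)
      if (length(s$mz)) min(s$mz) else 0, numeric(1)),
    highMZ = vapply(specs, function(s) safe_max(s$mz), numeric(1)),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0,
    mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)),
    centroided = TRUE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_,
    stringsAsFactors = FALSE)
  mzR::writeMSData(pk, path, header = hdr, outformat = "mzml")
  invisible(path)
}
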