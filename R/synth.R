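#' Specify a compound for the full MS/AIF simulator
#'
#' Encodes the measurement model the annotation pipeline assumes: a Gaussian
#' chromatographic elution profile shared by the precursor ion and all of
#' its CID fragments (fragmentation happens after the column), isotopologue
#' envelopes derived from the ion formulas, optional retention-shifted decoy
#' ions in the AIF channel, and optional in-source oxidation artifacts
#' (+O / +2O ions co-eluting in MS1).
#'
#' @param formula precursor ion formula: a `chemformula` (charge -1) or a
#'   formula string.
#' @param rt_apex apex retention time, minutes.
#' @param peak_sigma Gaussian peak width (sigma), minutes.
#' @param ms1_height precursor apex intensity in the MS1 channel, counts.
#' @param fragments named numeric vector: fragment ion formula strings ->
#'   relative AIF yield (fraction of the precursor MS1 height); every
#'   fragment must be a subformula of the precursor.
#' @param residual_precursor surviving precursor fraction in the AIF
#'   channel.
#' @param decoys data.frame with columns `mz`, `rt_offset` (minutes
#'   relative to `rt_apex`) and `height`: unrelated ions planted in the AIF
#'   channel.
#' @param oxidation numeric length-2 `c(O, O2)`: MS1 apex heights of the
#'   +O and +2O in-source oxidation ions (0 = absent).
#' @param label optional compound name.
#' @return an object of class `compound_spec`.
#' @export
compound_spec <- function(formula, rt_apex, peak_sigma = 0.05,
                          ms1_height = 1e6, fragments = NULL,
                          residual_precursor = 0.3, decoys = NULL,
                          oxidation = c(0, 0), label = NULL) {
  if (is.character(formula)) formula <- chem_formula(formula, charge = -1L)
  stopifnot(peak_sigma > 0, ms1_height > 0, residual_precursor >= 0)
  frag_formulas <- list()
  if (!is.null(fragments) && length(fragments)) {
    stopifnot(is.numeric(fragments), !is.null(names(fragments)),
              all(fragments >= 0))
    frag_formulas <- lapply(names(fragments), chem_formula, charge = -1L)
    for (ff in frag_formulas)
      if (!is_subformula(ff, formula))
        stop("fragment ", format(ff), " is not a subformula of ",
             format(formula))
  }
  if (!is.null(decoys))
    stopifnot(all(c("mz", "rt_offset", "height") %in% names(decoys)))
  structure(list(formula = formula, rt_apex = rt_apex,
                 peak_sigma = peak_sigma, ms1_height = ms1_height,
                 fragments = fragments, fragment_formulas = frag_formulas,
                 residual_precursor = residual_precursor,
                 decoys = decoys, oxidation = oxidation, label = label),
            class = "compound_spec")
}

#' Simulate a full MS/AIF acquisition with known ground truth
#'
#' Generates an alternating MS1/AIF scan sequence (one scan per
#' `scan_period`, starting with MS1).  Each compound contributes its
#' Gaussian elution profile; MS1 scans carry the precursor isotopologue
#' envelope (plus any oxidation-artifact ions), AIF scans carry the residual
#' precursor and the fragment envelopes sharing the precursor's profile,
#' and decoys appear in AIF at their shifted retention times.  Centroid m/z
#' values get Gaussian jitter (`mz_jitter_ppm`), intensities a Gaussian
#' noise floor plus a sqrt-scaled shot-noise term, and each scan a sprinkle
#' of random low-intensity noise centroids.  With a fixed `seed` the run is
#' bit-reproducible.
#'
#' @param compounds list of [compound_spec()] objects.
#' @param rt_start,rt_end time span of the run, minutes; must cover all
#'   apexes.
#' @param scan_period time between consecutive scans, minutes (default
#'   1/60 min = 1 s; MS1 scans therefore repeat every 2 s).
#' @param noise_level baseline noise scale, counts.
#' @param mz_jitter_ppm sigma of the centroid mass jitter, ppm.
#' @param n_noise_peaks random noise centroids per scan.
#' @param mz_range m/z span of the simulated instrument.
#' @param n_iso_peaks isotopologue peaks planted per envelope.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return list with elements `run` (an `aif_run`) and `truth` (a
#'   `ground_truth` list: per-compound planted formulas and m/z values,
#'   decoy m/z values, and the scan schedule).
#' @export
simulate_run <- function(compounds, rt_start = 0, rt_end = 4,
                         scan_period = 1 / 60, noise_level = 50,
                         mz_jitter_ppm = 1, n_noise_peaks = 10,
                         mz_range = c(50, 400), n_iso_peaks = 4,
                         seed = NULL) {
  if (inherits(compounds, "compound_spec")) compounds <- list(compounds)
  stopifnot(length(compounds) > 0, rt_end > rt_start)
  for (cs in compounds)
    if (cs$rt_apex < rt_start || cs$rt_apex > rt_end)
      stop("schedule does not cover apex at ", cs$rt_apex, " min")
  if (!is.null(seed)) set.seed(seed)
  times <- seq(rt_start, rt_end, by = scan_period)
  levels <- rep_len(c(1L, 2L), length(times))

  # precompute envelopes: list of (mz, rel) per planted ion
  envelope <- function(f) {
    pat <- isotopologue_pattern(f, n_peaks = n_iso_peaks)
    list(mz = monoisotopic_mz(f) + pat$mz_offset, rel = pat$rel_intensity)
  }
  plan <- lapply(compounds, function(cs) {
    ox <- list()
    if (length(cs$oxidation) && any(cs$oxidation > 0)) {
      for (k in which(cs$oxidation > 0)) {
        oxf <- formula_add(cs$formula,
                           chem_formula(c(O = k), charge = 0L))
        ox[[length(ox) + 1L]] <- list(env = envelope(oxf),
                                      height = cs$oxidation[k])
      }
    }
    list(spec = cs,
         prec_env = envelope(cs$formula),
         frag_env = lapply(cs$fragment_formulas, envelope),
         ox = ox)
  })

  gauss <- function(t, apex, sigma) exp(-(t - apex)^2 / (2 * sigma^2))

  make_scan <- function(t, lvl) {
    mzs <- numeric(0); ints <- numeric(0)
    add <- function(env, height) {
      if (height <= 0) return()
      mzs <<- c(mzs, env$mz)
      ints <<- c(ints, height * env$rel)
    }
    for (pl in plan) {
      cs <- pl$spec
      g <- gauss(t, cs$rt_apex, cs$peak_sigma)
      if (lvl == 1L) {
        add(pl$prec_env, cs$ms1_height * g)
        for (ox in pl$ox) add(ox$env, ox$height * g)
      } else {
        add(pl$prec_env, cs$ms1_height * cs$residual_precursor * g)
        if (length(pl$frag_env))
          for (k in seq_along(pl$frag_env))
            add(pl$frag_env[[k]], cs$ms1_height * cs$fragments[k] * g)
        if (!is.null(cs$decoys)) {
          gd <- gauss(t, cs$rt_apex + cs$decoys$rt_offset, cs$peak_sigma)
          mzs <- c(mzs, cs$decoys$mz)
          ints <- c(ints, cs$decoys$height * gd)
        }
      }
    }
    # noise centroids + measurement noise
    nm <- stats::runif(n_noise_peaks, mz_range[1], mz_range[2])
    ni <- stats::rexp(n_noise_peaks, rate = 1 / noise_level)
    mzs <- c(mzs, nm); ints <- c(ints, ni)
    mzs <- mzs * (1 + stats::rnorm(length(mzs), 0, mz_jitter_ppm * 1e-6))
    ints <- ints + stats::rnorm(length(ints),
                                0, noise_level / 10 + 0.01 * sqrt(ints))
    keep <- ints > 0 & mzs >= mz_range[1] & mzs <= mz_range[2]
    mzs <- mzs[keep]; ints <- ints[keep]
    o <- order(mzs); mzs <- mzs[o]; ints <- ints[o]
    # collapse pathological coincidences so mz stays strictly increasing
    if (length(mzs) > 1) {
      grp <- cumsum(c(TRUE, diff(mzs) > 1e-7))
      ints <- as.numeric(tapply(ints, grp, sum))
      mzs <- as.numeric(tapply(mzs, grp, max))
    }
    new_spectrum(lvl, t, mzs, ints)
  }

  specs <- mapply(make_scan, times, levels, SIMPLIFY = FALSE)
  run <- acquisition_run(specs[levels == 1L], specs[levels == 2L],
                         metadata = list(source_file = "simulated",
                                         polarity = "negative"))
  truth <- structure(list(
    compounds = lapply(plan, function(pl) {
      cs <- pl$spec
      list(label = cs$label,
           formula = format(cs$formula),
           mz = monoisotopic_mz(cs$formula),
           rt_apex = cs$rt_apex,
           fragment_formulas = vapply(cs$fragment_formulas, format,
                                      character(1)),
           fragment_mzs = vapply(cs$fragment_formulas, monoisotopic_mz,
                                 numeric(1)),
           decoy_mzs = if (is.null(cs$decoys)) numeric(0) else cs$decoys$mz)
    }),
    schedule = list(rt_start = rt_start, rt_end = rt_end,
                    scan_period = scan_period)),
    class = "ground_truth")
  list(run = run, truth = truth)
}

#' Write simulator ground truth as a delimited sidecar file
#'
#' One row per planted ion (precursor, fragment or decoy) so that recall
#' and false-positive counts can be scored without re-reading the simulator
#' parameters.
#'
#' @param truth a `ground_truth` object from [simulate_run()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  rows <- list()
  for (i in seq_along(truth$compounds)) {
    cp <- truth$compounds[[i]]
    lab <- if (is.null(cp$label)) sprintf("compound_%d", i) else cp$label
    rows[[length(rows) + 1L]] <- data.frame(
      compound = lab, role = "precursor", formula = cp$formula,
      mz = cp$mz, rt = cp$rt_apex, stringsAsFactors = FALSE)
    if (length(cp$fragment_formulas))
      rows[[length(rows) + 1L]] <- data.frame(
        compound = lab, role = "fragment", formula = cp$fragment_formulas,
        mz = cp$fragment_mzs, rt = cp$rt_apex, stringsAsFactors = FALSE)
    if (length(cp$decoy_mzs))
      rows[[length(rows) + 1L]] <- data.frame(
        compound = lab, role = "decoy", formula = NA_character_,
        mz = cp$decoy_mzs, rt = cp$rt_apex, stringsAsFactors = FALSE)
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
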