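# memoised isotopologue patterns -- the simulator and the predictor hit the
# same few formulas thousands of times
.pattern_cache <- new.env(parent = emptyenv())

cached_second_isotopologue <- function(formula) {
  key <- paste0(format(formula), "/", formula_charge(formula))
  if (!is.null(.pattern_cache[[key]])) return(.pattern_cache[[key]]$si)
  val <- list(si = second_isotopologue(formula))
  assign(key, val, envir = .pattern_cache)
  val$si
}

#' Evidence score for a candidate formula
#'
#' Linear clamped combination of the three evidence terms: each term
#' contributes its weight scaled by `max(0, 1 - error/clamp)`, and the
#' optional composition penalty is subtracted.  Perfect evidence with the
#' default unit weights scores 3.  The score is strictly decreasing in every
#' error term inside its clamp and decreases one-for-one with the penalty.
#'
#' @param ppm_error absolute mass error in ppm.
#' @param iso_ratio_error relative deviation of the measured vs theoretical
#'   second-isotopologue intensity ratio.
#' @param iso_shape_area area between the second-isotopologue XIC and the
#'   reference trace.
#' @param penalty composition plausibility penalty (>= 0).
#' @param weights named numeric with elements `mass`, `iso`, `shape`.
#' @param ppm_tol clamp for the mass term (ppm).
#' @param iso_ratio_max clamp for the isotope-ratio term.
#' @param iso_shape_max clamp for the shape term.
#' @return numeric score.
#' @export
score_candidate <- function(ppm_error, iso_ratio_error, iso_shape_area,
                            penalty = 0,
                            weights = c(mass = 1, iso = 1, shape = 1),
                            ppm_tol = 15, iso_ratio_max = 1,
                            iso_shape_max = 0.3) {
  stopifnot(ppm_error >= 0, iso_ratio_error >= 0, iso_shape_area >= 0)
  unname(weights["mass"] * max(0, 1 - ppm_error / ppm_tol) +
         weights["iso"] * max(0, 1 - iso_ratio_error / iso_ratio_max) +
         weights["shape"] * max(0, 1 - iso_shape_area / iso_shape_max) -
         penalty)
}

new_formula_candidate <- function(formula, ppm_error, iso_ratio_error,
                                  iso_shape_area, penalty, score) {
  structure(list(formula = formula, ppm_error = ppm_error,
                 iso_ratio_error = iso_ratio_error,
                 iso_shape_area = iso_shape_area,
                 penalty = penalty, score = score),
            class = "formula_candidate")
}

#' @export
print.formula_candidate <- function(x, ...) {
  cat(sprintf("<formula_candidate> %s  score %.3f (ppm %.2f, iso %.3f, shape %.3f, penalty %.2f)\n",
              format(x$formula), x$score, x$ppm_error, x$iso_ratio_error,
              x$iso_shape_area, x$penalty))
  invisible(x)
}

#' Predict the molecular formula of an ion from a full MS/AIF run
#'
#' Enumerates all formulas within `formula_tol_ppm` of the measured m/z,
#' then weighs each candidate by three pieces of evidence: mass error,
#' agreement of the measured second-isotopologue intensity ratio with
#' theory, and the similarity of the second-isotopologue XIC to the
#' reference trace.  A candidate is rejected outright when its theoretical
#' second isotopologue cannot be *found* in the data: apex below
#' `iso_detection_k` times the MAD of its trace, measured intensity ratio
#' off theory by more than `iso_ratio_max`, or a trace that does not
#' co-elute (shape area above `iso_shape_max`).  Exact mass alone is never
#' trusted, so when no candidate survives the result is `NULL`, not a
#' guess.  Candidates made only of monoisotopic elements (e.g. iodide)
#' have no second isotopologue to verify and are scored on mass error
#' alone.
#'
#' @param mz measured m/z in Th.
#' @param run an `aif_run`.
#' @param channel `"ms1"` (precursor ions) or `"aif"` (fragment ions).
#' @param rt retention time of the ion, minutes.
#' @param reference_xic the trace to compare isotopologue peak shapes
#'   against (normally the precursor's MS1 XIC); `NULL` uses the ion's own
#'   monoisotopic trace.
#' @param config a [run_config()].
#' @return a `formula_candidate`, or `NULL` when no formula survives.
#' @export
predict_formula <- function(mz, run, channel = c("ms1", "aif"), rt,
                            reference_xic = NULL, config = run_config()) {
  channel <- match.arg(channel)
  spectra <- run[[channel]]
  win <- rt + c(-1, 1) * config$rt_window
  cands <- enumerate_formulas(mz, config$formula_tol_ppm,
                              config$element_ranges, config$charge)
  if (!length(cands)) return(NULL)
  mono_xic <- tryCatch(
    extract_xic(spectra, mz, config$xic_tol_ppm, win, channel),
    error = function(e) NULL)
  if (is.null(mono_xic)) return(NULL)
  mono_apex <- max(mono_xic$intensities)
  if (mono_apex <= 0) return(NULL)
  if (is.null(reference_xic)) reference_xic <- mono_xic
  best <- NULL
  best_key <- c(-Inf, Inf, Inf)   # score (max), |ppm| (min), heteroatoms (min)
  for (f in cands) {
    ppm_err <- abs(monoisotopic_mz(f) - mz) / mz * 1e6
    si <- cached_second_isotopologue(f)
    if (is.null(si)) {
      # monoisotopic-element formula: nothing to verify
      iso_ratio_error <- 0
      iso_shape_area <- 0
    } else {
      iso_xic <- extract_xic(spectra, mz + si$mz_offset, config$xic_tol_ppm,
                             win, channel)
      iso_apex <- max(iso_xic$intensities)
      detect <- config$iso_detection_k *
        stats::mad(iso_xic$intensities, constant = 1.4826)
      if (iso_apex <= 0 || iso_apex < detect) next  # rejection rule
      measured_ratio <- iso_apex / mono_apex
      iso_ratio_error <- abs(measured_ratio - si$rel_intensity) /
        si$rel_intensity
      # "found" means quantitatively consistent: a signal far off the
      # expected intensity (e.g. a lone noise centroid standing in for a
      # missing isotopologue) is no detection at all
      if (iso_ratio_error > config$iso_ratio_max) next
      cmp <- tryCatch(
        area_between(iso_xic, reference_xic, win,
                     threshold = config$shape_threshold,
                     grid_points = config$grid_points),
        error = function(e) NULL)
      if (is.null(cmp)) next
      iso_shape_area <- cmp$area
      if (iso_shape_area > config$iso_shape_max) next  # not co-eluting
    }
    penalty <- if (isTRUE(config$use_heuristics))
      plausibility_penalty(f, config$heuristics) else 0
    sc <- score_candidate(ppm_err, iso_ratio_error, iso_shape_area, penalty,
                          weights = config$weights,
                          ppm_tol = config$formula_tol_ppm,
                          iso_ratio_max = config$iso_ratio_max,
                          iso_shape_max = config$iso_shape_max)
    cnt <- formula_counts(f)
    hetero <- sum(cnt[setdiff(names(cnt), c("C", "H"))])
    key <- c(sc, ppm_err, hetero)
    better <- key[1] > best_key[1] ||
      (key[1] == best_key[1] && key[2] < best_key[2]) ||
      (key[1] == best_key[1] && key[2] == best_key[2] && key[3] < best_key[3])
    if (better) {
      best_key <- key
      best <- new_formula_candidate(f, ppm_err, iso_ratio_error,
                                    iso_shape_area, penalty, sc)
    }
  }
  best
}
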