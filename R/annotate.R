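#' One precursor peak-list entry
#'
#' @param mz precursor m/z in Th (> 0).
#' @param rt retention time in minutes.
#' @param label optional compound label.
#' @return an object of class `peak_entry`.
#' @export
peak_entry <- function(mz, rt, label = NA_character_) {
  stopifnot(mz > 0)
  structure(list(mz = as.numeric(mz), rt = as.numeric(rt),
                 label = as.character(label)), class = "peak_entry")
}

empty_fragment_table <- function() {
  data.frame(mz = numeric(0), formula = character(0),
             neutral_loss = character(0), shape_area = numeric(0),
             ppm_error = numeric(0), score = numeric(0),
             ambiguous = logical(0), stringsAsFactors = FALSE)
}

#' Annotate the CID fragments of one precursor ion
#'
#' The two-step annotation process on a full MS/AIF run: (1) the precursor's
#' XIC is taken from the MS1 channel and its formula predicted by
#' isotopologue-pattern scoring; (2) candidate fragment masses from the AIF
#' scans around the precursor apex are first screened by peak-shape
#' similarity — the area between their normalized AIF-XIC and the precursor
#' MS1-XIC must not exceed the shape threshold (screening before any formula
#' work saves most of the computation); (3) surviving masses get a formula
#' prediction against the precursor's peak shape; (4) predicted fragment
#' formulas must be subformulas of the precursor formula; (5) neutral losses
#' are attached and a quasi-isolated MS2 spectrum is built.  Shape-passing
#' masses without a confident formula are retained unannotated.  When the
#' precursor formula itself cannot be predicted the result carries the
#' `"no-formula"` flag and only the shape-passing masses are listed.
#'
#' @param run an `aif_run`.
#' @param entry a [peak_entry()] (or a list with `mz`, `rt`).
#' @param config a [run_config()].
#' @return an object of class `annotation_result`: list with `entry`,
#'   `precursor_candidate` (a `formula_candidate` or `NULL`),
#'   `precursor_formula` (`chemformula` or `NULL`), `fragments` (data.frame
#'   with columns mz, formula, neutral_loss, shape_area, ppm_error, score,
#'   ambiguous; sorted by m/z), `quasi_ms2`, `flags`, `precursor_xic`.
#' @export
annotate_precursor <- function(run, entry, config = run_config()) {
  if (!inherits(entry, "peak_entry"))
    entry <- peak_entry(entry$mz, entry$rt, entry$label %||% NA_character_)
  rng <- run_rt_range(run)
  if (entry$rt < rng[1] || entry$rt > rng[2])
    stop("entry retention time ", entry$rt, " min outside run (",
         sprintf("%.2f-%.2f", rng[1], rng[2]), " min)")
  win <- entry$rt + c(-1, 1) * config$rt_window
  flags <- character(0)
  fragments <- empty_fragment_table()

  prec_xic <- tryCatch(
    extract_xic(run$ms1, entry$mz, config$xic_tol_ppm, win, "ms1"),
    error = function(e) NULL)
  if (is.null(prec_xic) || max(prec_xic$intensities) <= 0) {
    flags <- c(flags, "precursor-not-found")
    res <- structure(list(entry = entry, precursor_candidate = NULL,
                          precursor_formula = NULL, fragments = fragments,
                          quasi_ms2 = NULL, flags = flags,
                          precursor_xic = prec_xic),
                     class = "annotation_result")
    return(res)
  }

  prec_cand <- predict_formula(entry$mz, run, "ms1", entry$rt,
                               reference_xic = prec_xic, config = config)
  prec_formula <- if (is.null(prec_cand)) NULL else prec_cand$formula
  if (is.null(prec_formula)) flags <- c(flags, "no-formula")

  cand_mzs <- tryCatch(
    candidate_fragment_mzs(run, entry$mz, entry$rt, config),
    error = function(e) NULL)
  if (is.null(cand_mzs)) {
    flags <- c(flags, "no-aif-scans")
    cand_mzs <- numeric(0)
  }

  # step 1: shape filter, before any formula work
  passing <- list()
  for (mz in cand_mzs) {
    fx <- extract_xic(run$aif, mz, config$xic_tol_ppm, win, "aif")
    if (max(fx$intensities) <= 0) next
    cmp <- area_between(fx, prec_xic, win,
                        threshold = config$shape_threshold,
                        grid_points = config$grid_points)
    if (cmp$passed)
      passing[[length(passing) + 1L]] <- list(mz = mz, area = cmp$area)
  }

  # step 2: formula prediction + subformula constraint
  for (p in passing) {
    row <- data.frame(mz = p$mz, formula = NA_character_,
                      neutral_loss = NA_character_, shape_area = p$area,
                      ppm_error = NA_real_, score = NA_real_,
                      ambiguous = FALSE, stringsAsFactors = FALSE)
    if (!is.null(prec_formula)) {
      fc <- predict_formula(p$mz, run, "aif", entry$rt,
                            reference_xic = prec_xic, config = config)
      if (!is.null(fc)) {
        if (!is_subformula(fc$formula, prec_formula)) next  # cannot be a true fragment
        row$formula <- format(fc$formula)
        row$neutral_loss <- format(neutral_loss(prec_formula, fc$formula))
        row$ppm_error <- fc$ppm_error
        row$score <- fc$score
      }
    }
    fragments <- rbind(fragments, row)
  }
  if (nrow(fragments)) {
    fragments <- fragments[order(fragments$mz), , drop = FALSE]
    rownames(fragments) <- NULL
  }

  res <- structure(list(entry = entry, precursor_candidate = prec_cand,
                        precursor_formula = prec_formula,
                        fragments = fragments, quasi_ms2 = NULL,
                        flags = flags, precursor_xic = prec_xic),
                   class = "annotation_result")
  res$quasi_ms2 <- tryCatch(build_quasi_ms2(run, res, config),
                            error = function(e) NULL)
  if (is.null(res$quasi_ms2) && !"no-aif-scans" %in% res$flags)
    res$flags <- c(res$flags, "no-aif-scans")
  if (!is.null(prec_formula))
    res$flags <- c(res$flags,
                   flag_oxidation_artifacts(run, entry, prec_formula,
                                            prec_xic, config))
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.annotation_result <- function(x, ...) {
  f <- if (is.null(x$precursor_formula)) "none"
       else format(x$precursor_formula)
  cat(sprintf("<annotation_result> m/z %.4f @ %.2f min -> %s, %d fragment(s)%s\n",
              x$entry$mz, x$entry$rt, f, nrow(x$fragments),
              if (length(x$flags))
                paste0(" [", paste(x$flags, collapse = ", "), "]") else ""))
  invisible(x)
}

#' Build the quasi-isolated MS2 spectrum for an annotation result
#'
#' Takes the AIF scan nearest the precursor's chromatographic apex and
#' assigns each of its peaks a role: `precursor` (the residual precursor
#' ion), `annotated_fragment` (a shape- and formula-verified fragment, with
#' its neutral-loss label), or `unannotated`.  Intensities are exactly those
#' of the source scan — the spectrum reads like an isolated MS2 spectrum of
#' that one compound.
#'
#' @param run an `aif_run`.
#' @param result an in-progress `annotation_result`.
#' @param config a [run_config()].
#' @return an object of class `quasi_ms2`: list with `scan_rt`,
#'   `scan_index` (index into `run$aif`) and `peaks` (data.frame mz,
#'   intensity, role, label).
#' @export
build_quasi_ms2 <- function(run, result, config = run_config()) {
  entry <- result$entry
  win <- entry$rt + c(-1, 1) * config$rt_window
  rts <- vapply(run$aif, function(s) s$rt, numeric(1))
  sel <- which(rts >= win[1] & rts <= win[2])
  if (!length(sel)) stop("no AIF scan in precursor window")
  apex_rt <- entry$rt
  if (!is.null(result$precursor_xic) &&
      max(result$precursor_xic$intensities) > 0)
    apex_rt <- xic_apex(result$precursor_xic)$rt
  idx <- sel[which.min(abs(rts[sel] - apex_rt))]
  s <- run$aif[[idx]]
  tol <- config$xic_tol_ppm * 1e-6
  role <- rep("unannotated", length(s$mz))
  label <- rep(NA_character_, length(s$mz))
  ann <- result$fragments[!is.na(result$fragments$formula), , drop = FALSE]
  if (nrow(ann))
    for (k in seq_len(nrow(ann))) {
      j <- which(abs(s$mz - ann$mz[k]) <= s$mz * tol)
      if (length(j)) {
        j <- j[which.max(s$intensity[j])]
        role[j] <- "annotated_fragment"
        label[j] <- sprintf("%s (-%s)", ann$formula[k], ann$neutral_loss[k])
      }
    }
  jp <- which(abs(s$mz - entry$mz) <= s$mz * tol)
  if (length(jp)) {
    jp <- jp[which.max(s$intensity[jp])]
    role[jp] <- "precursor"
    label[jp] <- if (is.null(result$precursor_formula)) "precursor"
                 else format(result$precursor_formula)
  }
  structure(list(scan_rt = s$rt, scan_index = idx,
                 peaks = data.frame(mz = s$mz, intensity = s$intensity,
                                    role = role, label = label,
                                    stringsAsFactors = FALSE)),
            class = "quasi_ms2")
}

#' @export
print.quasi_ms2 <- function(x, ...) {
  cat(sprintf("<quasi_ms2> scan @ %.3f min, %d peaks (%d annotated, %s precursor)\n",
              x$scan_rt, nrow(x$peaks),
              sum(x$peaks$role == "annotated_fragment"),
              if (any(x$peaks$role == "precursor")) "with" else "no"))
  invisible(x)
}

#' Flag possible in-source oxidation artifacts
#'
#' Reactive oxygen species in the ESI source can oxygenate analyte
#' molecules, producing +O and +2O ions that co-elute exactly with the
#' precursor.  This searches the MS1 channel at the +O and +2O m/z of the
#' predicted precursor formula; a co-eluting trace passing the shape filter
#' yields an informational flag.  Annotations are never altered — oxygenated
#' species fail the subformula test anyway.
#'
#' @param run an `aif_run`.
#' @param entry a [peak_entry()].
#' @param precursor_formula the predicted precursor `chemformula`.
#' @param precursor_xic the precursor's MS1 XIC.
#' @param config a [run_config()].
#' @return character vector of flags (possibly empty).
#' @export
flag_oxidation_artifacts <- function(run, entry, precursor_formula,
                                     precursor_xic, config = run_config()) {
  win <- entry$rt + c(-1, 1) * config$rt_window
  flags <- character(0)
  for (k in 1:2) {
    oxf <- formula_add(precursor_formula, chem_formula(c(O = k)))
    mz <- monoisotopic_mz(oxf)
    ox_xic <- tryCatch(
      extract_xic(run$ms1, mz, config$xic_tol_ppm, win, "ms1"),
      error = function(e) NULL)
    if (is.null(ox_xic)) next
    apex <- max(ox_xic$intensities)
    detect <- config$iso_detection_k *
      stats::mad(ox_xic$intensities, constant = 1.4826)
    if (apex <= 0 || apex < detect) next
    cmp <- tryCatch(
      area_between(ox_xic, precursor_xic, win,
                   threshold = config$shape_threshold,
                   grid_points = config$grid_points),
      error = function(e) NULL)
    if (!is.null(cmp) && cmp$passed)
      flags <- c(flags, sprintf(
        "possible in-source oxidation product at %.4f (+%dO)", mz, k))
  }
  flags
}

#' Annotate every entry of a peak list and mark coelution ambiguity
#'
#' Runs [annotate_precursor()] for each entry, then compares all pairs of
#' results: when two precursors elute with indistinguishable peak shapes
#' (area between their MS1 XICs within the shape threshold) the workflow
#' cannot attribute a shared fragment mass to either one, so such fragments
#' are annotated to both results with `ambiguous = TRUE` and both results
#' get a `"coelution-ambiguity"` flag.
#'
#' @param run an `aif_run`.
#' @param entries list of [peak_entry()]s (or a data.frame with columns
#'   `mz`, `rt` and optionally `label`).
#' @param config a [run_config()].
#' @return list of `annotation_result`s.
#' @export
annotate_run <- function(run, entries, config = run_config()) {
  if (is.data.frame(entries))
    entries <- lapply(seq_len(nrow(entries)), function(i)
      peak_entry(entries$mz[i], entries$rt[i],
                 if ("label" %in% names(entries)) entries$label[i]
                 else NA_character_))
  results <- lapply(entries, function(e)
    annotate_precursor(run, e, config))
  tol <- config$xic_tol_ppm * 1e-6
  n <- length(results)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      ri <- results[[i]]; rj <- results[[j]]
      if (is.null(ri$precursor_xic) || is.null(rj$precursor_xic)) next
      if (max(ri$precursor_xic$intensities) <= 0 ||
          max(rj$precursor_xic$intensities) <= 0) next
      if (abs(ri$entry$rt - rj$entry$rt) > 2 * config$rt_window) next
      # same window length as the fragment shape filter, centered between
      # the two precursors, so the threshold keeps its meaning
      win <- mean(c(ri$entry$rt, rj$entry$rt)) + c(-1, 1) * config$rt_window
      cmp <- tryCatch(
        area_between(ri$precursor_xic, rj$precursor_xic, win,
                     threshold = config$shape_threshold,
                     grid_points = config$grid_points),
        error = function(e) NULL)
      if (is.null(cmp) || !cmp$passed) next
      shared_i <- shared_j <- FALSE
      if (nrow(ri$fragments) && nrow(rj$fragments)) {
        for (a in seq_len(nrow(ri$fragments))) {
          hit <- abs(rj$fragments$mz - ri$fragments$mz[a]) <=
            ri$fragments$mz[a] * tol
          if (any(hit)) {
            results[[i]]$fragments$ambiguous[a] <- TRUE
            results[[j]]$fragments$ambiguous[hit] <- TRUE
            shared_i <- TRUE; shared_j <- TRUE
          }
        }
      }
      if (shared_i && !"coelution-ambiguity" %in% results[[i]]$flags)
        results[[i]]$flags <- c(results[[i]]$flags, "coelution-ambiguity")
      if (shared_j && !"coelution-ambiguity" %in% results[[j]]$flags)
        results[[j]]$flags <- c(results[[j]]$flags, "coelution-ambiguity")
    }
  }
  results
}
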