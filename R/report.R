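#' Read a precursor peak list
#'
#' Comma- or tab-delimited text with a header row naming at least `mz` and
#' `rt` (retention time in minutes); an optional `label` column is carried
#' through.  Malformed numeric fields are reported with their line number.
#'
#' @param path peak-list file path.
#' @return data.frame with columns `mz`, `rt`, `label`.
#' @export
read_peaklist <- function(path) {
  if (!file.exists(path)) stop("peak list not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("peak list is empty (no header)")
  sep <- if (grepl("\t", lines[1])) "\t" else ","
  hdr <- tolower(trimws(strsplit(lines[1], sep, fixed = TRUE)[[1]]))
  if (!all(c("mz", "rt") %in% hdr))
    stop("peak list header must contain 'mz' and 'rt'")
  icol <- match(c("mz", "rt", "label"), hdr)
  out <- data.frame(mz = numeric(0), rt = numeric(0),
                    label = character(0), stringsAsFactors = FALSE)
  for (i in seq_along(lines)[-1]) {
    f <- trimws(strsplit(lines[i], sep, fixed = TRUE)[[1]])
    mz <- suppressWarnings(as.numeric(f[icol[1]]))
    rt <- suppressWarnings(as.numeric(f[icol[2]]))
    if (is.na(mz) || is.na(rt))
      stop("peak list line ", i, ": non-numeric mz or rt ('",
           lines[i], "')")
    lab <- if (!is.na(icol[3]) && length(f) >= icol[3]) f[icol[3]]
           else NA_character_
    out[nrow(out) + 1L, ] <- list(mz, rt, lab)
  }
  out
}

result_summary_row <- function(res) {
  frag <- res$fragments
  ann <- frag[!is.na(frag$formula), , drop = FALSE]
  una <- frag[is.na(frag$formula), , drop = FALSE]
  data.frame(
    label = res$entry$label,
    mz = res$entry$mz,
    rt = res$entry$rt,
    precursor_formula = if (is.null(res$precursor_formula)) "NO FORMULA"
                        else format(res$precursor_formula),
    precursor_ppm = if (is.null(res$precursor_candidate)) NA_real_
                    else res$precursor_candidate$ppm_error,
    precursor_score = if (is.null(res$precursor_candidate)) NA_real_
                      else res$precursor_candidate$score,
    n_fragments = nrow(ann),
    fragments = paste(ann$formula, collapse = ";"),
    neutral_losses = paste(ann$neutral_loss, collapse = ";"),
    fragment_mzs = paste(sprintf("%.4f", ann$mz), collapse = ";"),
    ambiguous = paste(ann$formula[ann$ambiguous], collapse = ";"),
    unannotated_mzs = paste(sprintf("%.4f", una$mz), collapse = ";"),
    flags = paste(res$flags, collapse = ";"),
    stringsAsFactors = FALSE)
}

#' Summarize annotation results as one table
#'
#' @param results list of `annotation_result`s.
#' @return data.frame, one row per peak-list entry.
#' @export
summarize_results <- function(results) {
  do.call(rbind, lapply(results, result_summary_row))
}

#' Run the full annotation workflow on files
#'
#' Reads the mzML run and the peak list, annotates every entry, and writes
#' a results bundle into `out_dir`: `summary.tsv` (one row per entry),
#' one `quasi_ms2_<i>.tsv` peak table per entry, and `config.yaml` echoing
#' the configuration for provenance.  Given the same inputs and
#' configuration the bundle is byte-identical — the pipeline has no hidden
#' randomness.
#'
#' @param mzml_path centroided mzML file.
#' @param peaklist_path delimited peak list, see [read_peaklist()].
#' @param config a [run_config()] or a path to a YAML config file.
#' @param out_dir output directory (created if missing).
#' @param zip logical; additionally bundle the directory into
#'   `<out_dir>.zip`.
#' @return the list of `annotation_result`s, invisibly.
#' @export
run_annotation <- function(mzml_path, peaklist_path,
                           config = run_config(), out_dir, zip = FALSE) {
  if (is.character(config)) config <- read_config(config)
  run <- read_run(mzml_path, config)
  peaks <- read_peaklist(peaklist_path)
  if (!nrow(peaks)) warning("peak list has no entries; writing empty summary")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- if (nrow(peaks)) annotate_run(run, peaks, config) else list()
  summ <- if (length(results)) summarize_results(results) else
    result_summary_row(structure(list(
      entry = peak_entry(1, 0), precursor_candidate = NULL,
      precursor_formula = NULL, fragments = empty_fragment_table(),
      quasi_ms2 = NULL, flags = character(0)),
      class = "annotation_result"))[0, ]
  utils::write.table(summ, file.path(out_dir, "summary.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  for (i in seq_along(results)) {
    q <- results[[i]]$quasi_ms2
    if (is.null(q)) next
    utils::write.table(q$peaks,
                       file.path(out_dir, sprintf("quasi_ms2_%03d.tsv", i)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  write_config(config, file.path(out_dir, "config.yaml"))
  if (zip) {
    owd <- setwd(dirname(normalizePath(out_dir)))
    on.exit(setwd(owd), add = TRUE)
    utils::zip(paste0(basename(out_dir), ".zip"), basename(out_dir))
  }
  invisible(results)
}

#' Van Krevelen coordinates and carbon oxidation state
#'
#' For every result with a carbon-containing precursor formula, computes
#' O/C, H/C and the carbon oxidation state OSc = 2 O/C - H/C on the
#' neutral molecule (one H is added to \eqn{[M-H]^-} ion formulas when
#' `neutralize` is on, the default).  Carbon-free or formula-less results
#' are excluded with a warning.  These are the standard aerosol-chemistry
#' summaries of how oxidized an annotated compound set is.
#'
#' @param results list of `annotation_result`s.
#' @param neutralize logical; add one H to anion formulas first.
#' @return data.frame with columns `label`, `formula` (neutral), `OC`,
#'   `HC`, `OSc`.
#' @export
van_krevelen_table <- function(results, neutralize = TRUE) {
  rows <- list(); skipped <- 0L
  for (res in results) {
    f <- res$precursor_formula
    if (is.null(f)) { skipped <- skipped + 1L; next }
    if (neutralize && formula_charge(f) == -1L) {
      cnt <- formula_counts(f)
      cnt["H"] <- cnt["H"] + 1L
      f <- chem_formula(cnt, charge = 0L)
    }
    cnt <- formula_counts(f)
    if (cnt["C"] == 0) { skipped <- skipped + 1L; next }
    oc <- unname(cnt["O"] / cnt["C"]); hc <- unname(cnt["H"] / cnt["C"])
    rows[[length(rows) + 1L]] <- data.frame(
      label = res$entry$label, formula = format(f),
      OC = oc, HC = hc, OSc = 2 * oc - hc, stringsAsFactors = FALSE)
  }
  if (skipped)
    warning(skipped, " result(s) without a carbon-containing formula excluded")
  if (!length(rows)) return(data.frame(label = character(0),
                                       formula = character(0), OC = numeric(0),
                                       HC = numeric(0), OSc = numeric(0)))
  do.call(rbind, rows)
}
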