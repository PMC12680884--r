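#' Pipeline configuration
#'
#' All tolerances and thresholds of the annotation workflow in one place.
#' These settings depend on the instrument, not the sample, and typically
#' need to be configured only once per instrument/method combination.
#'
#' @param xic_tol_ppm XIC extraction tolerance in ppm (default 5; tighter
#'   than the formula window because extraction works on measured masses).
#' @param formula_tol_ppm candidate-formula mass window in ppm (default 15).
#' @param rt_window half-width of the retention-time window around a
#'   precursor, minutes (default 0.5).
#' @param shape_threshold maximum allowed area between normalized XICs for
#'   a fragment to count as co-eluting (default 0.15; raise it for noisier
#'   chromatography).
#' @param grid_points interpolation grid size for the area metric.
#' @param element_ranges per-element count ranges for formula enumeration,
#'   see [default_element_ranges()].
#' @param charge ion charge assumed for all species (-1: ESI negative mode,
#'   formulas are \eqn{[M-H]^-} ion formulas).
#' @param weights named numeric, scoring weights `mass`, `iso`, `shape`.
#' @param iso_ratio_max maximum relative deviation of the measured vs
#'   theoretical second-isotopologue intensity ratio (default 0.5, i.e. the
#'   measured ratio must lie within 50 percent of theory).  Beyond it the
#'   isotopologue does not count as found and the candidate is rejected;
#'   within it the deviation is the clamp scale of the score's isotope term.
#' @param iso_shape_max maximum area between the second-isotopologue XIC
#'   and the reference trace for the isotopologue to count as co-eluting;
#'   doubles as the clamp scale of the score's shape term.
#' @param use_heuristics logical; apply the composition plausibility
#'   penalty (off by default).
#' @param heuristics rule set from [heuristic_rules()].
#' @param min_fragment_intensity minimum centroid intensity for fragment
#'   candidates (counts).
#' @param iso_detection_k the second isotopologue counts as detected when
#'   its XIC apex is at least `k` times the median absolute deviation of
#'   that trace (default 3).
#' @param polarity_default polarity assumed when the mzML carries none.
#' @param neutralize_vk logical; add one H to \eqn{[M-H]^-} formulas before
#'   computing Van Krevelen ratios.
#' @return an object of class `run_config` (a list).
#' @export
run_config <- function(xic_tol_ppm = 5,
                       formula_tol_ppm = 15,
                       rt_window = 0.5,
                       shape_threshold = 0.15,
                       grid_points = 200L,
                       element_ranges = default_element_ranges(),
                       charge = -1L,
                       weights = c(mass = 1, iso = 1, shape = 1),
                       iso_ratio_max = 0.5,
                       iso_shape_max = 0.3,
                       use_heuristics = FALSE,
                       heuristics = heuristic_rules(),
                       min_fragment_intensity = 1000,
                       iso_detection_k = 3,
                       polarity_default = "negative",
                       neutralize_vk = TRUE) {
  stopifnot(xic_tol_ppm > 0, formula_tol_ppm > 0, rt_window > 0,
            shape_threshold > 0, grid_points >= 10)
  weights <- stats::setNames(as.numeric(weights), names(weights))
  element_ranges <- lapply(element_ranges, as.integer)
  structure(list(xic_tol_ppm = as.numeric(xic_tol_ppm),
                 formula_tol_ppm = as.numeric(formula_tol_ppm),
                 rt_window = as.numeric(rt_window),
                 shape_threshold = shape_threshold,
                 grid_points = as.integer(grid_points),
                 element_ranges = element_ranges,
                 charge = as.integer(charge),
                 weights = weights,
                 iso_ratio_max = as.numeric(iso_ratio_max),
                 iso_shape_max = as.numeric(iso_shape_max),
                 use_heuristics = use_heuristics,
                 heuristics = heuristics,
                 min_fragment_intensity = as.numeric(min_fragment_intensity),
                 iso_detection_k = as.numeric(iso_detection_k),
                 polarity_default = polarity_default,
                 neutralize_vk = neutralize_vk),
            class = "run_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' The configuration written into every results bundle parses back to an
#' equal `run_config`, giving full provenance for a run.
#'
#' @param path a YAML file path.
#' @return `read_config()`: a `run_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$weights <- unlist(raw$weights)
  raw$element_ranges <- lapply(raw$element_ranges, as.integer)
  raw$heuristics <- do.call(heuristic_rules, lapply(raw$heuristics, unlist))
  do.call(run_config, raw)
}

#' @param config a `run_config` to serialize.
#' @rdname read_config
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$weights <- as.list(x$weights)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}
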