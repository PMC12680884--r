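#' Reference set of ESI(-)-ionizable standards
#'
#' Ion formulas ([M-H]- unless noted), measured m/z values and observed AIF
#' fragment ions for a 28-compound standard mixture typical of organic
#' aerosol constituents (nitroaromatics, aromatic and aliphatic acids,
#' methoxyphenols, an organosulfate-like sulfonic acid, an iodinated acid).
#' `standard_ions()` returns the table; `standard_mix_compounds()` converts
#' it into simulator [compound_spec()]s, spacing the apexes evenly so that
#' a desk-scale re-enactment of the mixture measurement can be generated
#' with [simulate_run()].
#'
#' @return `standard_ions()`: data.frame with columns `compound`,
#'   `measured_mz` (Th, as printed by the instrument), `ion_formula`
#'   (`NA` where no formula was assignable), and `fragments`
#'   (semicolon-separated fragment ion formulas, `""` when none).
#' @export
standard_ions <- function() {
  tab <- c(
    "Ibuprofen",                       205.1234, "C13H17O2", "",
    "3-Maleimidopropionic acid",       168.0302, "C7H6NO4",  "",
    "Maleic acid",                     115.0036, "C4H3O4",   "C3H3O2",
    "2-Methylsuccinic acid",           131.0349, "C5H7O4",   "C4H7O2;C4H5O",
    "4-Nitro-1-naphthol",              188.0352, "C10H6NO3", "C10H6O2;C9H5O2",
    "2-Nitrobenzoic acid",             166.0145, "C7H4NO4",  "C6H4NO2",
    "2-Nitrophenol",                   138.0196, "C6H4NO3",  "",
    "4-Methyl-2-nitrophenol",          152.0352, "C7H6NO3",  "C7H6O2;C6H5O;C7H5O2",
    "3-Nitrosalicylic acid",           182.0094, "C7H4NO5",  "C6H4NO3;C6H4O2",
    "2,6-Dimethyl-4-nitrophenol",      166.0509, "C8H8NO3",  "C8H8O2;C8H7O2;C7H7O",
    "4-Nitrocatechol",                 154.0145, "C6H4NO4",  "",
    "Salicylic acid",                  137.0244, "C7H5O3",   "C6H5O;C5H5",
    "2-Sulfobenzoic acid",             200.9858, "C7H5O5S",  "O3S;C6H5O3S",
    "Syringic acid",                   197.0455, "C9H9O5",   "",
    "Syringaldehyde",                  181.0506, "C9H9O4",   "C8H6O4;C4H3O",
    "Vanillin",                        151.0400, "C8H7O3",   "C7H4O3",
    "Nitrobenzene",                    122.0247, "C6H4NO2",  "",
    "Acetylsalicylic acid",            179.0350, "C9H7O4",   "C6H5O;C7H5O3",
    "Trihydroxybenzene",               125.0244, "C6H5O3",   "C3H5O;C5H3O3;C4H3O3",
    "4-Acetamidophenol",               150.0561, "C8H8NO2",
      "C6H5NO;C4H4NO;C7H4NO2;C6H4NO2;C5H4NO;C6H6NO2;C6H6NO;C5H4NO2;C7H6NO2",
    "Pimelic acid",                    159.0663, "C7H11O4",
      "C6H9O;C6H11O2;C6H7O;C2H3O3;C6H9O2;C7H9O3",
    "Benzoic acid",                    121.0295, "C7H5O2",   "C7H5O;C6H5O;C6H5",
    "3',5'-Dimethoxy-4'-hydroxyacetophenone", 195.0663, "C10H11O4", "",
    "2-Carboxybenzaldehyde",           149.0244, "C8H5O3",
      "C7H5O2;C7H5O;C2H3O3;C6H5O;C6H5",
    "Camphor-10-sulfonic acid",        231.0697, "C10H15O4S", "O3S",
    "trans-Cinnamic acid",             147.0452, NA,         "",
    "Glutaric acid",                   131.0350, "C5H7O4",   "C4H7O2;C4H5O",
    "2-Iodobenzoic acid",              246.9262, "C7H4IO2",  "I")
  m <- matrix(tab, ncol = 4, byrow = TRUE)
  data.frame(compound = m[, 1],
             measured_mz = as.numeric(m[, 2]),
             ion_formula = m[, 3],
             fragments = m[, 4],
             stringsAsFactors = FALSE)
}

#' @param rt_start apex of the first compound, minutes.
#' @param rt_spacing spacing between consecutive apexes, minutes.
#' @param peak_sigma,ms1_height passed to [compound_spec()].
#' @param fragment_yield AIF yield given to every fragment ion.
#' @rdname standard_ions
#' @return `standard_mix_compounds()`: list of [compound_spec()]s (the one
#'   entry without an assignable ion formula is skipped).
#' @export
standard_mix_compounds <- function(rt_start = 1, rt_spacing = 0.35,
                                   peak_sigma = 0.05, ms1_height = 1e6,
                                   fragment_yield = 0.4) {
  tab <- standard_ions()
  out <- list()
  for (i in seq_len(nrow(tab))) {
    if (is.na(tab$ion_formula[i])) next
    frs <- NULL
    if (nzchar(tab$fragments[i])) {
      nm <- strsplit(tab$fragments[i], ";")[[1]]
      frs <- stats::setNames(rep(fragment_yield, length(nm)), nm)
    }
    out[[length(out) + 1L]] <- compound_spec(
      tab$ion_formula[i],
      rt_apex = rt_start + (length(out)) * rt_spacing,
      peak_sigma = peak_sigma, ms1_height = ms1_height,
      fragments = frs, label = tab$compound[i])
  }
  out
}
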