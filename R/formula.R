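#' Molecular formulas for small-molecule mass spectrometry
#'
#' A `chemformula` is an element -> count map over the supported element set
#' C, H, N, O, S, I, P together with an ion charge (0 for neutrals, -1 for
#' deprotonated \eqn{[M-H]^-} anions).  It supports the algebra the fragment
#' annotation workflow needs: subtraction (neutral losses), the subformula
#' test, exact monoisotopic m/z and theoretical isotopologue patterns.
#'
#' @param x a formula string such as `"C9H7O4"` (Hill notation; the
#'   underscore style `"C_9_H_7_O_4_"` used in some tables is also accepted),
#'   or a named numeric vector of element counts.
#' @param charge integer ion charge; 0 (neutral), -1 or +1.
#' @return an object of class `chemformula`.
#' @examples
#' f <- chem_formula("C9H7O4", charge = -1)
#' monoisotopic_mz(f)          # 179.0350, the deprotonated aspirin ion
#' neutral_loss(f, chem_formula("C6H5O", charge = -1))
#' @export
chem_formula <- function(x, charge = 0L) {
  if (is.character(x)) {
    counts <- parse_formula_counts(x)
  } else if (is.numeric(x) && !is.null(names(x))) {
    bad <- setdiff(names(x), .ELEMENTS)
    if (length(bad))
      stop("unsupported element(s): ", paste(bad, collapse = ", "))
    counts <- stats::setNames(integer(length(.ELEMENTS)), .ELEMENTS)
    counts[names(x)] <- as.integer(round(x))
  } else {
    stop("'x' must be a formula string or a named count vector")
  }
  if (any(counts < 0)) stop("element counts must be nonnegative")
  charge <- as.integer(charge)
  if (!charge %in% c(-1L, 0L, 1L))
    stop("only singly charged ions or neutrals are supported")
  structure(counts, charge = charge, class = "chemformula")
}

parse_formula_counts <- function(text) {
  text <- gsub("_", "", trimws(text))      # "C_9_H_7_O_4_" -> "C9H7O4"
  counts <- stats::setNames(integer(length(.ELEMENTS)), .ELEMENTS)
  if (text == "" || identical(text, "0")) return(counts)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (sum(nchar(tokens)) != nchar(text))
    stop("cannot parse formula: ", text)
  for (tok in tokens) {
    el <- gsub("[0-9]", "", tok)
    n <- gsub("[^0-9]", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!el %in% .ELEMENTS)
      stop("unsupported element '", el, "' in formula ", text)
    counts[el] <- counts[el] + n
  }
  counts
}

#' @export
format.chemformula <- function(x, ...) {
  cnt <- unclass(x)
  attributes(cnt) <- list(names = names(cnt))
  if (all(cnt == 0)) return("(empty)")
  # Hill order: C, H first when carbon present, remaining alphabetical.
  if (cnt["C"] > 0) ord <- c("C", "H", sort(setdiff(.ELEMENTS, c("C", "H"))))
  else ord <- sort(.ELEMENTS)
  parts <- vapply(ord, function(el) {
    n <- cnt[el]
    if (n == 0) "" else if (n == 1) el else paste0(el, n)
  }, character(1))
  paste(parts[nzchar(parts)], collapse = "")
}

#' @export
print.chemformula <- function(x, ...) {
  chg <- attr(x, "charge")
  tag <- if (chg == 0) "" else if (chg == -1) " [-]" else " [+]"
  cat("<chemformula> ", format(x), tag, "\n", sep = "")
  invisible(x)
}

#' @export
as.character.chemformula <- function(x, ...) format(x)

formula_counts <- function(f) {
  stopifnot(inherits(f, "chemformula"))
  cnt <- unclass(f)
  attributes(cnt) <- list(names = names(cnt))
  cnt
}

formula_charge <- function(f) attr(f, "charge")

is_empty_formula <- function(f) all(formula_counts(f) == 0)

#' @export
`==.chemformula` <- function(e1, e2) {
  all(formula_counts(e1) == formula_counts(e2))
}

#' Elementwise sum of two formulas
#'
#' Used e.g. to construct the +O / +2O in-source oxidation ions.  The charge
#' of the first argument is kept.
#'
#' @param a,b `chemformula` objects.
#' @return a `chemformula`.
#' @export
formula_add <- function(a, b) {
  chem_formula(formula_counts(a) + formula_counts(b),
               charge = formula_charge(a))
}

#' Subformula test
#'
#' A true CID fragment cannot contain atoms that its precursor ion does not
#' have: `is_subformula(f, p)` is `TRUE` iff every element count of `f` is
#' less than or equal to the corresponding count of `p`.
#'
#' @param fragment,precursor `chemformula` objects.
#' @return logical scalar.
#' @export
is_subformula <- function(fragment, precursor) {
  all(formula_counts(fragment) <= formula_counts(precursor))
}

#' Neutral loss between a precursor ion and one of its fragments
#'
#' Elementwise difference `precursor - fragment`, returned as a neutral
#' (charge 0) formula.  Radical losses (e.g. NO from nitroaromatics) are
#' permitted; no ring-double-bond integrality constraint is imposed.
#'
#' @param precursor,fragment `chemformula` objects; `fragment` must be a
#'   subformula of `precursor`.
#' @return a neutral `chemformula` (possibly empty).
#' @export
neutral_loss <- function(precursor, fragment) {
  if (!is_subformula(fragment, precursor))
    stop("not a subformula")
  chem_formula(formula_counts(precursor) - formula_counts(fragment),
               charge = 0L)
}

#' Monoisotopic mass and m/z
#'
#' `monoisotopic_mass()` sums most-abundant-isotope atomic masses and ignores
#' the charge.  `monoisotopic_mz()` applies the electron-mass correction: for
#' a singly charged anion the ion mass is the atomic sum plus one electron
#' mass; for a cation one electron mass is subtracted; neutrals are returned
#' as-is.
#'
#' @param formula a `chemformula`.
#' @return mass in u (`monoisotopic_mass`) or m/z in Th (`monoisotopic_mz`).
#' @export
monoisotopic_mass <- function(formula) {
  cnt <- formula_counts(formula)
  if (all(cnt == 0)) stop("empty formula has no mass")
  sum(cnt * .MONO_MASS[names(cnt)])
}

#' @rdname monoisotopic_mass
#' @export
monoisotopic_mz <- function(formula) {
  m <- monoisotopic_mass(formula)
  m - formula_charge(formula) * .ELECTRON_MASS
}

#' Ring and double bond equivalents
#'
#' RDBE = C - H/2 + N/2 + 1.  Oxygen, sulfur and, by default, iodine
#' contribute nothing; set `halogens = "hydrogen_like"` to count iodine as
#' -1/2 per atom (the usual organic-chemistry convention).  Half-integer
#' values are expected for even-electron ion formulas such as deprotonated
#' acids.
#'
#' @param formula a `chemformula`.
#' @param halogens `"ignore"` (default) or `"hydrogen_like"`.
#' @return numeric RDBE value.
#' @export
rdbe <- function(formula, halogens = c("ignore", "hydrogen_like")) {
  halogens <- match.arg(halogens)
  cnt <- formula_counts(formula)
  out <- cnt["C"] - cnt["H"] / 2 + cnt["N"] / 2 + 1
  if (halogens == "hydrogen_like") out <- out - cnt["I"] / 2
  unname(out)
}

#' Heuristic plausibility limits for elemental compositions
#'
#' Element-ratio limits in the spirit of heuristic composition filtering
#' (RDBE window, H/C, O/C, N/C, S/C ranges and a P-to-O rule).  Each violated
#' rule adds `weight` to the penalty returned by [plausibility_penalty()].
#'
#' @param rdbe_range numeric length-2, allowed RDBE interval.
#' @param hc_range numeric length-2, allowed H/C interval.
#' @param oc_max,nc_max,sc_max upper bounds on O/C, N/C, S/C.
#' @param po_max upper bound on P/O.
#' @param weight penalty added per violated rule.
#' @return a list of rules for [plausibility_penalty()].
#' @export
heuristic_rules <- function(rdbe_range = c(-0.5, 40),
                            hc_range = c(0.1, 3.1),
                            oc_max = 3, nc_max = 2, sc_max = 1,
                            po_max = 1 / 3, weight = 1) {
  list(rdbe_range = as.numeric(rdbe_range), hc_range = as.numeric(hc_range),
       oc_max = as.numeric(oc_max), nc_max = as.numeric(nc_max),
       sc_max = as.numeric(sc_max), po_max = as.numeric(po_max),
       weight = as.numeric(weight))
}

#' Punishment score for unlikely elemental compositions
#'
#' Returns 0 when the formula sits inside all heuristic ranges of `rules`,
#' otherwise the sum of per-violation weights.  Ratio rules involving carbon
#' are skipped for carbon-free formulas (e.g. the SO3 fragment of sulfonic
#' acids), and the P/O rule is skipped when no phosphorus is present.  The
#' whole check is optional in the scoring pipeline and off by default.
#'
#' @param formula a `chemformula`.
#' @param rules a rule set from [heuristic_rules()].
#' @return nonnegative penalty.
#' @export
plausibility_penalty <- function(formula, rules = heuristic_rules()) {
  cnt <- formula_counts(formula)
  pen <- 0
  r <- rdbe(formula)
  if (r < rules$rdbe_range[1] || r > rules$rdbe_range[2])
    pen <- pen + rules$weight
  if (cnt["C"] > 0) {
    hc <- cnt["H"] / cnt["C"]
    if (hc < rules$hc_range[1] || hc > rules$hc_range[2])
      pen <- pen + rules$weight
    if (cnt["O"] / cnt["C"] > rules$oc_max) pen <- pen + rules$weight
    if (cnt["N"] / cnt["C"] > rules$nc_max) pen <- pen + rules$weight
    if (cnt["S"] / cnt["C"] > rules$sc_max) pen <- pen + rules$weight
  }
  if (cnt["P"] > 0) {
    if (cnt["O"] == 0 || cnt["P"] / cnt["O"] > rules$po_max)
      pen <- pen + rules$weight
  }
  pen
}

#' Default element count ranges for formula enumeration
#'
#' Covers typical ESI(-) organic-aerosol constituents below m/z 400 while
#' keeping enumeration fast.  Phosphorus is disabled by default.
#'
#' @return named list of `c(min, max)` integer ranges.
#' @export
default_element_ranges <- function() {
  list(C = c(0L, 50L), H = c(0L, 100L), N = c(0L, 5L), O = c(0L, 20L),
       S = c(0L, 3L), I = c(0L, 2L), P = c(0L, 0L))
}

#' Enumerate candidate molecular formulas for an exact mass
#'
#' Returns every formula inside `ranges` whose theoretical monoisotopic m/z
#' (at the given charge) lies within `mz * (1 +/- tol_ppm * 1e-6)`.  The list
#' is ordered by increasing absolute ppm error; ties are broken by the
#' lexicographic order of the element count vectors.
#'
#' @param mz target m/z in Th.
#' @param tol_ppm mass tolerance in ppm (default 15).
#' @param ranges per-element `c(min, max)` ranges, see
#'   [default_element_ranges()].
#' @param charge ion charge of the candidates (-1 for \eqn{[M-H]^-}).
#' @return list of `chemformula` objects (possibly empty).
#' @export
enumerate_formulas <- function(mz, tol_ppm = 15,
                               ranges = default_element_ranges(),
                               charge = -1L) {
  stopifnot(tol_ppm > 0, mz > 0)
  charge <- as.integer(charge)
  # work on the atomic mass sum: m/z minus the electron-mass correction
  target <- mz + charge * .ELECTRON_MASS
  tol <- mz * tol_ppm * 1e-6
  lo <- target - tol
  hi <- target + tol
  rng <- function(el) {
    r <- ranges[[el]]
    if (is.null(r)) c(0L, 0L) else as.integer(r)
  }
  mC <- .MONO_MASS[["C"]]; mH <- .MONO_MASS[["H"]]; mN <- .MONO_MASS[["N"]]
  mO <- .MONO_MASS[["O"]]; mS <- .MONO_MASS[["S"]]; mI <- .MONO_MASS[["I"]]
  mP <- .MONO_MASS[["P"]]
  rC <- rng("C"); rH <- rng("H"); rN <- rng("N"); rO <- rng("O")
  rS <- rng("S"); rI <- rng("I"); rP <- rng("P")
  out <- list()
  for (nI in rI[1]:rI[2]) {
    if (nI * mI > hi) break
    for (nS in rS[1]:rS[2]) {
      base_s <- nI * mI + nS * mS
      if (base_s > hi) break
      for (nP in rP[1]:rP[2]) {
        base_p <- base_s + nP * mP
        if (base_p > hi) break
        for (nN in rN[1]:rN[2]) {
          base_n <- base_p + nN * mN
          if (base_n > hi) break
          for (nO in rO[1]:rO[2]) {
            base_o <- base_n + nO * mO
            if (base_o > hi) break
            cmax <- min(rC[2], floor((hi - base_o) / mC))
            if (cmax < rC[1]) next
            for (nC in rC[1]:cmax) {
              res <- target - base_o - nC * mC
              # candidate hydrogen counts bracketing the residual mass
              hc <- unique(c(floor(res / mH), ceiling(res / mH)))
              hc <- hc[hc >= rH[1] & hc <= rH[2]]
              for (nH in hc) {
                m <- base_o + nC * mC + nH * mH
                if (m >= lo && m <= hi) {
                  out[[length(out) + 1L]] <- chem_formula(
                    c(C = nC, H = nH, N = nN, O = nO, S = nS, I = nI, P = nP),
                    charge = charge)
                }
              }
            }
          }
        }
      }
    }
  }
  if (!length(out)) return(out)
  ppm <- vapply(out, function(f) abs(monoisotopic_mz(f) - mz) / mz * 1e6,
                numeric(1))
  key <- vapply(out, function(f)
    paste(sprintf("%03d", formula_counts(f)), collapse = ""), character(1))
  out[order(ppm, key)]
}
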