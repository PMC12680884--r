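# Theoretical isotopologue envelopes.
#
# Per-element isotope distributions are expressed over nominal mass offsets
# (0, +1, +2 ... relative to the monoisotopic isotope); a molecule's envelope
# is the convolution of its elements' distributions.  Within each nominal
# bin the exact mass offset is centroided by abundance weighting, which
# collapses the fine structure (13C vs 2H vs 17O ...) the way a centroiding
# instrument at moderate resolution does.

# distribution representation: list(p = prob per bin, m = abundance-weighted
# mean exact-mass offset per bin), bins are nominal offsets 0..(len-1)

.element_dist <- function(el) {
  iso <- .ISOTOPES[[el]]
  off <- as.integer(round(iso$mass - iso$mass[1]))
  nb <- max(off) + 1L
  p <- numeric(nb); pm <- numeric(nb)
  for (i in seq_along(off)) {
    b <- off[i] + 1L
    p[b] <- p[b] + iso$abundance[i]
    pm[b] <- pm[b] + iso$abundance[i] * (iso$mass[i] - iso$mass[1])
  }
  list(p = p, pm = pm)
}

.dist_convolve <- function(a, b, max_bins = 12L) {
  na <- length(a$p); nb <- length(b$p)
  n <- min(na + nb - 1L, max_bins)
  p <- numeric(n); pm <- numeric(n)
  for (i in seq_len(na)) {
    if (a$p[i] == 0) next
    jmax <- min(nb, n - i + 1L)
    if (jmax < 1L) break
    j <- seq_len(jmax)
    k <- i + j - 1L
    p[k] <- p[k] + a$p[i] * b$p[j]
    pm[k] <- pm[k] + a$p[i] * b$pm[j] + a$pm[i] * b$p[j]
  }
  list(p = p, pm = pm)
}

# element distribution raised to the n-th power, by binary exponentiation
.dist_power <- function(d, n, max_bins = 12L) {
  out <- list(p = 1, pm = 0)
  base <- d
  while (n > 0) {
    if (n %% 2 == 1) out <- .dist_convolve(out, base, max_bins)
    base <- .dist_convolve(base, base, max_bins)
    n <- n %/% 2
  }
  out
}

#' Theoretical isotopologue pattern of a formula
#'
#' Convolves the natural-abundance isotope distributions of all atoms,
#' aggregated into nominal-mass-offset bins (the fine structure inside a bin
#' is centroided by abundance weighting).  Intensities are reported relative
#' to the monoisotopic peak, which is 1 by convention.
#'
#' @param formula a `chemformula`.
#' @param n_peaks number of most intense isotopologue peaks to return
#'   (>= 2; the monoisotopic peak counts as one of them).
#' @return a data.frame with columns `mz_offset` (exact-mass offset in u
#'   relative to the monoisotopic peak, increasing) and `rel_intensity`.
#' @examples
#' isotopologue_pattern(chem_formula("C9H7O4", charge = -1))
#' @export
isotopologue_pattern <- function(formula, n_peaks = 5L) {
  stopifnot(n_peaks >= 2)
  cnt <- formula_counts(formula)
  if (all(cnt == 0)) stop("empty formula has no isotopologue pattern")
  d <- list(p = 1, pm = 0)
  for (el in names(cnt)) {
    if (cnt[el] == 0) next
    d <- .dist_convolve(d, .dist_power(.element_dist(el), cnt[el]))
  }
  keep <- d$p > 1e-12
  keep[1] <- TRUE
  off <- ifelse(d$p > 0, d$pm / d$p, seq_along(d$p) - 1)
  rel <- d$p / d$p[1]
  res <- data.frame(mz_offset = off[keep], rel_intensity = rel[keep])
  res <- res[order(-res$rel_intensity), , drop = FALSE]
  res <- utils::head(res, n_peaks)
  res <- res[order(res$mz_offset), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Second-most-intense isotopologue of a formula
#'
#' The rejection rule of the formula predictor hinges on the second
#' isotopologue being detectable.  For formulas composed only of
#' monoisotopic elements (I, P) there is no second isotopologue and `NULL`
#' is returned.
#'
#' @param formula a `chemformula`.
#' @return `NULL`, or a list with `mz_offset` (u above the monoisotopic
#'   peak) and `rel_intensity` (fraction of the monoisotopic intensity).
#' @export
second_isotopologue <- function(formula) {
  if (is_empty_formula(formula)) return(NULL)
  pat <- isotopologue_pattern(formula, n_peaks = 6L)
  rest <- pat[pat$mz_offset > 1e-9, , drop = FALSE]
  rest <- rest[rest$rel_intensity > 1e-10, , drop = FALSE]
  if (!nrow(rest)) return(NULL)
  i <- which.max(rest$rel_intensity)
  list(mz_offset = rest$mz_offset[i], rel_intensity = rest$rel_intensity[i])
}

#' @rdname second_isotopologue
#' @return `second_isotopologue_mz()`: the m/z of that isotopologue, or `NA`.
#' @export
second_isotopologue_mz <- function(formula) {
  if (is_empty_formula(formula)) return(NA_real_)
  si <- second_isotopologue(formula)
  if (is.null(si)) return(NA_real_)
  monoisotopic_mz(formula) + si$mz_offset
}
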