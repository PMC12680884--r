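# Independent oracles, deliberately implemented along different routes than
# the package code they check.

# isotope table used by the oracles (same physical constants, different code
# paths): element -> data.frame(mass, abundance)
oracle_isotopes <- list(
  C = data.frame(mass = c(12.0, 13.00335483507), ab = c(0.9893, 0.0107)),
  H = data.frame(mass = c(1.00782503207, 2.01410177785),
                 ab = c(0.999885, 0.000115)),
  N = data.frame(mass = c(14.0030740048, 15.0001088982),
                 ab = c(0.99636, 0.00364)),
  O = data.frame(mass = c(15.9949146196, 16.9991316521, 17.9991596129),
                 ab = c(0.99757, 0.00038, 0.00205)),
  S = data.frame(mass = c(31.97207100, 32.97145876, 33.96786690,
                          35.96708076),
                 ab = c(0.9499, 0.0075, 0.0425, 0.0001)),
  I = data.frame(mass = 126.9044719, ab = 1.0),
  P = data.frame(mass = 30.97376163, ab = 1.0))
oracle_electron <- 5.48579909065e-4
oracle_mono <- vapply(oracle_isotopes, function(x) x$mass[1], numeric(1))

oracle_counts <- function(formula_string) {
  cnt <- c(C = 0, H = 0, N = 0, O = 0, S = 0, I = 0, P = 0)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", gsub("_", "", formula_string))[[1]]
  for (tok in regmatches(gsub("_", "", formula_string), list(m))[[1]]) {
    if (!nzchar(tok)) next
    el <- gsub("[0-9]", "", tok)
    n <- gsub("[^0-9]", "", tok)
    cnt[el] <- cnt[el] + if (nzchar(n)) as.integer(n) else 1L
  }
  cnt
}

# exhaustive formula enumeration: vectorized grid over C,N,O,S,I,P with the
# hydrogen count solved exactly against the residual mass (every integer H
# in range is checked)
oracle_enumerate <- function(mz, tol_ppm = 15,
                             ranges = default_element_ranges(),
                             charge = -1) {
  target <- mz + charge * oracle_electron
  tol <- mz * tol_ppm * 1e-6
  g <- expand.grid(C = ranges$C[1]:ranges$C[2],
                   N = ranges$N[1]:ranges$N[2],
                   O = ranges$O[1]:ranges$O[2],
                   S = ranges$S[1]:ranges$S[2],
                   I = ranges$I[1]:ranges$I[2],
                   P = ranges$P[1]:ranges$P[2])
  base <- g$C * oracle_mono["C"] + g$N * oracle_mono["N"] +
    g$O * oracle_mono["O"] + g$S * oracle_mono["S"] +
    g$I * oracle_mono["I"] + g$P * oracle_mono["P"]
  out <- character(0)
  for (H in ranges$H[1]:ranges$H[2]) {
    m <- base + H * oracle_mono["H"]
    hit <- which(abs(m - target) <= tol)
    for (i in hit) {
      f <- chem_formula(c(C = g$C[i], H = H, N = g$N[i], O = g$O[i],
                          S = g$S[i], I = g$I[i], P = g$P[i]),
                        charge = charge)
      out <- c(out, format(f))
    }
  }
  sort(out)
}

# closed-form multinomial isotopologue oracle: enumerates, per element, the
# ways of distributing up to `max_heavy` heavy isotopes over the atoms,
# scores each configuration with dmultinom, and combines elements by
# cartesian expansion; configurations are binned by nominal mass offset
oracle_isopattern <- function(formula_string, max_heavy = 4) {
  cnt <- oracle_counts(formula_string)
  configs <- list(data.frame(p = 1, mass = 0, nominal = 0))
  for (el in names(cnt)) {
    n <- cnt[[el]]
    if (n == 0) next
    iso <- oracle_isotopes[[el]]
    k <- nrow(iso)
    # heavy-isotope count vectors with total heavies <= max_heavy
    heavies <- expand.grid(rep(list(0:max_heavy), k - 1))
    if (k == 1) heavies <- data.frame(row.names = 1)
    el_cfg <- data.frame(p = numeric(0), mass = numeric(0),
                         nominal = numeric(0))
    for (r in seq_len(max(1, nrow(heavies)))) {
      hv <- if (k == 1) integer(0) else as.integer(heavies[r, ])
      if (sum(hv) > min(max_heavy, n)) next
      x <- c(n - sum(hv), hv)
      p <- stats::dmultinom(x, prob = iso$ab)
      mass <- sum(x * iso$mass) - n * iso$mass[1]
      nominal <- sum(x * round(iso$mass - iso$mass[1]))
      el_cfg <- rbind(el_cfg, data.frame(p = p, mass = mass,
                                         nominal = nominal))
    }
    new <- list()
    for (cfg in seq_len(nrow(el_cfg))) {
      for (prev in configs) {
        new[[length(new) + 1L]] <- data.frame(
          p = prev$p * el_cfg$p[cfg],
          mass = prev$mass + el_cfg$mass[cfg],
          nominal = prev$nominal + el_cfg$nominal[cfg])
      }
    }
    configs <- new
  }
  all <- do.call(rbind, configs)
  agg_p <- tapply(all$p, all$nominal, sum)
  agg_m <- tapply(all$p * all$mass, all$nominal, sum) / agg_p
  ord <- order(as.numeric(names(agg_p)))
  data.frame(nominal = as.numeric(names(agg_p))[ord],
             rel_intensity = as.numeric(agg_p[ord]) / agg_p[["0"]],
             mz_offset = as.numeric(agg_m[ord]))
}

# reference Gaussian for chromatographic oracles
gauss_curve <- function(t, apex, sigma, height = 1) {
  height * exp(-(t - apex)^2 / (2 * sigma^2))
}
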