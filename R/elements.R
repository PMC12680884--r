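# Isotope masses (u) and natural abundances, pinned so results are
# reproducible offline.  Values: IUPAC/CODATA atomic mass evaluation.
# First row of each element is the most abundant (monoisotopic) isotope.

.ELEMENTS <- c("C", "H", "N", "O", "S", "I", "P")

.ISOTOPES <- list(
  C = data.frame(mass = c(12.0, 13.00335483507),
                 abundance = c(0.9893, 0.0107)),
  H = data.frame(mass = c(1.00782503207, 2.01410177785),
                 abundance = c(0.999885, 0.000115)),
  N = data.frame(mass = c(14.0030740048, 15.0001088982),
                 abundance = c(0.99636, 0.00364)),
  O = data.frame(mass = c(15.9949146196, 16.9991316521, 17.9991596129),
                 abundance = c(0.99757, 0.00038, 0.00205)),
  S = data.frame(mass = c(31.97207100, 32.97145876, 33.96786690, 35.96708076),
                 abundance = c(0.9499, 0.0075, 0.0425, 0.0001)),
  I = data.frame(mass = 126.9044719, abundance = 1.0),
  P = data.frame(mass = 30.97376163, abundance = 1.0)
)

# Monoisotopic (most abundant isotope) atomic masses, u.
.MONO_MASS <- vapply(.ISOTOPES, function(x) x$mass[1], numeric(1))

# CODATA electron mass, u.
.ELECTRON_MASS <- 5.48579909065e-4
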