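# Physical constants used throughout. Monoisotopic masses in Da (IUPAC 2021).

MASS_PROTON <- 1.00727646688
MASS_ELECTRON <- 0.00054857990
MASS_H2O <- 18.0105646863

# 13C - 12C mass difference; fixed so consecutive isotopologue m/z values are
# exactly equispaced at the extraction tolerance used here.
MASS_DELTA_13C <- 1.003355

# Natural abundance of 13C.
NATURAL_13C <- 0.0107

MONOISOTOPIC_MASS <- c(
  C = 12.0, H = 1.0078250319, N = 14.0030740052, O = 15.9949146221,
  P = 30.97376151, S = 31.97207069, Na = 22.98976928, K = 38.9637069,
  Cl = 34.96885268, F = 18.99840322, Br = 78.9183376, I = 126.904473,
  Si = 27.9769265, Se = 73.9224766, Fe = 55.9349421, Mg = 23.9850423,
  Ca = 39.9625912, B = 11.0093055, Zn = 63.9291466, Cu = 62.9296011
)

# Reliable adducts (singly charged, carbon-free). `delta` is added to the
# neutral monoisotopic mass to give the observed m/z.
ADDUCTS <- tibble::tibble(
  adduct = c("[M+H]+", "[M+Na]+", "[M+NH4]+", "[M-H]-", "[M+Cl]-", "[M-H-H2O]-"),
  polarity = c("positive", "positive", "positive", "negative", "negative", "negative"),
  delta = c(
    MASS_PROTON,
    MONOISOTOPIC_MASS[["Na"]] - MASS_ELECTRON,
    MONOISOTOPIC_MASS[["N"]] + 4 * MONOISOTOPIC_MASS[["H"]] - MASS_ELECTRON,
    -MASS_PROTON,
    MONOISOTOPIC_MASS[["Cl"]] + MASS_ELECTRON,
    -MASS_H2O - MASS_PROTON
  )
)

# Accept typographic minus signs in adduct strings from external tables.
normalize_adduct <- function(x) {
  x <- gsub("−|–|—", "-", x)
  gsub("\\s+", "", x)
}
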