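## Amino-acid constants used across the package.

## Canonical one-letter alphabet, alphabetical (column order of every PSSM).
.AA1 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## Kyte-Doolittle hydropathy, used by the surrogate stability model.
.KD_HYDROPATHY <- c(
  A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
  G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
  M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3)

.WATER_RESNAMES <- c("HOH", "WAT", "DOD", "H2O")

## 3-letter -> 1-letter, delegating to bio3d's lookup; unknown codes -> X.
.aa321 <- function(resnames) {
  out <- suppressWarnings(bio3d::aa321(resnames))
  out[is.na(out) | !out %in% .AA1] <- "X"
  out
}

.aa123 <- function(aa1) {
  out <- suppressWarnings(bio3d::aa123(aa1))
  out[is.na(out)] <- "UNK"
  out
}
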