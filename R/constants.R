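# Physico-chemical reference tables. Values are pinned here so that reported
# masses and pI values are bit-stable across platforms.

#' @keywords internal
AA_LETTERS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                "M", "F", "P", "S", "T", "W", "Y", "V")

# Kyte-Doolittle hydropathy index
KD_SCALE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

# IUPAC average residue masses (Da); a peptide adds one water.
RESIDUE_AVG_MASS <- c(
  A =  71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  Q = 128.1307, E = 129.1155, G =  57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P =  97.1167,
  S =  87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V =  99.1326
)
WATER_AVG_MASS <- 18.01524

# Bjellqvist pKa values (the set behind the ExPASy ProtParam theoretical pI).
# N-terminal pKa depends on the first residue; the C-terminal carboxyl pKa is
# shifted when the last residue is D or E.
PK_SIDE_POS <- c(H = 5.98, K = 10.0, R = 12.0)
PK_SIDE_NEG <- c(C = 9.0, D = 4.05, E = 4.45, Y = 10.0)
PK_NTERM <- c(A = 7.59, M = 7.0, S = 6.93, P = 8.36, T = 6.82, V = 7.44,
              E = 7.7)
PK_NTERM_DEFAULT <- 7.5
PK_CTERM <- c(D = 4.55, E = 4.75)
PK_CTERM_DEFAULT <- 3.55

# Dayhoff-style physico-chemical residue classes used for "similarity" in the
# column consensus (hydrophobic aliphatic, aromatic, hydroxyl, acidic, amide,
# basic, and the three singletons whose substitution is rarely conservative).
RESIDUE_CLASSES <- list(
  aliphatic = c("A", "V", "L", "I", "M"),
  aromatic  = c("F", "W", "Y"),
  hydroxyl  = c("S", "T"),
  acidic    = c("D", "E"),
  amide     = c("N", "Q"),
  basic     = c("K", "R", "H"),
  cysteine  = "C",
  glycine   = "G",
  proline   = "P"
)

#' @keywords internal
residue_class_of <- local({
  map <- character(0)
  for (cl in names(RESIDUE_CLASSES)) map[RESIDUE_CLASSES[[cl]]] <- cl
  function(a) unname(map[a])
})

# standard genetic code (translation table 1), used by the six-frame scanner
# and by the reverse translator of the synthetic generator
GENETIC_CODE_1 <- Biostrings::GENETIC_CODE
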