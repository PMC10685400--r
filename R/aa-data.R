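# Amino-acid reference data shared across modules.

#' @keywords internal
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  MSE = "M"  # selenomethionine is treated as methionine
)

AA_ONE_TO_THREE <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
  Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
  L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
  S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL"
)

# Background amino-acid frequencies underlying the BLOSUM62 matrix,
# used as the reference distribution q for conservation scoring.
BLOSUM62_BACKGROUND <- c(
  A = 0.078, R = 0.051, N = 0.041, D = 0.052, C = 0.024,
  Q = 0.034, E = 0.059, G = 0.083, H = 0.025, I = 0.062,
  L = 0.092, K = 0.056, M = 0.024, F = 0.044, P = 0.043,
  S = 0.059, T = 0.055, W = 0.014, Y = 0.034, V = 0.072
)
BLOSUM62_BACKGROUND <- BLOSUM62_BACKGROUND / sum(BLOSUM62_BACKGROUND)
BLOSUM62_BACKGROUND <- BLOSUM62_BACKGROUND[AA_ALPHABET]

# Kyte-Doolittle hydropathy; drives the surrogate contact potential.
KYTE_DOOLITTLE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

# Theoretical maximum accessible surface area per residue type (Angstrom^2),
# Tien et al. 2013 "theoretical" column; denominators for relative SASA.
MAX_SASA <- c(
  A = 129.0, R = 274.0, N = 195.0, D = 193.0, C = 167.0,
  Q = 225.0, E = 223.0, G = 104.0, H = 224.0, I = 197.0,
  L = 201.0, K = 236.0, M = 224.0, F = 240.0, P = 159.0,
  S = 155.0, T = 172.0, W = 285.0, Y = 263.0, V = 174.0
)

# van der Waals radii (Angstrom) by element for sphere-sampling SASA.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, SE = 1.90,
               H = 1.20, P = 1.80)
VDW_DEFAULT_RADIUS <- 1.8

#' Charge class of an amino acid
#'
#' K and R are positive, D and E negative, everything else (including
#' histidine at physiological pH) neutral.
#'
#' @param aa character vector of 1-letter amino-acid codes.
#' @return character vector in \code{c("positive", "negative", "neutral")}.
#' @export
aa_charge_class <- function(aa) {
  out <- rep("neutral", length(aa))
  out[aa %in% c("K", "R")] <- "positive"
  out[aa %in% c("D", "E")] <- "negative"
  out
}

is_standard_aa <- function(aa) aa %in% AA_ALPHABET
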