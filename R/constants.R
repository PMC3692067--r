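# Shared amino-acid tables and scoring constants.
#
# The 20-letter alphabet is fixed in alphabetical one-letter order; every
# integer-coded sequence in the package (including the C++ kernel) indexes
# into this order.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @keywords internal
aa_index <- function(aa) {
  idx <- match(aa, AA_ALPHABET)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))
    stop("non-standard amino acid letter(s) at position(s) ",
         paste(bad, collapse = ", "), ": ",
         paste(unique(aa[bad]), collapse = ", "))
  }
  idx
}

#' @keywords internal
seq_to_int <- function(seq) {
  if (length(seq) == 1L && nchar(seq) > 1L) seq <- strsplit(seq, "")[[1]]
  aa_index(seq)
}

#' @keywords internal
int_to_seq <- function(idx) paste(AA_ALPHABET[idx], collapse = "")

# Background amino-acid frequencies of the BLOSUM62 matrix construction
# (marginals as used by BLAST); sum is exactly 1.
BLOSUM62_BACKGROUND <- c(
  A = 0.074, C = 0.025, D = 0.054, E = 0.054, F = 0.047,
  G = 0.074, H = 0.026, I = 0.068, K = 0.058, L = 0.099,
  M = 0.025, N = 0.045, P = 0.039, Q = 0.034, R = 0.052,
  S = 0.057, T = 0.051, V = 0.073, W = 0.013, Y = 0.032)

# cache for the Biostrings BLOSUM62 matrix restricted to the 20-AA alphabet
.pkg_cache <- new.env(parent = emptyenv())

#' BLOSUM62 substitution matrix over the 20 standard amino acids
#'
#' Returns the BLOSUM62 matrix (from Biostrings) subset to the standard
#' alphabet, rows/columns ordered as `AA_ALPHABET`.
#' @return 20 x 20 integer matrix.
#' @keywords internal
blosum62 <- function() {
  if (is.null(.pkg_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$blosum62 <- e$BLOSUM62[AA_ALPHABET, AA_ALPHABET]
  }
  .pkg_cache$blosum62
}

# Chou-Fasman conformational propensities (helix, strand, turn-as-coil),
# used by the propensity variant of the feature predictor.
CF_HELIX <- c(A = 1.42, C = 0.70, D = 1.01, E = 1.51, F = 1.13,
              G = 0.57, H = 1.00, I = 1.08, K = 1.16, L = 1.21,
              M = 1.45, N = 0.67, P = 0.57, Q = 1.11, R = 0.98,
              S = 0.77, T = 0.83, V = 1.06, W = 1.08, Y = 0.69)
CF_STRAND <- c(A = 0.83, C = 1.19, D = 0.54, E = 0.37, F = 1.38,
               G = 0.75, H = 0.87, I = 1.60, K = 0.74, L = 1.30,
               M = 1.05, N = 0.89, P = 0.55, Q = 1.10, R = 0.93,
               S = 0.75, T = 1.19, V = 1.70, W = 1.37, Y = 1.47)
CF_COIL <- c(A = 0.66, C = 1.19, D = 1.46, E = 0.74, F = 0.60,
             G = 1.56, H = 0.95, I = 0.47, K = 1.01, L = 0.59,
             M = 0.60, N = 1.56, P = 1.52, Q = 0.98, R = 0.95,
             S = 1.43, T = 0.96, V = 0.50, W = 0.96, Y = 1.14)

# Per-residue exposure propensity in [0,1], from Kyte-Doolittle hydropathy
# rescaled so the most hydrophobic residue (I, 4.5) maps to 0 and the most
# hydrophilic (R, -4.5) to 1. Used by the propensity RSA predictor.
KD_HYDROPATHY <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8,
                   G = -0.4, H = -3.2, I = 4.5, K = -3.9, L = 3.8,
                   M = 1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
                   S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)
EXPOSURE_PROPENSITY <- (4.5 - KD_HYDROPATHY) / 9

# Maximum theoretical solvent accessible surface areas (A^2) per residue type
# (Tien et al. 2013, theoretical values); denominator of relative SA.
MAX_ASA <- c(A = 129.0, C = 167.0, D = 193.0, E = 223.0, F = 240.0,
             G = 104.0, H = 224.0, I = 197.0, K = 236.0, L = 201.0,
             M = 224.0, N = 195.0, P = 159.0, Q = 225.0, R = 274.0,
             S = 155.0, T = 172.0, V = 174.0, W = 285.0, Y = 263.0)

# Ideal backbone torsion-bin centers (degrees) per 3-state class, used both
# by the torsion predictor (argmax-bin centers) and the synthetic builders.
SS_STATES <- c("H", "E", "C")
SS_BIN_CENTERS <- matrix(c(-62, -41,    # helix
                           -120, 135,   # strand
                           -75, 150),   # coil
                         nrow = 3, byrow = TRUE,
                         dimnames = list(SS_STATES, c("phi", "psi")))

# van der Waals radii (A) used by the sphere-sampling SA calculation
VDW_RADII <- c(N = 1.65, CA = 1.87, C = 1.76, O = 1.40, CB = 1.87,
               S = 1.85, DEFAULT = 1.80)

#' @keywords internal
atom_radius <- function(elety) {
  r <- VDW_RADII[elety]
  miss <- is.na(r)
  if (any(miss)) {
    # fall back on the first character as the element guess
    el <- substr(elety[miss], 1L, 1L)
    r[miss] <- ifelse(el == "N", VDW_RADII[["N"]],
               ifelse(el == "O", VDW_RADII[["O"]],
               ifelse(el == "S", VDW_RADII[["S"]], VDW_RADII[["DEFAULT"]])))
  }
  unname(r)
}

# Frozen registration offsets (Angstrom) for the idealized antiparallel
# strand pair builder; chosen once from a scan of the hydrogen-bond energy
# landscape of the ideal extended-strand geometry.
PAIRED_STRAND_DX <- 3.5
PAIRED_STRAND_DY <- 4.75
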