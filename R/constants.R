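# Field-standard constant tables used across modules.

#' The 20 standard amino acids, alphabetical one-letter order
#'
#' Feature vectors, weight vectors and composition encodings are always
#' ordered by this vector.
#' @export
AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Kyte-Doolittle hydropathy scale
#'
#' Published per-residue hydropathy values (Ile +4.5 through Arg -4.5).
#' @export
KYTE_DOOLITTLE <- c(
  A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
  G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
  M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3
)

#' Theoretical maximum accessible surface area per residue (A^2)
#'
#' Tien et al. (2013) theoretical max-ASA reference used to normalize
#' absolute ASA to relative exposure in [relativeASA()]. Overridable.
#' @export
MAX_ASA_TIEN2013 <- c(
  A = 129.0, C = 167.0, D = 193.0, E = 223.0, F = 240.0,
  G = 104.0, H = 224.0, I = 197.0, K = 236.0, L = 201.0,
  M = 224.0, N = 195.0, P = 159.0, Q = 225.0, R = 274.0,
  S = 155.0, T = 172.0, V = 174.0, W = 285.0, Y = 263.0
)

# van der Waals radii (A) for the elements seen in protein heavy atoms;
# overridable through the radii argument of shrakeRupleyASA().
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)

# Vector-side primer anchors flanking each 51-nt library insert in the
# expression construct; defaults for oligo synthesis and read trimming.
DEFAULT_FLANK5 <- "GATCAGCTGGCTCACCCG"
DEFAULT_FLANK3 <- "GCTAGCTGACTGATCATGTAATTAG"

STOP_CODONS <- c("TAA", "TAG", "TGA")
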