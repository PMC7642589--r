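# Residue alphabets and physicochemical partition tables shared by the
# descriptor encoders.

#' Canonical amino-acid alphabet
#'
#' The 20 canonical residues in the fixed order used by every encoder
#' (alphabetical one-letter codes). All feature-name canons derive from this
#' order.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Number of codons encoding each residue under the standard genetic code,
# after removing the 3 stop codons; total is 61. Used by the DDE theoretical
# mean T_m(x,y) = (C_x/61) * (C_y/61).
.codon_counts <- c(
  A = 4, C = 2, D = 2, E = 2, F = 2, G = 4, H = 2, I = 3, K = 2, L = 6,
  M = 1, N = 2, P = 4, Q = 2, R = 6, S = 6, T = 4, V = 4, W = 1, Y = 2
)

#' Codon-usage counts for the DDE encoder
#'
#' Per-residue counts of encoding codons under the standard genetic code with
#' the three stop codons removed (sum = 61). These define the theoretical mean
#' of each dipeptide frequency used by the deviation-from-expected-mean
#' descriptor.
#'
#' @return Named integer vector over the 20 canonical residues.
#' @export
codon_counts <- function() .codon_counts

# The 13-attribute composition/transition property set (Tomii-Kanehisa main
# clusters, iFeature convention): each property partitions the 20 residues
# into three groups. Seven hydrophobicity scales plus normalized van der
# Waals volume, polarity, polarizability, charge, secondary structure and
# solvent accessibility.
.ctd_properties <- list(
  hydrophobicity_PRAM900101 = list(
    g1 = c("R","K","E","D","Q","N"),
    g2 = c("G","A","S","T","P","H","Y"),
    g3 = c("C","L","V","I","M","F","W")),
  hydrophobicity_ARGP820101 = list(
    g1 = c("Q","S","T","N","G","D","E"),
    g2 = c("R","A","H","C","K","M","V"),
    g3 = c("L","Y","P","F","I","W")),
  hydrophobicity_ZIMJ680101 = list(
    g1 = c("Q","N","G","S","W","T","D","E","R","A"),
    g2 = c("H","M","C","K","V"),
    g3 = c("L","P","F","Y","I")),
  hydrophobicity_PONP930101 = list(
    g1 = c("K","P","D","E","S","N","Q","T"),
    g2 = c("G","R","H","A"),
    g3 = c("Y","C","L","V","I","M","F","W")),
  hydrophobicity_CASG920101 = list(
    g1 = c("K","D","E","Q","P","S","R","N","T","G"),
    g2 = c("A","H","Y","M","L","V"),
    g3 = c("F","I","W","C")),
  hydrophobicity_ENGD860101 = list(
    g1 = c("R","D","K","E","N","Q","H","Y","P"),
    g2 = c("S","G","T","A","W"),
    g3 = c("C","V","L","I","M","F")),
  hydrophobicity_FASG890101 = list(
    g1 = c("K","E","R","S","Q","D"),
    g2 = c("N","T","P","G"),
    g3 = c("A","Y","H","W","V","M","F","L","I","C")),
  normwaalsvolume = list(
    g1 = c("G","A","S","T","P","D","C"),
    g2 = c("N","V","E","Q","I","L"),
    g3 = c("M","H","K","F","R","Y","W")),
  polarity = list(
    g1 = c("L","I","F","W","C","M","V","Y"),
    g2 = c("P","A","T","G","S"),
    g3 = c("H","Q","R","K","N","E","D")),
  polarizability = list(
    g1 = c("G","A","S","D","T"),
    g2 = c("C","P","N","V","E","Q","I","L"),
    g3 = c("K","M","H","F","R","Y","W")),
  charge = list(
    g1 = c("K","R"),
    g2 = c("A","N","C","Q","G","H","I","L","M","F","P","S","T","W","Y","V"),
    g3 = c("D","E")),
  secondarystruct = list(
    g1 = c("E","A","L","M","Q","K","R","H"),
    g2 = c("V","I","Y","C","W","F","T"),
    g3 = c("G","N","P","S","D")),
  solventaccess = list(
    g1 = c("A","L","F","C","G","I","V","W"),
    g2 = c("R","K","Q","E","N","D"),
    g3 = c("M","S","P","T","H","Y"))
)

#' Physicochemical 3-group partitions for the CTD encoders
#'
#' Thirteen physicochemical properties, each dividing the 20 canonical
#' residues into three groups (Tomii-Kanehisa main-cluster convention):
#' seven hydrophobicity normalizations, normalized van der Waals volume,
#' polarity, polarizability, charge, secondary structure and solvent
#' accessibility. The composition (CTDC) and transition (CTDT) encoders emit
#' 3 values per property, 39 in total.
#'
#' @return Named list of 13 properties; each a list of character vectors
#'   `g1`, `g2`, `g3` partitioning the alphabet.
#' @export
ctd_properties <- function() .ctd_properties

# Five-group physicochemical recoding used by GDPC/GTPC/CKSAAGP:
# aliphatic, aromatic, positively charged, negatively charged, uncharged.
.aa_groups_5 <- list(
  g1 = c("G","A","V","L","M","I"),
  g2 = c("F","Y","W"),
  g3 = c("K","R","H"),
  g4 = c("D","E"),
  g5 = c("S","T","C","P","N","Q")
)

#' Five-group residue partition for grouped encoders
#'
#' Partition of the alphabet into aliphatic (`g1`), aromatic (`g2`),
#' positively charged (`g3`), negatively charged (`g4`) and uncharged
#' (`g5`) groups, used by the grouped dipeptide/tripeptide and k-spaced
#' group-pair encoders.
#'
#' @return Named list of 5 character vectors partitioning the alphabet.
#' @export
aa_groups_5 <- function() .aa_groups_5

# Seven-class partition (electrostatics and side-chain volume) used by the
# conjoint-triad encoder.
.ctriad_classes <- list(
  c1 = c("A","G","V"),
  c2 = c("I","L","F","P"),
  c3 = c("Y","M","T","S"),
  c4 = c("H","N","Q","W"),
  c5 = c("R","K"),
  c6 = c("D","E"),
  c7 = c("C")
)

#' Seven-class residue partition for the conjoint-triad encoder
#'
#' @return Named list of 7 character vectors partitioning the alphabet.
#' @export
ctriad_classes <- function() .ctriad_classes

# Map each residue to its group label under an arbitrary named partition.
# Returns a named character vector residue -> group name.
.partition_lookup <- function(partition) {
  lut <- character(0)
  for (g in names(partition)) {
    lut[partition[[g]]] <- g
  }
  lut[aa_alphabet()]
}
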