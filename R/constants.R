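# Chemical tables and method constants shared across modules.

# 3-letter -> 1-letter codes for the 20 standard amino acids.
AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

AA_ONE_TO_THREE <- structure(names(AA_THREE_TO_ONE), names = unname(AA_THREE_TO_ONE))

# Common modified/non-standard polymer residues and the standard parent they
# are reduced to for sequence mapping. Unknown polymer components become "X".
MODIFIED_AA_PARENT <- c(
  MSE = "M",  # selenomethionine
  SEC = "C",  # selenocysteine reduced to cysteine for alignment purposes
  PYL = "K",
  CSO = "C", CME = "C", OCS = "C", CSD = "C",
  MLY = "K", KCX = "K", LLP = "K",
  PTR = "Y", TPO = "T", SEP = "S",
  HYP = "P", M3L = "K", FME = "M", CGU = "E", PCA = "Q"
)

# Water component ids; excluded from het inventories and binding targets.
WATER_IDS <- c("HOH", "DOD", "WAT")

# Pseudo-ligands: crystallisation artifacts never treated as binding targets.
PSEUDO_LIGAND_IDS <- c("LA", "LU", "MSE", "OS", "PT", "RE", "SM", "SR",
                       "WO4", "XE", "YB")

# Curated polyatomic ions (monoatomic het groups are recognised by atom count).
ION_IDS <- c("SO4", "PO4", "NO3", "NH4", "CO3", "OH")

# Nucleotide component ids marking a polymer chain as nucleic acid.
NUCLEOTIDE_IDS <- c("A", "C", "G", "U", "I", "DA", "DC", "DG", "DT", "DU", "DI")

# Kyte-Doolittle hydropathy scale.
KYTE_DOOLITTLE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

# Kabsch-Sander secondary-structure constants.
DSSP_Q <- 0.084 * 332       # electrostatic H-bond factor, kcal*A/mol
DSSP_HBOND_CUTOFF <- -0.5   # kcal/mol; bond assigned below this energy
DSSP_BEND_KAPPA <- 70       # degrees; backbone bend threshold
DSSP_CHAIN_BREAK <- 4.5     # Angstrom Ca-Ca distance terminating patterns

# Karlin-Altschul parameters for ungapped BLOSUM62 scoring (natural-log units).
KA_LAMBDA <- 0.318
KA_K <- 0.13

.aa_from_three <- function(name3) {
  name3 <- toupper(trimws(name3))
  out <- AA_THREE_TO_ONE[name3]
  miss <- is.na(out)
  if (any(miss)) {
    out[miss] <- MODIFIED_AA_PARENT[name3[miss]]
    out[is.na(out)] <- "X"
  }
  unname(out)
}

.blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})
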