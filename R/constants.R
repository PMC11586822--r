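# Packaged constant tables for residue-level featurization.
# All tables are keyed by 3-letter residue code and cover the 20 standard
# amino acids plus selenocysteine (SEC).

AA3 <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
         "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL","SEC")

# Heavy-atom element counts per residue (backbone N,CA,C,O included;
# hydrogens and terminal OXT excluded).
RESIDUE_ELEMENT_COUNTS <- local({
  m <- rbind(
    ALA = c(3, 1, 1, 0), ARG = c(6, 4, 1, 0), ASN = c(4, 2, 2, 0),
    ASP = c(4, 1, 3, 0), CYS = c(3, 1, 1, 1), GLN = c(5, 2, 2, 0),
    GLU = c(5, 1, 3, 0), GLY = c(2, 1, 1, 0), HIS = c(6, 3, 1, 0),
    ILE = c(6, 1, 1, 0), LEU = c(6, 1, 1, 0), LYS = c(6, 2, 1, 0),
    MET = c(5, 1, 1, 1), PHE = c(9, 1, 1, 0), PRO = c(5, 1, 1, 0),
    SER = c(3, 1, 2, 0), THR = c(4, 1, 2, 0), TRP = c(11, 2, 1, 0),
    TYR = c(9, 1, 2, 0), VAL = c(5, 1, 1, 0), SEC = c(3, 1, 1, 0))
  colnames(m) <- c("C", "N", "O", "S")
  m
})

# Average residue masses (amino acid minus water), Da.
RESIDUE_MASS <- c(
  ALA = 71.08, ARG = 156.19, ASN = 114.10, ASP = 115.09, CYS = 103.14,
  GLN = 128.13, GLU = 129.12, GLY = 57.05, HIS = 137.14, ILE = 113.16,
  LEU = 113.16, LYS = 128.17, MET = 131.19, PHE = 147.18, PRO = 97.12,
  SER = 87.08, THR = 101.10, TRP = 186.21, TYR = 163.18, VAL = 99.13,
  SEC = 150.04)

# Side-chain nature classes used for the 5-way amino-acid type one-hot.
AA_CLASSES <- list(
  hydrophobic = c("ALA","VAL","LEU","ILE","MET","PHE","TYR","TRP"),
  polar       = c("SER","THR","ASN","GLN"),
  positive    = c("ARG","HIS","LYS"),
  negative    = c("ASP","GLU"),
  special     = c("CYS","SEC","GLY","PRO"))

aa_class_index <- function(resname) {
  for (i in seq_along(AA_CLASSES))
    if (resname %in% AA_CLASSES[[i]]) return(i)
  NA_integer_
}

# Formal side-chain charge at neutral pH used by the synthetic oracle.
RESIDUE_CHARGE <- c(
  ARG = 1, LYS = 1, HIS = 0, ASP = -1, GLU = -1)

residue_charge <- function(resname) {
  ch <- RESIDUE_CHARGE[resname]
  ifelse(is.na(ch), 0, ch)
}

# Five published per-residue hydrophobicity scales (Kyte-Doolittle,
# Hopp-Woods, Eisenberg consensus, Janin, Engelman GES). The registry
# accepts any replacement 21 x 5 table with the same row names.
HYDROPHOBICITY_SCALES <- local({
  kd <- c(ALA=1.8, ARG=-4.5, ASN=-3.5, ASP=-3.5, CYS=2.5, GLN=-3.5, GLU=-3.5,
          GLY=-0.4, HIS=-3.2, ILE=4.5, LEU=3.8, LYS=-3.9, MET=1.9, PHE=2.8,
          PRO=-1.6, SER=-0.8, THR=-0.7, TRP=-0.9, TYR=-1.3, VAL=4.2, SEC=2.5)
  hw <- c(ALA=-0.5, ARG=3.0, ASN=0.2, ASP=3.0, CYS=-1.0, GLN=0.2, GLU=3.0,
          GLY=0.0, HIS=-0.5, ILE=-1.8, LEU=-1.8, LYS=3.0, MET=-1.3, PHE=-2.5,
          PRO=0.0, SER=0.3, THR=-0.4, TRP=-3.4, TYR=-2.3, VAL=-1.5, SEC=-1.0)
  ei <- c(ALA=0.62, ARG=-2.53, ASN=-0.78, ASP=-0.90, CYS=0.29, GLN=-0.85,
          GLU=-0.74, GLY=0.48, HIS=-0.40, ILE=1.38, LEU=1.06, LYS=-1.50,
          MET=0.64, PHE=1.19, PRO=0.12, SER=-0.18, THR=-0.05, TRP=0.81,
          TYR=0.26, VAL=1.08, SEC=0.29)
  ja <- c(ALA=0.3, ARG=-1.4, ASN=-0.5, ASP=-0.6, CYS=0.9, GLN=-0.7, GLU=-0.7,
          GLY=0.3, HIS=-0.1, ILE=0.7, LEU=0.5, LYS=-1.8, MET=0.4, PHE=0.5,
          PRO=-0.3, SER=-0.1, THR=-0.2, TRP=0.3, TYR=-0.4, VAL=0.6, SEC=0.9)
  ge <- c(ALA=1.6, ARG=-12.3, ASN=-4.8, ASP=-9.2, CYS=2.0, GLN=-4.1, GLU=-8.2,
          GLY=1.0, HIS=-3.0, ILE=3.1, LEU=2.8, LYS=-8.8, MET=3.4, PHE=3.7,
          PRO=-0.2, SER=0.6, THR=1.2, TRP=1.9, TYR=-0.7, VAL=2.6, SEC=2.0)
  cbind(kd = kd[AA3], hw = hw[AA3], eisenberg = ei[AA3],
        janin = ja[AA3], ges = ge[AA3])
})

# Theoretical maximum accessible surface area per residue (A^2),
# used to normalise SASA into relative ASA.
MAX_ASA <- c(
  ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167, GLN = 225,
  GLU = 223, GLY = 104, HIS = 224, ILE = 197, LEU = 201, LYS = 236,
  MET = 224, PHE = 240, PRO = 159, SER = 155, THR = 172, TRP = 285,
  TYR = 263, VAL = 174, SEC = 167)

# van der Waals radii (A) for the Shrake-Rupley SASA provider.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, SE = 1.90,
               AU = 1.66, H = 1.20, P = 1.80)

vdw_radius <- function(element) {
  r <- VDW_RADII[toupper(element)]
  ifelse(is.na(r), 1.70, r)
}

DSSP_CLASSES <- c("H", "G", "I", "E", "B", "T", "S", "C")
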