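# Atom-role dictionaries for the 20 standard amino acids.
#
# Interaction typing needs to know, per residue, which heavy atoms can act as
# hydrogen-bond donors (N/O carrying at least one H), acceptors, C-H donors,
# members of formally charged side-chain groups, apolar carbons, and aromatic
# rings.  Structures solved at ~2 A carry no hydrogens, so all definitions are
# heavy-atom based.

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

AA1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
         GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
         MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
         TYR = "Y", VAL = "V")

WATER_NAMES <- c("HOH", "WAT", "H2O", "DOD")
METAL_ELEMENTS <- c("ZN", "MG", "MN", "FE", "CA", "NA", "K", "CU", "NI", "CO",
                    "CD", "HG")

#' Default residue chemistry dictionaries
#'
#' Returns the atom-role dictionaries used by [detect_interactions()] and
#' [hbond_populations()]: per residue type, the heavy atoms that can donate a
#' hydrogen bond (`donors`), accept one (`acceptors`), donate a weak C-H bond
#' (all carbons, resolved at run time), carry side-chain formal charge
#' (`positive` / `negative`), count as apolar carbon (`apolar`), or belong to
#' an aromatic ring (`rings`).  Histidine is treated as neutral by default;
#' set `his_charged = TRUE` to count its side-chain nitrogens as positive.
#'
#' @param his_charged logical; treat His as protonated (positively charged)?
#' @return A list of named lists, one entry per residue role class.
#' @export
default_chemistry <- function(his_charged = FALSE) {
  don <- list( # side-chain N/O donors
    ARG = c("NE", "NH1", "NH2"), LYS = c("NZ"),
    HIS = c("ND1", "NE2"), ASN = c("ND2"), GLN = c("NE2"),
    TRP = c("NE1"), SER = c("OG"), THR = c("OG1"), TYR = c("OH")
  )
  acc <- list( # side-chain N/O acceptors
    ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
    ASN = c("OD1"), GLN = c("OE1"),
    SER = c("OG"), THR = c("OG1"), TYR = c("OH"),
    HIS = c("ND1", "NE2")
  )
  pos <- list(ARG = c("NE", "NH1", "NH2"), LYS = c("NZ"))
  if (his_charged) pos$HIS <- c("ND1", "NE2")
  neg <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
  apolar <- list(
    ALA = "CB", VAL = c("CB", "CG1", "CG2"),
    LEU = c("CB", "CG", "CD1", "CD2"), ILE = c("CB", "CG1", "CG2", "CD1"),
    MET = c("CB", "CG", "CE"),
    PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
    TRP = c("CB", "CG", "CD2", "CE3", "CZ2", "CZ3", "CH2"),
    TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2"),
    PRO = c("CB", "CG"), LYS = c("CB", "CG", "CD"), ARG = c("CB", "CG"),
    GLU = c("CB", "CG"), GLN = c("CB", "CG"), ASP = "CB", ASN = "CB",
    HIS = "CB", THR = "CG2"
  )
  rings <- list(
    HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
    PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
    TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
    TRP = list(c("CG", "CD1", "CD2", "NE1", "CE2"),
               c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"))
  )
  list(donors = don, acceptors = acc, positive = pos, negative = neg,
       apolar = apolar, rings = rings, his_charged = his_charged)
}

# carboxylate oxygen pairs used for zinc denticity
CARBOXYLATE_O <- list(GLU = c("OE1", "OE2"), ASP = c("OD1", "OD2"))
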