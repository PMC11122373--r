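# Atom-type assignment for the solvent-contact model. The default scheme
# collapses protein heavy atoms into 9 classes (plus 2 hydrogen classes
# when hydrogens are present); parameters are fitted per class.

.type_classes <- c("C.ali", "C.aro", "C.car", "N.ami", "N.chg",
                   "O.car", "O.hyd", "O.chg", "S", "H.pol", "H.non")

# backbone, all residues
.bb_types <- c(N = "N.ami", CA = "C.ali", C = "C.car", O = "O.car",
               OXT = "O.chg")

# sidechain heavy atoms; standard charge states at neutral pH
# (Asp/Glu carboxylates and Lys/Arg amines charged)
.sc_types <- list(
  ALA = c(CB = "C.ali"),
  ARG = c(CB = "C.ali", CG = "C.ali", CD = "C.ali", CZ = "C.car",
          NE = "N.chg", NH1 = "N.chg", NH2 = "N.chg"),
  ASN = c(CB = "C.ali", CG = "C.car", OD1 = "O.car", ND2 = "N.ami"),
  ASP = c(CB = "C.ali", CG = "C.car", OD1 = "O.chg", OD2 = "O.chg"),
  CYS = c(CB = "C.ali", SG = "S"),
  GLN = c(CB = "C.ali", CG = "C.ali", CD = "C.car", OE1 = "O.car",
          NE2 = "N.ami"),
  GLU = c(CB = "C.ali", CG = "C.ali", CD = "C.car", OE1 = "O.chg",
          OE2 = "O.chg"),
  GLY = c(),
  HIS = c(CB = "C.ali", CG = "C.aro", CD2 = "C.aro", CE1 = "C.aro",
          ND1 = "N.chg", NE2 = "N.chg"),
  ILE = c(CB = "C.ali", CG1 = "C.ali", CG2 = "C.ali", CD1 = "C.ali"),
  LEU = c(CB = "C.ali", CG = "C.ali", CD1 = "C.ali", CD2 = "C.ali"),
  LYS = c(CB = "C.ali", CG = "C.ali", CD = "C.ali", CE = "C.ali",
          NZ = "N.chg"),
  MET = c(CB = "C.ali", CG = "C.ali", SD = "S", CE = "C.ali"),
  PHE = c(CB = "C.ali", CG = "C.aro", CD1 = "C.aro", CD2 = "C.aro",
          CE1 = "C.aro", CE2 = "C.aro", CZ = "C.aro"),
  PRO = c(CB = "C.ali", CG = "C.ali", CD = "C.ali"),
  SER = c(CB = "C.ali", OG = "O.hyd"),
  THR = c(CB = "C.ali", OG1 = "O.hyd", CG2 = "C.ali"),
  TRP = c(CB = "C.ali", CG = "C.aro", CD1 = "C.aro", CD2 = "C.aro",
          NE1 = "N.ami", CE2 = "C.aro", CE3 = "C.aro", CZ2 = "C.aro",
          CZ3 = "C.aro", CH2 = "C.aro"),
  TYR = c(CB = "C.ali", CG = "C.aro", CD1 = "C.aro", CD2 = "C.aro",
          CE1 = "C.aro", CE2 = "C.aro", CZ = "C.aro", OH = "O.hyd"),
  VAL = c(CB = "C.ali", CG1 = "C.ali", CG2 = "C.ali")
)

# synthetic structures carry one sidechain pseudo-atom named SC whose
# class summarizes the dominant sidechain chemistry of the residue
.sc_pseudo <- c(ALA = "C.ali", VAL = "C.ali", LEU = "C.ali",
                ILE = "C.ali", PRO = "C.ali",
                PHE = "C.aro", TRP = "C.aro", TYR = "C.aro",
                MET = "S", CYS = "S",
                SER = "O.hyd", THR = "O.hyd",
                ASP = "O.chg", GLU = "O.chg",
                ASN = "O.car", GLN = "O.car",
                LYS = "N.chg", ARG = "N.chg", HIS = "N.chg")

#' Atom-type classes of the default typing scheme
#' @return character vector of class names
#' @export
atom_type_classes <- function() .type_classes

#' Assign solvation atom types to a structure
#'
#' Maps every atom onto one of the default scheme's classes: aliphatic,
#' aromatic and carbonyl/carboxyl carbon; amide and charged nitrogen;
#' carbonyl, hydroxyl and charged oxygen; sulfur; and (when hydrogens
#' are present) polar vs nonpolar hydrogen, decided by the element of
#' the nearest heavy atom. Synthetic sidechain pseudo-atoms (name `SC`)
#' get a residue-dependent class.
#'
#' @param s a [protstruct]
#' @param scheme typing scheme name; only `"default"` is packaged.
#' @return the structure with `type` filled in for every atom.
#' @export
assign_atom_types <- function(s, scheme = "default") {
  stopifnot(inherits(s, "protstruct"))
  if (!identical(scheme, "default"))
    stop("unknown typing scheme '", scheme, "'", call. = FALSE)
  a <- s$atoms
  ty <- rep(NA_character_, nrow(a))

  bb <- a$name %in% names(.bb_types)
  ty[bb] <- .bb_types[a$name[bb]]
  pseudo <- a$name == "SC"
  ty[pseudo] <- .sc_pseudo[a$resname[pseudo]]
  rest <- which(is.na(ty) & a$element != "H")
  for (i in rest) {
    tab <- .sc_types[[a$resname[i]]]
    if (!is.null(tab)) ty[i] <- unname(tab[a$name[i]])
  }

  hyd <- which(a$element == "H")
  if (length(hyd)) {
    heavy <- which(a$element != "H")
    xyz <- coords(s)
    d2 <- cross_dist2(xyz[hyd, , drop = FALSE], xyz[heavy, , drop = FALSE])
    near <- heavy[apply(d2, 1, which.min)]
    ty[hyd] <- ifelse(a$element[near] %in% c("N", "O", "S"),
                      "H.pol", "H.non")
  }

  bad <- which(is.na(ty))
  if (length(bad))
    stop("unmappable atom(s): ",
         paste(unique(paste0(a$resname[bad], ":", a$name[bad])),
               collapse = ", "), call. = FALSE)
  s$atoms$type <- ty
  s
}
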