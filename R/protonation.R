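# Rule-based protonation-state assignment from local hydrogen-bonding
# geometry. States are decided on heavy-atom distances only, since the
# rules are applied before hydrogens are added to the model.

# hydrogen-bonding role of sidechain atoms, by residue
.hb_sidechain <- list(
  SER = c(OG  = "both"),
  THR = c(OG1 = "both"),
  TYR = c(OH  = "both"),
  ASN = c(OD1 = "acceptor", ND2 = "donor"),
  GLN = c(OE1 = "acceptor", NE2 = "donor"),
  ASP = c(OD1 = "acceptor", OD2 = "acceptor"),
  GLU = c(OE1 = "acceptor", OE2 = "acceptor"),
  LYS = c(NZ  = "donor"),
  ARG = c(NE  = "donor", NH1 = "donor", NH2 = "donor"),
  HIS = c(ND1 = "both", NE2 = "both"),
  TRP = c(NE1 = "donor"),
  CYS = c(SG  = "donor"),
  MET = c(SD  = "none")
)

#' Classify atoms as hydrogen-bond donors/acceptors
#'
#' Deterministic lookup: backbone carbonyl O (and OXT) are acceptors,
#' backbone amide N is a donor (except proline, which has no NH), and
#' sidechain N/O/S atoms follow a packaged chemistry table. Carbon atoms
#' and hydrogens are `"none"`. Unrecognized polar atom names are
#' classified `"none"` with a warning, never an error.
#'
#' @param s a [protstruct]
#' @return character vector, one of `"donor"`, `"acceptor"`, `"both"`,
#'   `"none"` per atom.
#' @export
classify_hb_groups <- function(s) {
  stopifnot(inherits(s, "protstruct"))
  a <- s$atoms
  out <- rep("none", nrow(a))
  bb_n <- a$name == "N"
  out[bb_n] <- ifelse(a$resname[bb_n] == "PRO", "none", "donor")
  out[a$name %in% c("O", "OXT")] <- "acceptor"
  side <- !(a$name %in% c("N", "O", "OXT", "CA", "C"))
  unknown <- character()
  for (i in which(side)) {
    el <- a$element[i]
    if (!el %in% c("N", "O", "S")) next  # apolar atoms carry no role
    tab <- .hb_sidechain[[a$resname[i]]]
    role <- tab[a$name[i]]
    if (is.null(tab) || is.na(role)) {
      unknown <- c(unknown, paste0(a$resname[i], ":", a$name[i]))
    } else {
      out[i] <- unname(role)
    }
  }
  if (length(unknown))
    warning("unclassified polar atom(s), treated as 'none': ",
            paste(unique(unknown), collapse = ", "), call. = FALSE)
  out
}

.ionizable <- c("ASP", "GLU", "LYS", "HIS")
.default_state <- c(ASP = "ASP-", GLU = "GLU-", LYS = "LYS+",
                    HIS = "HIS-NE2H")

#' Assign protonation states of ionizable residues
#'
#' Asp and Glu sidechains are taken as neutral if either carboxylate
#' oxygen lies within `cutoff` of a hydrogen-bond-accepting group of
#' another residue (two acceptors that close imply one of them carries
#' the proton); otherwise they are charged. Lys is protonated unless its
#' NZ atom lies within `cutoff` of a hydrogen-bond-donating group of
#' another residue. His follows the same geometric logic symmetrically:
#' it is doubly protonated (HIS+) when both ring nitrogens see an
#' acceptor within the cutoff, and otherwise adopts the tautomer whose
#' protonated nitrogen faces an acceptor (NE2-H by default).
#'
#' Ionizable residues with missing sidechain atoms receive their default
#' state (ASP-, GLU-, LYS+, HIS-NE2H) with a warning.
#'
#' @param s a [protstruct]
#' @param cutoff heavy-atom distance cutoff in Angstrom (default 3.5).
#' @return object of class `protonation`: a data frame with one row per
#'   ionizable residue (`chain`, `resid`, `resname`, `state`,
#'   `partner_atom`, `partner_resid`, `distance`), cutoff stored as an
#'   attribute. Partner columns are `NA` for default assignments.
#' @export
assign_protonation <- function(s, cutoff = 3.5) {
  stopifnot(inherits(s, "protstruct"), cutoff >= 0)
  a <- s$atoms
  roles <- classify_hb_groups(s)
  xyz <- coords(s)
  res <- residues(s)
  res <- res[res$resname %in% .ionizable, , drop = FALSE]

  acc <- roles %in% c("acceptor", "both")
  don <- roles %in% c("donor", "both")

  nearest_partner <- function(atom_idx, partner_mask) {
    # nearest qualifying atom of a *different* residue
    own <- a$chain == a$chain[atom_idx] & a$resid == a$resid[atom_idx]
    cand <- which(partner_mask & !own)
    if (!length(cand)) return(NULL)
    d <- sqrt(colSums((t(xyz[cand, , drop = FALSE]) - xyz[atom_idx, ])^2))
    j <- which.min(d)
    list(idx = cand[j], dist = d[j])
  }

  rows <- vector("list", nrow(res))
  missing_atoms <- character()
  for (k in seq_len(nrow(res))) {
    rn <- res$resname[k]
    in_res <- a$chain == res$chain[k] & a$resid == res$resid[k]
    pick <- function(nm) which(in_res & a$name == nm)
    state <- .default_state[[rn]]
    partner <- list(atom = NA_character_, resid = NA_integer_,
                    dist = NA_real_)

    key_atoms <- switch(rn,
      ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
      LYS = "NZ", HIS = c("ND1", "NE2"))
    have <- vapply(key_atoms, function(nm) length(pick(nm)) > 0, logical(1))

    if (!all(have)) {
      missing_atoms <- c(missing_atoms,
                         paste0(rn, res$resid[k], "/", res$chain[k]))
    } else if (rn %in% c("ASP", "GLU")) {
      best <- NULL
      for (nm in key_atoms) {
        hit <- nearest_partner(pick(nm), acc)
        if (!is.null(hit) && (is.null(best) || hit$dist < best$dist)) {
          best <- hit; best$via <- nm
        }
      }
      if (!is.null(best) && best$dist <= cutoff) {
        state <- paste0(rn, "0")
        partner <- list(atom = a$name[best$idx], resid = a$resid[best$idx],
                        dist = best$dist)
      }
    } else if (rn == "LYS") {
      hit <- nearest_partner(pick("NZ"), don)
      if (!is.null(hit) && hit$dist <= cutoff) {
        state <- "LYS0"
        partner <- list(atom = a$name[hit$idx], resid = a$resid[hit$idx],
                        dist = hit$dist)
      }
    } else if (rn == "HIS") {
      nd1 <- nearest_partner(pick("ND1"), acc)
      ne2 <- nearest_partner(pick("NE2"), acc)
      nd1_close <- !is.null(nd1) && nd1$dist <= cutoff
      ne2_close <- !is.null(ne2) && ne2$dist <= cutoff
      if (nd1_close && ne2_close) {
        state <- "HIS+"
        hit <- if (nd1$dist <= ne2$dist) nd1 else ne2
        partner <- list(atom = a$name[hit$idx], resid = a$resid[hit$idx],
                        dist = hit$dist)
      } else if (nd1_close) {
        state <- "HIS-ND1H"
        partner <- list(atom = a$name[nd1$idx], resid = a$resid[nd1$idx],
                        dist = nd1$dist)
      }  # NE2-H tautomer is the default
    }

    rows[[k]] <- data.frame(
      chain = res$chain[k], resid = res$resid[k], resname = rn,
      state = state, partner_atom = partner$atom,
      partner_resid = partner$resid, distance = partner$dist,
      stringsAsFactors = FALSE)
  }
  if (length(missing_atoms))
    warning("missing sidechain atoms, default state assigned for: ",
            paste(missing_atoms, collapse = ", "), call. = FALSE)

  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chain = character(), resid = integer(),
               resname = character(), state = character(),
               partner_atom = character(), partner_resid = integer(),
               distance = numeric(), stringsAsFactors = FALSE)
  attr(out, "cutoff") <- cutoff
  class(out) <- c("protonation", "data.frame")
  out
}

#' Write a protonation assignment as TSV
#' @param pa a `protonation` object from [assign_protonation()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_protonation <- function(pa, path) {
  utils::write.table(as.data.frame(pa), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
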