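# Interface contact enumeration between two chains of a complex:
# hydrogen bonds on a heavy-atom donor-acceptor distance criterion and
# van der Waals contacts on a plain distance criterion. No angle term:
# assignments are made on heavy atoms before hydrogens exist.

chain_atoms <- function(s, chain) {
  idx <- which(s$atoms$chain == chain & s$atoms$element != "H")
  if (!length(idx))
    stop("chain '", chain, "' not present in structure", call. = FALSE)
  idx
}

contact_pairs <- function(s, ia, ib, d_max) {
  xyz <- coords(s)
  d2 <- cross_dist2(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE])
  hit <- which(d2 <= d_max^2, arr.ind = TRUE)
  data.frame(i = ia[hit[, 1]], j = ib[hit[, 2]],
             distance = sqrt(d2[hit]))
}

atom_cols <- function(s, idx, prefix) {
  a <- s$atoms
  out <- data.frame(a$serial[idx], a$chain[idx], a$resid[idx],
                    a$resname[idx], a$name[idx], stringsAsFactors = FALSE)
  names(out) <- paste0(prefix, c("_serial", "_chain", "_resid",
                                 "_resname", "_name"))
  out
}

#' Find cross-chain hydrogen bonds
#'
#' Enumerates heavy-atom donor-acceptor pairs between two chains with
#' distance at most `d_max`, using the packaged donor/acceptor
#' chemistry table ([classify_hb_groups()]). Atoms classified `"both"`
#' can take either role; a pair of such atoms is reported once per
#' role assignment. Sorted by distance.
#'
#' @param s a [protstruct] containing both chains
#' @param chainA,chainB chain identifiers
#' @param d_max donor-acceptor distance cutoff, Angstrom (default 3.5)
#' @return data frame of hydrogen bonds (donor and acceptor identity
#'   plus distance)
#' @export
find_hbonds <- function(s, chainA, chainB, d_max = 3.5) {
  stopifnot(inherits(s, "protstruct"), d_max > 0)
  roles <- classify_hb_groups(s)
  ia <- chain_atoms(s, chainA)
  ib <- chain_atoms(s, chainB)
  don <- roles %in% c("donor", "both")
  acc <- roles %in% c("acceptor", "both")
  ab <- contact_pairs(s, ia[don[ia]], ib[acc[ib]], d_max)
  ba <- contact_pairs(s, ib[don[ib]], ia[acc[ia]], d_max)
  both <- rbind(ab, ba)
  out <- cbind(atom_cols(s, both$i, "donor"),
               atom_cols(s, both$j, "acceptor"),
               distance = both$distance)
  out <- out[order(out$distance, out$donor_serial, out$acceptor_serial), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find cross-chain van der Waals contacts
#'
#' Heavy-atom pairs between two chains within `d_max`, each unordered
#' pair reported once. With `nonpolar_only`, both atoms must be carbon
#' or sulfur.
#'
#' @param s a [protstruct] containing both chains
#' @param chainA,chainB chain identifiers
#' @param d_max contact distance cutoff, Angstrom (default 4.5)
#' @param nonpolar_only restrict both partners to C/S atoms
#' @return data frame of contacts, sorted by distance
#' @export
find_vdw_contacts <- function(s, chainA, chainB, d_max = 4.5,
                              nonpolar_only = FALSE) {
  stopifnot(inherits(s, "protstruct"), d_max > 0)
  ia <- chain_atoms(s, chainA)
  ib <- chain_atoms(s, chainB)
  if (nonpolar_only) {
    np <- s$atoms$element %in% c("C", "S")
    ia <- ia[np[ia]]; ib <- ib[np[ib]]
    if (!length(ia) || !length(ib))
      return(cbind(atom_cols(s, integer(), "atom1"),
                   atom_cols(s, integer(), "atom2"),
                   distance = numeric()))
  }
  pairs <- contact_pairs(s, ia, ib, d_max)
  out <- cbind(atom_cols(s, pairs$i, "atom1"),
               atom_cols(s, pairs$j, "atom2"),
               distance = pairs$distance)
  out <- out[order(out$distance, out$atom1_serial, out$atom2_serial), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Interface contact report for a two-chain complex
#'
#' Bundles hydrogen bonds, van der Waals contacts and a per-residue-pair
#' interface summary.
#'
#' @param s a [protstruct]
#' @param chainA,chainB chain identifiers
#' @param hb_dmax,vdw_dmax distance cutoffs, Angstrom
#' @return object of class `contact_report`
#' @export
contact_report <- function(s, chainA, chainB, hb_dmax = 3.5,
                           vdw_dmax = 4.5) {
  hb <- find_hbonds(s, chainA, chainB, hb_dmax)
  vdw <- find_vdw_contacts(s, chainA, chainB, vdw_dmax)
  respairs <- unique(data.frame(
    res1 = paste0(vdw$atom1_resname, vdw$atom1_resid, "/", vdw$atom1_chain),
    res2 = paste0(vdw$atom2_resname, vdw$atom2_resid, "/", vdw$atom2_chain),
    stringsAsFactors = FALSE))
  structure(list(hbonds = hb, vdw_contacts = vdw,
                 interface_residue_pairs = respairs,
                 chains = c(chainA, chainB),
                 cutoffs = c(hbond = hb_dmax, vdw = vdw_dmax)),
            class = "contact_report")
}

#' @export
print.contact_report <- function(x, ...) {
  cat(sprintf("Interface %s:%s | %d hydrogen bonds (<= %.1f A), %d vdW contacts (<= %.1f A), %d residue pairs\n",
              x$chains[1], x$chains[2], nrow(x$hbonds), x$cutoffs["hbond"],
              nrow(x$vdw_contacts), x$cutoffs["vdw"],
              nrow(x$interface_residue_pairs)))
  invisible(x)
}
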