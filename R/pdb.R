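# PDB reading and writing. Only the fixed-column ATOM/HETATM subset of the
# format is supported; no installed R package in this stack parses PDB, so
# the reader is implemented here against the standard column layout.

#' Read a protein structure from a PDB file
#'
#' Parses standard fixed-column `ATOM` records, preserving author residue
#' numbering. Waters and heteroatom (`HETATM`) records are dropped by
#' default, as are hydrogens; alternate locations are resolved by keeping
#' the highest-occupancy conformer (ties go to altloc `A`). Insertion
#' codes are rejected.
#'
#' @param path path to a PDB file.
#' @param keep_hydrogens keep hydrogen atoms (default `FALSE`).
#' @param keep_hetero keep non-water `HETATM` records (default `FALSE`).
#' @return a [protstruct].
#' @export
read_pdb <- function(path, keep_hydrogens = FALSE, keep_hetero = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  idx <- which(is_atom)
  if (!length(idx))
    stop("no ATOM/HETATM records in ", path, call. = FALSE)

  ln <- lines[idx]
  parse_num <- function(str, what, lineno) {
    v <- suppressWarnings(as.numeric(str))
    bad <- which(is.na(v) | !nzchar(trimws(str)))
    if (length(bad))
      stop("malformed ", what, " in PDB record at line ", lineno[bad[1]],
           call. = FALSE)
    v
  }
  serial <- parse_num(substr(ln, 7, 11), "serial", idx)
  name <- trimws(substr(ln, 13, 16))
  altloc <- substr(ln, 17, 17)
  resname <- trimws(substr(ln, 18, 20))
  chain <- substr(ln, 22, 22)
  resid <- parse_num(substr(ln, 23, 26), "residue number", idx)
  icode <- substr(ln, 27, 27)
  if (any(icode != " "))
    stop("insertion codes are not supported (line ",
         idx[which(icode != " ")[1]], ")", call. = FALSE)
  x <- parse_num(substr(ln, 31, 38), "x coordinate", idx)
  y <- parse_num(substr(ln, 39, 46), "y coordinate", idx)
  z <- parse_num(substr(ln, 47, 54), "z coordinate", idx)
  occ <- suppressWarnings(as.numeric(substr(ln, 55, 60)))
  occ[is.na(occ)] <- 1
  element <- trimws(substr(ln, 77, 78))
  # derive element from the atom name when columns 77-78 are blank
  noel <- !nzchar(element)
  if (any(noel)) {
    nm <- sub("^[0-9]+", "", name[noel])
    element[noel] <- ifelse(substr(nm, 1, 1) == "H", "H",
                            substr(nm, 1, 1))
  }

  a <- data.frame(serial = as.integer(serial), name = name,
                  element = element, resname = resname,
                  resid = as.integer(resid), chain = chain,
                  x = x, y = y, z = z, stringsAsFactors = FALSE)
  het <- rec[idx] == "HETATM"
  water <- a$resname %in% c("HOH", "WAT", "DOD")
  keep <- !water & (!het | keep_hetero)
  if (!keep_hydrogens) keep <- keep & a$element != "H"
  a <- a[keep, , drop = FALSE]
  altloc <- altloc[keep]; occ <- occ[keep]

  # altloc: per (chain, resid, name) keep highest occupancy, tie -> 'A'
  if (any(altloc != " ")) {
    key <- paste(a$chain, a$resid, a$name)
    pref <- order(key, -occ, altloc != "A", altloc)
    a <- a[pref, , drop = FALSE]
    a <- a[!duplicated(key[pref]), , drop = FALSE]
    a <- a[order(a$serial), , drop = FALSE]
  }
  if (!nrow(a))
    stop("structure is empty after filtering (", path, ")", call. = FALSE)

  title <- trimws(sub("^TITLE ", "", lines[rec == "TITLE "][1]))
  protstruct(a, title = if (is.na(title)) "" else title)
}

#' Write a structure to a PDB file
#'
#' Emits standard fixed-column `ATOM` records with coordinates to three
#' decimals, so that [read_pdb()] recovers the structure.
#'
#' @param s a non-empty [protstruct].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  stopifnot(inherits(s, "protstruct"))
  a <- s$atoms
  if (!nrow(a)) stop("cannot write an empty structure", call. = FALSE)
  if (any(a$resid > 9999L | a$resid < -999L))
    stop("residue numbers outside the PDB field width (-999..9999)",
         call. = FALSE)
  if (any(abs(c(a$x, a$y, a$z)) >= 10000))
    stop("coordinates outside the PDB field width", call. = FALSE)
  # atom names of <4 characters start in column 14 by convention
  nm <- ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name)
  lines <- sprintf(
    "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    a$serial %% 100000L, nm, a$resname, a$chain, a$resid,
    a$x, a$y, a$z, 1, 0, a$element)
  header <- if (nzchar(s$title)) paste0("TITLE ", s$title) else character()
  writeLines(c(header, lines, "END"), path)
  invisible(path)
}

#' Extract a residue range from one chain
#'
#' Residue ranges use author numbering and are inclusive on both ends,
#' e.g. the three-helix scaffold spans residues 164 to 232 of its source
#' chain (232 - 164 + 1 = 69 residues).
#'
#' @param s a [protstruct]
#' @param chain chain identifier
#' @param start,end first and last residue number to keep (inclusive)
#' @return a [protstruct] restricted to the requested residues, order
#'   preserved.
#' @export
extract_range <- function(s, chain, start, end) {
  stopifnot(inherits(s, "protstruct"))
  if (start > end) stop("start must be <= end", call. = FALSE)
  a <- s$atoms
  if (!any(a$chain == chain))
    stop("chain '", chain, "' not present in structure", call. = FALSE)
  keep <- a$chain == chain & a$resid >= start & a$resid <= end
  if (!any(keep))
    stop("chain '", chain, "' has no residues in range ", start, "-", end,
         call. = FALSE)
  protstruct(a[keep, , drop = FALSE], title = s$title)
}
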