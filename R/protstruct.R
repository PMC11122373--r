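#' Protein structure container
#'
#' A `protstruct` holds an ordered table of heavy (and optionally hydrogen)
#' atoms with author residue numbering, the geometric substrate of all
#' scoring in this package. It is a thin S3 wrapper around a data frame
#' with one row per atom.
#'
#' @param atoms data frame with columns `serial` (integer), `name` (atom
#'   name), `element` (element symbol), `resname` (3-letter residue code),
#'   `resid` (integer, author numbering), `chain` (single character), `x`,
#'   `y`, `z` (coordinates in Angstrom) and optionally `type` (atom-type
#'   key into a [solvation_params] table; `NA` until assigned).
#' @param title optional free-text title.
#' @return an object of class `protstruct`.
#' @examples
#' s <- protstruct(data.frame(
#'   serial = 1L, name = "CA", element = "C", resname = "ALA",
#'   resid = 1L, chain = "A", x = 0, y = 0, z = 0))
#' n_atoms(s)
#' @export
protstruct <- function(atoms, title = "") {
  need <- c("serial", "name", "element", "resname", "resid", "chain",
            "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atoms table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (!"type" %in% names(atoms))
    atoms[["type"]] <- rep(NA_character_, nrow(atoms))
  atoms$serial <- as.integer(atoms$serial)
  atoms$resid <- as.integer(atoms$resid)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (nrow(atoms) && !all(is.finite(xyz)))
    stop("atom coordinates must be finite", call. = FALSE)
  if (nrow(atoms) && any(!nzchar(atoms$element)))
    stop("every atom needs an element symbol", call. = FALSE)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, title = as.character(title)[1]),
            class = "protstruct")
}

#' @export
print.protstruct <- function(x, ...) {
  r <- residues(x)
  cat("<protstruct>", if (nzchar(x$title)) x$title else NULL, "\n")
  cat("  ", n_atoms(x), " atoms, ", nrow(r), " residues, chains: ",
      paste(unique(r$chain), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Number of atoms in a structure
#' @param s a [protstruct]
#' @return integer atom count
#' @export
n_atoms <- function(s) nrow(s$atoms)

#' Residue table of a structure
#'
#' @param s a [protstruct]
#' @return data frame with one row per residue (`chain`, `resid`,
#'   `resname`), in order of first appearance.
#' @export
residues <- function(s) {
  a <- s$atoms
  key <- paste(a$chain, a$resid)
  keep <- !duplicated(key)
  out <- data.frame(chain = a$chain[keep], resid = a$resid[keep],
                    resname = a$resname[keep], stringsAsFactors = FALSE)
  if (anyDuplicated(paste(out$chain, out$resid)))
    stop("residue identifiers are not unique", call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Atom coordinates as a matrix
#' @param s a [protstruct]
#' @return numeric matrix with columns x, y, z
#' @export
coords <- function(s) {
  m <- as.matrix(s$atoms[, c("x", "y", "z")])
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  m
}

#' Replace atom coordinates
#' @param s a [protstruct]
#' @param value numeric n-by-3 matrix
#' @return the modified structure
#' @export
`coords<-` <- function(s, value) {
  stopifnot(is.matrix(value), ncol(value) == 3, nrow(value) == n_atoms(s))
  if (!all(is.finite(value))) stop("coordinates must be finite", call. = FALSE)
  s$atoms$x <- value[, 1]; s$atoms$y <- value[, 2]; s$atoms$z <- value[, 3]
  s
}

#' Apply a rigid-body transform to a structure
#'
#' @param s a [protstruct]
#' @param rotation 3x3 rotation matrix (default identity)
#' @param translation length-3 shift in Angstrom (default none)
#' @return the transformed structure
#' @export
transform_structure <- function(s, rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(is.matrix(rotation), all(dim(rotation) == c(3, 3)),
            length(translation) == 3)
  xyz <- coords(s) %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  coords(s) <- xyz
  s
}

#' Sequence of a chain in 1-letter code
#' @param s a [protstruct]
#' @param chain chain identifier (default: first chain)
#' @return character scalar
#' @export
chain_sequence <- function(s, chain = NULL) {
  r <- residues(s)
  if (is.null(chain)) chain <- r$chain[1]
  r <- r[r$chain == chain, , drop = FALSE]
  if (!nrow(r)) stop("chain '", chain, "' not present", call. = FALSE)
  letters1 <- AA3to1[r$resname]
  letters1[is.na(letters1)] <- "X"
  paste(letters1, collapse = "")
}

#' @export
as.data.frame.protstruct <- function(x, ...) x$atoms
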