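# Point-mutation bookkeeping for receptor and scaffold preparation.

#' Parse a point-mutation specifier
#'
#' Mutations are written in the conventional `I543A` form: wild-type
#' residue, author-numbered position, replacement residue.
#'
#' @param text a string like `"V600E"`.
#' @return an object of class `mutation_spec` with fields `wt`, `pos`,
#'   `mut`.
#' @examples
#' parse_mutation_spec("V600E")
#' @export
parse_mutation_spec <- function(text) {
  text <- trimws(text)
  m <- regmatches(text, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", text))[[1]]
  if (length(m) != 4)
    stop("cannot parse mutation spec '", text,
         "' (expected letter-digits-letter)", call. = FALSE)
  wt <- toupper(m[2]); mut <- toupper(m[4])
  for (aa in c(wt, mut))
    if (!aa %in% AA1)
      stop("'", aa, "' in '", text, "' is not a standard amino acid",
           call. = FALSE)
  if (wt == mut)
    stop("mutation '", text, "' replaces a residue with itself",
         call. = FALSE)
  structure(list(wt = wt, pos = as.integer(m[3]), mut = mut),
            class = "mutation_spec")
}

#' @export
print.mutation_spec <- function(x, ...) {
  cat(sprintf("<mutation> %s%d%s\n", x$wt, x$pos, x$mut))
  invisible(x)
}

#' Parse a list of mutation specifiers
#'
#' @param text a character vector of specs, or a single comma-separated
#'   string like `"I543A, I544S"`.
#' @return a list of [parse_mutation_spec()] results.
#' @export
parse_mutation_list <- function(text) {
  parts <- trimws(unlist(strsplit(text, ",")))
  parts <- parts[nzchar(parts)]
  lapply(parts, parse_mutation_spec)
}

#' The 15 solubilizing mutations of the BRAF kinase-domain construct
#'
#' The kinase domain of BRAF expresses in soluble form in E. coli only
#' after 15 surface mutations in the C-terminal lobe; this set, plus
#' V600E, defines the receptor construct the screen designs against.
#'
#' @return character vector of 15 mutation specs.
#' @export
braf_solubilizing_mutations <- function() {
  c("I543A", "I544S", "I551K", "Q562R", "L588N", "K630S", "Y673S",
    "A688R", "L706S", "Q709R", "S713E", "L716E", "S720E", "P722S",
    "K723G")
}

#' Apply point mutations to a numbered sequence
#'
#' The sequence carries an explicit numbering offset so UniProt-style
#' positions (e.g. 600 in a kinase-domain construct starting at residue
#' 449) map unambiguously onto string indices. Every mutation's wild-type
#' letter is checked against the sequence before anything is changed.
#'
#' @param seq 1-letter amino-acid string.
#' @param muts list of `mutation_spec` (or character specs, parsed on the
#'   fly).
#' @param offset author number of the first residue in `seq` (default 1).
#' @return the mutated sequence, with attribute `offset` preserved.
#' @export
apply_mutations <- function(seq, muts, offset = 1L) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (is.character(muts)) muts <- parse_mutation_list(muts)
  muts <- lapply(muts, function(m)
    if (inherits(m, "mutation_spec")) m else parse_mutation_spec(m))
  n <- nchar(seq)
  pos <- vapply(muts, function(m) m$pos, integer(1))
  if (anyDuplicated(pos))
    stop("duplicate mutation positions: ",
         paste(unique(pos[duplicated(pos)]), collapse = ", "),
         call. = FALSE)
  idx <- pos - as.integer(offset) + 1L
  out_of_range <- idx < 1L | idx > n
  if (any(out_of_range))
    stop("mutation position(s) outside the numbered range ",
         offset, "-", offset + n - 1L, ": ",
         paste(pos[out_of_range], collapse = ", "), call. = FALSE)
  chars <- strsplit(seq, "")[[1]]
  for (k in seq_along(muts)) {
    m <- muts[[k]]
    found <- chars[idx[k]]
    if (found != m$wt)
      stop("wild-type mismatch at position ", m$pos, ": expected ", m$wt,
           ", found ", found, call. = FALSE)
    chars[idx[k]] <- m$mut
  }
  out <- paste(chars, collapse = "")
  attr(out, "offset") <- as.integer(offset)
  out
}
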