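# Sequence-composition solubility analytics. Helical miniproteins tend
# to be hydrophobic at the helix-helix interfaces; low hydrophobic and
# cysteine content is the standard proxy for soluble expression.

#' Default hydrophobic amino-acid set
#'
#' The set under which the packaged solubility rules are evaluated:
#' A, V, L, I, M, F, W, C. The set is always echoed in reports so that
#' fraction claims are tied to a stated definition.
#'
#' @return character vector of 1-letter codes
#' @export
default_hydrophobic_set <- function() {
  c("A", "V", "L", "I", "M", "F", "W", "C")
}

#' Amino-acid composition of a sequence
#'
#' @param seq 1-letter sequence (standard letters only).
#' @param hydrophobic_set amino acids counted as hydrophobic.
#' @return object of class `composition`: list with `length`, `counts`
#'   (named integer vector over the 20 amino acids),
#'   `hydrophobic_fraction`, `cys_fraction` (exact ratios),
#'   `hydrophobic_percent`, `cys_percent` (rounded half-up to 2
#'   decimals) and the echoed `hydrophobic_set`.
#' @export
composition <- function(seq, hydrophobic_set = default_hydrophobic_set()) {
  stopifnot(is.character(seq), length(seq) == 1L)
  chars <- strsplit(seq, "")[[1]]
  if (!length(chars)) stop("empty sequence", call. = FALSE)
  bad <- which(!chars %in% AA1)
  if (length(bad))
    stop("non-standard letter '", chars[bad[1]], "' at position ", bad[1],
         call. = FALSE)
  stopifnot(all(hydrophobic_set %in% AA1))
  counts <- vapply(AA1, function(a) sum(chars == a), integer(1))
  n <- length(chars)
  hf <- sum(counts[hydrophobic_set]) / n
  cf <- counts[["C"]] / n
  structure(list(length = n, counts = counts,
                 hydrophobic_fraction = hf, cys_fraction = cf,
                 hydrophobic_percent = round_half_up(100 * hf, 2),
                 cys_percent = round_half_up(100 * cf, 2),
                 hydrophobic_set = hydrophobic_set),
            class = "composition")
}

#' @export
print.composition <- function(x, ...) {
  cat(sprintf("<composition> %d residues | hydrophobic %.2f%% (set %s) | Cys %.2f%%\n",
              x$length, x$hydrophobic_percent,
              paste(x$hydrophobic_set, collapse = ""), x$cys_percent))
  invisible(x)
}

#' Composition-based solubility check
#'
#' Passes a sequence when its hydrophobic fraction and cysteine
#' fraction both fall within the limits (comparisons are `<=`).
#' Defaults correspond to the envelope observed over soluble designed
#' miniproteins: at most 60% hydrophobic residues and at most 4.35%
#' (3 of 69) cysteine.
#'
#' @param seq 1-letter sequence.
#' @param hydrophobic_max maximum hydrophobic fraction (default 0.60).
#' @param cys_max maximum cysteine fraction (default 0.0435).
#' @param hydrophobic_set amino acids counted as hydrophobic.
#' @return list with `pass`, `hydrophobic_ok`, `cys_ok`, the measured
#'   fractions, and the full `report` ([composition]).
#' @export
solubility_check <- function(seq, hydrophobic_max = 0.60,
                             cys_max = 0.0435,
                             hydrophobic_set = default_hydrophobic_set()) {
  rep <- composition(seq, hydrophobic_set)
  h_ok <- rep$hydrophobic_fraction <= hydrophobic_max
  c_ok <- rep$cys_fraction <= cys_max
  list(pass = h_ok && c_ok, hydrophobic_ok = h_ok, cys_ok = c_ok,
       hydrophobic_fraction = rep$hydrophobic_fraction,
       cys_fraction = rep$cys_fraction, report = rep)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA path
#' @return named character vector of sequences
#' @export
read_fasta_sequences <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' The 24 soluble candidate miniprotein sequences
#'
#' The packaged fixture of 24 miniprotein sequences (69 residues each)
#' that expressed in soluble form, keyed by their design serial numbers.
#' Fixture integrity is pinned by an MD5 checksum.
#'
#' @return data frame with columns `id` (character serial number) and
#'   `sequence`.
#' @export
load_miniprotein_fixture <- function() {
  path <- system.file("extdata", "miniproteins_24.fasta",
                      package = "solvscreen", mustWork = TRUE)
  md5 <- unname(tools::md5sum(path))
  expect <- "a53fc0741d66e4898004b931f7f3acad"
  if (!identical(md5, expect))
    stop("miniprotein fixture checksum mismatch (", md5, ")",
         call. = FALSE)
  seqs <- read_fasta_sequences(path)
  data.frame(id = names(seqs), sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Composition report for a set of sequences
#'
#' One row per sequence; convenient TSV-ready summary used by the
#' sequence-statistics entry point.
#'
#' @param seqs named character vector of sequences
#' @param hydrophobic_set amino acids counted as hydrophobic
#' @param hydrophobic_max,cys_max limits passed to [solubility_check()]
#' @return data frame with id, length, fractions, rule outcomes
#' @export
composition_table <- function(seqs,
                              hydrophobic_set = default_hydrophobic_set(),
                              hydrophobic_max = 0.60, cys_max = 0.0435) {
  ids <- names(seqs) %||% as.character(seq_along(seqs))
  rows <- lapply(seq_along(seqs), function(k) {
    chk <- solubility_check(seqs[[k]], hydrophobic_max, cys_max,
                            hydrophobic_set)
    data.frame(id = ids[k], length = chk$report$length,
               hydrophobic_fraction = chk$hydrophobic_fraction,
               hydrophobic_percent = chk$report$hydrophobic_percent,
               cys_fraction = chk$cys_fraction,
               cys_percent = chk$report$cys_percent,
               hydrophobic_ok = chk$hydrophobic_ok, cys_ok = chk$cys_ok,
               pass = chk$pass, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "hydrophobic_set") <- hydrophobic_set
  out
}
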