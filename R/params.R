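# Solvation parameter tables: per-atom-type triplets (S, Omax, V) plus
# the Gaussian envelope width sigma, the single portable artifact of the
# solvent-contact model.

#' Solvation parameter table
#'
#' Holds, for every atom type, the atomic solvation parameter `S`
#' (kcal/mol per cubic Angstrom), the maximum atomic occupancy `Omax`
#' (cubic Angstrom) and the atomic fragmental volume `V` (cubic
#' Angstrom), together with the Gaussian envelope width `sigma`
#' (Angstrom, default 3.5). `sigma` lives in the table, not per call,
#' so a fitted table travels as one artifact.
#'
#' @param types data frame with columns `type`, `S`, `Omax`, `V` (or a
#'   named list of 3-vectors).
#' @param sigma envelope width in Angstrom.
#' @return object of class `solvation_params`.
#' @export
solvation_params <- function(types, sigma = 3.5) {
  if (is.list(types) && !is.data.frame(types)) {
    types <- data.frame(
      type = names(types),
      S = vapply(types, function(v) as.numeric(v[["S"]]), numeric(1)),
      Omax = vapply(types, function(v) as.numeric(v[["Omax"]]), numeric(1)),
      V = vapply(types, function(v) as.numeric(v[["V"]]), numeric(1)),
      stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(types),
            all(c("type", "S", "Omax", "V") %in% names(types)))
  if (anyDuplicated(types$type)) stop("duplicate atom types", call. = FALSE)
  if (!all(is.finite(types$S) & is.finite(types$Omax) & is.finite(types$V)))
    stop("parameters must be finite", call. = FALSE)
  if (any(types$Omax <= 0) || any(types$V <= 0))
    stop("Omax and V must be strictly positive", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("sigma must be a single positive number", call. = FALSE)
  rownames(types) <- NULL
  structure(list(types = types[, c("type", "S", "Omax", "V")],
                 sigma = as.numeric(sigma)),
            class = "solvation_params")
}

#' @export
print.solvation_params <- function(x, ...) {
  cat("<solvation_params> sigma =", x$sigma, "A,",
      nrow(x$types), "atom types\n")
  print(x$types, row.names = FALSE)
  invisible(x)
}

# parameter vectors indexed by a structure's type column
param_lookup <- function(p, types_needed) {
  stopifnot(inherits(p, "solvation_params"))
  miss <- setdiff(unique(types_needed), p$types$type)
  if (length(miss))
    stop("parameter table lacks atom type(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  i <- match(types_needed, p$types$type)
  list(S = p$types$S[i], Omax = p$types$Omax[i], V = p$types$V[i])
}

#' Read a solvation parameter table from JSON
#'
#' Schema: `{"sigma": 3.5, "types": {"C.ali": {"S": ..., "Omax": ...,
#' "V": ...}, ...}}`.
#'
#' @param path JSON file path
#' @return a [solvation_params]
#' @export
read_solvation_params <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$types)) stop("no 'types' entry in ", path, call. = FALSE)
  types <- if (is.data.frame(j$types)) j$types else {
    data.frame(type = names(j$types),
               S = vapply(j$types, function(v) v$S, numeric(1)),
               Omax = vapply(j$types, function(v) v$Omax, numeric(1)),
               V = vapply(j$types, function(v) v$V, numeric(1)),
               stringsAsFactors = FALSE)
  }
  solvation_params(types, sigma = j$sigma %||% 3.5)
}

#' Write a solvation parameter table as JSON
#' @param p a [solvation_params]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_solvation_params <- function(p, path) {
  stopifnot(inherits(p, "solvation_params"))
  types <- lapply(seq_len(nrow(p$types)), function(i)
    list(S = p$types$S[i], Omax = p$types$Omax[i], V = p$types$V[i]))
  names(types) <- p$types$type
  jsonlite::write_json(list(sigma = p$sigma, types = types), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Packaged default solvation parameter table
#'
#' The reference parameter values behind this class of screen are not
#' printed anywhere reproducible, so the package ships a synthetic
#' reference table with chemically sensible signs and magnitudes
#' (favourable hydration for polar/charged types, mildly unfavourable
#' for apolar ones). It is the ground truth of the synthetic-data
#' generators and the provenance of every energy this package reports;
#' user tables in the same JSON schema drop in via
#' [read_solvation_params()].
#'
#' @return a [solvation_params]
#' @export
default_solvation_params <- function() {
  read_solvation_params(system.file("extdata",
    "solvation_params_synthetic.json", package = "solvscreen",
    mustWork = TRUE))
}
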