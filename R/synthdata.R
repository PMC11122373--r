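# Synthetic structure and candidate generators. These stand in for the
# Rosetta-designed coordinates such screens consume but rarely
# deposit: coarse but clash-free helical lattices with one sidechain
# pseudo-atom per residue, enough to exercise the hydration model,
# parameter fitting, and the screen end to end.

#' Helical lattice geometry
#'
#' Canonical alpha-helix values: 1.5 Angstrom rise and 100 degree twist
#' per residue, with the C-alpha trace on a 2.3 Angstrom radius.
#'
#' @param rise_per_residue rise along the helix axis, Angstrom.
#' @param twist_per_residue rotation per residue, degrees.
#' @param radius C-alpha helix radius, Angstrom.
#' @param bundle_spacing axis-to-axis distance between bundle helices,
#'   Angstrom.
#' @return object of class `helix_geometry`.
#' @export
helix_geometry <- function(rise_per_residue = 1.5, twist_per_residue = 100,
                           radius = 2.3, bundle_spacing = 10) {
  stopifnot(rise_per_residue > 0,
            twist_per_residue > 0, twist_per_residue < 180,
            radius > 0, bundle_spacing > 0)
  structure(list(rise = rise_per_residue, twist = twist_per_residue,
                 radius = radius, spacing = bundle_spacing),
            class = "helix_geometry")
}

# geometry used for extended dipeptide backbones
extended_geometry <- function() {
  helix_geometry(rise_per_residue = 3.2, twist_per_residue = 160,
                 radius = 2.3)
}

check_sequence <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  if (!length(chars)) stop("empty sequence", call. = FALSE)
  bad <- which(!chars %in% AA1)
  if (length(bad))
    stop("invalid amino-acid letter '", chars[bad[1]], "' at position ",
         bad[1], call. = FALSE)
  chars
}

.sc_pseudo_element <- c(A = "C", V = "C", L = "C", I = "C", P = "C",
                        F = "C", W = "C", Y = "C", M = "S", C = "S",
                        S = "O", T = "O", D = "O", E = "O", N = "O",
                        Q = "O", K = "N", R = "N", H = "N")

# Atoms of a whole chain on the helical lattice. Residue k sits at
# fractional lattice position t = k - 1; radial/angular offsets keep
# bonded pairs at roughly bonded distances and atoms of non-adjacent
# residues >= 2 Angstrom apart. The sidechain pseudo-atom SC sits 2
# Angstrom above CA along the axis (absent for glycine).
build_chain_atoms <- function(chars, g, start_resid = 1L) {
  omega <- g$twist * pi / 180
  scale <- g$radius / 2.3  # offsets scale with the CA radius
  n <- length(chars)
  t0 <- seq_len(n) - 1
  slot <- function(ord, name, element, r, dt, dz = 0) {
    a <- omega * (t0 + dt)
    data.frame(name = name, element = element,
               resname = unname(AA3[chars]),
               resid = start_resid + t0,
               x = r * cos(a), y = r * sin(a),
               z = g$rise * (t0 + dt) + dz,
               ord = ord, stringsAsFactors = FALSE)
  }
  parts <- list(
    slot(1L, "N", "N", 1.5 * scale, -0.30),
    slot(2L, "CA", "C", g$radius, 0),
    slot(3L, "C", "C", 1.7 * scale, +0.30),
    slot(4L, "O", "O", 2.93 * scale, +0.30),
    slot(5L, "SC", unname(.sc_pseudo_element[chars]), g$radius, 0,
         dz = 2.0))
  parts[[5]] <- parts[[5]][chars != "G", , drop = FALSE]
  a <- do.call(rbind, parts)
  a <- a[order(a$resid, a$ord), , drop = FALSE]
  a$ord <- NULL
  rownames(a) <- NULL
  a
}

#' Build an ideal single helix
#'
#' Places backbone N, CA, C, O and one sidechain pseudo-atom (`SC`,
#' absent for glycine) per residue on an ideal helical lattice.
#' Deterministic; residues numbered 1..length, chain A.
#'
#' @param seq 1-letter amino-acid sequence.
#' @param g a [helix_geometry].
#' @return a [protstruct].
#' @export
build_helix <- function(seq, g = helix_geometry()) {
  chars <- check_sequence(seq)
  a <- build_chain_atoms(chars, g)
  a$chain <- "A"
  a$serial <- seq_len(nrow(a))
  protstruct(a, title = paste0("synthetic helix ", seq))
}

#' Build a three-helix bundle
#'
#' Three ideal helices on an equilateral-triangle cross-section at
#' `bundle_spacing`, with the middle helix antiparallel (rotated 180
#' degrees about the x axis), merged into a single chain with
#' sequential numbering — a synthetic stand-in for the 69-residue
#' three-helix miniprotein fold.
#'
#' @param seqs character vector of exactly 3 sequences.
#' @param g a [helix_geometry].
#' @return a [protstruct].
#' @export
build_bundle <- function(seqs, g = helix_geometry()) {
  if (length(seqs) != 3L)
    stop("a bundle needs exactly 3 helix sequences", call. = FALSE)
  s <- g$spacing
  centers <- rbind(c(0, 0), c(s, 0), c(s / 2, s * sqrt(3) / 2))
  parts <- vector("list", 3L)
  next_resid <- 1L
  for (h in 1:3) {
    chars <- check_sequence(seqs[[h]])
    a <- build_chain_atoms(chars, g, start_resid = next_resid)
    next_resid <- next_resid + length(chars)
    if (h == 2L) {  # antiparallel: rotate 180 deg about x, re-anchor z
      zspan <- min(a$z) + max(a$z)
      a$y <- -a$y
      a$z <- zspan - a$z
    }
    a$x <- a$x + centers[h, 1]
    a$y <- a$y + centers[h, 2]
    parts[[h]] <- a
  }
  a <- do.call(rbind, parts)
  a$chain <- "A"
  a$serial <- seq_len(nrow(a))
  protstruct(a, title = "synthetic three-helix bundle")
}

#' Generate extended dipeptide structures
#'
#' Two-residue extended-backbone structures, the training substrate for
#' parameter fitting. Deterministic.
#'
#' @param pairs character vector of 2-letter sequences (e.g. `"AD"`).
#' @return named list of [protstruct].
#' @export
gen_dipeptides <- function(pairs) {
  stopifnot(all(nchar(pairs) == 2L))
  g <- extended_geometry()
  out <- lapply(pairs, function(pp) {
    st <- build_helix(pp, g)
    st$title <- paste0("synthetic dipeptide ", pp)
    st
  })
  names(out) <- pairs
  out
}

#' A dipeptide reference record
#' @param name two-letter name
#' @param structure a [protstruct]
#' @param dG_ref reference hydration free energy, kcal/mol
#' @return object of class `dipeptide_record`
#' @export
dipeptide_record <- function(name, structure, dG_ref) {
  stopifnot(inherits(structure, "protstruct"), n_atoms(structure) > 0,
            is.finite(dG_ref))
  structure(list(name = name, structure = structure,
                 dG_ref = as.numeric(dG_ref)),
            class = "dipeptide_record")
}

#' Synthetic-data specification
#'
#' @param n_candidates number of candidates for [gen_candidate_set()].
#' @param seed RNG seed; every generator is a pure function of its
#'   inputs and this seed.
#' @param score_mean,score_sd normal distribution of synthetic binding
#'   scores (Rosetta-like total-score scale, lower = better).
#' @param noise_sd Gaussian observation noise on reference hydration
#'   energies, kcal/mol.
#' @param true_params ground-truth [solvation_params] used to generate
#'   reference energies.
#' @return object of class `synth_spec`
#' @export
synth_spec <- function(n_candidates = 1000L, seed = 1L,
                       score_mean = -250, score_sd = 15,
                       noise_sd = 0,
                       true_params = default_solvation_params()) {
  stopifnot(n_candidates >= 0, score_sd >= 0, noise_sd >= 0,
            inherits(true_params, "solvation_params"))
  structure(list(n_candidates = as.integer(n_candidates),
                 seed = as.integer(seed), score_mean = score_mean,
                 score_sd = score_sd, noise_sd = noise_sd,
                 true_params = true_params),
            class = "synth_spec")
}

#' Generate reference hydration data with known ground truth
#'
#' For each structure, the reference energy is the solvent-contact
#' energy under `spec$true_params` plus seeded Gaussian noise of
#' standard deviation `spec$noise_sd`.
#'
#' @param structs list of [protstruct] (typed or not; types are
#'   assigned as needed).
#' @param spec a [synth_spec].
#' @return list of [dipeptide_record].
#' @export
gen_reference_hydration <- function(structs, spec = synth_spec()) {
  stopifnot(inherits(spec, "synth_spec"))
  nms <- names(structs) %||% paste0("rec", seq_along(structs))
  with_seed(spec$seed, {
    noise <- stats::rnorm(length(structs), 0, spec$noise_sd)
    lapply(seq_along(structs), function(k) {
      st <- structs[[k]]
      if (anyNA(st$atoms$type)) st <- assign_atom_types(st)
      tot <- hydration_energy(st, spec$true_params, mode = "oracle")$total
      dipeptide_record(nms[k], st, tot + noise[k])
    })
  })
}

# amino-acid sampling weights loosely following helical-design usage:
# helix formers and solubilizing charged/polar residues common, Gly/Pro
# and Cys rare
.design_aa_weights <- c(
  A = 9, R = 6, N = 4, D = 5, C = 0.5, Q = 5, E = 8, G = 1, H = 2,
  I = 5, L = 10, K = 7, M = 3, F = 3, P = 0.5, S = 5, T = 4, W = 1.5,
  Y = 2.5, V = 6)

#' Generate a synthetic candidate population
#'
#' Random 69-residue sequences with a helical-design-biased composition,
#' binding scores drawn from the spec's normal distribution, and
#' three-helix bundle structures (23+23+23 partition). Reproducible
#' given the seed.
#'
#' @param spec a [synth_spec].
#' @param build_structures build bundle structures (default `TRUE`;
#'   set `FALSE` when only sequences and scores are needed).
#' @return list with `candidates` (data frame: `id`, `sequence`,
#'   `binding_score`, `hydration` all `NA`) and `structures` (named
#'   list of [protstruct], or `NULL`).
#' @export
gen_candidate_set <- function(spec = synth_spec(), build_structures = TRUE) {
  stopifnot(inherits(spec, "synth_spec"))
  n <- spec$n_candidates
  if (n == 0L)
    return(list(candidates = data.frame(id = character(),
                sequence = character(), binding_score = numeric(),
                hydration = numeric(), stringsAsFactors = FALSE),
                structures = if (build_structures) list() else NULL))
  cands <- with_seed(spec$seed, {
    seqs <- vapply(seq_len(n), function(k)
      paste(sample(AA1, 69, replace = TRUE,
                   prob = .design_aa_weights[AA1]), collapse = ""),
      character(1))
    scores <- stats::rnorm(n, spec$score_mean, spec$score_sd)
    data.frame(id = sprintf("mp%04d", seq_len(n)), sequence = seqs,
               binding_score = scores, hydration = NA_real_,
               stringsAsFactors = FALSE)
  })
  structures <- NULL
  if (build_structures) {
    structures <- lapply(cands$sequence, function(sq)
      build_bundle(c(substr(sq, 1, 23), substr(sq, 24, 46),
                     substr(sq, 47, 69))))
    names(structures) <- cands$id
  }
  list(candidates = cands, structures = structures)
}

#' Write a candidate table as TSV
#' @param candidates candidate data frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_candidates <- function(candidates, path) {
  utils::write.table(candidates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a candidate table from TSV
#'
#' Expected columns: `id`, `sequence`, `binding_score`, optionally
#' `structure_path` and `hydration`.
#'
#' @param path TSV path
#' @return candidate data frame
#' @export
read_candidates <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "sequence", "binding_score")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("candidate table is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!"hydration" %in% names(d)) d$hydration <- NA_real_
  d
}
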