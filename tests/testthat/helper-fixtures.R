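# Fixtures built in code: tiny hand-placed structures with exact
# geometry, and canonical synthetic data sets.

make_atoms <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(serial = r[[1]], name = r[[2]], element = r[[3]],
               resname = r[[4]], resid = r[[5]], chain = r[[6]],
               x = r[[7]], y = r[[8]], z = r[[9]],
               stringsAsFactors = FALSE)))
}

# one alanine-like residue (N, CA, CB, C, O) at a given offset
ala_residue <- function(resid, chain = "A", serial0 = (resid - 1) * 5,
                        dx = 0, dy = 0, dz = 0) {
  make_atoms(
    list(serial0 + 1, "N", "N", "ALA", resid, chain, dx + 0.0, dy, dz),
    list(serial0 + 2, "CA", "C", "ALA", resid, chain, dx + 1.4, dy, dz),
    list(serial0 + 3, "CB", "C", "ALA", resid, chain, dx + 1.9, dy + 1.3, dz),
    list(serial0 + 4, "C", "C", "ALA", resid, chain, dx + 2.2, dy - 1.2, dz),
    list(serial0 + 5, "O", "O", "ALA", resid, chain, dx + 3.4, dy - 1.3, dz))
}

# a minimal single-atom PDB text
one_atom_pdb_lines <- function() {
  c("ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "END")
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# random heavy-atom cloud with valid types, for hydration stress tests
random_cloud <- function(n, box = 30, seed = 1) {
  solvscreen:::with_seed(seed, {
    types <- sample(c("C.ali", "C.aro", "C.car", "N.ami", "N.chg",
                      "O.car", "O.hyd", "O.chg", "S"), n, replace = TRUE)
    a <- data.frame(serial = seq_len(n), name = "CA",
                    element = substr(types, 1, 1), resname = "ALA",
                    resid = seq_len(n), chain = "A",
                    x = stats::runif(n, 0, box),
                    y = stats::runif(n, 0, box),
                    z = stats::runif(n, 0, box),
                    stringsAsFactors = FALSE)
    s <- protstruct(a, title = "random cloud")
    s$atoms$type <- types
    s
  })
}

# canonical dipeptide reference sets for the GA tests: neutral
# alphabetical tiling of the 400 ordered pairs
canonical_pairs <- function() sort(as.vector(outer(
  c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S",
    "T","V","W","Y"),
  c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S",
    "T","V","W","Y"), paste0)))

canonical_training_data <- function(n = 40, noise_sd = 0, seed = 11) {
  pairs <- canonical_pairs()[seq_len(n)]
  gen_reference_hydration(gen_dipeptides(pairs),
                          synth_spec(seed = seed, noise_sd = noise_sd))
}

canonical_heldout_data <- function(n = 20, seed = 12) {
  pairs <- canonical_pairs()[40 + seq_len(n)]
  gen_reference_hydration(gen_dipeptides(pairs),
                          synth_spec(seed = seed))
}
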