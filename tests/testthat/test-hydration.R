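simple_params <- function(S = -0.01, Omax = 100, V = 20, sigma = 3.5) {
  solvation_params(data.frame(
    type = c("C.ali", "C.aro", "C.car", "N.ami", "N.chg",
             "O.car", "O.hyd", "O.chg", "S"),
    S = S, Omax = Omax, V = V, stringsAsFactors = FALSE), sigma = sigma)
}

test_that("atom typing covers the 20 amino acids and flags gaps", {
  s <- assign_atom_types(build_helix(paste(solvscreen:::AA1, collapse = "")))
  expect_false(anyNA(s$atoms$type))

  ala <- protstruct(ala_residue(1))
  ala <- assign_atom_types(ala)
  expect_equal(ala$atoms$type[ala$atoms$name == "CB"], "C.ali")

  asp <- protstruct(make_atoms(
    list(1, "OD1", "O", "ASP", 1, "A", 0, 0, 0),
    list(2, "CA", "C", "ASP", 1, "A", 2, 0, 0)))
  expect_equal(assign_atom_types(asp)$atoms$type, c("O.chg", "C.ali"))

  weird <- protstruct(make_atoms(
    list(1, "XX9", "P", "ALA", 1, "A", 0, 0, 0)))
  expect_error(assign_atom_types(weird), "ALA:XX9")
})

test_that("hydrogens are typed by their nearest heavy atom", {
  s <- protstruct(make_atoms(
    list(1, "N", "N", "ALA", 1, "A", 0, 0, 0),
    list(2, "H", "H", "ALA", 1, "A", 0, 1.0, 0),
    list(3, "CB", "C", "ALA", 1, "A", 5, 0, 0),
    list(4, "HB1", "H", "ALA", 1, "A", 5, 1.1, 0)))
  ty <- assign_atom_types(s)$atoms$type
  expect_equal(ty[c(2, 4)], c("H.pol", "H.non"))
})

test_that("atomic occupancy matches its closed forms", {
  p <- simple_params(V = 20)
  one <- random_cloud(1)
  expect_equal(atomic_occupancy(one, 1, p), 0)

  two_at <- function(r) {
    a <- make_atoms(list(1, "CA", "C", "ALA", 1, "A", 0, 0, 0),
                    list(2, "CA", "C", "ALA", 2, "A", r, 0, 0))
    s <- protstruct(a); s$atoms$type <- "C.ali"; s
  }
  # envelope half-height at r = sigma * sqrt(2 ln 2)
  r_half <- 3.5 * sqrt(2 * log(2))
  expect_equal(atomic_occupancy(two_at(r_half), 1, p), 20 / 2,
               tolerance = 1e-12)
  # coincident neighbour contributes its full fragmental volume
  expect_equal(atomic_occupancy(two_at(0), 1, p), 20, tolerance = 1e-12)
  # generic distance: V * exp(-r^2 / (2 sigma^2))
  expect_equal(atomic_occupancy(two_at(4.2), 2, p),
               20 * exp(-4.2^2 / (2 * 3.5^2)), tolerance = 1e-12)
})

test_that("hydration energy honours its trivial identities", {
  p <- simple_params(S = -0.02, Omax = 120)
  iso <- random_cloud(1)
  h <- hydration_energy(iso, p, mode = "oracle")
  expect_equal(h$total, -0.02 * 120)            # F = Omax for a lone atom

  cloud <- random_cloud(80, seed = 4)
  h0 <- hydration_energy(cloud, simple_params(S = 0), mode = "oracle")
  expect_equal(h0$total, 0)

  h1 <- hydration_energy(cloud, p, mode = "oracle")
  expect_equal(h1$total, sum(h1$atoms$dG), tolerance = 1e-12)
  expect_true(all(h1$atoms$F >= 0 & h1$atoms$F <= 120))

  expect_error(hydration_energy(protstruct(ala_residue(1)[0, ]), p),
               "empty")
  untyped <- protstruct(ala_residue(1))
  expect_error(hydration_energy(untyped, p), "atom types")
})

test_that("clamping reports deeply buried atoms and can be disabled", {
  # Omax small enough that the central atom over-occupies
  p <- simple_params(S = -0.05, Omax = 25, V = 20)
  a <- rbind(make_atoms(list(1, "CA", "C", "ALA", 1, "A", 0, 0, 0)),
             make_atoms(list(2, "CA", "C", "ALA", 2, "A", 1, 0, 0)),
             make_atoms(list(3, "CA", "C", "ALA", 3, "A", 0, 1, 0)))
  s <- protstruct(a); s$atoms$type <- "C.ali"
  h <- hydration_energy(s, p, mode = "oracle")
  expect_gt(h$clamped_count, 0)
  expect_true(all(h$atoms$F >= 0))
  h2 <- hydration_energy(s, p, mode = "oracle", clamp = FALSE)
  expect_lt(min(h2$atoms$F), 0)
  expect_equal(h2$total, sum(h2$atoms$dG), tolerance = 1e-12)
})

test_that("fast mode matches the oracle within the truncation bound", {
  p <- default_solvation_params()
  for (seed in 1:3) {
    s <- random_cloud(200, box = 30, seed = seed)
    ho <- hydration_energy(s, p, mode = "oracle")
    hf <- hydration_energy(s, p, mode = "fast")
    # documented per-pair bound, summed over all ordered pairs
    vmax <- max(p$types$V); smax <- max(abs(p$types$S))
    n <- n_atoms(s)
    bound <- smax * n * (n - 1) * vmax * exp(-(6 * p$sigma)^2 / (2 * p$sigma^2))
    expect_lt(abs(hf$total - ho$total), max(bound, 1e-12))
    expect_lt(abs(hf$total - ho$total), 1e-6 * max(1, abs(ho$total)))
  }
})

test_that("total energy is invariant under rigid-body transforms", {
  p <- default_solvation_params()
  s <- assign_atom_types(build_bundle(c("ADKLEQSVMFWYCHRNTGIPVAD",
                                        "KLEQSVMFWYCHRNTGIPVADKL",
                                        "EQSVMFWYCHRNTGIPVADKLEQ")))
  base <- hydration_energy(s, p, mode = "oracle")$total
  solvscreen:::with_seed(9, {
    for (k in 1:4) {
      s2 <- transform_structure(s, random_rotation(), stats::rnorm(3, 0, 50))
      expect_equal(hydration_energy(s2, p, mode = "oracle")$total, base,
                   tolerance = 1e-9)
    }
  })
})

test_that("moving a neighbour closer increases occupancy and burial", {
  p <- simple_params()
  occ_at <- function(r) {
    a <- make_atoms(list(1, "CA", "C", "ALA", 1, "A", 0, 0, 0),
                    list(2, "CA", "C", "ALA", 2, "A", r, 0, 0))
    s <- protstruct(a); s$atoms$type <- "C.ali"
    hydration_energy(s, p, mode = "oracle", clamp = FALSE)
  }
  rs <- c(8, 6, 4, 2, 1)
  hs <- lapply(rs, occ_at)
  O <- vapply(hs, function(h) h$atoms$O[1], numeric(1))
  Fi <- vapply(hs, function(h) h$atoms$F[1], numeric(1))
  expect_true(all(diff(O) > 0))
  expect_true(all(diff(Fi) < 0))
})

test_that("well-separated monomers score like the sum of their parts", {
  p <- default_solvation_params()
  m1 <- assign_atom_types(build_helix("ADKLEQSVMF"))
  m2 <- assign_atom_types(build_helix("WYCHRNTGIP"))
  t1 <- hydration_energy(m1, p, mode = "oracle")$total
  t2 <- hydration_energy(m2, p, mode = "oracle")$total
  sep <- 10 * p$sigma
  shifted <- transform_structure(m2, diag(3), c(sep + 40, 0, 0))
  both <- protstruct(rbind(m1$atoms,
                           within(shifted$atoms, {
                             serial <- serial + n_atoms(m1)
                             resid <- resid + 100L
                           })), title = "dimer")
  both$atoms$type <- c(m1$atoms$type, shifted$atoms$type)
  tt <- hydration_energy(both, p, mode = "oracle")$total
  # pair bound: every cross term is at most V e^{-d^2/2s^2}
  nc <- n_atoms(m1) * n_atoms(m2) * 2
  bound <- max(abs(p$types$S)) * nc * max(p$types$V) *
    exp(-sep^2 / (2 * p$sigma^2))
  expect_lt(abs(tt - (t1 + t2)), max(bound, 1e-9))
})

test_that("hydration_profile is consistent with per-structure calls", {
  p <- default_solvation_params()
  cs <- gen_candidate_set(synth_spec(n_candidates = 4, seed = 21))
  out <- hydration_profile(cs$candidates, p, cs$structures)
  expect_equal(nrow(out), 4L)
  expect_true(all(is.finite(out$hydration)))
  singles <- vapply(cs$candidates$id, function(id)
    hydration_energy(assign_atom_types(cs$structures[[id]]), p)$total,
    numeric(1))
  expect_equal(out$hydration, unname(singles))

  empty <- hydration_profile(cs$candidates[0, ], p, cs$structures)
  expect_equal(nrow(empty), 0L)

  # failures are reported per candidate, never fatal
  bad <- cs$candidates
  res <- hydration_profile(bad, p, cs$structures[-2])
  expect_equal(sum(is.na(res$hydration)), 1L)
  errs <- attr(res, "errors")
  expect_equal(errs$id, cs$candidates$id[2])
})
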