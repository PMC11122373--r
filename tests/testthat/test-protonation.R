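# Constructed geometries: residues are placed far apart (>= 8 A) except
# for the single deliberate contact whose distance each case controls.

asp_stub <- function(resid, origin, od1_at, chain = "A") {
  make_atoms(
    list(resid * 10 + 1, "CA", "C", "ASP", resid, chain,
         origin[1], origin[2], origin[3]),
    list(resid * 10 + 2, "OD1", "O", "ASP", resid, chain,
         od1_at[1], od1_at[2], od1_at[3]),
    list(resid * 10 + 3, "OD2", "O", "ASP", resid, chain,
         od1_at[1] + 1.2, od1_at[2], od1_at[3]))
}

lys_stub <- function(resid, origin, nz_at, chain = "A") {
  make_atoms(
    list(resid * 10 + 1, "CA", "C", "LYS", resid, chain,
         origin[1], origin[2], origin[3]),
    list(resid * 10 + 2, "NZ", "N", "LYS", resid, chain,
         nz_at[1], nz_at[2], nz_at[3]))
}

his_stub <- function(resid, origin, nd1_at, ne2_at, chain = "A") {
  make_atoms(
    list(resid * 10 + 1, "CA", "C", "HIS", resid, chain,
         origin[1], origin[2], origin[3]),
    list(resid * 10 + 2, "ND1", "N", "HIS", resid, chain,
         nd1_at[1], nd1_at[2], nd1_at[3]),
    list(resid * 10 + 3, "NE2", "N", "HIS", resid, chain,
         ne2_at[1], ne2_at[2], ne2_at[3]))
}

# an alanine whose backbone O (acceptor) / N (donor) sits at a chosen spot
partner_stub <- function(resid, o_at, chain = "A") {
  make_atoms(
    list(resid * 10 + 1, "N", "N", "ALA", resid, chain,
         o_at[1], o_at[2] + 1.0, o_at[3]),
    list(resid * 10 + 2, "CA", "C", "ALA", resid, chain,
         o_at[1] + 1.4, o_at[2] + 1.0, o_at[3]),
    list(resid * 10 + 3, "O", "O", "ALA", resid, chain,
         o_at[1], o_at[2], o_at[3]))
}

test_that("hydrogen-bond group classification follows the chemistry table", {
  s <- protstruct(make_atoms(
    list(1, "N", "N", "ALA", 1, "A", 0, 0, 0),
    list(2, "CA", "C", "ALA", 1, "A", 1.4, 0, 0),
    list(3, "CB", "C", "ALA", 1, "A", 1.9, 1.3, 0),
    list(4, "O", "O", "ALA", 1, "A", 3.0, 0, 0),
    list(5, "N", "N", "PRO", 2, "A", 8, 0, 0),
    list(6, "OG", "O", "SER", 3, "A", 16, 0, 0),
    list(7, "NZ", "N", "LYS", 4, "A", 24, 0, 0),
    list(8, "OD1", "O", "ASP", 5, "A", 32, 0, 0)))
  roles <- classify_hb_groups(s)
  expect_equal(roles, c("donor", "none", "none", "acceptor", "none",
                        "both", "donor", "acceptor"))
})

test_that("unrecognized polar atoms warn and classify as none", {
  s <- protstruct(make_atoms(
    list(1, "OQ9", "O", "ALA", 1, "A", 0, 0, 0),
    list(2, "CA", "C", "ALA", 1, "A", 2, 0, 0)))
  expect_warning(roles <- classify_hb_groups(s), "OQ9")
  expect_equal(roles, c("none", "none"))
})

test_that("Asp goes neutral only with an acceptor inside the cutoff", {
  near <- protstruct(rbind(partner_stub(1, c(0, 0, 0)),
                           asp_stub(2, c(10, 10, 10), c(3, 0, 0))))
  pa <- assign_protonation(near)               # OD1 at 3.0 A from O
  asp <- pa[pa$resname == "ASP", ]
  expect_equal(asp$state, "ASP0")
  expect_equal(asp$partner_atom, "O")
  expect_equal(asp$distance, 3.0, tolerance = 1e-12)

  far <- protstruct(rbind(partner_stub(1, c(0, 0, 0)),
                          asp_stub(2, c(10, 10, 10), c(5, 0, 0))))
  expect_equal(assign_protonation(far)$state, "ASP-")
})

test_that("Lys stays protonated unless NZ meets a donor", {
  iso <- protstruct(lys_stub(1, c(0, 0, 0), c(2, 0, 0)))
  expect_equal(assign_protonation(iso)$state, "LYS+")

  # partner backbone N (donor) at 3.0 A from NZ
  s <- protstruct(rbind(partner_stub(1, c(0, -1, 0)),
                        lys_stub(2, c(10, 10, 10), c(3, 0, 0))))
  pa <- assign_protonation(s)
  expect_equal(pa[pa$resname == "LYS", "state"], "LYS0")
})

test_that("His tautomer logic follows the symmetric acceptor rule", {
  # ND1 near an acceptor, NE2 far -> ND1-H tautomer
  s1 <- protstruct(rbind(partner_stub(1, c(0, 0, 0)),
                         his_stub(2, c(10, 10, 10), c(3, 0, 0),
                                  c(10, 0, 0))))
  expect_equal(assign_protonation(s1)$state, "HIS-ND1H")

  # both ring nitrogens near acceptors -> doubly protonated
  s2 <- protstruct(rbind(partner_stub(1, c(0, 0, 0)),
                         partner_stub(3, c(20, 0, 0)),
                         his_stub(2, c(10, 10, 10), c(2.8, 0, 0),
                                  c(17.2, 0, 0))))
  expect_equal(assign_protonation(s2)$state, "HIS+")

  # nothing close -> default NE2-H tautomer
  s3 <- protstruct(his_stub(1, c(0, 0, 0), c(2, 0, 0), c(4, 0, 0)))
  expect_equal(assign_protonation(s3)$state, "HIS-NE2H")
})

test_that("missing sidechain atoms fall back to defaults with a warning", {
  s <- protstruct(make_atoms(
    list(1, "CA", "C", "ASP", 1, "A", 0, 0, 0),
    list(2, "CA", "C", "LYS", 2, "A", 8, 0, 0)))
  expect_warning(pa <- assign_protonation(s), "missing sidechain")
  expect_equal(pa$state, c("ASP-", "LYS+"))
  expect_true(all(is.na(pa$distance)))
})

test_that("assignments are invariant under rigid-body transforms", {
  s <- protstruct(rbind(partner_stub(1, c(0, 0, 0)),
                        asp_stub(2, c(10, 10, 10), c(3.2, 0, 0)),
                        lys_stub(3, c(-10, -10, 0), c(0, 0, 3.4))))
  base <- assign_protonation(s)
  solvscreen:::with_seed(7, {
    for (k in 1:5) {
      s2 <- transform_structure(s, random_rotation(), stats::rnorm(3, 0, 20))
      moved <- assign_protonation(s2)
      expect_equal(moved$state, base$state)
      expect_equal(moved$distance, base$distance, tolerance = 1e-9)
    }
  })
})

test_that("raising the cutoff only grows the neutral sets; zero cutoff is all-default", {
  # isolated partner/ionizable pairs in far-apart regions, contacts
  # staggered at 2.5, 3.5, 4.5 (Asp) and 3.0, 5.0 (Lys)
  s <- protstruct(rbind(
    partner_stub(1, c(0, 0, 0)),
    asp_stub(2, c(0, 8, 0), c(2.5, 0, 0)),
    partner_stub(3, c(30, 0, 0)),
    asp_stub(4, c(30, 8, 0), c(33.5, 0, 0)),
    partner_stub(5, c(60, 0, 0)),
    asp_stub(6, c(60, 8, 0), c(64.5, 0, 0)),
    partner_stub(7, c(0, 30, 0)),
    lys_stub(8, c(8, 30, 0), c(0, 34, 0)),      # NZ 3.0 from donor N
    partner_stub(9, c(0, 60, 0)),
    lys_stub(10, c(8, 60, 0), c(0, 66, 0))))    # NZ 5.0 from donor N
  neutral_ids <- function(cutoff) {
    pa <- assign_protonation(s, cutoff = cutoff)
    pa$resid[pa$state %in% c("ASP0", "GLU0", "LYS0")]
  }
  cuts <- c(0, 2.0, 2.6, 3.1, 3.6, 4.6, 5.1)
  sets <- lapply(cuts, neutral_ids)
  for (k in seq_along(sets)[-1])
    expect_true(all(sets[[k - 1]] %in% sets[[k]]))
  expect_length(sets[[1]], 0)            # cutoff 0: everything default
  expect_equal(sort(sets[[length(sets)]]), c(2L, 4L, 6L, 8L, 10L))
  # rationale distances never exceed the cutoff for non-default states
  pa <- assign_protonation(s, cutoff = 3.5)
  nd <- pa[pa$state %in% c("ASP0", "LYS0"), ]
  expect_true(nrow(nd) >= 2)
  expect_true(all(nd$distance <= 3.5))
})
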