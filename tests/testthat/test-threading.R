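test_that("threading the template's own sequence is the identity", {
  cx <- test_groove()
  th <- thread(cx, peptide_sequence(cx))
  expect_equal(rmsd_full_atom(th, cx, frame = "groove"), 0, tolerance = 1e-12)
  expect_identical(as.matrix(th[, c("x", "y", "z")]),
                   as.matrix(cx[, c("x", "y", "z")]))
})

test_that("threading rebuilds only changed side chains, never the groove", {
  cx <- test_groove()
  th <- thread(cx, "LLFGYPVYV")
  expect_identical(as.matrix(groove_atoms(th)[, c("x", "y", "z")]),
                   as.matrix(groove_atoms(cx)[, c("x", "y", "z")]))
  expect_equal(peptide_sequence(th), "LLFGYPVYV")
  # backbone coordinates identical to the template
  for (nm in c("N", "CA", "C", "O")) {
    expect_equal(peptide_coords(th, nm), peptide_coords(cx, nm),
                 tolerance = 1e-12)
  }
  # glycine position has no side-chain heavy atoms
  g <- peptide_atoms(th)
  expect_equal(sort(g$atom[g$resno == 4]), sort(c("N", "CA", "C", "O")))
})

test_that("rebuilt phenylalanine ring has ideal bond lengths", {
  cx <- test_groove()
  th <- thread(cx, "AAAAFAAAA")
  f <- peptide_atoms(th)
  f <- f[f$resno == 5, ]
  gx <- function(nm) unlist(f[f$atom == nm, c("x", "y", "z")])
  ring <- list(c("CG", "CD1"), c("CG", "CD2"), c("CD1", "CE1"),
               c("CD2", "CE2"), c("CE1", "CZ"), c("CE2", "CZ"))
  for (b in ring) {
    expect_equal(sqrt(sum((gx(b[1]) - gx(b[2]))^2)), 1.39, tolerance = 0.02,
                 label = paste(b, collapse = "-"))
  }
  expect_equal(sqrt(sum((gx("CA") - gx("CB"))^2)), 1.53, tolerance = 0.02)
})

test_that("thread rejects bad sequences", {
  cx <- test_groove()
  expect_error(thread(cx, "LLFGYPVY"), "9 residues")
  expect_error(thread(cx, "LLFGYPVYX"), "invalid letter")
})

test_that("refinement is seed-deterministic and tracks best energies", {
  cx <- test_groove()
  th <- thread(cx, "LLFGYPVYV")
  cfg <- refinement_config(cycles = 3, decoys = 2, keep_lowest = 1, seed = 9)
  e1 <- refine(th, cfg)
  e2 <- refine(th, cfg)
  expect_identical(tidy(e1)$total, tidy(e2)$total)
  expect_identical(as.matrix(e1$decoys[[1]]$complex[, c("x", "y", "z")]),
                   as.matrix(e2$decoys[[1]]$complex[, c("x", "y", "z")]))
  # different seeds generally explore differently
  e3 <- refine(th, refinement_config(cycles = 3, decoys = 2, keep_lowest = 1,
                                     seed = 10))
  expect_false(identical(tidy(e1)$total, tidy(e3)$total))
  # best-visited energy is non-increasing within every trajectory
  for (d in e1$decoys) {
    expect_true(all(diff(d$best_trace) <= 1e-9))
  }
})

test_that("refinement strictly lowers the energy of a clash-seeded model", {
  cx <- test_groove()
  th <- thread(cx, "WLFWYPVYW")   # bulky substitutions seed steric clashes
  before <- score_complex(th)$total
  ens <- refine(th, refinement_config(cycles = 4, decoys = 1, keep_lowest = 1,
                                      seed = 4))
  after <- ens$decoys[[1]]$breakdown$total
  expect_lt(after, before)
})

test_that("refinement keeps the peptide chain intact", {
  cx <- test_groove()
  th <- thread(cx, "LLFGYPVYV")
  ens <- refine(th, refinement_config(cycles = 3, decoys = 1, keep_lowest = 1,
                                      seed = 2))
  ref <- ens$decoys[[1]]$complex
  pep <- peptide_atoms(ref)
  for (i in 1:8) {
    c_i <- unlist(pep[pep$resno == i & pep$atom == "C", c("x", "y", "z")])
    n_j <- unlist(pep[pep$resno == i + 1 & pep$atom == "N", c("x", "y", "z")])
    expect_lt(abs(sqrt(sum((c_i - n_j)^2)) - 1.329), 0.101)
  }
  # groove backbone atoms never move
  gr <- groove_atoms(ref); g0 <- groove_atoms(cx)
  bb <- gr$atom %in% c("N", "CA", "C", "O")
  expect_identical(as.matrix(gr[bb, c("x", "y", "z")]),
                   as.matrix(g0[g0$atom %in% c("N", "CA", "C", "O"),
                                c("x", "y", "z")]))
})

test_that("consensus features average the lowest-energy decoys", {
  cx <- test_groove()
  th <- thread(cx, "LLFGYPVYV")
  ens <- refine(th, refinement_config(cycles = 2, decoys = 3, keep_lowest = 3,
                                      seed = 1))
  # hand-build the expected averages from the two lowest totals
  tot <- vapply(ens$decoys, function(d) d$breakdown$total, numeric(1))
  keep <- order(tot)[1:2]
  cons <- consensus_features(ens, keep_lowest = 2, n_points = 120)
  exp_un <- (ens$decoys[[keep[1]]]$breakdown$unweighted +
               ens$decoys[[keep[2]]]$breakdown$unweighted) / 2
  expect_equal(cons$energy$unweighted, exp_un, tolerance = 1e-12)
  exp_sasa <- (sasa(ens$decoys[[keep[1]]]$complex, n_points = 120)$peptide_total +
                 sasa(ens$decoys[[keep[2]]]$complex, n_points = 120)$peptide_total) / 2
  expect_equal(cons$sasa$peptide_total, exp_sasa, tolerance = 1e-12)

  # keep_lowest = 1 is exactly the minimum-energy decoy
  cons1 <- consensus_features(ens, keep_lowest = 1, n_points = 120)
  expect_equal(cons1$energy$total, min(tot), tolerance = 1e-12)
  expect_error(consensus_features(ens, keep_lowest = 5), "exceeds")
})
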