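test_that("the default registry carries 18 complex and 9 residue terms", {
  reg <- term_registry()
  expect_length(list_terms(reg, "complex"), 18)
  expect_length(list_terms(reg, "residue"), 9)
  expect_identical(list_terms(reg), list_terms(reg))  # stable ordering
  expect_false(anyDuplicated(list_terms(reg)) > 0)
  # per-residue terms are atomic-level only: no amino-acid-specific terms
  expect_false(any(c("yhh_planarity", "ref", "fa_dun", "p_aa_pp") %in%
                     list_terms(reg, "residue")))
})

# minimal two-atom system pushed straight through the pairwise kernel
pair_kernel <- function(r, element = "C", charge = c(0, 0)) {
  par <- structimm:::atom_param_table()
  i <- match(element, par$atom_type)
  xyz <- rbind(c(0, 0, 0), c(r, 0, 0))
  structimm:::score_pairwise_cpp(
    xyz, rep(par$well_depth[i], 2), rep(par$radius[i], 2),
    rep(par$solvation_dG[i], 2), rep(par$volume[i], 2),
    rep(par$sasa_radius[i], 2), charge,
    0:1, c(TRUE, FALSE), integer(0), integer(0),
    integer(0), integer(0), logical(0), integer(0), integer(0), logical(0),
    c(1L, 1L), c(1L, 2L), 2L)
}

test_that("pairwise terms vanish beyond the cutoff", {
  out <- pair_kernel(50)
  expect_true(all(abs(out$totals) < 1e-6))
})

test_that("the attractive branch equals -epsilon at the LJ optimum", {
  par <- structimm:::atom_param_table()
  i <- match("C", par$atom_type)
  out <- pair_kernel(2 * par$radius[i])
  expect_equal(unname(out$totals["fa_atr"]), -par$well_depth[i],
               tolerance = 1e-9)
  expect_equal(unname(out$totals["fa_rep"]), 0, tolerance = 1e-12)
})

test_that("a 1 A steric clash produces a dominating positive repulsion", {
  out <- pair_kernel(1)
  expect_gt(out$totals["fa_rep"], 100)
  expect_gt(out$totals["fa_rep"], sum(abs(out$totals[c("fa_atr", "fa_sol")])))
})

test_that("scoring is deterministic and invariant to rigid transforms", {
  cx <- test_groove()
  b1 <- score_complex(cx)
  b2 <- score_complex(cx)
  expect_identical(b1$unweighted, b2$unweighted)
  expect_identical(b1$total, b2$total)
  set.seed(3)
  moved <- transform_complex(cx, random_rotation(), rnorm(3, sd = 20))
  b3 <- score_complex(moved)
  expect_equal(b3$total, b1$total, tolerance = 1e-6 * abs(b1$total))
  expect_equal(b3$unweighted, b1$unweighted,
               tolerance = 1e-6 * max(abs(b1$unweighted)))
})

test_that("the weighted total is the weight-sum of unweighted terms", {
  cx <- test_groove()
  bd <- score_complex(cx)
  w <- bd$registry$complex_terms
  expect_equal(bd$total, sum(w * bd$unweighted[names(w)]),
               tolerance = 1e-9)
  td <- tidy(bd)
  expect_equal(sum(td$weighted), bd$total, tolerance = 1e-9)
})

test_that("per-residue decomposition conserves the pairwise terms", {
  cx <- test_groove()
  ctx <- structimm:::score_context(cx, term_registry())
  nb <- structimm:::nb_pairwise(ctx, as.matrix(cx[, c("x", "y", "z")]))
  shared <- c("fa_atr", "fa_rep", "fa_sol", "fa_elec",
              "hbond_sr_bb", "hbond_lr_bb", "hbond_bb_sc", "hbond_sc")
  cols <- match(shared, structimm:::RESIDUE_TERMS)
  sums <- colSums(nb$per_res)[cols]
  expect_equal(unname(sums), unname(nb$totals[shared]),
               tolerance = 1e-6 * max(1, abs(nb$totals[shared])))
})

test_that("peptide-only scoring attributes cross terms to the peptide", {
  cx <- test_groove()
  pb <- score_peptide_in_groove(cx)
  # conservation per term over the nine positions
  for (t in colnames(pb$per_residue)) {
    expect_equal(unname(sum(pb$per_residue[, t])), unname(pb$unweighted[t]),
                 tolerance = 1e-6 * max(1, abs(pb$unweighted[t])),
                 label = t)
  }
  # with the groove pushed 100 A away, peptide-only pairwise terms reduce
  # to intra-peptide interactions
  far <- cx
  g <- far$chain != "P"
  far$x[g] <- far$x[g] + 100
  pb_far <- score_peptide_in_groove(far)
  # groove at 100 A contributes nothing: every pairwise peptide term equals
  # the same term computed with the groove at 200 A
  far2 <- cx
  far2$x[g] <- far2$x[g] + 200
  expect_equal(pb_far$unweighted, score_peptide_in_groove(far2)$unweighted,
               tolerance = 1e-9)
})

test_that("scoring errors are informative", {
  cx <- test_groove()
  broken <- cx[!(cx$chain == "P" & cx$resno == 4 & cx$atom == "CA"), ]
  attr(broken, "peptide_chain") <- "P"
  expect_error(score_complex(broken), "backbone")
  expect_error(new_complex(cx[0, ], "P"), "empty")
})

test_that("externally computed term tables import as breakdowns", {
  f <- withr::local_tempfile(fileext = ".tsv")
  reg <- term_registry()
  writeLines(c("term\tvalue\tposition",
               "fa_atr\t-120.5\tNA",
               "fa_rep\t33.25\tNA",
               "fa_atr\t-2.5\t4"), f)
  bd <- read_breakdown_tsv(f, reg)
  expect_equal(unname(bd$unweighted["fa_atr"]), -120.5)
  expect_equal(unname(bd$unweighted["fa_rep"]), 33.25)
  expect_equal(unname(bd$per_residue["p4", "fa_atr"]), -2.5)
  expect_equal(bd$total,
               sum(reg$complex_terms * bd$unweighted[names(reg$complex_terms)]))
})
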