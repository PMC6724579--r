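toy_records <- function() {
  tibble::tibble(
    sequence = c("LLFGYPVYV", "GILGFVFTL", "NLVPMVATV",  # valid immunogenic
                 "AAGIGILTV", "SLYNTVATL",               # valid self
                 "KTWGQYWQV", "RMFPNAPYL",               # valid nonbinder x2
                 "LLFGYPVY", "GILGFVFT", "AAGIGILT",     # octamers
                 "ILKEPVHGV", "YLLPAIVHI"),              # immunogenic, low RF
    pool = c("immunogenic", "immunogenic", "immunogenic", "self", "self",
             "nonbinder", "nonbinder", "immunogenic", "self", "nonbinder",
             "immunogenic", "immunogenic"),
    allele = c(rep("HLA-A2", 5), "HLA-B*07:02", "HLA-A*03:01",
               "HLA-A*02:01", "HLA-A2", "HLA-B*07:02", "A*02:01", "A0201"),
    response_frequency = c(80, 120, 55, NA, NA, NA, NA, 90, NA, NA, 30, 30))
}

test_that("curation keeps exactly the valid records of the toy table", {
  ds <- curate(toy_records())
  expect_equal(nrow(ds), 7)   # 3 octamers and 2 low-RF immunogenic dropped
  expect_s3_class(ds, "labeled_dataset")
  rej <- attr(ds, "rejected")
  expect_equal(sum(rej$reason == "not a nonamer"), 3)
  expect_equal(sum(rej$reason == "response frequency below threshold"), 2)
})

test_that("labels follow the pool assignment exactly", {
  ds <- curate(toy_records())
  expect_true(all(ds$y[ds$pool == "immunogenic"] == 1))
  expect_true(all(ds$y[ds$pool != "immunogenic"] == 0))
  expect_equal(sum(ds$y), 3)
  # label marginal equals pool composition
  expect_equal(as.vector(table(ds$y)), as.vector(table(ds$pool == "immunogenic")))
})

test_that("curation is idempotent and handles empty input", {
  ds <- curate(toy_records())
  ds2 <- curate(ds)
  attr(ds, "rejected") <- NULL; attr(ds2, "rejected") <- NULL
  expect_equal(tibble::as_tibble(ds2), tibble::as_tibble(ds))
  e <- curate(toy_records()[0, ])
  expect_equal(nrow(e), 0)
})

test_that("alleles normalize through the alias table", {
  ds <- curate(toy_records())
  expect_true(all(ds$allele[ds$pool != "nonbinder"] == "HLA-A*02:01"))
  off <- tibble::tibble(sequence = "LLFGYPVYV", pool = "self",
                        allele = "HLA-B*07:02", response_frequency = NA)
  expect_equal(nrow(curate(off)), 0)
  expect_equal(attr(curate(off), "rejected")$reason, "allele mismatch")
})

test_that("cross-pool duplicates keep the immunogenic assignment", {
  recs <- tibble::tibble(
    sequence = c("LLFGYPVYV", "LLFGYPVYV", "AAGIGILTV"),
    pool = c("self", "immunogenic", "self"),
    allele = "HLA-A2",
    response_frequency = c(NA, 99, NA))
  ds <- curate(recs)
  expect_equal(nrow(ds), 2)
  expect_equal(ds$pool[ds$sequence == "LLFGYPVYV"], "immunogenic")
})

test_that("identical pools give zero differences and p near one", {
  pool <- c("LLFGYPVYV", "AAGIGILTV", "KTWGQYWQV", "NLVPMVATV", "SLYNTVATL")
  cmp <- positional_hydropathy_compare(pool, pool)
  expect_equal(cmp$mean_diff, rep(0, 9))
  expect_true(all(cmp$p > 0.99))
})

test_that("maximal separation is significant at every position", {
  a <- rep("LLLLLLLLL", 50)
  b <- rep("SSSSSSSSS", 50)
  cmp <- positional_hydropathy_compare(a, b)
  ww <- hydropathy_scale()
  expect_equal(cmp$mean_diff, rep(unname(ww["L"] - ww["S"]), 9))
  expect_true(all(cmp$mean_diff < 0))   # leucine pool more hydrophobic
  expect_true(all(cmp$p < 0.001))
})

test_that("means match hand averages and Welch p agrees with permutation", {
  a <- c("LLFGYPVYV", "GILGFVFTL", "NLVPMVATV", "YLEPGPVTA", "VLQELNVTV")
  b <- c("KTWGQYWQV", "RMFPNAPYL", "EEKLIVVLF", "DTDHYFLRY", "QQKEQRSRR")
  cmp <- positional_hydropathy_compare(a, b)
  ww <- hydropathy_scale()
  for (p in c(1, 5, 9)) {
    ha <- mean(ww[substr(a, p, p)])
    hb <- mean(ww[substr(b, p, p)])
    expect_equal(cmp$mean_diff[p], ha - hb, tolerance = 1e-12)
  }
  # antisymmetry in pool order
  rev <- positional_hydropathy_compare(b, a)
  expect_equal(rev$mean_diff, -cmp$mean_diff)
  # permutation p agrees with an exhaustive split enumeration at position 1
  perm <- positional_hydropathy_compare(a, b, test = "permutation",
                                        n_perm = 4000, seed = 3)
  va <- unname(ww[substr(a, 1, 1)]); vb <- unname(ww[substr(b, 1, 1)])
  pooled <- c(va, vb)
  obs <- abs(mean(va) - mean(vb))
  splits <- utils::combn(10, 5)
  exact <- mean(apply(splits, 2, function(ix) {
    abs(mean(pooled[ix]) - mean(pooled[-ix])) >= obs - 1e-12
  }))
  expect_equal(perm$p[1], exact, tolerance = 0.05)
  # Bonferroni column is the raw p capped at one
  expect_equal(cmp$p_bonferroni, pmin(1, cmp$p * 9))
})

test_that("mixed lengths and empty pools are rejected", {
  expect_error(positional_hydropathy_compare(character(0), "LLFGYPVYV"),
               "non-empty")
  expect_error(positional_hydropathy_compare("LLFGYPVYV", "LLFGYPVY"),
               "nonamer")
})

test_that("peptide tables read from TSV, CSV and FASTA", {
  recs <- toy_records()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(recs, tsv)
  expect_equal(nrow(read_peptide_table(tsv)), nrow(recs))
  csv <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(recs, csv)
  expect_equal(read_peptide_table(csv)$sequence, recs$sequence)
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">pep1", "LLFGYPVYV", ">pep2", "AAGIG", "ILTV"), fa)
  ft <- read_peptide_table(fa)
  expect_equal(ft$sequence, c("LLFGYPVYV", "AAGIGILTV"))
})
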