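fake_dataset <- function(n_self = 60, n_imm = 30, n_non = 10) {
  tibble::tibble(
    sequence = replicate(n_self + n_imm + n_non,
                         paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                      9, replace = TRUE), collapse = "")),
    pool = c(rep("self", n_self), rep("immunogenic", n_imm),
             rep("nonbinder", n_non)),
    y = c(rep(0L, n_self), rep(1L, n_imm), rep(0L, n_non)))
}

test_that("stratified folds spread each pool evenly and cover everything", {
  set.seed(1)
  ds <- fake_dataset(60, 30, 10)
  plan <- stratified_folds(ds, k = 5, seed = 2)
  expect_setequal(plan$index, seq_len(100))
  expect_equal(anyDuplicated(plan$index), 0)
  tab <- table(plan$pool, plan$fold)
  expect_true(all(tab["self", ] == 12))
  expect_true(all(tab["immunogenic", ] == 6))
  expect_true(all(tab["nonbinder", ] == 2))
  expect_identical(stratified_folds(ds, k = 5, seed = 2), plan)
  expect_false(identical(stratified_folds(ds, k = 5, seed = 3)$fold, plan$fold))
  expect_error(stratified_folds(fake_dataset(10, 3, 10), k = 5), "smaller")
})

test_that("oversampling balances classes using existing positives only", {
  set.seed(4)
  y <- c(rep(0L, 90), rep(1L, 10))
  idx <- seq_along(y)
  aug <- oversample_minority(idx, y, seed = 1)
  expect_equal(sum(y[aug] == 1), 90)
  expect_equal(sum(y[aug] == 0), 90)
  expect_true(all(setdiff(aug, idx) %in% idx[y == 1] |
                    table(aug)[as.character(idx[y == 1])] >= 1))
  expect_true(all(aug %in% idx))          # closure: only existing indices
  # training-only contract: an index outside the train set never appears
  train <- c(1:45, 91:95)
  aug2 <- oversample_minority(train, y, seed = 2)
  expect_true(all(aug2 %in% train))
  balanced <- c(rep(0L, 5), rep(1L, 5))
  expect_identical(oversample_minority(1:10, balanced), 1:10)
  expect_error(oversample_minority(1:90, y), "both classes")
})

test_that("AUC equals the exhaustive pairwise probability", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)

  scores <- c(0.9, 0.7, 0.7, 0.4, 0.3, 0.1)
  labels <- c(1, 1, 0, 0, 1, 0)
  pairs <- expand.grid(p = which(labels == 1), n = which(labels == 0))
  brute <- mean(ifelse(scores[pairs$p] > scores[pairs$n], 1,
                       ifelse(scores[pairs$p] == scores[pairs$n], 0.5, 0)))
  expect_equal(roc_auc(scores, labels), brute)

  set.seed(6)
  s <- round(runif(40), 2)  # rounded scores force ties
  l <- rbinom(40, 1, 0.5)
  pairs <- expand.grid(p = which(l == 1), n = which(l == 0))
  brute <- mean(ifelse(s[pairs$p] > s[pairs$n], 1,
                       ifelse(s[pairs$p] == s[pairs$n], 0.5, 0)))
  expect_equal(roc_auc(s, l), brute)
  expect_equal(roc_auc(s, l), as.numeric(suppressMessages(
    pROC::auc(l, s, direction = "<"))))
  # complement identity for tie-free scores
  s2 <- seq(0.01, 0.4, by = 0.01)
  expect_equal(roc_auc(s2, l) + roc_auc(-s2, l), 1)
  expect_error(roc_auc(s, rep(1, 40)), "both classes")
})

test_that("a single perfectly predictive feature is recovered by nested CV", {
  set.seed(2)
  ds <- fake_dataset(120, 40, 40)
  x <- tibble::tibble(signal = ds$y + rnorm(200, sd = 0.05),
                      noise1 = rnorm(200), noise2 = rnorm(200))
  rep <- nested_cv(ds, x, hidden_grid = 3, seed = 1, max_epochs = 100,
                   refit = FALSE)
  expect_gte(rep$cross_validated_auc, 0.98)
  expect_equal(nrow(rep$folds), 5)
  expect_equal(rep$chosen$n_hidden, 3)   # single-point grid chooses itself
})

test_that("no augmented training index leaks into validation or test folds", {
  ds <- fake_dataset(60, 30, 10)
  plan <- stratified_folds(ds, k = 5, seed = 7)
  fold_of <- integer(100); fold_of[plan$index] <- plan$fold
  for (f in 1:5) {
    val_f <- f %% 5 + 1
    tr <- which(!fold_of %in% c(f, val_f))
    aug <- oversample_minority(tr, ds$y, seed = f)
    expect_length(intersect(aug, which(fold_of %in% c(f, val_f))), 0)
  }
})

test_that("redundant terms are eliminated at the correlation stage", {
  set.seed(5)
  ds <- fake_dataset(60, 30, 10)
  base <- matrix(rnorm(500), 100, 5)
  x <- tibble::as_tibble(as.data.frame(base))
  names(x) <- c("fa_atr", "fa_rep", "fa_sol", "fa_elec", "ref")
  x$fa_dup <- x$fa_atr          # exact duplicate column
  x$fa_const <- 1               # constant column
  mask <- eliminate_redundant_terms(ds, x, backward = FALSE)
  expect_true("fa_atr" %in% mask$complex_terms)
  expect_false("fa_dup" %in% mask$complex_terms)   # duplicate dropped
  expect_false("fa_const" %in% mask$complex_terms) # constant dropped
  # independent features all survive the correlation stage
  expect_true(all(c("fa_rep", "fa_sol", "fa_elec", "ref") %in%
                    mask$complex_terms))
})

test_that("backward elimination drops pure-noise terms at positive tolerance", {
  set.seed(9)
  ds <- fake_dataset(60, 30, 10)
  x <- tibble::tibble(signal = ds$y + rnorm(100, sd = 0.05),
                      noise = rnorm(100))
  mask <- eliminate_redundant_terms(ds, x, tol = 0.02, seed = 2,
                                    max_epochs = 40, backward = TRUE)
  expect_true("signal" %in% mask$complex_terms)
  expect_false("noise" %in% mask$complex_terms)
})

test_that("per-residue terms are masked uniformly across positions", {
  set.seed(3)
  ds <- fake_dataset(30, 15, 5)
  cols <- list()
  for (p in 1:9) {
    cols[[paste0("p", p, "_fa_atr")]] <- rnorm(50)
    cols[[paste0("p", p, "_fa_dup")]] <- cols[[paste0("p", p, "_fa_atr")]]
  }
  x <- tibble::as_tibble(cols)
  mask <- eliminate_redundant_terms(ds, x, backward = FALSE)
  expect_identical(mask$residue_terms, "fa_atr")
})
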