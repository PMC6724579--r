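# Nested 5-fold cross-validation: pool-stratified splits, training-fold
# minority oversampling, rank-statistic ROC/AUC and grid selection over
# hidden sizes and input subsets.

#' Pool-stratified fold assignment
#'
#' Randomly partitions the dataset into `k` folds so that every pool
#' (nonbinder / self / immunogenic) is spread evenly: within each pool the
#' records are shuffled and dealt round-robin, so per-fold pool proportions
#' match the global ones up to rounding and fold sizes differ by at most
#' one per pool.  Deterministic given the seed.
#'
#' @param dataset a `labeled_dataset` (needs a `pool` column)
#' @param k number of folds
#' @param seed RNG seed
#' @return a `fold_plan` tibble: `index`, `pool`, `fold`
#' @export
stratified_folds <- function(dataset, k = 5, seed = 1) {
  pools <- split(seq_len(nrow(dataset)), dataset$pool)
  small <- names(pools)[vapply(pools, length, integer(1)) < k]
  if (length(small) > 0) {
    stop("stratified_folds: pool(s) smaller than k: ",
         paste(small, collapse = ", "))
  }
  set.seed(seed)
  out <- lapply(names(pools), function(p) {
    idx <- sample(pools[[p]])
    tibble::tibble(index = idx, pool = p,
                   fold = rep_len(seq_len(k), length(idx)))
  })
  plan <- dplyr::arrange(dplyr::bind_rows(out), .data$index)
  structure(plan, class = c("fold_plan", class(plan)), k = k, seed = seed)
}

#' Oversample the minority class in a training index set
#'
#' Positives are resampled with replacement until the class counts are
#' equal.  Applied to training folds only; validation and test folds are
#' never touched.
#'
#' @param train_indices integer indices of the training portion
#' @param labels full 0/1 label vector the indices point into
#' @param seed RNG seed
#' @return augmented index multiset (integer vector)
#' @export
oversample_minority <- function(train_indices, labels, seed = 1) {
  y <- labels[train_indices]
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("oversample_minority: both classes must be present")
  }
  if (n_pos == n_neg) return(train_indices)
  set.seed(seed)
  minority <- if (n_pos < n_neg) train_indices[y == 1] else train_indices[y == 0]
  extra <- sample(minority, abs(n_neg - n_pos), replace = TRUE)
  c(train_indices, extra)
}

#' Rank-statistic ROC AUC with ties counted one half
#'
#' Equals the probability that a random positive outscores a random
#' negative, with tied scores contributing 1/2 (exact pairwise
#' definition).
#'
#' @param scores numeric scores
#' @param labels 0/1 labels
#' @return AUC in `[0, 1]`
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("roc_auc: both classes required; got ", n1, " positives / ",
         n0, " negatives")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#' @inheritParams roc_auc
#' @return tibble of `fpr`, `tpr` steps (class `roc_points`)
#' @export
roc_points <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  y <- as.integer(labels)[ord]
  tpr <- cumsum(y) / sum(y)
  fpr <- cumsum(1 - y) / sum(1 - y)
  out <- tibble::tibble(fpr = c(0, fpr), tpr = c(0, tpr))
  class(out) <- c("roc_points", class(out))
  out
}

#' Nested k-fold cross-validation with architecture/input selection
#'
#' For each of the five fold rotations, one fold is the test set, the next
#' is the validation set (network stopping criterion) and the remaining
#' folds train the network after minority oversampling.  Every grid point
#' (hidden size x input subset) is trained on every rotation and scored by
#' test AUC; the configuration with the highest mean test AUC is selected
#' and optionally refit on the full dataset to report a total AUC.
#'
#' @param dataset a `labeled_dataset`
#' @param features numeric feature matrix/tibble, rows aligned with
#'   `dataset`
#' @param hidden_grid hidden-layer sizes to try
#' @param masks named list of column subsets (NULL entry = all columns)
#' @param k folds
#' @param seed seed controlling folds, oversampling and initialization
#' @param patience,max_epochs forwarded to [scg_train()]
#' @param refit refit the chosen configuration on all data and report the
#'   total (training) AUC, as a companion to the cross-validated AUC
#' @return a `cv_report`: per-fold grid results, summary, chosen
#'   configuration, optional final model and total AUC
#' @export
nested_cv <- function(dataset, features, hidden_grid = c(2, 3, 4, 6, 8, 10),
                      masks = list(all = NULL), k = 5, seed = 1,
                      patience = 6, max_epochs = 200, refit = TRUE) {
  x_all <- as.matrix(dplyr::select(tibble::as_tibble(features),
                                   dplyr::where(is.numeric)))
  y <- dataset$y
  stopifnot(nrow(x_all) == length(y))
  plan <- stratified_folds(dataset, k = k, seed = seed)
  fold_of <- integer(nrow(dataset))
  fold_of[plan$index] <- plan$fold

  grid <- tidyr::expand_grid(n_hidden = hidden_grid,
                             input_set = names(masks))
  rows <- list()
  for (g in seq_len(nrow(grid))) {
    cols <- masks[[grid$input_set[g]]]
    x <- if (is.null(cols)) x_all else x_all[, cols, drop = FALSE]
    for (f in seq_len(k)) {
      test_f <- f
      val_f <- f %% k + 1
      tr_idx <- which(!fold_of %in% c(test_f, val_f))
      va_idx <- which(fold_of == val_f)
      te_idx <- which(fold_of == test_f)
      tr_aug <- oversample_minority(tr_idx, y, seed = seed * 131 + f)
      net <- scg_train(x[tr_aug, , drop = FALSE], y[tr_aug],
                       x[va_idx, , drop = FALSE], y[va_idx],
                       n_hidden = grid$n_hidden[g],
                       patience = patience, max_epochs = max_epochs,
                       seed = seed * 977 + f * 13 + g)
      auc <- roc_auc(nn_forward(net, x[te_idx, , drop = FALSE]), y[te_idx])
      rows[[length(rows) + 1]] <- tibble::tibble(
        n_hidden = grid$n_hidden[g], input_set = grid$input_set[g],
        fold = f, test_auc = auc)
    }
  }
  folds_tbl <- dplyr::bind_rows(rows)
  summary_tbl <- folds_tbl |>
    dplyr::group_by(.data$n_hidden, .data$input_set) |>
    dplyr::summarise(mean_auc = mean(.data$test_auc), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_auc))
  chosen <- summary_tbl[1, ]

  final_model <- NULL; total_auc <- NA_real_
  if (refit) {
    cols <- masks[[chosen$input_set]]
    x <- if (is.null(cols)) x_all else x_all[, cols, drop = FALSE]
    set.seed(seed * 53 + 1)
    va_idx <- sample(seq_along(y), max(2, round(0.2 * length(y))))
    tr_idx <- setdiff(seq_along(y), va_idx)
    tr_aug <- oversample_minority(tr_idx, y, seed = seed * 53 + 2)
    final_model <- scg_train(x[tr_aug, , drop = FALSE], y[tr_aug],
                             x[va_idx, , drop = FALSE], y[va_idx],
                             n_hidden = chosen$n_hidden,
                             patience = patience, max_epochs = max_epochs,
                             seed = seed * 53 + 3)
    total_auc <- roc_auc(nn_forward(final_model, x), y)
  }
  structure(list(folds = folds_tbl, summary = summary_tbl, chosen = chosen,
                 cross_validated_auc = chosen$mean_auc,
                 total_auc = total_auc, final_model = final_model,
                 plan = plan, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<nested CV report> chosen:", x$chosen$n_hidden, "hidden /",
      x$chosen$input_set, "inputs | cross-validated AUC",
      format(x$cross_validated_auc, digits = 3))
  if (!is.na(x$total_auc)) cat(" | total AUC", format(x$total_auc, digits = 3))
  cat("\n")
  invisible(x)
}

#' @rdname tidy_structimm
#' @exportS3Method generics::tidy
tidy.cv_report <- function(x, ...) x$folds

#' @rdname tidy_structimm
#' @exportS3Method generics::glance
glance.cv_report <- function(x, ...) {
  tibble::tibble(n_hidden = x$chosen$n_hidden, input_set = x$chosen$input_set,
                 cross_validated_auc = x$cross_validated_auc,
                 total_auc = x$total_auc)
}

#' Eliminate redundant feature terms
#'
#' Two-stage, name-level elimination producing a [selection_mask()]:
#' constant terms are dropped first, then one member of every term pair
#' whose feature columns correlate above `cor_threshold` (per-residue terms
#' are compared position-wise and dropped uniformly across the nine
#' positions), then a single backward sweep drops any term whose removal
#' does not reduce the mean cross-validated AUC by more than `tol`.
#'
#' @param dataset a `labeled_dataset`
#' @param features candidate-layout feature tibble/matrix (columns named as
#'   in [build_candidate_vector()])
#' @param cor_threshold absolute-correlation threshold for the redundancy
#'   stage
#' @param tol AUC tolerance for the backward-elimination stage
#' @param seed seed for the internal cross-validation
#' @param hidden hidden size of the internal evaluator network
#' @param max_epochs epoch cap for the evaluator
#' @param backward run the (more expensive) backward sweep
#' @return a `selection_mask`
#' @export
eliminate_redundant_terms <- function(dataset, features, cor_threshold = 0.95,
                                      tol = 0.002, seed = 1, hidden = 3,
                                      max_epochs = 80, backward = TRUE) {
  x <- as.matrix(dplyr::select(tibble::as_tibble(features),
                               dplyr::where(is.numeric)))
  nms <- colnames(x)
  is_pos <- grepl("^p[1-9]_", nms)
  term_of <- ifelse(is_pos, sub("^p[1-9]_", "", nms), nms)
  complex_terms <- unique(term_of[!is_pos])
  residue_terms <- unique(term_of[is_pos])

  col_sd <- apply(x, 2, stats::sd)
  dropped <- character(0)
  # constant terms first
  for (t in complex_terms) {
    if (all(col_sd[!is_pos & term_of == t] == 0)) dropped <- c(dropped, t)
  }
  for (t in residue_terms) {
    if (all(col_sd[is_pos & term_of == t] == 0)) dropped <- c(dropped, t)
  }
  kept_c <- setdiff(complex_terms, dropped)
  kept_r <- setdiff(residue_terms, dropped)

  # correlation stage: later term in layout order is dropped
  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
    abs(stats::cor(a, b))
  }
  keep <- kept_c
  for (i in seq_along(kept_c)) {
    for (j in seq_len(i - 1)) {
      if (!(kept_c[i] %in% keep) || !(kept_c[j] %in% keep)) next
      if (safe_cor(x[, kept_c[i]], x[, kept_c[j]]) > cor_threshold) {
        keep <- setdiff(keep, kept_c[i])
      }
    }
  }
  kept_c <- keep
  keep <- kept_r
  for (i in seq_along(kept_r)) {
    for (j in seq_len(i - 1)) {
      if (!(kept_r[i] %in% keep) || !(kept_r[j] %in% keep)) next
      cors <- vapply(1:9, function(p) {
        safe_cor(x[, paste0("p", p, "_", kept_r[i])],
                 x[, paste0("p", p, "_", kept_r[j])])
      }, numeric(1))
      if (all(cors > cor_threshold)) keep <- setdiff(keep, kept_r[i])
    }
  }
  kept_r <- keep

  if (backward) {
    mask_cols <- function(kc, kr) {
      c(kc, unlist(lapply(1:9, function(p) {
        paste0("p", p, "_", kr, recycle0 = TRUE)
      })))
    }
    eval_auc <- function(kc, kr) {
      cols <- mask_cols(kc, kr)
      if (length(cols) == 0) return(0.5)
      rep <- nested_cv(dataset, x[, cols, drop = FALSE], hidden_grid = hidden,
                       seed = seed, max_epochs = max_epochs, refit = FALSE)
      rep$cross_validated_auc
    }
    base_auc <- eval_auc(kept_c, kept_r)
    for (t in rev(kept_c)) {
      if (length(kept_c) + length(kept_r) <= 1) break
      auc_wo <- eval_auc(setdiff(kept_c, t), kept_r)
      if (auc_wo >= base_auc - tol) {
        kept_c <- setdiff(kept_c, t); base_auc <- max(base_auc, auc_wo)
      }
    }
    for (t in rev(kept_r)) {
      if (length(kept_c) + length(kept_r) <= 1) break
      auc_wo <- eval_auc(kept_c, setdiff(kept_r, t))
      if (auc_wo >= base_auc - tol) {
        kept_r <- setdiff(kept_r, t); base_auc <- max(base_auc, auc_wo)
      }
    }
  }
  selection_mask(kept_c, kept_r)
}
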