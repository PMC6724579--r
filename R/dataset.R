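# Peptide pool ingestion, curation filters, binary labeling and the
# positional hydropathy comparison between pools.

HLA_A2_ALIASES <- c("HLA-A*02:01", "HLA-A2", "HLA-A*0201", "HLA-A02:01",
                    "A*02:01", "A*0201", "A2", "A0201")

normalize_allele <- function(x) {
  ifelse(toupper(trimws(x)) %in% toupper(HLA_A2_ALIASES), "HLA-A*02:01",
         trimws(x))
}

#' Curation rules for peptide records
#'
#' @param peptide_length required length (nonamers)
#' @param allele required presented allele for the self and immunogenic
#'   pools (the nonbinder pool is HLA-A2-incompatible by definition and is
#'   exempt from the allele filter)
#' @param min_response_frequency evidence threshold applied to the
#'   immunogenic pool only
#' @return list of rules for [curate()]
#' @export
curation_rules <- function(peptide_length = 9, allele = "HLA-A*02:01",
                           min_response_frequency = 50) {
  list(peptide_length = peptide_length, allele = allele,
       min_response_frequency = min_response_frequency)
}

#' Curate peptide records into a labeled dataset
#'
#' Keeps nonamers over the 20-letter alphabet; self and immunogenic records
#' must be HLA-A2-presented (allele aliases normalized), and immunogenic
#' records additionally need a response frequency at or above the
#' threshold.  Duplicates within a pool are collapsed; a sequence listed
#' both as immunogenic and in another pool keeps the immunogenic
#' assignment.  Labels: y = 1 for the immunogenic pool, 0 for self and
#' nonbinder.
#'
#' @param records tibble with columns `sequence`, `pool`
#'   (immunogenic/self/nonbinder) and optionally `allele`,
#'   `response_frequency`, `provenance`
#' @param rules a [curation_rules()] list
#' @return a `labeled_dataset` tibble with a binary `y` column; dropped
#'   records with reasons are attached as attribute `"rejected"`
#' @export
curate <- function(records, rules = curation_rules()) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) {
    out <- tibble::tibble(sequence = character(0), pool = character(0),
                          allele = character(0),
                          response_frequency = numeric(0),
                          provenance = character(0), y = integer(0))
    return(structure(out, class = c("labeled_dataset", class(out)),
                     rejected = tibble::tibble(sequence = character(0),
                                               reason = character(0))))
  }
  if (!"allele" %in% names(records)) records$allele <- rules$allele
  if (!"response_frequency" %in% names(records)) {
    records$response_frequency <- NA_real_
  }
  if (!"provenance" %in% names(records)) records$provenance <- ""
  records$sequence <- toupper(records$sequence)
  records$allele <- normalize_allele(records$allele)
  stopifnot(all(records$pool %in% c("immunogenic", "self", "nonbinder")))

  reason <- rep(NA_character_, nrow(records))
  ok_alpha <- vapply(strsplit(records$sequence, ""),
                     function(a) all(a %in% the_20_aa()), logical(1))
  reason[!ok_alpha] <- "invalid alphabet"
  ok_len <- nchar(records$sequence) == rules$peptide_length
  reason[is.na(reason) & !ok_len] <- "not a nonamer"
  need_allele <- records$pool %in% c("self", "immunogenic")
  ok_allele <- !need_allele | records$allele == normalize_allele(rules$allele)
  reason[is.na(reason) & !ok_allele] <- "allele mismatch"
  imm <- records$pool == "immunogenic"
  ok_rf <- !imm | (!is.na(records$response_frequency) &
                     records$response_frequency >= rules$min_response_frequency)
  reason[is.na(reason) & !ok_rf] <- "response frequency below threshold"

  kept <- records[is.na(reason), , drop = FALSE]
  rejected <- tibble::tibble(sequence = records$sequence[!is.na(reason)],
                             reason = reason[!is.na(reason)])
  # collapse within-pool duplicates
  kept <- kept[!duplicated(paste(kept$sequence, kept$pool)), , drop = FALSE]
  # cross-pool conflicts: immunogenic assignment wins
  imm_seqs <- kept$sequence[kept$pool == "immunogenic"]
  conflict <- kept$pool != "immunogenic" & kept$sequence %in% imm_seqs
  if (any(conflict)) {
    rejected <- dplyr::bind_rows(rejected, tibble::tibble(
      sequence = kept$sequence[conflict],
      reason = "conflicts with immunogenic listing"))
    kept <- kept[!conflict, , drop = FALSE]
  }
  kept$y <- as.integer(kept$pool == "immunogenic")
  out <- kept[, c("sequence", "pool", "allele", "response_frequency",
                  "provenance", "y")]
  structure(out, class = c("labeled_dataset", class(tibble::tibble())),
            rejected = rejected)
}

#' Read a peptide table (TSV/CSV) or unlabeled FASTA
#'
#' @param path input file; `.csv` is comma-separated, anything else
#'   tab-separated; `.fasta`/`.fa` yields unlabeled records
#' @return tibble of peptide records
#' @export
read_peptide_table <- function(path) {
  if (grepl("\\.(fasta|fa)$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    heads <- grepl("^>", lines)
    seqs <- split(lines[!heads], cumsum(heads)[!heads])
    return(tibble::tibble(
      sequence = unname(toupper(vapply(seqs, paste0, "", collapse = ""))),
      pool = NA_character_))
  }
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
}

#' Positional hydropathy comparison between two peptide pools
#'
#' For each position 1..9, the difference in mean Wimley-White interface
#' hydropathy (pool A minus pool B) and a two-sample significance test.
#' Negative differences indicate greater hydrophobicity in pool A (the
#' interface scale is negative for hydrophobic residues).  Raw p-values are
#' reported with a Bonferroni column across the nine positions.
#'
#' @param pool_a,pool_b character vectors of nonamers
#' @param test `"welch"` (default) or `"permutation"`
#' @param n_perm permutation count when `test = "permutation"`
#' @param seed permutation seed
#' @return tibble: `position`, `mean_diff`, `p`, `p_bonferroni`
#' @export
positional_hydropathy_compare <- function(pool_a, pool_b,
                                          test = c("welch", "permutation"),
                                          n_perm = 2000, seed = 1) {
  test <- match.arg(test)
  if (length(pool_a) == 0 || length(pool_b) == 0) {
    stop("positional_hydropathy_compare: both pools must be non-empty")
  }
  if (any(nchar(c(pool_a, pool_b)) != 9)) {
    stop("positional_hydropathy_compare: all sequences must be nonamers")
  }
  ww <- hydropathy_scale()
  ma <- t(vapply(strsplit(toupper(pool_a), ""), function(a) unname(ww[a]),
                 numeric(9)))
  mb <- t(vapply(strsplit(toupper(pool_b), ""), function(a) unname(ww[a]),
                 numeric(9)))
  res <- lapply(1:9, function(p) {
    a <- ma[, p]; b <- mb[, p]
    md <- mean(a) - mean(b)
    pv <- if (test == "welch") {
      if (stats::sd(a) == 0 && stats::sd(b) == 0) {
        if (md == 0) 1 else 0
      } else {
        stats::t.test(a, b)$p.value
      }
    } else {
      perm_p(a, b, n_perm, seed + p)
    }
    tibble::tibble(position = p, mean_diff = md, p = pv)
  })
  out <- dplyr::bind_rows(res)
  out$p_bonferroni <- pmin(1, out$p * 9)
  class(out) <- c("hydropathy_comparison", class(out))
  out
}

perm_p <- function(a, b, n_perm, seed) {
  set.seed(seed)
  obs <- abs(mean(a) - mean(b))
  pooled <- c(a, b)
  na <- length(a)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(length(pooled), na)
    if (abs(mean(pooled[idx]) - mean(pooled[-idx])) >= obs - 1e-12) {
      hits <- hits + 1L
    }
  }
  (hits + 1) / (n_perm + 1)
}
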