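# Pipeline entry points tying the modules together: sequence -> model ->
# features -> network -> scores, with plain-text artifacts and run
# manifests.  These functions are the package's command surface; the
# exec/structimm script is a thin dispatcher over them.

write_manifest <- function(out_dir, call_name, params) {
  manifest <- c(
    paste0("tool\tstructimm ", as.character(utils::packageVersion("structimm"))),
    paste0("command\t", call_name),
    paste0("timestamp\t", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    paste0(names(params), "\t", vapply(params, function(p)
      paste(format(p), collapse = ","), "")))
  writeLines(manifest, file.path(out_dir, "manifest.tsv"))
}

#' Model peptides and extract consensus structure features
#'
#' For each nonamer: thread onto the template, refine (unless `decoys = 0`,
#' which scores the threaded model directly), average the best trajectories
#' and assemble the candidate feature vector.  Peptides that fail (wrong
#' length, invalid letters) are skipped with a logged reason.
#'
#' @param sequences character vector of nonamers
#' @param template a `structimm_complex` groove template
#' @param config a [refinement_config()]; `decoys = 0` skips refinement
#' @param registry a [term_registry()]
#' @param mask optional [selection_mask()] applied to each vector
#' @param n_points SASA sampling density
#' @param verbose print per-peptide progress
#' @return tibble: `sequence` plus one column per feature; skipped
#'   peptides in attribute `"skipped"`
#' @export
model_features <- function(sequences, template,
                           config = refinement_config(),
                           registry = term_registry(), mask = NULL,
                           n_points = 240, verbose = FALSE) {
  rows <- list(); skipped <- list()
  for (s in sequences) {
    res <- tryCatch({
      if (verbose) message("modeling ", s)
      if (config$decoys == 0) {
        cx <- thread(template, s)
        bd <- score_complex(cx, registry)
        cons <- structure(list(
          energy = list(unweighted = bd$unweighted,
                        per_residue = bd$per_residue, total = bd$total),
          sasa = local({
            sr <- sasa(cx, n_points = n_points)
            list(per_residue = sr$per_residue,
                 peptide_total = sr$peptide_total,
                 peptide_hydrophobic = sr$peptide_hydrophobic)
          }),
          keep_lowest = 1, n_decoys = 0, registry = registry),
          class = "consensus_features")
        cons
      } else {
        cfg <- config
        cfg$seed <- decoy_seed(config$seed, match(s, sequences))
        ens <- refine(thread(template, s), cfg, registry)
        consensus_features(ens, keep_lowest = config$keep_lowest,
                           n_points = n_points)
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped[[s]] <- conditionMessage(res)
      next
    }
    v <- build_candidate_vector(res, registry)
    if (!is.null(mask)) v <- apply_mask(v, mask)
    rows[[s]] <- dplyr::bind_cols(tibble::tibble(sequence = s),
                                  tibble::as_tibble(as.list(unclass(v))))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "skipped") <- skipped
  out
}

#' Generate the synthetic template and peptide pools on disk
#'
#' @param out_dir output directory (created if needed)
#' @param groove a [groove_config()]
#' @param pools a [peptide_pool_config()]
#' @return paths of the written files, invisibly
#' @export
run_synth <- function(out_dir, groove = groove_config(),
                      pools = peptide_pool_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pdb <- file.path(out_dir, "groove_template.pdb")
  make_groove_fixture(groove, path = pdb)
  tsv <- file.path(out_dir, "peptides.tsv")
  readr::write_tsv(make_labeled_peptides(pools), tsv)
  write_manifest(out_dir, "synth",
                 list(seed = groove$seed, peptide = groove$peptide,
                      n_total = pools$n_total, pool_seed = pools$seed))
  invisible(c(template = pdb, peptides = tsv))
}

#' Model a peptide list against a template and write feature/decoy files
#'
#' @param peptides_path TSV/CSV/FASTA peptide list
#' @param template_path template PDB
#' @param out_dir output directory
#' @param config a [refinement_config()]
#' @param write_decoys also write per-peptide decoy PDBs and an ensemble
#'   manifest
#' @return the feature tibble, invisibly
#' @export
run_model <- function(peptides_path, template_path, out_dir,
                      config = refinement_config(), write_decoys = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  template <- read_pdb(template_path)
  peps <- read_peptide_table(peptides_path)
  feats <- model_features(peps$sequence, template, config = config)
  readr::write_tsv(feats, file.path(out_dir, "features.tsv"))
  skipped <- attr(feats, "skipped")
  if (length(skipped) > 0) {
    writeLines(paste0(names(skipped), "\t", unlist(skipped)),
               file.path(out_dir, "skipped.tsv"))
    message(length(skipped), " peptide(s) skipped; see skipped.tsv")
  }
  if (write_decoys && config$decoys > 0) {
    for (s in feats$sequence) {
      ddir <- file.path(out_dir, "decoys", s)
      dir.create(ddir, showWarnings = FALSE, recursive = TRUE)
      cfg <- config
      cfg$seed <- decoy_seed(config$seed, match(s, peps$sequence))
      ens <- refine(thread(template, s), cfg)
      man <- tidy(ens)
      man$selected <- rank(man$total, ties.method = "first") <=
        config$keep_lowest
      readr::write_tsv(man, file.path(ddir, "ensemble.tsv"))
      for (d in seq_along(ens$decoys)) {
        write_pdb(ens$decoys[[d]]$complex,
                  file.path(ddir, sprintf("decoy_%02d.pdb", d)))
      }
    }
  }
  write_manifest(out_dir, "model",
                 list(seed = config$seed, cycles = config$cycles,
                      decoys = config$decoys, template = template_path))
  invisible(feats)
}

#' Train and evaluate an immunogenicity network
#'
#' Curates the dataset, encodes it with the requested encoder (or takes a
#' precomputed structure-feature table), runs nested cross-validation and
#' writes the model, report and ROC points.
#'
#' @param dataset_path labeled peptide TSV/CSV
#' @param out_dir output directory
#' @param encoder `"structure"`, `"onehot"` or `"hydropathy"`
#' @param features_path structure-feature TSV (required for
#'   `encoder = "structure"`)
#' @param hidden_grid hidden sizes to try
#' @param seed global seed
#' @param max_epochs epoch cap per training
#' @return a list with the curated dataset, `cv_report` and final model
#' @export
run_train <- function(dataset_path, out_dir, encoder = "onehot",
                      features_path = NULL, hidden_grid = c(2, 3, 4, 6, 8, 10),
                      seed = 1, max_epochs = 200) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- curate(read_peptide_table(dataset_path))
  if (length(unique(ds$y)) < 2) {
    stop("run_train: dataset has a single class; AUC is undefined")
  }
  if (encoder == "structure") {
    if (is.null(features_path)) {
      stop("run_train: encoder 'structure' needs features_path")
    }
    ft <- readr::read_tsv(features_path, show_col_types = FALSE,
                          progress = FALSE)
    ds <- ds[ds$sequence %in% ft$sequence, , drop = FALSE]
    feats <- ft[match(ds$sequence, ft$sequence), , drop = FALSE]
  } else {
    feats <- encode_sequences(ds$sequence, encoder)
  }
  report <- nested_cv(ds, feats, hidden_grid = hidden_grid, seed = seed,
                      max_epochs = max_epochs)
  readr::write_tsv(report$folds, file.path(out_dir, "cv_folds.tsv"))
  readr::write_tsv(report$summary, file.path(out_dir, "cv_summary.tsv"))
  x <- as.matrix(dplyr::select(feats, dplyr::where(is.numeric)))
  rp <- roc_points(nn_forward(report$final_model, x), ds$y)
  readr::write_tsv(rp, file.path(out_dir, "roc.tsv"))
  write_network(report$final_model, file.path(out_dir, "model.json"))
  write_manifest(out_dir, "train",
                 list(seed = seed, encoder = encoder,
                      n = nrow(ds), chosen_hidden = report$chosen$n_hidden))
  list(dataset = ds, report = report, model = report$final_model)
}

#' Score peptides with a trained network
#'
#' @param model an `scg_net` or path to a serialized model file
#' @param peptides character vector of nonamers, or a tibble with
#'   `sequence` (and optionally `wildtype` for delta mode)
#' @param encoder `"onehot"` or `"hydropathy"`, or a function mapping
#'   sequences to a feature tibble (for structure features)
#' @param delta if the input has a `wildtype` column, also report
#'   score(mutant) - score(wildtype)
#' @return tibble of `sequence`, `score` (and `wildtype`, `delta`)
#' @export
run_predict <- function(model, peptides, encoder = "onehot", delta = TRUE) {
  if (is.character(model) && length(model) == 1 && file.exists(model)) {
    model <- read_network(model)
  }
  tab <- if (is.character(peptides)) tibble::tibble(sequence = peptides)
         else tibble::as_tibble(peptides)
  enc <- if (is.function(encoder)) encoder else
    function(s) encode_sequences(s, encoder)
  featurize <- function(seqs) {
    as.matrix(dplyr::select(enc(seqs), dplyr::where(is.numeric)))
  }
  out <- tibble::tibble(sequence = tab$sequence,
                        score = nn_forward(model, featurize(tab$sequence)))
  if (delta && "wildtype" %in% names(tab)) {
    out$wildtype <- tab$wildtype
    out$delta <- out$score - nn_forward(model, featurize(tab$wildtype))
  }
  out
}
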