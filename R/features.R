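# Network input vectors: the structure-derived candidate (117) and selected
# (81) layouts, and the two sequence-only baseline encodings.

ALPHABET <- function() sort(the_20_aa())

#' Build the candidate structure feature vector (length 117)
#'
#' Deterministic layout: the 18 whole-complex terms in registry order, then
#' for each peptide position p1..p9 the nine per-residue energy terms plus
#' total and hydrophobic SASA (11 values per position).
#'
#' @param consensus a [consensus_features()] result
#' @param registry a [term_registry()]; defaults to the registry the
#'   consensus was scored with
#' @return named numeric vector of class `structure_features`
#' @export
build_candidate_vector <- function(consensus, registry = NULL) {
  stopifnot(inherits(consensus, "consensus_features"))
  if (is.null(registry)) registry <- consensus$registry
  if (is.null(registry)) registry <- term_registry()
  cterms <- list_terms(registry, "complex")
  rterms <- list_terms(registry, "residue")
  un <- consensus$energy$unweighted
  if (!all(cterms %in% names(un))) {
    stop("build_candidate_vector: missing complex term(s): ",
         paste(setdiff(cterms, names(un)), collapse = ", "))
  }
  per <- consensus$energy$per_residue
  if (!all(rterms %in% colnames(per))) {
    stop("build_candidate_vector: missing per-residue term(s): ",
         paste(setdiff(rterms, colnames(per)), collapse = ", "))
  }
  sas <- consensus$sasa$per_residue
  vals <- unname(un[cterms])
  nms <- cterms
  for (p in 1:9) {
    vals <- c(vals, unname(per[p, rterms]),
              sas$total[sas$position == p], sas$hydrophobic[sas$position == p])
    nms <- c(nms, paste0("p", p, "_", rterms),
             paste0("p", p, "_sasa_total"), paste0("p", p, "_sasa_hydrophobic"))
  }
  structure(setNames(vals, nms), selected = FALSE,
            class = "structure_features")
}

#' Selection mask over the candidate layout
#'
#' A mask names the kept whole-complex terms and the kept per-residue terms
#' (applied uniformly to all nine positions).  The shipped default keeps all
#' 18 complex terms and 7 per-position terms (both SASA terms plus five
#' energy terms), giving the 81-input selected layout.
#'
#' @param complex_terms kept complex-term names
#' @param residue_terms kept per-residue term names (SASA terms are
#'   `"sasa_total"`, `"sasa_hydrophobic"`)
#' @return a `selection_mask`
#' @export
selection_mask <- function(complex_terms, residue_terms) {
  structure(list(complex_terms = complex_terms, residue_terms = residue_terms),
            class = "selection_mask")
}

#' @rdname selection_mask
#' @param registry a [term_registry()]
#' @export
default_selection_mask <- function(registry = term_registry()) {
  selection_mask(
    complex_terms = list_terms(registry, "complex"),
    residue_terms = c("fa_atr", "fa_rep", "fa_sol", "fa_elec", "hbond_sc",
                      "sasa_total", "sasa_hydrophobic"))
}

#' Apply a selection mask to a candidate feature vector
#'
#' @param vector a `structure_features` candidate vector
#' @param mask a [selection_mask()]
#' @return the masked `structure_features` vector (length 81 with the
#'   default mask)
#' @export
apply_mask <- function(vector, mask) {
  stopifnot(inherits(vector, "structure_features"),
            inherits(mask, "selection_mask"))
  nms <- names(vector)
  keep_complex <- mask$complex_terms
  keep_res <- unlist(lapply(1:9, function(p) {
    paste0("p", p, "_", mask$residue_terms, recycle0 = TRUE)
  }))
  wanted <- c(keep_complex, keep_res)
  missing <- setdiff(wanted, nms)
  if (length(missing) > 0) {
    stop("apply_mask: mask names absent from layout: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  keep <- nms[nms %in% wanted]
  structure(vector[keep], selected = TRUE, class = "structure_features")
}

#' One-hot (sparse sequence) encoding of a nonamer
#'
#' Flattened 20 x 9 indicator layout (position-major, amino acids in
#' alphabetical one-letter order): 180 values with exactly nine ones.
#'
#' @param sequence 9-letter peptide
#' @return named numeric vector of length 180
#' @export
one_hot_encode <- function(sequence) {
  aas <- check_nonamer(sequence)
  ab <- ALPHABET()
  v <- numeric(180)
  nms <- as.vector(vapply(1:9, function(p) paste0("p", p, "_", ab),
                          character(20)))
  for (p in 1:9) v[(p - 1) * 20 + match(aas[p], ab)] <- 1
  setNames(v, nms)
}

#' Wimley-White hydropathy encoding of a nonamer
#'
#' Position-wise lookup in the packaged interface hydropathy scale.
#'
#' @param sequence 9-letter peptide
#' @return named numeric vector of length 9
#' @export
hydropathy_encode <- function(sequence) {
  aas <- check_nonamer(sequence)
  ww <- hydropathy_scale()
  setNames(unname(ww[aas]), paste0("p", 1:9))
}

check_nonamer <- function(sequence) {
  aas <- strsplit(toupper(sequence), "")[[1]]
  if (length(aas) != 9) {
    stop("encoding error: expected a nonamer, got length ", length(aas))
  }
  if (!all(aas %in% the_20_aa())) {
    stop("encoding error: invalid letter(s): ",
         paste(unique(aas[!aas %in% the_20_aa()]), collapse = ", "))
  }
  aas
}

#' Encode many sequences as a feature tibble
#'
#' @param sequences character vector of nonamers
#' @param encoder `"onehot"` or `"hydropathy"`
#' @return tibble with `sequence` plus one column per feature
#' @export
encode_sequences <- function(sequences, encoder = c("onehot", "hydropathy")) {
  encoder <- match.arg(encoder)
  f <- if (encoder == "onehot") one_hot_encode else hydropathy_encode
  mat <- t(vapply(sequences, f, f(sequences[1])))
  dplyr::bind_cols(tibble::tibble(sequence = sequences),
                   tibble::as_tibble(mat))
}

#' Write / read feature matrices and masks as plain text
#'
#' @param features tibble from [encode_sequences()] or [model_features()]
#' @param path output file
#' @return `path` invisibly (`write_*`); a tibble or mask (`read_*`)
#' @export
write_features_tsv <- function(features, path) {
  readr::write_tsv(features, path)
  invisible(path)
}

#' @rdname write_features_tsv
#' @param mask a [selection_mask()]
#' @export
write_mask <- function(mask, path) {
  writeLines(c(paste0("complex\t", mask$complex_terms),
               paste0("residue\t", mask$residue_terms)), path)
  invisible(path)
}

#' @rdname write_features_tsv
#' @export
read_mask <- function(path) {
  lines <- strsplit(readLines(path), "\t")
  kind <- vapply(lines, `[`, "", 1)
  term <- vapply(lines, `[`, "", 2)
  selection_mask(term[kind == "complex"], term[kind == "residue"])
}
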