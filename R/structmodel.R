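# Data model for peptide/MHC structures.  A complex is a tibble of heavy
# atoms (one row per atom) carrying the designated peptide chain and a
# template provenance tag as attributes, so that every downstream module can
# use ordinary data-frame verbs on it.

#' Construct a peptide/MHC complex from an atom table
#'
#' @param atoms tibble/data.frame with columns `chain`, `resno`, `aa`
#'   (one-letter code), `atom`, `element`, `x`, `y`, `z` and optionally
#'   `occ`, `b`
#' @param peptide_chain chain identifier of the designated peptide
#' @param template_id free-text provenance tag
#' @param nonamer require the peptide chain to have exactly 9 residues
#' @return a `structimm_complex` tibble
#' @export
new_complex <- function(atoms, peptide_chain, template_id = "unknown",
                        nonamer = TRUE) {
  atoms <- tibble::as_tibble(atoms)
  if (!"occ" %in% names(atoms)) atoms$occ <- 1
  if (!"b" %in% names(atoms)) atoms$b <- 0
  atoms <- atoms[, c("chain", "resno", "aa", "atom", "element",
                     "x", "y", "z", "occ", "b")]
  atoms$resno <- as.integer(atoms$resno)
  cx <- structure(atoms,
                  class = c("structimm_complex", class(tibble::tibble())),
                  peptide_chain = peptide_chain,
                  template_id = template_id,
                  nonamer = nonamer)
  validate_complex(cx)
  cx
}

validate_complex <- function(cx) {
  if (nrow(cx) == 0) stop("complex: empty structure")
  if (!all(is.finite(cx$x) & is.finite(cx$y) & is.finite(cx$z))) {
    bad <- which(!(is.finite(cx$x) & is.finite(cx$y) & is.finite(cx$z)))[1]
    stop("complex: non-finite coordinates at atom record ", bad)
  }
  if (any(!cx$aa %in% the_20_aa())) {
    stop("complex: residue outside the 20-letter alphabet: ",
         paste(unique(cx$aa[!cx$aa %in% the_20_aa()]), collapse = ", "))
  }
  pc <- attr(cx, "peptide_chain")
  if (is.null(pc) || !pc %in% cx$chain) {
    stop("complex: no designated peptide chain present")
  }
  if (isTRUE(attr(cx, "nonamer"))) {
    # strict peptide/MHC mode: a groove chain and a 9-residue peptide
    if (!any(cx$chain != pc)) stop("complex: no groove chain present")
    npos <- length(unique(cx$resno[cx$chain == pc]))
    if (npos != 9L) {
      stop("complex: designated peptide has ", npos, " residues, expected 9")
    }
  }
  invisible(cx)
}

#' @export
print.structimm_complex <- function(x, ...) {
  pc <- attr(x, "peptide_chain")
  cat("<peptide/MHC complex> template:", attr(x, "template_id"),
      "| peptide chain", pc, ":", peptide_sequence(x),
      "|", nrow(x), "atoms in", length(unique(x$chain)), "chains\n")
  NextMethod()
}

peptide_atoms <- function(cx) {
  cx[cx$chain == attr(cx, "peptide_chain"), , drop = FALSE]
}

groove_atoms <- function(cx) {
  cx[cx$chain != attr(cx, "peptide_chain"), , drop = FALSE]
}

peptide_coords <- function(cx, atom_name = NULL) {
  p <- peptide_atoms(cx)
  if (!is.null(atom_name)) p <- p[p$atom %in% atom_name, , drop = FALSE]
  as.matrix(p[order(p$resno), c("x", "y", "z")])
}

groove_coords <- function(cx, atom_name = NULL) {
  g <- groove_atoms(cx)
  if (!is.null(atom_name)) g <- g[g$atom %in% atom_name, , drop = FALSE]
  as.matrix(g[, c("x", "y", "z")])
}

#' Peptide sequence of a complex
#' @param cx a `structimm_complex`
#' @return one-letter sequence string of the designated peptide, p1..p9
#' @export
peptide_sequence <- function(cx) {
  p <- peptide_atoms(cx)
  res <- p[!duplicated(p$resno), ]
  paste(res$aa[order(res$resno)], collapse = "")
}

#' Read a PDB file into a complex
#'
#' Parses ATOM records (via bio3d), drops HETATM/hydrogens, resolves
#' alternate locations to the highest-occupancy copy (ties to the first
#' occurrence) and renumbers the designated peptide chain 1..9 so that
#' positional features are indexed p1..p9 regardless of author numbering.
#'
#' @param path PDB file
#' @param peptide_chain chain id of the peptide; by default the chain with
#'   exactly nine residues (the shortest chain if none has nine)
#' @param template_id provenance tag stored on the complex
#' @param nonamer require a 9-residue peptide
#' @return a `structimm_complex`
#' @export
read_pdb <- function(path, peptide_chain = NULL, template_id = basename(path),
                     nonamer = TRUE) {
  if (!file.exists(path)) stop("read_pdb: file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE),
                  error = function(e) stop("read_pdb: parse error in ", path,
                                           ": ", conditionMessage(e)))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("read_pdb: no ATOM records in ", path)
  at$elety <- trimws(at$elety)
  # heavy atoms only; hydrogens are never used
  keep <- !grepl("^H|^[0-9]H", at$elety)
  at <- at[keep, , drop = FALSE]
  if (any(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z))) {
    bad <- which(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z))[1]
    stop("read_pdb: malformed coordinates at ATOM record ", bad, " of ", path)
  }
  # altloc: keep the highest-occupancy copy per (chain, residue, atom name)
  at$alt[is.na(at$alt)] <- ""
  key <- paste(at$chain, at$resno, at$elety)
  ord <- order(key, -replace(at$o, is.na(at$o), 1), seq_len(nrow(at)))
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$elety)), , drop = FALSE]
  at <- at[order(match(paste(at$chain, at$resno, at$elety), key)), , drop = FALSE]
  aa <- unname(AA1[at$resid])
  known <- !is.na(aa)
  if (any(!known)) at <- at[known, , drop = FALSE]
  aa <- aa[known]

  atoms <- tibble::tibble(
    chain = at$chain, resno = as.integer(at$resno), aa = aa,
    atom = at$elety, element = atom_element(at$elety),
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o), b = ifelse(is.na(at$b), 0, at$b))

  if (is.null(peptide_chain)) {
    sizes <- vapply(split(atoms$resno, atoms$chain),
                    function(r) length(unique(r)), integer(1))
    peptide_chain <- if (any(sizes == 9)) names(sizes)[sizes == 9][1]
                     else names(sizes)[which.min(sizes)]
  }
  # normalize peptide numbering to 1..9 preserving order of appearance
  pep <- atoms$chain == peptide_chain
  atoms$resno[pep] <- as.integer(factor(atoms$resno[pep],
                                        levels = unique(atoms$resno[pep])))
  new_complex(atoms, peptide_chain, template_id, nonamer = nonamer)
}

#' Write a complex as a PDB file
#'
#' Fixed-column ATOM records with three-decimal coordinates, a TER record
#' between chains and a terminating END.
#'
#' @param cx a `structimm_complex`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_pdb <- function(cx, path) {
  validate_complex(cx)
  lines <- character(0)
  serial <- 0L
  chains <- unique(cx$chain)
  for (ch in chains) {
    sub <- cx[cx$chain == ch, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      serial <- serial + 1L
      nm <- sub$atom[i]
      nm_fmt <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else nm
      lines <- c(lines, sprintf(
        "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, nm_fmt, AA3[sub$aa[i]], ch, sub$resno[i],
        sub$x[i], sub$y[i], sub$z[i], sub$occ[i], sub$b[i], sub$element[i]))
    }
    serial <- serial + 1L
    lines <- c(lines, sprintf("TER   %5d      %3s %1s%4d",
                              serial, AA3[sub$aa[nrow(sub)]], ch,
                              sub$resno[nrow(sub)]))
  }
  lines <- c(lines, "END")
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) stop("write_pdb: cannot write ", path,
                                          ": ", conditionMessage(e)))
  invisible(path)
}

#' Extract the peptide residues of a complex
#'
#' @param cx a `structimm_complex`
#' @return a 9-row tibble, one row per peptide position p1..p9, with columns
#'   `resno`, `aa`, `n_atoms` and a nested `atoms` list-column
#' @export
extract_peptide <- function(cx) {
  pc <- attr(cx, "peptide_chain")
  if (is.null(pc)) stop("extract_peptide: no designated peptide chain")
  p <- peptide_atoms(cx)
  p |>
    dplyr::group_by(.data$resno) |>
    tidyr::nest(atoms = !c("resno", "aa")) |>
    dplyr::ungroup() |>
    dplyr::mutate(n_atoms = vapply(atoms, nrow, integer(1))) |>
    dplyr::arrange(.data$resno) |>
    dplyr::select("resno", "aa", "n_atoms", "atoms")
}
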