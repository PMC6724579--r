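# Solvent-accessible surface area by deterministic golden-spiral sphere
# sampling.  Peptide aggregates are computed in the context of the whole
# complex, so the groove occludes the peptide.

#' Solvent-accessible surface area of a complex
#'
#' Per-atom accessible area is computed by testing a fixed golden-spiral
#' point layout on each atom's probe-expanded sphere against all neighbours
#' (Shrake-Rupley-style, but with a deterministic point set so results are
#' exactly reproducible).  Hydrophobic area is the area contributed by
#' carbon and sulfur atoms.
#'
#' @param cx a `structimm_complex`
#' @param probe_radius probe radius in Angstrom (water: 1.4)
#' @param n_points sphere sample points per atom; more points converge the
#'   estimate
#' @return a `sasa_result`: `per_atom` tibble (atom rows plus `area`),
#'   `per_residue` tibble for peptide positions (`position`, `total`,
#'   `hydrophobic`), and scalars `peptide_total`, `peptide_hydrophobic`
#'   (Angstrom squared)
#' @export
sasa <- function(cx, probe_radius = 1.4, n_points = 960) {
  if (nrow(cx) == 0) stop("sasa: empty structure")
  par <- atom_param_table()
  idx <- match(cx$element, par$atom_type)
  idx[is.na(idx)] <- match("C", par$atom_type)
  radii <- par$sasa_radius[idx]
  xyz <- as.matrix(cx[, c("x", "y", "z")])
  area <- sasa_cpp(xyz, radii, probe_radius, as.integer(n_points))
  per_atom <- dplyr::mutate(tibble::as_tibble(cx), area = area,
                            hydrophobic = .data$element %in% c("C", "S"))
  pep <- per_atom[per_atom$chain == attr(cx, "peptide_chain"), ]
  per_res <- pep |>
    dplyr::group_by(position = .data$resno) |>
    dplyr::summarise(total = sum(.data$area),
                     hydrophobic = sum(.data$area[.data$hydrophobic]),
                     .groups = "drop") |>
    dplyr::arrange(.data$position)
  out <- list(per_atom = per_atom, per_residue = per_res,
              peptide_total = sum(per_res$total),
              peptide_hydrophobic = sum(per_res$hydrophobic),
              probe_radius = probe_radius, n_points = n_points)
  class(out) <- "sasa_result"
  out
}

#' @export
print.sasa_result <- function(x, ...) {
  cat("<SASA> peptide total", format(x$peptide_total, digits = 5),
      "A^2 | hydrophobic", format(x$peptide_hydrophobic, digits = 5),
      "A^2 (probe", x$probe_radius, "A,", x$n_points, "points)\n")
  invisible(x)
}

#' Hydrophobic fraction of exposed peptide surface
#'
#' @param result a [sasa()] result
#' @return tibble with one row per peptide position plus an `"overall"`
#'   row: `position`, `fraction` (hydrophobic / total, 0 where total is 0)
#' @export
hydrophobic_fraction <- function(result) {
  stopifnot(inherits(result, "sasa_result"))
  pr <- result$per_residue
  frac <- ifelse(pr$total > 0, pr$hydrophobic / pr$total, 0)
  overall <- if (result$peptide_total > 0) {
    result$peptide_hydrophobic / result$peptide_total
  } else 0
  tibble::tibble(position = c(as.character(pr$position), "overall"),
                 fraction = c(frac, overall))
}

#' @rdname tidy_structimm
#' @exportS3Method generics::tidy
tidy.sasa_result <- function(x, ...) x$per_residue
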