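# Term-decomposed energy scoring.  The built-in desk backend mirrors the
# Talaris2014 term taxonomy with standard functional forms (12-6 split
# attraction/repulsion, gaussian-exclusion solvation, distance-dependent
# dielectric Coulomb, heavy-atom geometric hydrogen bonds, cosine-series
# torsion preferences, constant reference energies).  It is an approximate
# reimplementation of the taxonomy, not of any licensed parameter set.

PAIRWISE_TERMS <- c("fa_atr", "fa_rep", "fa_sol", "fa_intra_rep",
                    "fa_intra_sol", "fa_elec", "hbond_sr_bb", "hbond_lr_bb",
                    "hbond_bb_sc", "hbond_sc")
RESIDUE_TERMS <- c("fa_atr", "fa_rep", "fa_sol", "fa_intra_rep", "fa_elec",
                   "hbond_sr_bb", "hbond_lr_bb", "hbond_bb_sc", "hbond_sc")
TORSION_TERMS <- c("pro_close", "dslf_fa13", "rama", "omega", "fa_dun",
                   "p_aa_pp", "yhh_planarity", "ref")

#' Default energy term registry
#'
#' Eighteen whole-complex terms with weights following the published
#' Talaris2014 weight set (Alford et al.), plus nine per-residue
#' atomic-level terms (attraction, repulsion, solvation, intra-residue
#' repulsion, electrostatics and the four hydrogen-bond classes) chosen to
#' avoid amino-acid-specific terms.  Both lists are configurable.
#'
#' @param complex_terms named numeric vector of term weights (18 by default)
#' @param residue_terms character vector of per-residue term names (9)
#' @return a `term_registry` object
#' @export
#' @examples
#' length(list_terms(term_registry(), "complex"))
term_registry <- function(complex_terms = NULL, residue_terms = RESIDUE_TERMS) {
  if (is.null(complex_terms)) {
    complex_terms <- c(
      fa_atr = 1.0, fa_rep = 0.55, fa_sol = 0.9375, fa_intra_rep = 0.005,
      fa_intra_sol = 0.005, fa_elec = 0.875, pro_close = 1.25,
      hbond_sr_bb = 1.17, hbond_lr_bb = 1.17, hbond_bb_sc = 1.17,
      hbond_sc = 1.1, dslf_fa13 = 1.25, rama = 0.25, omega = 0.625,
      fa_dun = 0.7, p_aa_pp = 0.4, yhh_planarity = 0.625, ref = 1.0)
  }
  stopifnot(!is.null(names(complex_terms)),
            !anyDuplicated(names(complex_terms)),
            all(is.finite(complex_terms)),
            !anyDuplicated(residue_terms))
  reg <- list(complex_terms = complex_terms, residue_terms = residue_terms)
  class(reg) <- "term_registry"
  reg
}

#' List the registry terms in their stable feature-layout order
#' @param registry a [term_registry()]
#' @param which `"complex"` or `"residue"`
#' @return character vector of term names
#' @export
list_terms <- function(registry = term_registry(),
                       which = c("complex", "residue")) {
  which <- match.arg(which)
  if (which == "complex") names(registry$complex_terms) else registry$residue_terms
}

# ---- scoring context: per-atom parameter arrays, bonds, donors/acceptors --

compute_bonds <- function(cx) {
  n <- nrow(cx)
  xyz <- as.matrix(cx[, c("x", "y", "z")])
  bi <- integer(0); bj <- integer(0)
  # intra-residue bonds by distance on (well-formed) input geometry
  res_key <- paste(cx$chain, cx$resno)
  for (idx in split(seq_len(n), res_key)) {
    if (length(idx) < 2) next
    d <- as.matrix(stats::dist(xyz[idx, , drop = FALSE]))
    lim <- 1.95 + 0.25 * (outer(cx$element[idx] == "S", cx$element[idx] == "S", "|"))
    hit <- which(d > 0 & d < lim, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    bi <- c(bi, idx[hit[, 1]]); bj <- c(bj, idx[hit[, 2]])
  }
  # peptide bonds C(i)-N(i+1) within each chain
  for (ch in unique(cx$chain)) {
    sub <- which(cx$chain == ch)
    rn <- sort(unique(cx$resno[sub]))
    for (k in seq_len(length(rn) - 1)) {
      ci <- sub[cx$resno[sub] == rn[k] & cx$atom[sub] == "C"]
      ni <- sub[cx$resno[sub] == rn[k + 1] & cx$atom[sub] == "N"]
      if (length(ci) == 1 && length(ni) == 1) {
        dd <- sqrt(sum((xyz[ci, ] - xyz[ni, ])^2))
        if (dd < 1.8) { bi <- c(bi, ci); bj <- c(bj, ni) }
      }
    }
  }
  list(i = bi - 1L, j = bj - 1L)
}

# all unordered pairs within `depth` bonds of each other (0-based)
exclusion_pairs <- function(n, bonds, depth = 3) {
  adj <- vector("list", n)
  for (k in seq_along(bonds$i)) {
    i <- bonds$i[k] + 1L; j <- bonds$j[k] + 1L
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  ei <- integer(0); ej <- integer(0)
  for (a in seq_len(n)) {
    reach <- a
    cur <- a
    for (d in seq_len(depth)) {
      cur <- unique(unlist(adj[cur]))
      reach <- union(reach, cur)
    }
    reach <- reach[reach > a]
    ei <- c(ei, rep.int(a, length(reach))); ej <- c(ej, reach)
  }
  list(i = ei - 1L, j = ej - 1L)
}

score_context <- function(cx, registry = term_registry()) {
  validate_complex(cx)
  par <- atom_param_table()
  eidx <- match(cx$element, par$atom_type)
  if (anyNA(eidx)) {
    # unknown elements fall back to carbon defaults
    warning("score: unknown atom type(s) ",
            paste(unique(cx$element[is.na(eidx)]), collapse = ", "),
            "; using element-default (carbon) parameters")
    eidx[is.na(eidx)] <- match("C", par$atom_type)
  }
  res_key <- paste(cx$chain, cx$resno)
  res_levels <- unique(res_key)
  res_of <- match(res_key, res_levels)
  first <- !duplicated(res_key)
  res_chain <- match(cx$chain[first], unique(cx$chain))
  res_seq <- cx$resno[first]
  res_aa <- cx$aa[first]
  pep <- cx$chain == attr(cx, "peptide_chain")

  # donors/acceptors (0-based atom indices with their bonded base atoms)
  don <- integer(0); don_base <- integer(0); don_bb <- logical(0)
  acc <- integer(0); acc_base <- integer(0); acc_bb <- logical(0)
  find_atom <- function(ridx, name) which(res_of == ridx & cx$atom == name)
  for (r in seq_along(res_levels)) {
    aa <- res_aa[r]
    nN <- find_atom(r, "N"); nCA <- find_atom(r, "CA")
    nC <- find_atom(r, "C"); nO <- find_atom(r, "O")
    if (aa != "P" && length(nN) == 1 && length(nCA) == 1) {
      don <- c(don, nN); don_base <- c(don_base, nCA); don_bb <- c(don_bb, TRUE)
    }
    if (length(nO) == 1 && length(nC) == 1) {
      acc <- c(acc, nO); acc_base <- c(acc_base, nC); acc_bb <- c(acc_bb, TRUE)
    }
    dlist <- SC_DONORS[[aa]]
    for (nm in names(dlist)) {
      da <- find_atom(r, nm); ba <- find_atom(r, dlist[[nm]])
      if (length(da) == 1 && length(ba) == 1) {
        don <- c(don, da); don_base <- c(don_base, ba); don_bb <- c(don_bb, FALSE)
      }
    }
    alist <- SC_ACCEPTORS[[aa]]
    for (nm in names(alist)) {
      da <- find_atom(r, nm); ba <- find_atom(r, alist[[nm]])
      if (length(da) == 1 && length(ba) == 1) {
        acc <- c(acc, da); acc_base <- c(acc_base, ba); acc_bb <- c(acc_bb, FALSE)
      }
    }
  }
  bonds <- compute_bonds(cx)
  excl <- exclusion_pairs(nrow(cx), bonds)
  list(
    registry = registry,
    eps = par$well_depth[eidx], rmin2 = par$radius[eidx],
    dg = par$solvation_dG[eidx], vol = par$volume[eidx],
    lkr = par$sasa_radius[eidx],
    charge = atom_charge(cx$aa, cx$atom),
    res_of = res_of - 1L, pep_atom = pep,
    excl_i = excl$i, excl_j = excl$j,
    don = don - 1L, don_base = don_base - 1L, don_bb = don_bb,
    acc = acc - 1L, acc_base = acc_base - 1L, acc_bb = acc_bb,
    res_chain = res_chain, res_seq = res_seq, res_aa = res_aa,
    nres = length(res_levels),
    res_atoms = split(seq_len(nrow(cx)), res_of),
    atom_name = cx$atom,
    pep_res = sort(unique(res_of[pep])),
    ww = hydropathy_scale()
  )
}

nb_pairwise <- function(ctx, xyz) {
  score_pairwise_cpp(xyz, ctx$eps, ctx$rmin2, ctx$dg, ctx$vol, ctx$lkr,
                     ctx$charge, ctx$res_of, ctx$pep_atom,
                     ctx$excl_i, ctx$excl_j,
                     ctx$don, ctx$don_base, ctx$don_bb,
                     ctx$acc, ctx$acc_base, ctx$acc_bb,
                     ctx$res_chain, ctx$res_seq, ctx$nres)
}

nb_subset <- function(ctx, xyz, sel) {
  score_subset_cpp(xyz, ctx$eps, ctx$rmin2, ctx$dg, ctx$vol, ctx$lkr,
                   ctx$charge, ctx$res_of, ctx$pep_atom,
                   ctx$excl_i, ctx$excl_j,
                   ctx$don, ctx$don_base, ctx$don_bb,
                   ctx$acc, ctx$acc_base, ctx$acc_bb,
                   ctx$res_chain, ctx$res_seq, as.integer(sel) - 1L)
}

# ---- torsion / constant terms (R side; cheap, dihedral-only) -------------

res_atom_xyz <- function(ctx, xyz, ridx, name) {
  idx <- ctx$res_atoms[[ridx]]
  hit <- idx[ctx$atom_name[idx] == name]
  if (length(hit) != 1) return(NULL)
  xyz[hit, ]
}

chi_quads <- function(aa) {
  z <- SIDECHAIN_Z[[aa]]
  if (is.null(z)) return(NULL)
  z <- z[z$chi > 0 & !duplicated(z$chi), , drop = FALSE]
  z
}

# per-residue torsion-family energies for residues `rset`
torsion_residue_terms <- function(ctx, xyz, rset = seq_len(ctx$nres)) {
  out <- c(pro_close = 0, dslf_fa13 = 0, rama = 0, omega = 0, fa_dun = 0,
           p_aa_pp = 0, yhh_planarity = 0, ref = 0)
  same_chain_prev <- function(r) r > 1 && ctx$res_chain[r - 1] == ctx$res_chain[r] &&
    ctx$res_seq[r] - ctx$res_seq[r - 1] == 1L
  same_chain_next <- function(r) r < ctx$nres &&
    ctx$res_chain[r + 1] == ctx$res_chain[r] &&
    ctx$res_seq[r + 1] - ctx$res_seq[r] == 1L
  for (r in rset) {
    aa <- ctx$res_aa[r]
    out["ref"] <- out["ref"] + REF_ENERGY[[aa]]
    N <- res_atom_xyz(ctx, xyz, r, "N")
    CA <- res_atom_xyz(ctx, xyz, r, "CA")
    C <- res_atom_xyz(ctx, xyz, r, "C")
    if (is.null(N) || is.null(CA) || is.null(C)) {
      stop("score: missing backbone atoms in residue ", r, " (", aa, ")")
    }
    phi <- psi <- NA_real_
    if (same_chain_prev(r)) {
      Cp <- res_atom_xyz(ctx, xyz, r - 1, "C")
      if (!is.null(Cp)) phi <- dihedral_angle(Cp, N, CA, C)
    }
    if (same_chain_next(r)) {
      Nn <- res_atom_xyz(ctx, xyz, r + 1, "N")
      CAn <- res_atom_xyz(ctx, xyz, r + 1, "CA")
      if (!is.null(Nn)) psi <- dihedral_angle(N, CA, C, Nn)
      if (!is.null(Nn) && !is.null(CAn)) {
        om <- dihedral_angle(CA, C, Nn, CAn)
        out["omega"] <- out["omega"] + 0.5 * (1 - cos(2 * deg2rad(om - 180)))
      }
    }
    if (!is.na(phi) && !is.na(psi)) {
      # two smooth basins (helical and extended); knowledge-light
      out["rama"] <- out["rama"] -
        0.5 * exp(-((phi + 63)^2 + (psi + 43)^2) / (2 * 30^2)) -
        0.5 * exp(-((phi + 120)^2 + (psi - 130)^2) / (2 * 40^2))
      out["p_aa_pp"] <- out["p_aa_pp"] +
        (1 + 0.1 * ctx$ww[[aa]]) *
        (0.1 * cos(deg2rad(phi + 60)) + 0.1 * cos(deg2rad(psi - 40)))
    }
    cq <- chi_quads(aa)
    if (!is.null(cq) && nrow(cq) > 0) {
      env <- list(N = N, CA = CA, C = C)
      for (k in seq_len(nrow(cq))) {
        pa <- res_atom_xyz(ctx, xyz, r, cq$a[k])
        pb <- res_atom_xyz(ctx, xyz, r, cq$b[k])
        pc <- res_atom_xyz(ctx, xyz, r, cq$c[k])
        pd <- res_atom_xyz(ctx, xyz, r, cq$atom[k])
        if (is.null(pa) || is.null(pb) || is.null(pc) || is.null(pd)) next
        chi <- dihedral_angle(pa, pb, pc, pd)
        out["fa_dun"] <- out["fa_dun"] + 0.15 * (1 + cos(3 * deg2rad(chi)))
      }
    }
    if (aa == "P") {
      CD <- res_atom_xyz(ctx, xyz, r, "CD")
      if (!is.null(CD)) {
        d <- vnorm(CD - N)
        out["pro_close"] <- out["pro_close"] + 5 * (d - 1.474)^2
      }
    }
    # dslf_fa13 and yhh_planarity are registry placeholders (hydrogen-free
    # heavy-atom backend); they contribute zero
  }
  out
}

weighted_total <- function(unweighted, registry) {
  w <- registry$complex_terms
  sum(w * unweighted[names(w)])
}

full_score_total <- function(ctx, xyz) {
  nb <- nb_pairwise(ctx, xyz)
  tor <- torsion_residue_terms(ctx, xyz)
  un <- c(nb$totals, tor)
  weighted_total(un, ctx$registry)
}

# ---- public scoring ------------------------------------------------------

new_breakdown <- function(unweighted, per_residue, registry, scope) {
  total <- weighted_total(unweighted, registry)
  structure(list(unweighted = unweighted[names(registry$complex_terms)],
                 per_residue = per_residue, total = total,
                 registry = registry, scope = scope),
            class = "energy_breakdown")
}

#' Score a peptide/MHC complex with the desk energy backend
#'
#' Deterministically evaluates every registry term on the complex and
#' decomposes the atomic-level pairwise terms over the nine peptide
#' positions (each pairwise interaction contributing half to each
#' participating residue).  The weighted total is on a
#' Rosetta-energy-unit-like scale where lower is more favourable.
#'
#' @param cx a `structimm_complex`
#' @param registry a [term_registry()]
#' @return an `energy_breakdown`: `unweighted` named term values,
#'   `per_residue` 9 x 9 matrix (peptide positions x residue terms),
#'   `total` weighted sum
#' @export
score_complex <- function(cx, registry = term_registry()) {
  ctx <- score_context(cx, registry)
  xyz <- as.matrix(cx[, c("x", "y", "z")])
  nb <- nb_pairwise(ctx, xyz)
  tor <- torsion_residue_terms(ctx, xyz)
  un <- c(nb$totals, tor)
  per <- nb$per_res[ctx$pep_res, , drop = FALSE]
  colnames(per) <- RESIDUE_TERMS
  rownames(per) <- paste0("p", seq_len(nrow(per)))
  per <- per[, registry$residue_terms[registry$residue_terms %in% RESIDUE_TERMS],
             drop = FALSE]
  new_breakdown(un, per, registry, scope = "complex")
}

#' Score only the peptide, in the context of the groove
#'
#' Sums the terms with at least one peptide-atom participant: intra-peptide
#' interactions fully, and peptide-groove pair terms attributed fully to the
#' peptide.  Torsion and reference terms are restricted to peptide residues.
#' Positive totals are expected and meaningful (the peptide pays reference
#' and torsion penalties that the groove contacts only partly repay).
#'
#' @inheritParams score_complex
#' @return an `energy_breakdown` with scope `"peptide"`
#' @export
score_peptide_in_groove <- function(cx, registry = term_registry()) {
  ctx <- score_context(cx, registry)
  if (length(ctx$pep_res) == 0) stop("score: peptide chain is empty")
  xyz <- as.matrix(cx[, c("x", "y", "z")])
  nb <- nb_pairwise(ctx, xyz)
  tor <- torsion_residue_terms(ctx, xyz, rset = ctx$pep_res)
  un <- c(nb$pep_totals, tor)
  per <- nb$per_res_pep[ctx$pep_res, , drop = FALSE]
  colnames(per) <- RESIDUE_TERMS
  rownames(per) <- paste0("p", seq_len(nrow(per)))
  per <- per[, registry$residue_terms[registry$residue_terms %in% RESIDUE_TERMS],
             drop = FALSE]
  new_breakdown(un, per, registry, scope = "peptide")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat("<energy breakdown> scope:", x$scope,
      "| total:", format(x$total, digits = 6), "energy units\n")
  invisible(x)
}

#' @rdname tidy_structimm
#' @exportS3Method generics::tidy
tidy.energy_breakdown <- function(x, ...) {
  w <- x$registry$complex_terms
  tibble::tibble(term = names(w), unweighted = unname(x$unweighted[names(w)]),
                 weight = unname(w),
                 weighted = unname(w * x$unweighted[names(w)]))
}

#' Import externally computed unweighted term tables as a breakdown
#'
#' Backend contract hook: any scorer producing per-term (and optionally
#' per-position) values over the registry can stand in for the desk backend,
#' e.g. term tables exported from licensed modeling software.
#'
#' @param path TSV with columns `term`, `value` and optional `position`
#' @param registry a [term_registry()]
#' @return an `energy_breakdown`
#' @export
read_breakdown_tsv <- function(path, registry = term_registry()) {
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  stopifnot(all(c("term", "value") %in% names(tab)))
  glob <- tab[is.na(tab$position) | !("position" %in% names(tab)), ]
  if (!"position" %in% names(tab)) glob <- tab
  un <- setNames(rep(0, length(registry$complex_terms)),
                 names(registry$complex_terms))
  keep <- glob$term %in% names(un)
  un[glob$term[keep]] <- glob$value[keep]
  per <- matrix(0, 9, length(registry$residue_terms),
                dimnames = list(paste0("p", 1:9), registry$residue_terms))
  if ("position" %in% names(tab)) {
    pr <- tab[!is.na(tab$position), ]
    for (i in seq_len(nrow(pr))) {
      if (pr$term[i] %in% colnames(per) && pr$position[i] %in% 1:9) {
        per[pr$position[i], pr$term[i]] <- pr$value[i]
      }
    }
  }
  new_breakdown(un, per, registry, scope = "complex")
}
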