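# Threading a nonamer sequence onto a template groove, Metropolis
# simulated-annealing refinement of side chains and peptide backbone, and
# consensus feature extraction over the best decoys.

#' Refinement configuration
#'
#' Defaults follow the modeling protocol the package emulates: 50 annealing
#' sweeps, 10 independent decoys, features averaged over the 3
#' lowest-scoring trajectories.
#'
#' @param cycles annealing sweeps per decoy
#' @param decoys independent trajectories per peptide
#' @param keep_lowest decoys averaged by [consensus_features()]
#' @param seed base seed; each decoy derives its own stream
#' @param t_start,t_end reduced-temperature schedule endpoints (geometric
#'   cooling); defaults keep late-stage uphill acceptance rare
#' @param bb_rot_deg,bb_trans max backbone perturbation (degrees, Angstrom)
#' @param bb_moves_per_cycle backbone proposals per sweep
#' @param contact_cutoff groove residues with any atom within this distance
#'   of the peptide are repacked (Angstrom)
#' @return a `refinement_config` list
#' @export
refinement_config <- function(cycles = 50, decoys = 10, keep_lowest = 3,
                              seed = 1, t_start = 3, t_end = 0.3,
                              bb_rot_deg = 3, bb_trans = 0.15,
                              bb_moves_per_cycle = 3, contact_cutoff = 8) {
  stopifnot(cycles >= 1, decoys >= 1, keep_lowest >= 1, keep_lowest <= decoys,
            t_start > 0, t_end > 0)
  structure(list(cycles = as.integer(cycles), decoys = as.integer(decoys),
                 keep_lowest = as.integer(keep_lowest), seed = as.integer(seed),
                 t_start = t_start, t_end = t_end, bb_rot_deg = bb_rot_deg,
                 bb_trans = bb_trans,
                 bb_moves_per_cycle = as.integer(bb_moves_per_cycle),
                 contact_cutoff = contact_cutoff),
            class = "refinement_config")
}

#' Thread a nonamer sequence onto a template complex
#'
#' The peptide backbone keeps the template coordinates exactly; side chains
#' at changed positions are rebuilt from ideal internal geometry in a
#' default rotamer, unchanged positions keep the template side chains, and
#' groove chains are never touched.
#'
#' @param template a `structimm_complex` with a 9-residue peptide
#' @param sequence 9-letter peptide sequence
#' @return a threaded `structimm_complex`
#' @export
thread <- function(template, sequence) {
  validate_complex(template)
  aas <- strsplit(toupper(sequence), "")[[1]]
  if (length(aas) != 9) {
    stop("thread: sequence must have 9 residues, got ", length(aas))
  }
  if (!all(aas %in% the_20_aa())) {
    stop("thread: invalid letter(s): ",
         paste(unique(aas[!aas %in% the_20_aa()]), collapse = ", "))
  }
  pc <- attr(template, "peptide_chain")
  pieces <- list(groove_atoms(template))
  pep <- peptide_atoms(template)
  for (i in 1:9) pieces[[i + 1]] <- pep[pep$resno == i, , drop = FALSE]
  for (i in 1:9) {
    res <- pieces[[i + 1]]
    if (res$aa[1] == aas[i]) next
    bb <- res[res$atom %in% c("N", "CA", "C", "O", "OXT"), , drop = FALSE]
    if (!all(c("N", "CA", "C") %in% bb$atom)) {
      stop("thread: template peptide residue ", i, " lacks backbone atoms")
    }
    gx <- function(nm) unlist(bb[bb$atom == nm, c("x", "y", "z")],
                              use.names = FALSE)
    ctx <- as.matrix(dplyr::bind_rows(
      c(pieces[-(i + 1)],
        list(bb[bb$atom == "O", ])))[, c("x", "y", "z")])
    chis <- choose_default_chis(aas[i], gx("N"), gx("CA"), gx("C"), ctx)
    sc <- build_sidechain(aas[i], gx("N"), gx("CA"), gx("C"), chis)
    bb$aa <- aas[i]
    if (nrow(sc) > 0) {
      sc <- dplyr::mutate(sc, chain = pc, resno = i, aa = aas[i],
                          occ = 1, b = 0, .before = 1)
    }
    pieces[[i + 1]] <- dplyr::bind_rows(bb, sc)
  }
  atoms <- dplyr::bind_rows(pieces)
  new_complex(atoms, pc, template_id = attr(template, "template_id"),
              nonamer = TRUE)
}

decoy_seed <- function(base, d) (as.integer(base) * 1009L + d * 7919L) %% 2147483647L

#' Refine a threaded model by Metropolis simulated annealing
#'
#' Each decoy runs `cycles` annealing sweeps.  A sweep proposes a rotamer
#' swap for every peptide and groove-contact residue (coarse
#' gauche-/trans/gauche+ chi library with small jitter) and a handful of
#' small rigid backbone perturbations of interior peptide residues; a
#' backbone proposal that stretches a peptide-bond length by more than
#' 0.1 Angstrom is rejected as broken geometry.  Moves are accepted by the
#' Metropolis criterion at the scheduled temperature and the best-visited
#' conformation of each trajectory is recorded.  Fully deterministic given
#' the config seed.
#'
#' @param model a scoreable `structimm_complex`
#' @param config a [refinement_config()]
#' @param registry a [term_registry()]
#' @return a `decoy_ensemble`: list of decoys (complex, energy breakdown,
#'   trajectory seed, per-sweep best-energy trace)
#' @export
refine <- function(model, config = refinement_config(),
                   registry = term_registry()) {
  validate_complex(model)
  ctx <- score_context(model, registry)
  xyz0 <- as.matrix(model[, c("x", "y", "z")])
  w <- registry$complex_terms

  pep_res <- ctx$pep_res
  # groove residues with any atom near the peptide
  pep_xyz <- xyz0[ctx$pep_atom, , drop = FALSE]
  contact <- vapply(seq_len(ctx$nres), function(r) {
    if (r %in% pep_res) return(FALSE)
    idx <- ctx$res_atoms[[r]]
    m <- xyz0[idx, , drop = FALSE]
    any(apply(m, 1, function(p) {
      min(sqrt(rowSums(sweep(pep_xyz, 2, p)^2))) < config$contact_cutoff
    }))
  }, logical(1))
  movable <- c(pep_res, which(contact))
  movable <- movable[N_CHI[ctx$res_aa[movable]] > 0]

  sc_atoms <- lapply(seq_len(ctx$nres), function(r) {
    idx <- ctx$res_atoms[[r]]
    expected <- sidechain_atoms(ctx$res_aa[r])
    if (length(expected) == 0 || !all(expected %in% ctx$atom_name[idx])) {
      return(NULL)
    }
    idx[match(expected, ctx$atom_name[idx])]
  })
  movable <- movable[!vapply(sc_atoms[movable], is.null, logical(1))]
  bb_candidates <- pep_res[seq_along(pep_res) %in% 2:8]

  weighted_nb <- function(v) sum(w[names(v)] * v)
  weighted_tor <- function(ctx, xyz, rset) {
    v <- torsion_residue_terms(ctx, xyz, rset)
    sum(w[names(v)] * v)
  }

  run_trajectory <- function(seed_d) {
    set.seed(seed_d)
    xyz <- xyz0
    e_cur <- full_score_total(ctx, xyz)
    e_best <- e_cur
    best_xyz <- xyz
    trace <- numeric(config$cycles)
    n_cy <- config$cycles
    for (cy in seq_len(n_cy)) {
      tt <- if (n_cy == 1) config$t_end else
        config$t_start * (config$t_end / config$t_start)^((cy - 1) / (n_cy - 1))
      order_mv <- sample(movable)
      n_bb <- min(config$bb_moves_per_cycle, length(bb_candidates))
      bb_pick <- if (n_bb > 0) sample(bb_candidates, n_bb, replace = TRUE) else integer(0)
      moves <- c(as.list(order_mv),
                 lapply(bb_pick, function(r) structure(r, bb = TRUE)))
      for (mv in moves) {
        r <- as.integer(mv)
        is_bb <- isTRUE(attr(mv, "bb"))
        if (is_bb) {
          idx <- ctx$res_atoms[[r]]
          ca <- xyz[idx[ctx$atom_name[idx] == "CA"][1], ]
          ax <- vunit(rnorm(3))
          th <- deg2rad(runif(1, -config$bb_rot_deg, config$bb_rot_deg))
          K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                      3, 3, byrow = TRUE)
          rot <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
          tr <- runif(3, -config$bb_trans, config$bb_trans)
          new_pts <- t(rot %*% t(sweep(xyz[idx, , drop = FALSE], 2, ca))) +
            matrix(ca + tr, length(idx), 3, byrow = TRUE)
          # broken-geometry rejection: peptide bonds across the junctions
          ok <- TRUE
          for (nb in c(r - 1, r + 1)) {
            if (!(nb %in% pep_res)) next
            jdx <- ctx$res_atoms[[nb]]
            if (nb == r - 1) {
              a_old <- xyz[jdx[ctx$atom_name[jdx] == "C"][1], ]
              b_i <- which(ctx$atom_name[idx] == "N")[1]
            } else {
              a_old <- xyz[jdx[ctx$atom_name[jdx] == "N"][1], ]
              b_i <- which(ctx$atom_name[idx] == "C")[1]
            }
            d_new <- vnorm(a_old - new_pts[b_i, ])
            if (abs(d_new - BB_GEOM$c_n) > 0.1) { ok <- FALSE; break }
          }
          if (!ok) next
          sel <- idx
          rset <- intersect((r - 1):(r + 1), seq_len(ctx$nres))
        } else {
          aa <- ctx$res_aa[r]
          nc <- N_CHI[[aa]]
          chis <- sample(c(-60, 60, 180), nc, replace = TRUE) +
            runif(nc, -8, 8)
          idx <- ctx$res_atoms[[r]]
          gx <- function(nm) xyz[idx[ctx$atom_name[idx] == nm][1], ]
          sc <- build_sidechain_xyz(aa, gx("N"), gx("CA"), gx("C"), chis)
          sel <- sc_atoms[[r]]
          new_pts <- sc[match(ctx$atom_name[sel], rownames(sc)), , drop = FALSE]
          rset <- r
        }
        e_old <- weighted_nb(nb_subset(ctx, xyz, sel)) +
          weighted_tor(ctx, xyz, rset)
        xyz_new <- xyz
        xyz_new[sel, ] <- new_pts
        e_new <- weighted_nb(nb_subset(ctx, xyz_new, sel)) +
          weighted_tor(ctx, xyz_new, rset)
        de <- e_new - e_old
        if (de <= 0 || runif(1) < exp(-de / tt)) {
          xyz <- xyz_new
          e_cur <- e_cur + de
          if (e_cur < e_best) { e_best <- e_cur; best_xyz <- xyz }
        }
      }
      # periodic exact rescore kills incremental drift
      e_cur <- full_score_total(ctx, xyz)
      if (e_cur < e_best) { e_best <- e_cur; best_xyz <- xyz }
      trace[cy] <- e_best
    }
    list(best_xyz = best_xyz, trace = trace)
  }

  decoys <- vector("list", config$decoys)
  for (d in seq_len(config$decoys)) {
    sd <- decoy_seed(config$seed, d)
    tr <- run_trajectory(sd)
    cxd <- model
    cxd$x <- tr$best_xyz[, 1]; cxd$y <- tr$best_xyz[, 2]; cxd$z <- tr$best_xyz[, 3]
    decoys[[d]] <- list(complex = cxd,
                        breakdown = score_complex(cxd, registry),
                        seed = sd, best_trace = tr$trace)
  }
  structure(list(decoys = decoys,
                 template_id = attr(model, "template_id"),
                 config = config, registry = registry),
            class = "decoy_ensemble")
}

#' @export
print.decoy_ensemble <- function(x, ...) {
  tot <- vapply(x$decoys, function(d) d$breakdown$total, numeric(1))
  cat("<decoy ensemble>", length(x$decoys), "decoys from", x$template_id,
      "| totals:", paste(format(sort(tot), digits = 5), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname tidy_structimm
#' @exportS3Method generics::tidy
tidy.decoy_ensemble <- function(x, ...) {
  tibble::tibble(
    decoy = seq_along(x$decoys),
    seed = vapply(x$decoys, function(d) d$seed, numeric(1)),
    total = vapply(x$decoys, function(d) d$breakdown$total, numeric(1)))
}

#' Average energy and surface features over the best decoys
#'
#' Sorts the ensemble by weighted total, keeps the `keep_lowest` best
#' trajectories and arithmetic-averages their unweighted terms, per-residue
#' terms and SASA aggregates.  These averages are the network inputs.
#'
#' @param ensemble a [refine()] result
#' @param keep_lowest how many lowest-scoring decoys to average
#' @param probe_radius,n_points forwarded to [sasa()]
#' @return a `consensus_features` object with `energy` and `sasa` components
#' @export
consensus_features <- function(ensemble, keep_lowest = 3,
                               probe_radius = 1.4, n_points = 960) {
  stopifnot(inherits(ensemble, "decoy_ensemble"))
  nd <- length(ensemble$decoys)
  if (keep_lowest > nd) {
    stop("consensus_features: keep_lowest (", keep_lowest,
         ") exceeds ensemble size (", nd, ")")
  }
  tot <- vapply(ensemble$decoys, function(d) d$breakdown$total, numeric(1))
  keep <- order(tot)[seq_len(keep_lowest)]
  sel <- ensemble$decoys[keep]
  un <- Reduce(`+`, lapply(sel, function(d) d$breakdown$unweighted)) / keep_lowest
  per <- Reduce(`+`, lapply(sel, function(d) d$breakdown$per_residue)) / keep_lowest
  sas <- lapply(sel, function(d) sasa(d$complex, probe_radius, n_points))
  per_sas <- Reduce(`+`, lapply(sas, function(s) {
    as.matrix(s$per_residue[, c("total", "hydrophobic")])
  })) / keep_lowest
  structure(list(
    energy = list(unweighted = un, per_residue = per,
                  total = mean(vapply(sel, function(d) d$breakdown$total,
                                      numeric(1)))),
    sasa = list(per_residue = tibble::tibble(
                  position = sas[[1]]$per_residue$position,
                  total = per_sas[, "total"],
                  hydrophobic = per_sas[, "hydrophobic"]),
                peptide_total = mean(vapply(sas, function(s) s$peptide_total,
                                            numeric(1))),
                peptide_hydrophobic = mean(vapply(
                  sas, function(s) s$peptide_hydrophobic, numeric(1)))),
    keep_lowest = keep_lowest, n_decoys = nd,
    registry = ensemble$registry),
    class = "consensus_features")
}
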