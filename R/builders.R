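# Construction of residues and chains from ideal internal geometry.
# Backbone bond lengths/angles are standard peptide values; side chains are
# grown from the z-matrix templates in aa-tables.R.

BB_GEOM <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
                ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
                ang_ca_c_o = 120.8)

default_chis <- function(aa) {
  if (aa == "P") return(PRO_PUCKERS[[1]])
  nc <- N_CHI[[aa]]
  if (nc == 0) return(numeric(0))
  rep(180, nc)
}

# deterministic "default rotamer": the coarse gauche-/gauche+/trans combo
# (first two chis; distal chis trans) whose side-chain atoms stay farthest
# from the surrounding context atoms
cross_min_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * tcrossprod(a, b)
  sqrt(max(0, min(d2)))
}

choose_default_chis <- function(aa, N, CA, C, context_xyz = NULL) {
  nc <- N_CHI[[aa]]
  if (aa == "P") {
    combos <- PRO_PUCKERS
  } else if (nc == 0) {
    return(numeric(0))
  } else {
    grid1 <- c(180, -65, 65)
    combos <- if (nc == 1) as.list(grid1) else {
      eg <- expand.grid(chi2 = grid1, chi1 = grid1)
      lapply(seq_len(nrow(eg)),
             function(i) c(eg$chi1[i], eg$chi2[i], rep(180, 2))[seq_len(nc)])
    }
  }
  if (is.null(context_xyz) || nrow(context_xyz) == 0) return(combos[[1]])
  best <- NULL
  for (ch in combos) {
    pts <- build_sidechain_xyz(aa, N, CA, C, ch)
    pts <- pts[rownames(pts) != "CB", , drop = FALSE]
    if (nrow(pts) == 0) return(ch)
    dmin <- cross_min_dist(pts, context_xyz)
    if (is.null(best) || dmin > best$d + 1e-9) best <- list(chis = ch, d = dmin)
  }
  best$chis
}

# side-chain heavy-atom positions (matrix with atom-name rownames)
build_sidechain_xyz <- function(aa, N, CA, C, chis = default_chis(aa)) {
  if (aa == "G") return(matrix(numeric(0), 0, 3))
  rows <- rbind(CB_ROW, SIDECHAIN_Z[[aa]])
  pos <- list(N = N, CA = CA, C = C)
  m <- matrix(0, nrow(rows), 3, dimnames = list(rows$atom, NULL))
  for (k in seq_len(nrow(rows))) {
    dih <- if (rows$chi[k] > 0) chis[rows$chi[k]] + rows$off[k] else rows$off[k]
    p <- place_atom(pos[[rows$a[k]]], pos[[rows$b[k]]], pos[[rows$c[k]]],
                    rows$d[k], rows$ang[k], dih)
    pos[[rows$atom[k]]] <- p
    m[k, ] <- p
  }
  m
}

# side-chain heavy-atom coordinates for residue `aa` on a backbone frame
build_sidechain <- function(aa, N, CA, C, chis = default_chis(aa)) {
  m <- build_sidechain_xyz(aa, N, CA, C, chis)
  tibble::tibble(atom = rownames(m) %||% character(0),
                 element = atom_element(rownames(m) %||% character(0)),
                 x = m[, 1] %||% numeric(0), y = m[, 2] %||% numeric(0),
                 z = m[, 3] %||% numeric(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# full-atom chain with given per-residue phi/psi (degrees); omega fixed 180
build_chain <- function(sequence, phi, psi, chain_id = "A",
                        chis = NULL) {
  aas <- strsplit(sequence, "")[[1]]
  n <- length(aas)
  stopifnot(length(phi) == n, length(psi) == n,
            all(aas %in% the_20_aa()))
  g <- BB_GEOM
  Ns <- CAs <- Cs <- Os <- vector("list", n)
  Ns[[1]] <- c(0, 0, 0)
  CAs[[1]] <- c(g$n_ca, 0, 0)
  Cs[[1]] <- place_atom(c(0, 0, 1), Ns[[1]], CAs[[1]], g$ca_c, g$ang_n_ca_c, -60)
  for (i in seq_len(n)) {
    if (i > 1) {
      Ns[[i]] <- place_atom(Ns[[i - 1]], CAs[[i - 1]], Cs[[i - 1]],
                            g$c_n, g$ang_ca_c_n, psi[i - 1])
      CAs[[i]] <- place_atom(CAs[[i - 1]], Cs[[i - 1]], Ns[[i]],
                             g$n_ca, g$ang_c_n_ca, 180)
      Cs[[i]] <- place_atom(Cs[[i - 1]], Ns[[i]], CAs[[i]],
                            g$ca_c, g$ang_n_ca_c, phi[i])
    }
    Os[[i]] <- place_atom(Ns[[i]], CAs[[i]], Cs[[i]], g$c_o, g$ang_ca_c_o,
                          psi[i] + 180)
  }
  res <- vector("list", n)
  for (i in seq_len(n)) {
    res[[i]] <- tibble::tibble(
      atom = c("N", "CA", "C", "O"), element = c("N", "C", "C", "O"),
      x = c(Ns[[i]][1], CAs[[i]][1], Cs[[i]][1], Os[[i]][1]),
      y = c(Ns[[i]][2], CAs[[i]][2], Cs[[i]][2], Os[[i]][2]),
      z = c(Ns[[i]][3], CAs[[i]][3], Cs[[i]][3], Os[[i]][3]))
  }
  # side chains after the full backbone, so the default-rotamer choice can
  # see the whole-chain context
  bb_xyz <- do.call(rbind, lapply(res, function(r) cbind(r$x, r$y, r$z)))
  bb_res <- rep(seq_len(n), each = 4)
  sc_xyz <- NULL
  for (i in seq_len(n)) {
    ctx <- rbind(bb_xyz[bb_res != i | seq_along(bb_res) %% 4 == 0, ,
                        drop = FALSE],   # other backbones plus own O
                 sc_xyz)
    ch <- if (is.null(chis)) {
      choose_default_chis(aas[i], Ns[[i]], CAs[[i]], Cs[[i]], ctx)
    } else chis[[i]]
    sc <- build_sidechain(aas[i], Ns[[i]], CAs[[i]], Cs[[i]], ch)
    if (nrow(sc) > 0) sc_xyz <- rbind(sc_xyz, cbind(sc$x, sc$y, sc$z))
    res[[i]] <- dplyr::bind_rows(res[[i]], sc)
  }
  dplyr::bind_rows(lapply(seq_len(n), function(i) {
    dplyr::mutate(res[[i]], chain = chain_id, resno = i, aa = aas[i],
                  .before = 1)
  }))
}

# principal-axis alignment helpers for placing built chains
align_to_x <- function(atoms, ca_only_axis = TRUE) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  ca <- as.matrix(atoms[atoms$atom == "CA", c("x", "y", "z")])
  ctr <- colMeans(ca)
  pc <- svd(sweep(ca, 2, ctr))$v[, 1]
  if (pc[1] < 0) pc <- -pc
  # rotation taking pc -> x axis
  ax <- vcross(pc, c(1, 0, 0))
  s <- vnorm(ax)
  if (s < 1e-12) {
    rot <- diag(3)
  } else {
    ax <- ax / s
    th <- acos(pmin(1, pmax(-1, pc[1])))
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                3, 3, byrow = TRUE)
    rot <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  }
  moved <- t(rot %*% t(sweep(xyz, 2, ctr)))
  atoms$x <- moved[, 1]; atoms$y <- moved[, 2]; atoms$z <- moved[, 3]
  atoms
}

# deterministic sequential re-choice of default rotamers in the context of
# the assembled complex (used after chains are placed relative to each other)
repack_default_rotamers <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno)
  for (k in unique(key)) {
    idx <- which(key == k)
    aa <- atoms$aa[idx[1]]
    if (N_CHI[[aa]] == 0 && aa != "P") next
    gx <- function(nm) {
      i <- idx[atoms$atom[idx] == nm]
      if (length(i) != 1) return(NULL)
      c(atoms$x[i], atoms$y[i], atoms$z[i])
    }
    N <- gx("N"); CA <- gx("CA"); C <- gx("C")
    if (is.null(N) || is.null(CA) || is.null(C)) next
    sc_idx <- idx[!atoms$atom[idx] %in% c("N", "CA", "C", "O", "OXT", "CB")]
    if (length(sc_idx) == 0) next
    keep <- setdiff(seq_len(nrow(atoms)), c(sc_idx, idx[atoms$atom[idx] %in%
                                                          c("N", "CA", "C", "CB")]))
    ctx <- cbind(atoms$x[keep], atoms$y[keep], atoms$z[keep])
    chis <- choose_default_chis(aa, N, CA, C, ctx)
    sc <- build_sidechain_xyz(aa, N, CA, C, chis)
    m <- match(atoms$atom[sc_idx], rownames(sc))
    atoms$x[sc_idx] <- sc[m, 1]
    atoms$y[sc_idx] <- sc[m, 2]
    atoms$z[sc_idx] <- sc[m, 3]
  }
  atoms
}

rotate_about_x <- function(atoms, theta_deg) {
  th <- deg2rad(theta_deg)
  y <- atoms$y * cos(th) - atoms$z * sin(th)
  z <- atoms$y * sin(th) + atoms$z * cos(th)
  atoms$y <- y; atoms$z <- z
  atoms
}
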