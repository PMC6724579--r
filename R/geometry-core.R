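# Vector geometry: internal-coordinate atom placement (NeRF), dihedrals,
# least-squares superposition (Kabsch, reflections excluded) and the two
# RMSD metrics used to compare models against reference structures.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
vnorm <- function(a) sqrt(sum(a * a))
vunit <- function(a) a / vnorm(a)

# place atom D bonded to C, with angle(B,C,D) and dihedral(A,B,C,D)
place_atom <- function(a, b, c, d_len, ang_deg, dih_deg) {
  ang <- deg2rad(ang_deg)
  dih <- deg2rad(dih_deg)
  bc <- vunit(c - b)
  n <- vunit(vcross(vunit(b - a), bc))
  m <- vcross(bc, n)
  d2 <- c(-d_len * cos(ang),
          -d_len * sin(ang) * cos(dih),
          -d_len * sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

bond_angle <- function(a, b, c) {
  v1 <- a - b
  v2 <- c - b
  cs <- sum(v1 * v2) / (vnorm(v1) * vnorm(v2))
  rad2deg(acos(pmin(1, pmax(-1, cs))))
}

dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vunit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  rad2deg(atan2(y, x))
}

#' Least-squares rigid superposition of paired coordinate sets
#'
#' Closed-form Kabsch superposition minimising the sum of squared distances
#' between paired points; reflections are excluded so the returned rotation
#' is always proper (determinant +1).
#'
#' @param mobile n x 3 numeric matrix of coordinates to move
#' @param reference n x 3 numeric matrix of target coordinates, row-paired
#'   with `mobile`
#' @return an object of class `superposition`: list with `rotation` (3 x 3),
#'   `translation` (length 3) and `fit_rmsd` (Angstrom).  The transform maps
#'   a mobile point x to `rotation %*% x + translation`.
#' @export
#' @examples
#' m <- matrix(rnorm(12), 4, 3)
#' s <- superpose(m + 2, m)
#' s$fit_rmsd
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3, ncol(reference) == 3)
  if (nrow(mobile) != nrow(reference)) {
    stop("superpose: coordinate sets must be paired (equal row counts)")
  }
  n <- nrow(mobile)
  if (n < 3) stop("superpose: need at least 3 paired points")
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  p <- sweep(mobile, 2, cm)
  q <- sweep(reference, 2, cr)
  h <- crossprod(p, q)
  sv <- svd(h)
  if (sv$d[2] < 1e-10) stop("superpose: degenerate (collinear) point set")
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- cr - as.vector(rot %*% cm)
  moved <- t(rot %*% t(mobile)) + matrix(trans, n, 3, byrow = TRUE)
  res <- list(rotation = rot, translation = trans,
              fit_rmsd = coord_rmsd(moved, reference))
  class(res) <- "superposition"
  res
}

#' @export
print.superposition <- function(x, ...) {
  cat("Rigid superposition: fit RMSD", format(x$fit_rmsd, digits = 4), "A\n")
  invisible(x)
}

apply_transform <- function(xyz, sp) {
  t(sp$rotation %*% t(as.matrix(xyz))) +
    matrix(sp$translation, nrow(xyz), 3, byrow = TRUE)
}

coord_rmsd <- function(a, b) {
  d <- as.matrix(a) - as.matrix(b)
  sqrt(sum(d^2) / nrow(d))
}

#' Peptide RMSD between a model and a reference complex
#'
#' `rmsd_ca()` evaluates the peptide C-alpha RMSD; `rmsd_full_atom()`
#' evaluates all paired peptide heavy atoms (paired by residue position and
#' atom name; positions with differing residue identity contribute their
#' common atoms only).  With `frame = "groove"` the superposition is fitted
#' on groove C-alpha atoms and the peptide deviation is evaluated without
#' refitting, measuring peptide placement within the groove; with
#' `frame = "peptide"` both fit and evaluation use the peptide atoms.
#'
#' @param model,reference complexes sharing a 9-residue peptide (see
#'   [read_pdb()])
#' @param frame `"groove"` (default) or `"peptide"`
#' @return RMSD in Angstrom
#' @export
rmsd_ca <- function(model, reference, frame = c("groove", "peptide")) {
  frame <- match.arg(frame)
  pm <- peptide_coords(model, "CA")
  pr <- peptide_coords(reference, "CA")
  if (nrow(pm) != nrow(pr)) stop("rmsd_ca: peptide C-alpha sets differ in size")
  if (frame == "peptide") {
    return(superpose(pm, pr)$fit_rmsd)
  }
  sp <- groove_superposition(model, reference)
  coord_rmsd(apply_transform(pm, sp), pr)
}

#' @rdname rmsd_ca
#' @export
rmsd_full_atom <- function(model, reference, frame = c("groove", "peptide")) {
  frame <- match.arg(frame)
  am <- peptide_atoms(model)
  ar <- peptide_atoms(reference)
  key_m <- paste(am$resno, am$atom)
  key_r <- paste(ar$resno, ar$atom)
  common <- intersect(key_m, key_r)
  if (length(common) == 0) stop("rmsd_full_atom: no paired peptide atoms")
  pm <- as.matrix(am[match(common, key_m), c("x", "y", "z")])
  pr <- as.matrix(ar[match(common, key_r), c("x", "y", "z")])
  if (frame == "peptide") {
    return(superpose(pm, pr)$fit_rmsd)
  }
  sp <- groove_superposition(model, reference)
  coord_rmsd(apply_transform(pm, sp), pr)
}

groove_superposition <- function(model, reference) {
  gm <- groove_coords(model, "CA")
  gr <- groove_coords(reference, "CA")
  if (nrow(gm) != nrow(gr)) {
    stop("rmsd: groove C-alpha sets differ in size (",
         nrow(gm), " vs ", nrow(gr), "); cannot fit the groove frame")
  }
  superpose(gm, gr)
}
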