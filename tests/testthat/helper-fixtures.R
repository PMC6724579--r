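# Shared fixtures, built in code and memoized per test run.

.fixture_env <- new.env(parent = emptyenv())

# small groove used throughout the suite (shorter helices than the default
# so scoring/refinement stay fast)
test_groove <- function() {
  if (is.null(.fixture_env$groove)) {
    .fixture_env$groove <- make_groove_fixture(
      groove_config(helix_len = 14, peptide = "AAGIGILTV"))
  }
  .fixture_env$groove
}

# a complex without validation, for module-level toys (e.g. single atoms)
toy_complex <- function(atoms, peptide_chain = "P", template_id = "toy") {
  atoms <- tibble::as_tibble(atoms)
  if (!"occ" %in% names(atoms)) atoms$occ <- 1
  if (!"b" %in% names(atoms)) atoms$b <- 0
  structure(atoms, class = c("structimm_complex", class(tibble::tibble())),
            peptide_chain = peptide_chain, template_id = template_id,
            nonamer = FALSE)
}

toy_atom <- function(chain, resno, aa, atom, x, y, z) {
  tibble::tibble(chain = chain, resno = as.integer(resno), aa = aa,
                 atom = atom, element = substr(atom, 1, 1),
                 x = x, y = y, z = z, occ = 1, b = 0)
}

# independent dense-grid SASA oracle (latitude-longitude quadrature in R)
grid_sasa_oracle <- function(xyz, radii, probe, n_theta = 60, n_phi = 120) {
  n <- nrow(xyz)
  areas <- numeric(n)
  th <- (seq_len(n_theta) - 0.5) * pi / n_theta
  ph <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
  for (i in seq_len(n)) {
    ri <- radii[i] + probe
    acc <- 0
    wsum <- 0
    for (t in th) {
      st <- sin(t); ct <- cos(t)
      px <- xyz[i, 1] + ri * st * cos(ph)
      py <- xyz[i, 2] + ri * st * sin(ph)
      pz <- xyz[i, 3] + ri * ct
      free <- rep(TRUE, n_phi)
      for (j in seq_len(n)) {
        if (j == i) next
        rj <- radii[j] + probe
        free <- free & ((px - xyz[j, 1])^2 + (py - xyz[j, 2])^2 +
                          (pz - xyz[j, 3])^2 >= rj^2)
      }
      acc <- acc + sum(free) * st
      wsum <- wsum + n_phi * st
    }
    areas[i] <- 4 * pi * ri^2 * acc / wsum
  }
  areas
}

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

transform_complex <- function(cx, rot, trans) {
  xyz <- as.matrix(cx[, c("x", "y", "z")]) %*% t(rot)
  cx$x <- xyz[, 1] + trans[1]
  cx$y <- xyz[, 2] + trans[2]
  cx$z <- xyz[, 3] + trans[3]
  cx
}
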