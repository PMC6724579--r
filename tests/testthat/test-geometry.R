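test_that("superposition recovers exact rigid transforms", {
  set.seed(11)
  m <- matrix(rnorm(12), 4, 3)
  sp0 <- superpose(m, m)
  expect_equal(sp0$rotation, diag(3), tolerance = 1e-10)
  expect_equal(sp0$fit_rmsd, 0, tolerance = 1e-10)

  sp1 <- superpose(m, m + matrix(c(1, 2, 3), 4, 3, byrow = TRUE))
  expect_equal(sp1$translation, c(1, 2, 3), tolerance = 1e-10)
  expect_equal(sp1$fit_rmsd, 0, tolerance = 1e-10)

  # known 90-degree rotation about z, checked against a brute-force scan
  # over discretized z-rotations refined locally
  rz <- function(th) matrix(c(cos(th), -sin(th), 0,
                              sin(th), cos(th), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  ref <- t(rz(pi / 2) %*% t(m))
  sp <- superpose(m, ref)
  expect_equal(sp$rotation, rz(pi / 2), tolerance = 1e-6)
  brute <- function(mob, ref) {
    f <- function(deg) {
      sqrt(mean(rowSums((t(rz(deg * pi / 180) %*% t(mob)) - ref)^2)))
    }
    grid <- 0:359
    best <- grid[which.min(vapply(grid, f, numeric(1)))]
    stats::optimize(f, c(best - 2, best + 2))$objective
  }
  expect_equal(sp$fit_rmsd, brute(m, ref), tolerance = 1e-6)
})

test_that("superposition is least-squares optimal against random transforms", {
  set.seed(42)
  m <- matrix(rnorm(24), 8, 3)
  ref <- m + matrix(rnorm(24, sd = 0.3), 8, 3)
  sp <- superpose(m, ref)
  for (k in 1:20) {
    rot <- random_rotation()
    tr <- rnorm(3)
    moved <- m %*% t(rot) + matrix(tr, 8, 3, byrow = TRUE)
    expect_lte(sp$fit_rmsd,
               sqrt(mean(rowSums((moved - ref)^2))) + 1e-12)
  }
  expect_equal(det(sp$rotation), 1, tolerance = 1e-6)
  # cross-check against the independent bio3d implementation
  fit <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.vector(t(ref)), mobile = as.vector(t(m))))
  expect_equal(sp$fit_rmsd,
               sqrt(mean(rowSums((matrix(fit, ncol = 3, byrow = TRUE) - ref)^2))),
               tolerance = 1e-6)
})

test_that("degenerate superposition inputs error", {
  expect_error(superpose(matrix(0, 2, 3), matrix(0, 2, 3)), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line), "degenerate")
  expect_error(superpose(matrix(0, 4, 3), matrix(0, 5, 3)), "paired")
})

test_that("C-alpha RMSD matches the closed form in the groove frame", {
  cx <- test_groove()
  expect_equal(rmsd_ca(cx, cx, frame = "groove"), 0, tolerance = 1e-12)
  expect_equal(rmsd_full_atom(cx, cx), 0, tolerance = 1e-12)

  # rigid 2 A shift of the peptide inside a fixed groove
  shifted <- cx
  pep <- shifted$chain == "P"
  shifted$z[pep] <- shifted$z[pep] + 2
  expect_equal(rmsd_ca(shifted, cx, frame = "groove"), 2, tolerance = 1e-6)
  # fitting on the peptide itself removes the displacement
  expect_equal(rmsd_ca(shifted, cx, frame = "peptide"), 0, tolerance = 1e-6)

  # per-atom displacements reproduce sqrt(sum d^2 / 9)
  jig <- cx
  dz <- seq(0.1, 0.9, by = 0.1)
  for (i in 1:9) {
    sel <- jig$chain == "P" & jig$resno == i & jig$atom == "CA"
    jig$z[sel] <- jig$z[sel] + dz[i]
  }
  expect_equal(rmsd_ca(jig, cx, frame = "groove"),
               sqrt(sum(dz^2) / 9), tolerance = 1e-9)
})

test_that("full-atom RMSD pairs by name and handles mutations", {
  cx <- test_groove()
  n_pep <- sum(cx$chain == "P")
  one <- cx
  sel <- which(one$chain == "P" & one$resno == 4 & one$atom == "CB")
  stopifnot(length(sel) == 1)
  one$x[sel] <- one$x[sel] + 1
  expect_equal(rmsd_full_atom(one, cx, frame = "groove"),
               sqrt(1 / n_pep), tolerance = 1e-9)

  # mutation: pairing restricted to atoms common to both residues
  mut <- thread(cx, sub("^(....)I", "\\1A", peptide_sequence(cx)))
  am <- peptide_atoms(mut); ar <- peptide_atoms(cx)
  common <- intersect(paste(am$resno, am$atom), paste(ar$resno, ar$atom))
  pm <- as.matrix(am[match(common, paste(am$resno, am$atom)), c("x", "y", "z")])
  pr <- as.matrix(ar[match(common, paste(ar$resno, ar$atom)), c("x", "y", "z")])
  expect_equal(rmsd_full_atom(mut, cx, frame = "groove"),
               sqrt(sum((pm - pr)^2) / nrow(pm)), tolerance = 1e-9)
})

test_that("RMSD is invariant under a joint rigid transform", {
  cx <- test_groove()
  mutant <- thread(cx, "LLFGYPVYV")
  base_ca <- rmsd_ca(mutant, cx, frame = "groove")
  base_fa <- rmsd_full_atom(mutant, cx, frame = "groove")
  set.seed(7)
  for (k in 1:5) {
    rot <- random_rotation(); tr <- rnorm(3, sd = 10)
    m2 <- transform_complex(mutant, rot, tr)
    c2 <- transform_complex(cx, rot, tr)
    expect_equal(rmsd_ca(m2, c2, frame = "groove"), base_ca, tolerance = 1e-8)
    expect_equal(rmsd_full_atom(m2, c2, frame = "groove"), base_fa,
                 tolerance = 1e-8)
  }
})
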