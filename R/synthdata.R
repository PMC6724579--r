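# Synthetic fixtures: an idealized two-helix groove holding an extended
# nonamer (standing in for crystallographic templates), and labeled peptide
# pools with planted positional-hydropathy structure.

#' Configuration for the synthetic groove fixture
#'
#' @param seed seed for the geometric noise
#' @param helix_len residues per flanking helix
#' @param groove_width axis-to-axis helix separation (Angstrom)
#' @param peptide nonamer threaded into the fixture
#' @param noise Gaussian coordinate jitter (Angstrom; 0 = ideal geometry)
#' @param helix_seq helix sequence (recycled/truncated to `helix_len`)
#' @return a `groove_config` list
#' @export
groove_config <- function(seed = 1, helix_len = 30, groove_width = 12.5,
                          peptide = "AAGIGILTV", noise = 0,
                          helix_seq = "LAEKIGALV") {
  stopifnot(nchar(peptide) == 9, noise >= 0, helix_len >= 5)
  structure(list(seed = as.integer(seed), helix_len = as.integer(helix_len),
                 groove_width = groove_width, peptide = toupper(peptide),
                 noise = noise, helix_seq = toupper(helix_seq)),
            class = "groove_config")
}

#' Build a synthetic two-helix groove holding an extended nonamer
#'
#' Two idealized antiparallel alpha-helices flank an extended 9-mer with
#' ideal backbone geometry and default side-chain rotamers.  Deliberately
#' minimal realism: the fixture exercises the pipeline's contracts (chains,
#' occlusion, contacts), not MHC biochemistry.  Deterministic given the
#' seed.
#'
#' @param config a [groove_config()]
#' @param path optional PDB output file
#' @return a `structimm_complex` (written to `path` if given)
#' @export
make_groove_fixture <- function(config = groove_config(), path = NULL) {
  if (nchar(config$peptide) != 9) {
    stop("make_groove_fixture: peptide must have 9 residues")
  }
  hseq <- paste(rep_len(strsplit(config$helix_seq, "")[[1]],
                        config$helix_len), collapse = "")
  helix <- build_chain(hseq, phi = rep(-57, config$helix_len),
                       psi = rep(-47, config$helix_len), chain_id = "A")
  helix <- align_to_x(helix)
  hw <- config$groove_width / 2

  pep <- build_chain(config$peptide, phi = rep(-150, 9), psi = rep(150, 9),
                     chain_id = "P")
  pep <- align_to_x(pep)
  # orient side chains perpendicular to the helix plane: first CB points +z
  ca1 <- unlist(pep[pep$resno == 1 & pep$atom == "CA", c("y", "z")])
  cb1 <- pep[pep$resno == 1 & pep$atom == "CB", c("y", "z")]
  if (nrow(cb1) == 1) {
    v <- unlist(cb1) - ca1
    pep <- rotate_about_x(pep, 90 - rad2deg(atan2(v[2], v[1])))
  }
  pep_xyz <- as.matrix(pep[, c("x", "y", "z")])

  # spin each helix about its own axis to the orientation with the largest
  # clearance from the peptide (deterministic scan), then shift into place
  place_helix <- function(base, y_shift, chain_id) {
    best <- NULL
    for (theta in seq(0, 350, by = 10)) {
      cand <- rotate_about_x(base, theta)
      cand$y <- cand$y + y_shift
      m <- as.matrix(cand[, c("x", "y", "z")])
      dmin <- cross_min_dist(m, pep_xyz)
      if (is.null(best) || dmin > best$dmin + 1e-9) {
        best <- list(atoms = cand, dmin = dmin)
      }
    }
    best$atoms$chain <- chain_id
    best$atoms
  }
  ha <- place_helix(helix, +hw, "A")
  hb_base <- helix
  hb_base$x <- -hb_base$x; hb_base$y <- -hb_base$y  # antiparallel partner
  hb <- place_helix(hb_base, -hw, "B")
  atoms <- dplyr::bind_rows(ha, hb, pep)
  atoms <- repack_default_rotamers(atoms)
  atoms$occ <- 1; atoms$b <- 0
  if (config$noise > 0) {
    set.seed(config$seed)
    n <- nrow(atoms)
    atoms$x <- atoms$x + rnorm(n, sd = config$noise)
    atoms$y <- atoms$y + rnorm(n, sd = config$noise)
    atoms$z <- atoms$z + rnorm(n, sd = config$noise)
  }
  cx <- new_complex(atoms, peptide_chain = "P",
                    template_id = "synthetic two-helix groove")
  if (!is.null(path)) write_pdb(cx, path)
  cx
}

# amino-acid background frequencies for synthetic pools (roughly natural
# abundance, renormalized over the 20-letter alphabet)
AA_FREQ <- c(A = 8.3, R = 5.5, N = 4.0, D = 5.5, C = 1.4, Q = 3.9, E = 6.7,
             G = 7.1, H = 2.3, I = 6.0, L = 9.7, K = 5.8, M = 2.4, F = 3.9,
             P = 4.7, S = 6.6, T = 5.3, W = 1.1, Y = 2.9, V = 6.9)

#' Configuration for synthetic labeled peptide pools
#'
#' Pool proportions default to the study corpus composition
#' (self : immunogenic : nonbinder = 2756 : 155 : 1044) so stratification
#' and oversampling behave as they would on the real corpus.  The
#' immunogenic pool is enriched for hydrophobic residues at the
#' TCR-proximal positions via a logistic propensity in positional
#' hydropathy; the nonbinder pool violates the HLA-A2 anchor rules at
#' positions 2 and 9.
#'
#' @param n_total total records when pools are drawn multinomially
#' @param pool_weights unnormalized pool proportions (self, immunogenic,
#'   nonbinder)
#' @param n_pools optional named exact counts overriding the multinomial
#'   draw, e.g. `c(self = 100, immunogenic = 20, nonbinder = 40)`
#' @param coef logistic coefficients on hydrophobicity (negative
#'   hydropathy) at the emphasized positions
#' @param intercept logistic intercept (controls enrichment strength)
#' @param seed RNG seed
#' @return a `peptide_pool_config`
#' @export
peptide_pool_config <- function(n_total = 400,
                                pool_weights = c(self = 2756,
                                                 immunogenic = 155,
                                                 nonbinder = 1044),
                                n_pools = NULL,
                                coef = c(p4 = 0.8, p5 = 0.6, p7 = 0.8,
                                         p8 = 0.7),
                                intercept = -0.3, seed = 1) {
  stopifnot(all(pool_weights > 0), all(is.finite(coef)))
  structure(list(n_total = as.integer(n_total),
                 pool_counts = pool_weights,
                 pool_weights = pool_weights / sum(pool_weights),
                 n_pools = n_pools, coef = coef, intercept = intercept,
                 seed = as.integer(seed)),
            class = "peptide_pool_config")
}

ANCHOR_P2 <- c(L = 0.55, M = 0.2, I = 0.15, V = 0.1)
ANCHOR_P9 <- c(V = 0.5, L = 0.3, I = 0.2)
NON_ANCHOR_SET <- c("D", "E", "K", "R", "N", "Q", "S", "T", "G", "P", "H")

sample_binder <- function() {
  aas <- sample(names(AA_FREQ), 9, replace = TRUE, prob = AA_FREQ)
  aas[2] <- sample(names(ANCHOR_P2), 1, prob = ANCHOR_P2)
  aas[9] <- sample(names(ANCHOR_P9), 1, prob = ANCHOR_P9)
  aas
}

#' Generate synthetic labeled peptide records
#'
#' @param config a [peptide_pool_config()]
#' @return tibble of peptide records (`sequence`, `pool`, `allele`,
#'   `response_frequency`, `provenance`)
#' @export
make_labeled_peptides <- function(config = peptide_pool_config()) {
  set.seed(config$seed)
  if (is.null(config$n_pools)) {
    pools <- sample(names(config$pool_weights), config$n_total,
                    replace = TRUE, prob = config$pool_weights)
    counts <- table(factor(pools, levels = names(config$pool_weights)))
  } else {
    counts <- config$n_pools
  }
  ww <- hydropathy_scale()
  pos <- as.integer(sub("p", "", names(config$coef)))
  propensity <- function(aas) {
    stats::plogis(config$intercept +
                    sum(config$coef * (-unname(ww[aas[pos]]))))
  }
  recs <- list()
  for (pl in names(counts)) {
    n <- as.integer(counts[[pl]])
    if (n == 0) next
    seqs <- character(n)
    for (i in seq_len(n)) {
      if (pl == "nonbinder") {
        aas <- sample(names(AA_FREQ), 9, replace = TRUE, prob = AA_FREQ)
        aas[2] <- sample(NON_ANCHOR_SET, 1)
        aas[9] <- sample(NON_ANCHOR_SET, 1)
      } else if (pl == "self") {
        aas <- sample_binder()
      } else {
        repeat {
          aas <- sample_binder()
          if (runif(1) < propensity(aas)) break
        }
      }
      seqs[i] <- paste(aas, collapse = "")
    }
    recs[[pl]] <- tibble::tibble(
      sequence = seqs, pool = pl,
      allele = if (pl == "nonbinder") {
        sample(c("HLA-B*07:02", "HLA-A*01:01", "HLA-A*03:01"), n,
               replace = TRUE)
      } else "HLA-A*02:01",
      response_frequency = if (pl == "immunogenic") {
        50 + stats::rpois(n, 40)
      } else NA_real_,
      provenance = paste0("synthetic-", pl))
  }
  dplyr::bind_rows(recs)
}
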