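# Synthetic input generators: ideal/perturbed helical CG chains, toy PDB
# files, Boltzmann samples from known 1-D potentials, and cross-link sets
# with a controlled number of false (over-length) restraints.  All
# generators are deterministic given their seed.

#' Ideal helical coarse-grained chain
#'
#' Places alpha carbons on a regular helical lattice (default rise
#' 1.5 angstrom/residue, twist 100 degrees/residue, radius 2.3 angstrom —
#' the alpha-helical geometry) with side-chain centers offset radially
#' outward.  Consecutive alpha-carbon distances are exactly constant and the
#' interior backbone virtual-bond dihedrals fall in the helical window.
#'
#' @param n_res number of residues, at least 4.
#' @param rise helical rise per residue (angstrom).
#' @param twist twist per residue (degrees).
#' @param radius helix radius (angstrom).
#' @param sc_offset radial side-chain-center offset (angstrom).
#' @param aa one-letter residue codes, recycled to `n_res`; default
#'   alanine.
#' @param chain_id chain identifier.
#' @return a [cg_chain()] numbered 1..n_res.
#' @export
ideal_helix <- function(n_res = 20, rise = 1.5, twist = 100, radius = 2.3,
                        sc_offset = 2.0, aa = "A", chain_id = "A") {
  stopifnot(n_res >= 4, rise > 0, radius > 0, sc_offset >= 0)
  k <- seq_len(n_res) - 1
  ang <- deg2rad(twist) * k
  ca <- cbind(radius * cos(ang), radius * sin(ang), rise * k)
  out <- cbind(cos(ang), sin(ang), 0)
  sc <- ca + sc_offset * out
  aa <- rep_len(aa, n_res)
  sc[aa == "G", ] <- ca[aa == "G", ]
  cg_chain(resno = seq_len(n_res), aa = aa, ca = ca, sc = sc,
           chain_id = chain_id)
}

#' Perturb a coarse-grained chain into a decoy
#'
#' Applies hinge rotations (all residues past each hinge rotated by the
#' given magnitude about a random axis through the hinge alpha carbon) and
#' then independent Gaussian coordinate noise.  With no hinges and zero
#' noise the chain is returned unchanged.
#'
#' @param chain a [cg_chain()].
#' @param hinge_indices author residue numbers of interior hinges.
#' @param rotation_magnitudes rotation magnitude per hinge, degrees.
#' @param noise_sd Gaussian noise standard deviation (angstrom).
#' @param seed integer seed; the perturbation is deterministic given it.
#' @return perturbed `cg_chain`.
#' @export
perturb_chain <- function(chain, hinge_indices = integer(),
                          rotation_magnitudes = numeric(), noise_sd = 0,
                          seed = 1) {
  stopifnot(length(hinge_indices) == length(rotation_magnitudes),
            noise_sd >= 0)
  if (length(hinge_indices) == 0 && noise_sd == 0) return(chain)
  set.seed(seed)
  n <- n_res(chain)
  for (h in seq_along(hinge_indices)) {
    p <- res_index(chain, hinge_indices[h])
    if (p <= 1 || p >= n) stop("hinges must be interior residues",
                               call. = FALSE)
    axis <- unit_vec(stats::rnorm(3))
    rot <- axis_rotation(axis, deg2rad(rotation_magnitudes[h]))
    pivot <- chain$ca[p, ]
    sel <- (p + 1):n
    chain$ca[sel, ] <- sweep(sweep(chain$ca[sel, , drop = FALSE], 2, pivot) %*%
                               t(rot), 2, pivot, `+`)
    chain$sc[sel, ] <- sweep(sweep(chain$sc[sel, , drop = FALSE], 2, pivot) %*%
                               t(rot), 2, pivot, `+`)
  }
  if (noise_sd > 0) {
    chain$ca <- chain$ca + matrix(stats::rnorm(3 * n, sd = noise_sd), n, 3)
    chain$sc <- chain$sc + matrix(stats::rnorm(3 * n, sd = noise_sd), n, 3)
  }
  chain
}

#' Metropolis samples from a one-dimensional Boltzmann distribution
#'
#' Samples exp(-V(x)/RT) by Metropolis Monte Carlo with a uniform
#' plus/minus `step` proposal; the first 10 percent of the run is discarded
#' as burn-in.  For dihedral coordinates set `periodic = TRUE` to wrap
#' proposals into (-pi, pi].
#'
#' @param potential function of one numeric argument returning kcal/mol.
#' @param T temperature, Kelvin.
#' @param n number of returned samples.
#' @param seed integer seed.
#' @param x0 starting coordinate.
#' @param step proposal half-width.
#' @param periodic wrap coordinate to (-pi, pi].
#' @param domain optional length-2 physical domain; proposals outside it are
#'   rejected (valid for the symmetric uniform proposal).  Use it for
#'   coordinates with hard physical bounds (angles in \[0, pi\], distances
#'   above contact), where an unbounded walker would otherwise diffuse over
#'   the flat tail of a localized model potential.
#' @return numeric vector of `n` samples with attribute `acceptance_rate`.
#' @export
boltzmann_sample <- function(potential, T = 300, n = 5000, seed = 1,
                             x0 = 0, step = 0.5, periodic = FALSE,
                             domain = NULL) {
  stopifnot(n >= 1, T > 0, step > 0)
  set.seed(seed)
  RT <- GAS_CONSTANT * T
  n_total <- ceiling(n / 0.9)
  burn <- n_total - n
  x <- x0
  vx <- potential(x)
  out <- numeric(n_total)
  acc <- 0L
  for (t in seq_len(n_total)) {
    prop <- x + stats::runif(1, -step, step)
    if (periodic) prop <- wrap_pi(prop)
    in_domain <- is.null(domain) || (prop >= domain[1] && prop <= domain[2])
    if (in_domain) {
      vp <- potential(prop)
      if (vp <= vx || stats::runif(1) < exp(-(vp - vx) / RT)) {
        x <- prop; vx <- vp; acc <- acc + 1L
      }
    }
    out[t] <- x
  }
  samples <- out[(burn + 1):n_total]
  attr(samples, "acceptance_rate") <- acc / n_total
  samples
}

#' Construct a cross-link fixture with controlled false restraints
#'
#' Picks `n_true` type-allowed residue pairs satisfied in the source chain
#' (alpha-carbon distance within the reagent's maximum span) and `n_false`
#' pairs violating the span by more than 5 angstrom — by construction a
#' violation census of the returned set against the source chain reports
#' exactly `n_false` links over the 5-angstrom margin.
#'
#' @param chain a [cg_chain()].
#' @param reagent a [reagent_spec()].
#' @param n_true,n_false numbers of satisfied and false links.
#' @param seed integer seed for the pair sampling.
#' @return an [xlink_set()].
#' @export
make_xlink_fixture <- function(chain, reagent, n_true, n_false, seed = 1) {
  stopifnot(inherits(reagent, "reagent_spec"), n_true >= 0, n_false >= 0)
  set.seed(seed)
  n <- n_res(chain)
  cand_t <- list(); cand_f <- list()
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      if (!pair_allowed(reagent, chain$aa[a], chain$aa[b])) next
      dca <- vec_norm(chain$ca[b, ] - chain$ca[a, ])
      excess <- dca - reagent$max_ca_span
      if (excess <= 0) {
        cand_t[[length(cand_t) + 1]] <- c(chain$resno[a], chain$resno[b])
      } else if (excess > 5) {
        cand_f[[length(cand_f) + 1]] <- c(chain$resno[a], chain$resno[b])
      }
    }
  }
  if (length(cand_t) < n_true || length(cand_f) < n_false) {
    stop(sprintf(
      "cannot construct fixture: %d satisfied / %d false pair(s) available, %d / %d requested",
      length(cand_t), length(cand_f), n_true, n_false), call. = FALSE)
  }
  pick <- function(cands, m) {
    if (m == 0) return(NULL)
    do.call(rbind, cands[sample.int(length(cands), m)])
  }
  sel <- rbind(pick(cand_t, n_true), pick(cand_f, n_false))
  xlink_set(sel[, 1], sel[, 2], reagent$name, 1,
            protein_id = "synthetic-fixture")
}

#' Write a toy all-atom-readable PDB of a coarse-grained chain
#'
#' Emits genuine ATOM records that [read_structure()] can ingest: a CA atom
#' at each alpha-carbon position and one real side-chain heavy atom placed
#' at the side-chain center (CB for residues other than lysine, CD for
#' lysine; nothing for glycine).  The side-chain centroid of the re-read
#' structure therefore reproduces the chain's SC positions exactly, closing
#' the I/O loop.  Multiple chains (models) can be written as a multi-model
#' file.
#'
#' @param chains a [cg_chain()] or list of them (one MODEL each).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_toy_pdb <- function(chains, path) {
  if (inherits(chains, "cg_chain")) chains <- list(chains)
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(chains) > 1
  for (m in seq_along(chains)) {
    chain <- chains[[m]]
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    serial <- 0L
    aa3 <- vapply(chain$aa, bio3d::aa123, character(1))
    for (k in seq_len(n_res(chain))) {
      serial <- serial + 1L
      writeLines(pdb_atom_line(serial, "CA", aa3[k], chain$chain_id,
                               chain$resno[k], chain$ca[k, ], "C"), con)
      if (chain$aa[k] != "G") {
        serial <- serial + 1L
        sc_name <- if (chain$aa[k] == "K") "CD" else "CB"
        writeLines(pdb_atom_line(serial, sc_name, aa3[k], chain$chain_id,
                                 chain$resno[k], chain$sc[k, ], "C"), con)
      }
    }
    writeLines("TER", con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
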