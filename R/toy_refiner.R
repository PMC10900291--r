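#' Configuration for the restrained toy minimizer
#'
#' @param tether_weight harmonic tether force constant, kcal/(mol A^2).
#' @param step_size initial gradient-descent step (angstrom per unit
#'   gradient).
#' @param max_iter maximum iterations.
#' @param tol energy-decrease convergence tolerance, kcal/mol.
#' @param seed integer seed (recorded; the minimizer itself is
#'   deterministic).
#' @return object of class `refine_config`.
#' @export
refine_config <- function(tether_weight = 1, step_size = 0.1, max_iter = 500,
                          tol = 1e-6, seed = 1) {
  stopifnot(tether_weight > 0, step_size > 0, max_iter > 0, tol > 0)
  structure(list(tether_weight = tether_weight, step_size = step_size,
                 max_iter = max_iter, tol = tol, seed = as.integer(seed)),
            class = "refine_config")
}

# total energy and Cartesian gradient of tether + restraints; coords is the
# (2n x 3) stack of ca then sc positions
refine_energy <- function(coords, coords0, chain, xlinks, pots,
                          dihedral_restraints, w_tether) {
  n <- n_res(chain)
  chain$ca <- coords[seq_len(n), , drop = FALSE]
  chain$sc <- coords[n + seq_len(n), , drop = FALSE]
  grad <- matrix(0, nrow(coords), 3)
  diff0 <- coords - coords0
  E <- w_tether * sum(diff0^2)
  grad <- grad + 2 * w_tether * diff0
  nl <- if (is.null(xlinks)) 0L else nrow(xlinks)
  for (k in seq_len(nl)) {
    pk <- pots[[k]]
    pi_ <- res_index(chain, xlinks$i[k])
    pj_ <- res_index(chain, xlinks$j[k])
    if (pk$type == "lorentz") {
      v <- chain$sc[pj_, ] - chain$sc[pi_, ]
      d <- vec_norm(v)
      le <- lorentz_energy(d, pk$params)
      E <- E + le$energy
      if (d > 0 && le$dE_dd != 0) {
        u <- v / d
        grad[n + pi_, ] <- grad[n + pi_, ] - le$dE_dd * u
        grad[n + pj_, ] <- grad[n + pj_, ] + le$dE_dd * u
      }
    } else if (pk$type == "statistical") {
      v <- chain$ca[pj_, ] - chain$ca[pi_, ]
      d <- vec_norm(v)
      se <- statistical_energy(d, pk$params)
      E <- E + se$energy
      u <- v / d
      grad[pi_, ] <- grad[pi_, ] - se$dE_dd * u
      grad[pj_, ] <- grad[pj_, ] + se$dE_dd * u
    } else if (pk$type == "mdbased") {
      # energy analytic; Cartesian chain rule by central differences over
      # the 12 coordinates of the two residues involved
      eval_link <- function(ch) {
        g <- xlink_geometry(ch, xlinks$i[k], xlinks$j[k],
                            pk$params$d_Xi, pk$params$d_Xj)
        mdbased_energy(g, pk$params)$energy
      }
      E <- E + eval_link(chain)
      h <- 1e-5
      for (site in c(pi_, n + pi_, pj_, n + pj_)) {
        for (ax in 1:3) {
          chp <- chain; chm <- chain
          if (site <= n) {
            chp$ca[site, ax] <- chp$ca[site, ax] + h
            chm$ca[site, ax] <- chm$ca[site, ax] - h
          } else {
            chp$sc[site - n, ax] <- chp$sc[site - n, ax] + h
            chm$sc[site - n, ax] <- chm$sc[site - n, ax] - h
          }
          grad[site, ax] <- grad[site, ax] +
            (eval_link(chp) - eval_link(chm)) / (2 * h)
        }
      }
    }
  }
  for (dr in dihedral_restraints) {
    p <- res_index(chain, dr$i)
    pts <- lapply(0:3, function(o) chain$ca[p + o, ])
    gam <- torsion(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
    if (is.na(gam)) next
    dp <- dihedral_penalty(rad2deg(gam), dr$restraint)
    E <- E + dp$energy
    if (dp$dE_dgamma != 0) {
      tg <- torsion_gradient(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
      for (o in 0:3) {
        grad[p + o, ] <- grad[p + o, ] + dp$dE_dgamma * tg[[o + 1]]
      }
    }
  }
  if (any(!is.finite(grad))) {
    stop("NaN/Inf gradient encountered in restraint term", call. = FALSE)
  }
  list(E = E, grad = grad)
}

#' Minimize restraint energy on a tethered coarse-grained chain
#'
#' Demonstrates the restraint gradients end to end: gradient descent with
#' backtracking on the sum of (i) a per-site harmonic tether to the starting
#' coordinates — a deliberately simple stand-in for the physical force
#' field, isolating restraint behavior — (ii) the cross-link penalties and
#' (iii) the backbone dihedral penalties.  The energy trace is monotone
#' non-increasing by construction.
#'
#' @param chain starting [cg_chain()].
#' @param xlinks an [xlink_set()] (may be `NULL` / empty).
#' @param potentials as in [total_restraint_energy()].
#' @param dihedral_restraints as in [total_restraint_energy()].
#' @param cfg a [refine_config()].
#' @return list with `chain` (minimized), `trace` (energy per accepted
#'   iteration, kcal/mol), `converged`, `n_iter`.
#' @export
restrained_minimize <- function(chain, xlinks, potentials,
                                dihedral_restraints = list(),
                                cfg = refine_config()) {
  stopifnot(inherits(cfg, "refine_config"))
  n <- n_res(chain)
  nl <- if (is.null(xlinks)) 0L else nrow(xlinks)
  pots <- if (nl > 0 && !is.null(potentials$type)) {
    rep(list(potentials), nl)
  } else {
    potentials
  }
  coords0 <- rbind(chain$ca, chain$sc)
  coords <- coords0
  st <- refine_energy(coords, coords0, chain, xlinks, pots,
                      dihedral_restraints, cfg$tether_weight)
  trace <- st$E
  converged <- FALSE
  iter <- 0L
  while (iter < cfg$max_iter) {
    iter <- iter + 1L
    step <- cfg$step_size
    accepted <- FALSE
    for (bt in 1:30) {
      cand <- coords - step * st$grad
      stc <- refine_energy(cand, coords0, chain, xlinks, pots,
                           dihedral_restraints, cfg$tether_weight)
      if (stc$E <= st$E) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) { converged <- TRUE; break }
    decrease <- st$E - stc$E
    coords <- cand
    st <- stc
    trace <- c(trace, st$E)
    if (decrease < cfg$tol) { converged <- TRUE; break }
  }
  chain$ca <- coords[seq_len(n), , drop = FALSE]
  chain$sc <- coords[n + seq_len(n), , drop = FALSE]
  list(chain = chain, trace = trace, converged = converged, n_iter = iter)
}
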