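# Shared fixtures and oracles used across the suite.

# central finite difference of a scalar function, the gradient oracle
fd_grad <- function(f, x, h = 1e-6) {
  (f(x + h) - f(x - h)) / (2 * h)
}

# four coplanar points making a square: Ca_i, X_i, X_j, Ca_j
square_points <- function() {
  list(ca_i = c(0, 0, 0), x_i = c(0, 1, 0),
       x_j = c(1, 1, 0), ca_j = c(1, 0, 0))
}

# two-residue chain whose SC centers sit `d` apart along x
two_residue_chain <- function(d = 10) {
  suppressWarnings(cg_chain(
    resno = c(1, 2), aa = c("K", "K"),
    ca = rbind(c(0, 0, 0), c(d, 0, 0)),
    sc = rbind(c(0, 2, 0), c(d, 2, 0))))
}

# compact helix dimer: two ideal helices side by side so residues at the
# interface are buried
helix_bundle <- function(n = 12, sep = 7) {
  h1 <- ideal_helix(n, aa = "A")
  h2 <- transform_chain(ideal_helix(n, aa = "A"), diag(3), c(sep, 0, 0))
  suppressWarnings(cg_chain(resno = seq_len(2 * n), aa = rep("A", 2 * n),
                            ca = rbind(h1$ca, h2$ca),
                            sc = rbind(h1$sc, h2$sc)))
}

gauss_eval <- function(x, terms) xlinkforge:::gauss_sum(x, terms)$e
cos_eval <- function(x, terms) xlinkforge:::cos_series(x, terms)$e

# direct pmf_table constructor for noiseless fit tests
make_pmf <- function(x, W, variable = "distance") {
  structure(list(variable = variable, midpoints = x, W = W, T = 300,
                 mask = rep(FALSE, length(x)), counts = rep(10L, length(x))),
            class = "pmf_table")
}

random_mdbased_params <- function(seed) {
  set.seed(seed)
  mdbased_params(
    d_Xi = runif(1, 1, 4), d_Xj = runif(1, 1, 4),
    dist_terms = cbind(runif(2, -3, 3), runif(2, 4, 10), runif(2, 0.5, 2)),
    angle_terms_i = cbind(runif(1, -2, 2), runif(1, 0.5, 2.5),
                          runif(1, 0.3, 1)),
    angle_terms_j = cbind(runif(1, -2, 2), runif(1, 0.5, 2.5),
                          runif(1, 0.3, 1)),
    dihedral_terms = cbind(runif(2, -1.5, 1.5), runif(2, 0, 2 * pi), 1:2))
}

random_xl_geometry <- function(seed) {
  set.seed(seed)
  structure(list(d = runif(1, 3, 12), theta_i = runif(1, 0.2, 2.9),
                 theta_j = runif(1, 0.2, 2.9), gamma = runif(1, -pi, pi),
                 d_Xi = 2, d_Xj = 2), class = "xl_geometry")
}
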