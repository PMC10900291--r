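test_that("histograms conserve counts and bin dihedrals periodically", {
  set.seed(1)
  s <- runif(5000, 2, 9)
  h <- xl_histogram(s, "distance", n_bins = 50)
  expect_equal(sum(h$counts), 5000)
  expect_length(h$counts, 50)
  expect_length(h$bin_edges, 51)

  h1 <- xl_histogram(rep(3.7, 100), "distance")
  expect_equal(max(h1$counts), 100)
  expect_equal(sum(h1$counts > 0), 1)

  # +-179 degrees fall in the two periodically adjacent end bins
  gam <- c(rep(179, 10), rep(-179, 10)) * pi / 180
  hd <- xl_histogram(gam, "dihedral", n_bins = 72)
  occupied <- which(hd$counts > 0)
  expect_equal(occupied, c(1, 72))
  expect_error(xl_histogram(numeric(0), "distance"), "no samples")
})

test_that("Boltzmann inversion recovers relative free energies", {
  # uniform counts -> flat PMF at zero
  h <- structure(list(variable = "distance",
                      bin_edges = seq(0, 10, length.out = 11),
                      counts = rep(100L, 10)), class = "xl_histogram")
  pmf <- pmf_from_histogram(h, T = 300)
  expect_equal(pmf$W, rep(0, 10))

  # count ratio e gives a free-energy gap of RT = 0.596 kcal/mol at 300 K
  h2 <- structure(list(variable = "distance",
                       bin_edges = c(0, 1, 2), counts = c(2718L, 1000L)),
                  class = "xl_histogram")
  pmf2 <- pmf_from_histogram(h2, T = 300)
  expect_equal(pmf2$W[1], 0)
  expect_equal(pmf2$W[2], 1.9872e-3 * 300, tolerance = 1e-3)

  # overall count scaling drops out after normalization
  h3 <- h2; h3$counts <- h3$counts * 10L
  expect_equal(pmf_from_histogram(h3, 300)$W, pmf2$W, tolerance = 1e-12)

  # empty bins are masked, all-empty errors
  h4 <- h; h4$counts <- c(0L, rep(100L, 9))
  expect_true(pmf_from_histogram(h4, 300)$mask[1])
  h5 <- h; h5$counts <- rep(0L, 10)
  expect_error(pmf_from_histogram(h5, 300), "no data")
})

test_that("inverting the PMF back reproduces the empirical frequencies", {
  set.seed(2)
  s <- rnorm(20000, mean = 7, sd = 1.2)
  h <- xl_histogram(s, "distance", n_bins = 40)
  pmf <- pmf_from_histogram(h, T = 300)
  RT <- 1.9872e-3 * pmf$T
  prob <- exp(-pmf$W[!pmf$mask] / RT)
  prob <- prob / sum(prob)
  emp <- h$counts[!pmf$mask] / sum(h$counts[!pmf$mask])
  expect_equal(prob, emp, tolerance = 1e-12)
})

test_that("noiseless synthetic PMFs are recovered exactly", {
  # Gaussian-sum form
  x <- seq(1, 11, length.out = 50)
  terms <- rbind(c(-3, 5, 1.2), c(-1.5, 8, 0.8))
  fr <- fit_potential(make_pmf(x, gauss_eval(x, terms) + 2), "distance",
                      n_terms = 2)
  expect_lt(fr$residual_norm, 1e-6)
  expect_true(fr$converged)
  ord <- order(fr$params[, "center"])
  expect_equal(unname(fr$params[ord, "coef"]), c(-3, -1.5), tolerance = 1e-4)
  expect_equal(unname(fr$params[ord, "center"]), c(5, 8), tolerance = 1e-4)

  # cosine-series form
  xg <- seq(-pi, pi, length.out = 72)
  dterms <- rbind(c(1.2, 0.5, 1), c(0.6, 2.1, 2))
  fg <- fit_potential(make_pmf(xg, cos_eval(xg, dterms) + 0.4, "dihedral"),
                      "dihedral", n_terms = 2)
  expect_lt(fg$residual_norm, 1e-6)

  # constant PMF: all oscillatory coefficients vanish
  fc <- fit_potential(make_pmf(xg, rep(1.3, 72), "dihedral"), "dihedral",
                      n_terms = 2)
  expect_true(all(abs(fc$params[, "coef"]) < 1e-6))
  expect_equal(fc$const, 1.3, tolerance = 1e-6)

  # under-determined data refuses to fit
  expect_error(fit_potential(make_pmf(x[1:4], gauss_eval(x[1:4], terms)),
                             "distance", n_terms = 2), "insufficient bins")
})

test_that("fit objective is non-increasing across accepted iterations", {
  x <- seq(1, 11, length.out = 50)
  terms <- rbind(c(-3, 5, 1.2), c(-1.5, 8, 0.8))
  set.seed(5)
  fr <- fit_potential(make_pmf(x, gauss_eval(x, terms) + rnorm(50, sd = 0.1)),
                      "distance", n_terms = 2)
  expect_true(all(diff(fr$rss_trace) <= 1e-12))
})

test_that("random noiseless draws are recovered in at least 95% of trials", {
  recover <- function(form, seed) {
    set.seed(seed)
    nt <- sample(1:2, 1)
    if (form == "dihedral") {
      terms <- cbind(runif(nt, 0.3, 2), runif(nt, 0, 2 * pi), seq_len(nt))
      x <- seq(-pi, pi, length.out = 72)
      W <- cos_eval(x, terms) + runif(1, 0, 2)
    } else {
      terms <- cbind(runif(nt, -4, -0.5), sort(runif(nt, 2, 10)),
                     runif(nt, 0.5, 2))
      x <- seq(0, 12, length.out = 50)
      W <- gauss_eval(x, terms) + runif(1, 0, 2)
    }
    fit_potential(make_pmf(x, W, form), form, n_terms = nt)$residual_norm
  }
  for (form in c("distance", "dihedral")) {
    res <- vapply(1:100, function(s) recover(form, s), numeric(1))
    expect_gte(mean(res < 1e-4), 0.95)
  }
})

test_that("minima of a two-term dihedral potential are recovered from
           5000 Boltzmann samples to within 5 degrees", {
  dterms <- rbind(c(1.2, 0.5, 1), c(0.6, 2.1, 2))
  s <- boltzmann_sample(function(x) cos_eval(x, dterms), T = 300, n = 5000,
                        seed = 21, x0 = pi, step = 0.7, periodic = TRUE)
  fr <- fit_potential(pmf_from_histogram(xl_histogram(s, "dihedral"), 300),
                      "dihedral", n_terms = 2, weights = "counts")
  grid <- seq(-pi, pi, length.out = 7200)
  m_true <- grid[which.min(cos_eval(grid, dterms))]
  m_fit <- grid[which.min(cos_eval(grid, fr$params))]
  expect_lt(abs(wrap_pi(m_fit - m_true)) * 180 / pi, 5)
})

test_that("the full ensemble pipeline round-trips a known potential", {
  truthp <- mdbased_params(
    d_Xi = 2, d_Xj = 2,
    dist_terms = c(-3, 8, 1.0), angle_terms_i = c(-2.5, 1.8, 0.4),
    angle_terms_j = c(-2.5, 1.4, 0.5), dihedral_terms = c(1.2, 0.5, 1))
  ens <- data.frame(
    d = boltzmann_sample(function(x) gauss_eval(x, truthp$dist_terms),
                         300, 5000, 11, x0 = 8, step = 0.7, domain = c(4, 12)),
    theta_i = boltzmann_sample(function(x) gauss_eval(x, truthp$angle_terms_i),
                               300, 5000, 12, x0 = 1.8, step = 0.3,
                               domain = c(0, pi)),
    theta_j = boltzmann_sample(function(x) gauss_eval(x, truthp$angle_terms_j),
                               300, 5000, 13, x0 = 1.4, step = 0.3,
                               domain = c(0, pi)),
    gamma = boltzmann_sample(function(x) cos_eval(x, truthp$dihedral_terms),
                             300, 5000, 14, x0 = pi, step = 0.7,
                             periodic = TRUE))
  dp <- derive_mdbased_params(ens, d_Xi = 2, d_Xj = 2,
                              n_terms = c(distance = 1, angle = 1,
                                          dihedral = 1),
                              weights = "counts")
  # energy surfaces agree (up to the PMF's arbitrary zero) over the central
  # 90% sampled region, within 0.3 kcal/mol RMS
  surfaces <- list(
    d = list(t = truthp$dist_terms, f = dp$dist_terms, eval = gauss_eval),
    theta_i = list(t = truthp$angle_terms_i, f = dp$angle_terms_i,
                   eval = gauss_eval),
    theta_j = list(t = truthp$angle_terms_j, f = dp$angle_terms_j,
                   eval = gauss_eval),
    gamma = list(t = truthp$dihedral_terms, f = dp$dihedral_terms,
                 eval = cos_eval))
  for (cn in names(surfaces)) {
    q <- quantile(ens[[cn]], c(0.05, 0.95))
    x <- seq(q[1], q[2], length.out = 100)
    sf <- surfaces[[cn]]
    tt <- sf$eval(x, sf$t)
    ff <- sf$eval(x, sf$f)
    rms <- sqrt(mean(((ff - mean(ff)) - (tt - mean(tt)))^2))
    expect_lt(rms, 0.3)
  }
  prov <- attr(dp, "provenance")
  expect_true(all(prov$converged))

  # a degenerate ensemble cannot be inverted
  same <- data.frame(d = rep(8, 200), theta_i = rep(1.5, 200),
                     theta_j = rep(1.5, 200), gamma = rep(0.5, 200))
  expect_error(derive_mdbased_params(same, 2, 2), "insufficient bins")
  expect_error(derive_mdbased_params(ens[1:50, ], 2, 2), ">= 100")
})

test_that("more samples do not worsen expected fit residuals", {
  dterms <- rbind(c(1.5, 0.5, 1))
  res_at <- function(n, seed) {
    s <- boltzmann_sample(function(x) cos_eval(x, dterms), 300, n, seed,
                          x0 = pi, step = 0.7, periodic = TRUE)
    h <- xl_histogram(s, "dihedral")
    fit <- fit_potential(pmf_from_histogram(h, 300), "dihedral",
                         n_terms = 1, weights = "counts")
    # count-weighted RMS misfit per sample: comparable across sample sizes
    fit$residual_norm / sqrt(sum(h$counts))
  }
  seeds <- 1:10
  small <- mean(vapply(seeds, function(s) res_at(2000, s), numeric(1)))
  big <- mean(vapply(seeds, function(s) res_at(4000, s + 100), numeric(1)))
  expect_lte(big, small)
})

test_that("snapshot tables round-trip through TSV", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(d = c(7.5, 8.1), theta_i = c(1.2, 1.3),
                   theta_j = c(1.4, 1.5), gamma = c(-0.2, 0.4))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_samples_tsv(path), df)
  writeLines("a\tb", path)
  expect_error(read_samples_tsv(path), "columns")
})
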