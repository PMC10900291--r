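# Gas constant, kcal/(mol K)
GAS_CONSTANT <- 1.9872e-3

default_bins <- c(distance = 50, angle = 36, dihedral = 72)

#' Histogram a coordinate sample
#'
#' Bins samples of one cross-link internal coordinate.  Dihedral samples are
#' wrapped to (-pi, pi] and binned on that periodic interval, so values near
#' +pi and -pi land in periodically adjacent bins; distances and angles are
#' binned on their (data-driven or supplied) range.
#'
#' @param samples numeric vector, at least one value.
#' @param variable one of `"distance"`, `"angle"`, `"dihedral"`.
#' @param n_bins number of bins; defaults to 50 for distances, 36 for
#'   angles and 72 for dihedrals (5-degree bins).
#' @param range optional length-2 range; ignored for dihedrals, which always
#'   use (-pi, pi].
#' @return object of class `xl_histogram`: list with `variable`,
#'   `bin_edges`, `counts`.
#' @export
xl_histogram <- function(samples, variable = c("distance", "angle", "dihedral"),
                         n_bins = NULL, range = NULL) {
  variable <- match.arg(variable)
  samples <- samples[is.finite(samples)]
  if (length(samples) == 0) stop("no samples", call. = FALSE)
  if (is.null(n_bins)) n_bins <- default_bins[[variable]]
  if (variable == "dihedral") {
    samples <- wrap_pi(samples)
    edges <- seq(-pi, pi, length.out = n_bins + 1)
  } else {
    if (is.null(range)) {
      range <- base::range(samples)
      if (diff(range) == 0) range <- range + c(-0.5, 0.5)
    }
    edges <- seq(range[1], range[2], length.out = n_bins + 1)
    samples <- pmin(pmax(samples, range[1]), range[2])
  }
  # left-open bins so upper boundary values (incl. +pi) fall in the last bin
  idx <- findInterval(samples, edges, left.open = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(variable = variable, bin_edges = edges,
                 counts = as.integer(counts)),
            class = "xl_histogram")
}

#' Potential of mean force by Boltzmann inversion
#'
#' Converts a histogram into a free-energy profile W_i = -RT ln h_i on
#' populated bins (R = 1.9872e-3 kcal/(mol K)), shifted so the minimum over
#' populated bins is zero.  Empty bins are masked rather than
#' pseudo-counted: the inversion is undefined at zero counts and invented
#' counts would pollute any downstream fit.
#'
#' @param h an [xl_histogram()].
#' @param T absolute temperature in Kelvin, default 300.
#' @return object of class `pmf_table`: list with `variable`, `midpoints`,
#'   `W` (kcal/mol, `NA` on masked bins), `T`, logical `mask` of excluded
#'   bins, and the bin `counts`.
#' @export
pmf_from_histogram <- function(h, T = 300) {
  stopifnot(inherits(h, "xl_histogram"), T > 0)
  if (all(h$counts == 0)) stop("no data", call. = FALSE)
  RT <- GAS_CONSTANT * T
  mask <- h$counts == 0
  W <- rep(NA_real_, length(h$counts))
  W[!mask] <- -RT * log(h$counts[!mask])
  W <- W - min(W, na.rm = TRUE)
  mids <- (h$bin_edges[-1] + h$bin_edges[-length(h$bin_edges)]) / 2
  structure(list(variable = h$variable, midpoints = mids, W = W, T = T,
                 mask = mask, counts = h$counts),
            class = "pmf_table")
}

# basis evaluators used by the fit; `par` packs (const, terms...)
fit_model <- function(form, x, par, n_terms) {
  c0 <- par[1]
  rest <- par[-1]
  if (form == "dihedral") {
    a <- rest[seq_len(n_terms)]
    ph <- rest[n_terms + seq_len(n_terms)]
    v <- c0
    for (k in seq_len(n_terms)) v <- v + a[k] * cos(k * x - ph[k])
    v
  } else {
    a <- rest[seq_len(n_terms)]
    mu <- rest[n_terms + seq_len(n_terms)]
    w <- rest[2 * n_terms + seq_len(n_terms)]
    v <- c0
    for (k in seq_len(n_terms)) {
      v <- v + a[k] * exp(-(x - mu[k])^2 / (2 * w[k]^2))
    }
    v
  }
}

fit_starts <- function(form, x, y, n_terms) {
  # five deterministic initializations spread over the data range
  spread <- diff(range(x))
  amp <- max(y) - min(y)
  if (amp == 0) amp <- 1
  starts <- list()
  if (form == "dihedral") {
    phases <- seq(0, 2 * pi, length.out = 6)[1:5]
    for (s in seq_len(5)) {
      starts[[s]] <- c(mean(y), rep(amp / 2, n_terms),
                       rep(phases[s], n_terms))
    }
  } else {
    # candidate centers: local minima of the PMF (wells), deepest first,
    # padded with quantiles when fewer wells than terms
    ord <- order(x)
    xs <- x[ord]; ys <- y[ord]
    m <- length(ys)
    is_min <- c(FALSE, ys[2:(m - 1)] < ys[1:(m - 2)] &
                  ys[2:(m - 1)] <= ys[3:m], FALSE)
    wells <- xs[is_min][order(ys[is_min])]
    pad <- stats::quantile(x, probs = seq(0.25, 0.75, length.out = n_terms),
                           names = FALSE)
    well_centers <- c(wells, pad)[seq_len(n_terms)]
    centers <- list(
      well_centers, well_centers,
      rep(xs[which.min(ys)], n_terms),
      seq(min(x), max(x), length.out = n_terms + 2)[1 + seq_len(n_terms)],
      stats::quantile(x, probs = seq(0.1, 0.9, length.out = n_terms),
                      names = FALSE))
    widths <- c(0.08, 0.25, 0.15, 0.3, 0.2) * spread
    for (s in seq_len(5)) {
      cen <- centers[[s]]
      depth <- stats::approx(xs, ys, xout = cen, rule = 2)$y - max(y)
      depth[depth > -0.05 * amp] <- -0.5 * amp
      starts[[s]] <- c(max(y), depth, cen,
                       rep(max(widths[s], 1e-3), n_terms))
    }
  }
  starts
}

#' Fit an analytic restraint form to a potential of mean force
#'
#' Least-squares fit of the Gaussian-sum (distance/angle) or cosine-series
#' (dihedral) restraint basis to a PMF, using the Levenberg-Marquardt
#' algorithm with five deterministic multi-starts; the best residual is
#' kept.  An additive constant is always fitted to absorb the arbitrary
#' free-energy zero.
#'
#' @param pmf a [pmf_table()] (or a list with `midpoints`, `W`, optional
#'   `mask`).
#' @param form one of `"distance"`, `"angle"`, `"dihedral"`.
#' @param n_terms number of basis terms.
#' @param init optional full start vector (const first), tried in addition
#'   to the defaults.
#' @param weights optional per-bin fit weights; `"counts"` selects Boltzmann
#'   weighting by bin population, default is uniform.
#' @return object of class `fit_result`: `params` (an [mdbased_params()]
#'   component matrix plus `const`), `residual_norm` (kcal/mol), `n_iterations`,
#'   `converged`, and `rss_trace` (objective across accepted iterations).
#' @export
fit_potential <- function(pmf, form = c("distance", "angle", "dihedral"),
                          n_terms = 2, init = NULL, weights = NULL) {
  form <- match.arg(form)
  mask <- pmf$mask %||% rep(FALSE, length(pmf$W))
  x <- pmf$midpoints[!mask]
  y <- pmf$W[!mask]
  npar <- if (form == "dihedral") 2 * n_terms + 1 else 3 * n_terms + 1
  if (length(x) < npar + 1) stop("insufficient bins", call. = FALSE)
  w <- if (identical(weights, "counts")) {
    sqrt(pmf$counts[!mask])
  } else if (is.null(weights)) {
    rep(1, length(x))
  } else {
    sqrt(weights[!mask])
  }
  resid_fn <- function(par) w * (fit_model(form, x, par, n_terms) - y)
  starts <- fit_starts(form, x, y, n_terms)
  if (!is.null(init)) starts <- c(list(init), starts)
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rn <- sqrt(sum(fit$fvec^2))
    if (is.null(best) || rn < best$rn) best <- list(fit = fit, rn = rn)
  }
  if (is.null(best)) stop("fit failed from every initialization", call. = FALSE)
  fit <- best$fit
  par <- fit$par
  rss <- function(p) sum(resid_fn(p)^2)
  hgrad <- 1e-7
  grad_norm <- sqrt(sum(vapply(seq_along(par), function(q) {
    pp <- par; pp[q] <- pp[q] + hgrad
    pm <- par; pm[q] <- pm[q] - hgrad
    (rss(pp) - rss(pm)) / (2 * hgrad)
  }, numeric(1))^2))
  converged <- fit$info %in% 1:3 || grad_norm < 1e-8
  terms <- if (form == "dihedral") {
    cbind(coef = par[1 + seq_len(n_terms)],
          phase = par[1 + n_terms + seq_len(n_terms)],
          order = seq_len(n_terms))
  } else {
    cbind(coef = par[1 + seq_len(n_terms)],
          center = par[1 + n_terms + seq_len(n_terms)],
          width = abs(par[1 + 2 * n_terms + seq_len(n_terms)]))
  }
  structure(list(form = form, params = terms, const = par[1],
                 residual_norm = best$rn, n_iterations = fit$niter,
                 converged = converged, rss_trace = fit$rsstrace),
            class = "fit_result")
}

#' Derive MD-based restraint parameters from a conformational ensemble
#'
#' Runs the histogram -> Boltzmann inversion -> least-squares pipeline for
#' each of the four cross-link internal coordinates of an ensemble and
#' assembles the result into an [mdbased_params()] object.  The ensemble
#' plays the role of snapshots from a simulation of the cross-linked model
#' compound; any sampler producing the four coordinates can feed it.
#'
#' @param ensemble data frame (or list of `xl_geometry`) with columns
#'   `d`, `theta_i`, `theta_j`, `gamma`; at least 100 rows.
#' @param d_Xi,d_Xj anchor offsets recorded in the result (angstrom).
#' @param T temperature for the inversion (Kelvin), default 300.
#' @param n_bins named vector of bin counts per coordinate class; defaults
#'   as in [xl_histogram()].
#' @param n_terms named list/vector with elements `distance`, `angle`,
#'   `dihedral`; default 2 terms each.
#' @param weights passed to [fit_potential()].
#' @return an [mdbased_params()] with attribute `provenance` holding the
#'   per-coordinate fit residuals and convergence flags.
#' @export
derive_mdbased_params <- function(ensemble, d_Xi, d_Xj, T = 300,
                                  n_bins = default_bins,
                                  n_terms = c(distance = 2, angle = 2,
                                              dihedral = 2),
                                  weights = NULL) {
  if (inherits(ensemble, "xl_geometry")) ensemble <- list(ensemble)
  if (!is.data.frame(ensemble)) {
    ensemble <- data.frame(
      d = vapply(ensemble, `[[`, numeric(1), "d"),
      theta_i = vapply(ensemble, `[[`, numeric(1), "theta_i"),
      theta_j = vapply(ensemble, `[[`, numeric(1), "theta_j"),
      gamma = vapply(ensemble, `[[`, numeric(1), "gamma"))
  }
  if (nrow(ensemble) < 100) stop("need >= 100 ensemble samples", call. = FALSE)
  one <- function(col, variable, form) {
    h <- xl_histogram(ensemble[[col]], variable = variable,
                      n_bins = n_bins[[variable]])
    fit_potential(pmf_from_histogram(h, T = T), form = form,
                  n_terms = n_terms[[form]], weights = weights)
  }
  fd <- one("d", "distance", "distance")
  fi <- one("theta_i", "angle", "angle")
  fj <- one("theta_j", "angle", "angle")
  fg <- one("gamma", "dihedral", "dihedral")
  out <- mdbased_params(
    d_Xi = d_Xi, d_Xj = d_Xj,
    dist_terms = fd$params, angle_terms_i = fi$params,
    angle_terms_j = fj$params, dihedral_terms = fg$params,
    const = fd$const + fi$const + fj$const + fg$const)
  attr(out, "provenance") <- data.frame(
    coordinate = c("d", "theta_i", "theta_j", "gamma"),
    residual_norm = c(fd$residual_norm, fi$residual_norm, fj$residual_norm,
                      fg$residual_norm),
    converged = c(fd$converged, fi$converged, fj$converged, fg$converged))
  out
}

#' Read coordinate samples from a TSV snapshot table
#'
#' One row per snapshot with columns `d`, `theta_i`, `theta_j`, `gamma`
#' (angstrom / radians); header required.
#'
#' @param path TSV file path.
#' @return data frame of samples.
#' @export
read_samples_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE)
  need <- c("d", "theta_i", "theta_j", "gamma")
  if (!all(need %in% names(df))) {
    stop("sample table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df[need]
}
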