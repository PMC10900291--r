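#' Bounded Lorentz-like flat-bottom restraint parameters
#'
#' The flat-bottom wall potential is zero on `[d_l, d_u]`, rises with a
#' Lorentzian wall of thickness `sigma` outside the bottom, and saturates at
#' the well depth `A`, so a grossly violated restraint exerts (almost) no
#' force.  The sub-`d_l` branch mirrors the wall shape, preventing
#' side-chain fusion.
#'
#' @param d_l lower flat-bottom boundary (angstrom), default 2.5.
#' @param d_u upper flat-bottom boundary (angstrom); set by the reagent's
#'   maximum dimension.
#' @param sigma wall thickness (angstrom).
#' @param A well depth / asymptotic plateau (kcal/mol).
#' @return object of class `lorentz_params`.
#' @export
lorentz_params <- function(d_u, sigma, A, d_l = 2.5) {
  if (!(d_l >= 0 && d_l < d_u)) stop("parameter error: need 0 <= d_l < d_u",
                                     call. = FALSE)
  if (sigma <= 0 || A <= 0) stop("parameter error: sigma and A must be > 0",
                                 call. = FALSE)
  structure(list(d_l = d_l, d_u = d_u, sigma = sigma, A = A),
            class = "lorentz_params")
}

#' Named Lorentz wall presets
#'
#' Four (sigma, A) combinations commonly explored for cross-link walls:
#' `LR(5,8)`, `LR(15,8)`, `LR(5,20)`, `LR(15,20)` (sigma in angstrom, A in
#' kcal/mol).  The flat-bottom boundaries still depend on the reagent, so
#' `d_u` must be supplied.
#'
#' @param name preset name, e.g. `"LR(15,8)"`.
#' @param d_u upper flat-bottom boundary (angstrom).
#' @param d_l lower boundary (angstrom), default 2.5.
#' @return a [lorentz_params()] object.
#' @export
lorentz_preset <- function(name, d_u, d_l = 2.5) {
  tab <- list("LR(5,8)" = c(5, 8), "LR(15,8)" = c(15, 8),
              "LR(5,20)" = c(5, 20), "LR(15,20)" = c(15, 20))
  if (!name %in% names(tab)) {
    stop("parameter error: unknown preset '", name, "'; available: ",
         paste(names(tab), collapse = ", "), call. = FALSE)
  }
  p <- tab[[name]]
  lorentz_params(d_u = d_u, sigma = p[1], A = p[2], d_l = d_l)
}

#' Lorentz-like flat-bottom restraint energy and gradient
#'
#' @param d distance(s), angstrom; vectorized.
#' @param p a [lorentz_params()] object.
#' @return list with `energy` (kcal/mol) and `dE_dd` (kcal/mol/angstrom),
#'   each the length of `d`.
#' @export
lorentz_energy <- function(d, p) {
  stopifnot(inherits(p, "lorentz_params"))
  if (any(d < 0)) stop("parameter error: d must be >= 0", call. = FALSE)
  over <- pmax(d - p$d_u, 0)
  under <- pmax(p$d_l - d, 0)
  x <- over + under
  s2 <- p$sigma^2
  denom <- x^2 + s2
  energy <- p$A * x^2 / denom
  # dE/dx, then signed by which wall is active
  dE_dx <- 2 * p$A * s2 * x / denom^2
  sign <- ifelse(over > 0, 1, ifelse(under > 0, -1, 0))
  list(energy = energy, dE_dd = sign * dE_dx)
}

#' Statistical cross-link potential parameters
#'
#' The statistical potential acts on the alpha-carbon distance of the
#' cross-linked pair and derives from Boltzmann inversion of empirical
#' cross-link distance distributions.  The family implemented here inverts a
#' generalized distance distribution p(d) proportional to
#' d^a * exp(-c d - (d - b)^2 / (2 sigma^2)), giving
#' V(d) = A RT ((d - b)^2 / (2 sigma^2) + c d - a ln d), which is finite,
#' continuous and once-differentiable for d > 0 and scales linearly in the
#' confidence weight `A`.  The shape parameters `a`, `b`, `c`, `sigma` are
#' cross-link-specific and load from JSON parameter files.
#'
#' @param a,b,c shape parameters (dimensionless, angstrom, 1/angstrom).
#' @param sigma width parameter (angstrom).
#' @param A confidence weight (dimensionless), default 15.
#' @param RT thermal energy (kcal/mol), default 0.591 (T = 298 K).
#' @return object of class `statistical_params`.
#' @export
statistical_params <- function(a, b, c, sigma, A = 15, RT = 0.591) {
  if (sigma <= 0) stop("parameter error: sigma must be > 0", call. = FALSE)
  structure(list(a = a, b = b, c = c, sigma = sigma, A = A, RT = RT),
            class = "statistical_params")
}

#' Statistical cross-link potential energy and gradient
#'
#' @param d alpha-carbon distance(s), angstrom, strictly positive;
#'   vectorized.
#' @param p a [statistical_params()] object.
#' @return list with `energy` (kcal/mol) and `dE_dd` (kcal/mol/angstrom).
#' @export
statistical_energy <- function(d, p) {
  stopifnot(inherits(p, "statistical_params"))
  if (any(d <= 0)) stop("domain error: d must be > 0", call. = FALSE)
  w <- p$A * p$RT
  energy <- w * ((d - p$b)^2 / (2 * p$sigma^2) + p$c * d - p$a * log(d))
  dE_dd <- w * ((d - p$b) / p$sigma^2 + p$c - p$a / d)
  list(energy = energy, dE_dd = dE_dd)
}

#' MD-derived cross-link potential parameters
#'
#' The MD-based potential is a sum of four components in the cross-link
#' internal coordinates: the anchor-anchor virtual-bond length, the two
#' virtual-bond angles at the anchors, and the virtual-bond dihedral.  The
#' length and angle components are sums of Gaussian terms
#' `coef * exp(-(x - center)^2 / (2 width^2))`; the dihedral component is a
#' cosine series `coef * cos(order * gamma - phase)` (2-pi periodic by
#' construction), with integer orders.  An optional additive constant
#' absorbs the arbitrary zero of a fitted potential of mean force.
#'
#' @param d_Xi,d_Xj anchor offsets from the alpha carbons (angstrom).
#' @param dist_terms,angle_terms_i,angle_terms_j numeric matrices with
#'   columns (coef, center, width), one row per Gaussian term.
#' @param dihedral_terms numeric matrix with columns (coef, phase, order).
#' @param const additive constant (kcal/mol), default 0.
#' @return object of class `mdbased_params`.
#' @export
mdbased_params <- function(d_Xi, d_Xj, dist_terms, angle_terms_i,
                           angle_terms_j, dihedral_terms, const = 0) {
  chk_gauss <- function(m, what) {
    m <- matrix(as.numeric(m), ncol = 3,
                dimnames = list(NULL, c("coef", "center", "width")))
    if (nrow(m) < 1) stop("parameter error: ", what, " needs >= 1 term",
                          call. = FALSE)
    if (any(m[, "width"] <= 0)) stop("parameter error: ", what,
                                     " widths must be > 0", call. = FALSE)
    m
  }
  dih <- matrix(as.numeric(dihedral_terms), ncol = 3,
                dimnames = list(NULL, c("coef", "phase", "order")))
  if (nrow(dih) < 1) stop("parameter error: dihedral_terms needs >= 1 term",
                          call. = FALSE)
  if (any(dih[, "order"] %% 1 != 0) || any(dih[, "order"] < 0)) {
    stop("parameter error: dihedral orders must be non-negative integers",
         call. = FALSE)
  }
  structure(list(
    d_Xi = d_Xi, d_Xj = d_Xj,
    dist_terms = chk_gauss(dist_terms, "dist_terms"),
    angle_terms_i = chk_gauss(angle_terms_i, "angle_terms_i"),
    angle_terms_j = chk_gauss(angle_terms_j, "angle_terms_j"),
    dihedral_terms = dih, const = const), class = "mdbased_params")
}

gauss_sum <- function(x, terms) {
  e <- 0; g <- 0
  for (k in seq_len(nrow(terms))) {
    a <- terms[[k, 1]]; mu <- terms[[k, 2]]; w <- terms[[k, 3]]
    ex <- a * exp(-(x - mu)^2 / (2 * w^2))
    e <- e + ex
    g <- g - ex * (x - mu) / w^2
  }
  list(e = e, g = g)
}

cos_series <- function(x, terms) {
  e <- 0; g <- 0
  for (k in seq_len(nrow(terms))) {
    a <- terms[[k, 1]]; ph <- terms[[k, 2]]; n <- terms[[k, 3]]
    e <- e + a * cos(n * x - ph)
    g <- g - a * n * sin(n * x - ph)
  }
  list(e = e, g = g)
}

#' MD-based cross-link restraint energy and gradient
#'
#' Evaluates the four-component MD-based potential at a cross-link geometry
#' and returns the energy with its analytic gradient over the internal
#' coordinates.
#'
#' @param g an `xl_geometry` from [xlink_geometry()]; `gamma` must be
#'   defined.
#' @param p an [mdbased_params()] object.
#' @return list with `energy` (kcal/mol), `gradient` (named vector over
#'   `d`, `theta_i`, `theta_j`, `gamma`), and per-component `breakdown`.
#' @export
mdbased_energy <- function(g, p) {
  stopifnot(inherits(p, "mdbased_params"))
  if (is.na(g$gamma)) stop("degenerate geometry: dihedral undefined",
                           call. = FALSE)
  cd <- gauss_sum(g$d, p$dist_terms)
  ci <- gauss_sum(g$theta_i, p$angle_terms_i)
  cj <- gauss_sum(g$theta_j, p$angle_terms_j)
  cg <- cos_series(g$gamma, p$dihedral_terms)
  list(energy = cd$e + ci$e + cj$e + cg$e + p$const,
       gradient = c(d = cd$g, theta_i = ci$g, theta_j = cj$g, gamma = cg$g),
       breakdown = c(dist = cd$e, angle_i = ci$e, angle_j = cj$e,
                     dihedral = cg$e, const = p$const))
}

#' Backbone virtual-bond dihedral restraint
#'
#' Flat-bottom quartic restraint on a backbone virtual-bond dihedral: zero
#' inside the window `[gamma_l, gamma_u]` (modulo 360 degrees) and
#' `w_dih * excess^4` outside, with the excess measured in radians along the
#' shorter angular path to the window.  The canonical windows are
#' (30, 70) degrees for helical and (120, 240) degrees for extended
#' conformations, with `w_dih = 50` kcal/(mol rad^4).
#'
#' @param gamma_l,gamma_u window boundaries in degrees.
#' @param w_dih restraint weight, kcal/(mol rad^4); default 50.
#' @return object of class `dihedral_restraint`.
#' @export
dihedral_restraint <- function(gamma_l, gamma_u, w_dih = 50) {
  if (w_dih < 0) stop("parameter error: w_dih must be >= 0", call. = FALSE)
  width <- (gamma_u - gamma_l) %% 360
  if (width == 0) stop("parameter error: empty or full window", call. = FALSE)
  structure(list(gamma_l = gamma_l, gamma_u = gamma_u, w_dih = w_dih),
            class = "dihedral_restraint")
}

#' Dihedral restraint energy and gradient
#'
#' @param gamma dihedral angle(s) in degrees; vectorized.
#' @param r a [dihedral_restraint()].
#' @return list with `energy` (kcal/mol) and `dE_dgamma`
#'   (kcal/mol/radian).
#' @export
dihedral_penalty <- function(gamma, r) {
  stopifnot(inherits(r, "dihedral_restraint"))
  width <- (r$gamma_u - r$gamma_l) %% 360
  a <- (gamma - r$gamma_l) %% 360            # position past lower edge
  inside <- a <= width
  up <- a - width                            # excess past the upper edge
  down <- 360 - a                            # excess below the lower edge
  excess_deg <- ifelse(inside, 0, pmin(up, down))
  sgn <- ifelse(inside, 0, ifelse(up < down, 1, -1))
  excess <- deg2rad(excess_deg)
  list(energy = r$w_dih * excess^4,
       dE_dgamma = sgn * 4 * r$w_dih * excess^3)
}

#' Cross-linking reagent specification
#'
#' Captures a reagent's residue-pair specificity, the contact-distance
#' boundaries its geometry imposes on the side-chain-center distance, and
#' the maximum alpha-carbon span used in violation analysis
#' (`d_u + 2 * sc_reach`, with `sc_reach` the alpha-carbon-to-side-chain-end
#' reach of the reactive residue, 6.4 angstrom for lysine by default).
#'
#' @param name reagent name.
#' @param pair_specificity character vector of allowed unordered one-letter
#'   residue-type pairs, e.g. `c("K-K")`.
#' @param d_u upper contact-distance boundary (angstrom).
#' @param d_l lower boundary (angstrom), default 2.5.
#' @param sc_reach side-chain reach used for the maximum alpha-carbon span
#'   (angstrom), default 6.4.
#' @return object of class `reagent_spec` with a derived `max_ca_span`.
#' @export
reagent_spec <- function(name, pair_specificity, d_u, d_l = 2.5,
                         sc_reach = 6.4) {
  if (d_u <= d_l) stop("parameter error: need d_u > d_l", call. = FALSE)
  structure(list(name = name, pair_specificity = pair_specificity,
                 d_l = d_l, d_u = d_u, sc_reach = sc_reach,
                 max_ca_span = d_u + 2 * sc_reach),
            class = "reagent_spec")
}

#' Built-in reagent presets
#'
#' Upper contact-distance boundaries by reagent maximum dimension:
#' TATA 4, SDA 5, ABAS and DSG 6, DSA 7, BS3 12, and the disulfide
#' pseudo-reagent SS 4.5 angstrom; `d_l = 2.5` throughout.  Amine-reactive
#' NHS-ester reagents (DSG, DSA, BS3, and both arms of TATA) pair lysines;
#' SDA's photo arm is modeled against Ser/Cys/Met/Thr/Glu; ABAS's photo arm
#' is unrestricted; SS pairs cysteines (reach 2.8 angstrom).
#'
#' @return named list of [reagent_spec()] objects.
#' @export
reagent_presets <- function() {
  others <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
              "M", "F", "P", "S", "T", "W", "Y", "V")
  list(
    TATA = reagent_spec("TATA", "K-K", d_u = 4),
    SDA  = reagent_spec("SDA", paste0("K-", c("S", "C", "M", "T", "E")),
                        d_u = 5),
    ABAS = reagent_spec("ABAS", paste0("K-", others), d_u = 6),
    DSG  = reagent_spec("DSG", "K-K", d_u = 6),
    DSA  = reagent_spec("DSA", "K-K", d_u = 7),
    BS3  = reagent_spec("BS3", "K-K", d_u = 12),
    SS   = reagent_spec("SS", "C-C", d_u = 4.5, sc_reach = 2.8))
}

pair_allowed <- function(spec, aa_i, aa_j) {
  paste(aa_i, aa_j, sep = "-") %in% spec$pair_specificity ||
    paste(aa_j, aa_i, sep = "-") %in% spec$pair_specificity
}

#' Composite restraint energy of a chain
#'
#' Sums the cross-link penalty terms and the backbone dihedral penalty terms
#' over a chain.  (In full-model refinement this sum extends a physical
#' force field; here the force-field term is outside scope and contributes
#' zero, or is supplied as a tether by [restrained_minimize()].)
#'
#' @param chain a [cg_chain()].
#' @param xlinks an [xlink_set()].
#' @param potentials either one potential description applied to every link
#'   or a list with one per link; each is `list(type, params)` with `type`
#'   one of `"lorentz"` (acts on the side-chain-center distance),
#'   `"statistical"` (alpha-carbon distance) or `"mdbased"` (anchor
#'   geometry).
#' @param dihedral_restraints list of `list(i = resno, restraint =
#'   dihedral_restraint)` entries; each acts on the backbone virtual-bond
#'   dihedral starting at residue `i`.
#' @return list with `total` (kcal/mol) and a `breakdown` data frame
#'   (term, i, j, coordinate value, energy).
#' @export
total_restraint_energy <- function(chain, xlinks, potentials,
                                   dihedral_restraints = list()) {
  nl <- if (is.null(xlinks)) 0L else nrow(xlinks)
  pots <- if (nl > 0 && !is.null(potentials) && !is.null(potentials$type)) {
    rep(list(potentials), nl)
  } else {
    potentials
  }
  if (nl > 0) {
    bad <- setdiff(unique(c(xlinks$i, xlinks$j)), chain$resno)
    if (length(bad) > 0) {
      stop("mapping error: residue number(s) not in chain: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (length(pots) != nl) stop("parameter error: one potential per link needed",
                                 call. = FALSE)
  }
  rows <- list()
  total <- 0
  for (k in seq_len(nl)) {
    pk <- pots[[k]]
    i <- xlinks$i[k]; j <- xlinks$j[k]
    res <- switch(pk$type,
      lorentz = {
        dd <- sc_distance(chain, i, j)
        c(dd, lorentz_energy(dd, pk$params)$energy)
      },
      statistical = {
        dd <- ca_distance(chain, i, j)
        c(dd, statistical_energy(dd, pk$params)$energy)
      },
      mdbased = {
        geo <- xlink_geometry(chain, i, j, pk$params$d_Xi, pk$params$d_Xj)
        c(geo$d, mdbased_energy(geo, pk$params)$energy)
      },
      stop("parameter error: unknown potential type '", pk$type, "'",
           call. = FALSE))
    total <- total + res[2]
    rows[[length(rows) + 1]] <- data.frame(
      term = pk$type, i = i, j = j, coord = res[1], energy = res[2])
  }
  for (dr in dihedral_restraints) {
    gam <- rad2deg(backbone_dihedral(chain, dr$i))
    if (is.na(gam)) next
    e <- dihedral_penalty(gam, dr$restraint)$energy
    total <- total + e
    rows[[length(rows) + 1]] <- data.frame(
      term = "dihedral", i = dr$i, j = NA_integer_, coord = gam, energy = e)
  }
  breakdown <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(term = character(), i = integer(), j = integer(),
               coord = numeric(), energy = numeric())
  list(total = total, breakdown = breakdown)
}

#' Read and write potential parameter files (JSON)
#'
#' Schema: `{"schema_version": 1, "reagent": ..., "potential_type":
#' "lorentz"|"statistical"|"mdbased", "params": {...}}`.  Nothing numeric is
#' hard-coded beyond the documented defaults; fitted coefficient tables are
#' expected to be distributed this way.
#'
#' @param path JSON file path.
#' @return `read_potential_json`: a list with `reagent`, `type` and a
#'   constructed `params` object.
#' @export
read_potential_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema_version) || obj$schema_version != 1) {
    stop("parameter error: unsupported schema_version", call. = FALSE)
  }
  p <- obj$params
  params <- switch(obj$potential_type,
    lorentz = lorentz_params(d_u = p$d_u, sigma = p$sigma, A = p$A,
                             d_l = p$d_l %||% 2.5),
    statistical = statistical_params(a = p$a, b = p$b, c = p$c,
                                     sigma = p$sigma, A = p$A %||% 15,
                                     RT = p$RT %||% 0.591),
    mdbased = {
      as_terms <- function(x) {
        if (is.matrix(x)) x else matrix(unlist(x), ncol = 3, byrow = TRUE)
      }
      mdbased_params(
        d_Xi = p$d_Xi, d_Xj = p$d_Xj,
        dist_terms = as_terms(p$dist_terms),
        angle_terms_i = as_terms(p$angle_terms_i),
        angle_terms_j = as_terms(p$angle_terms_j),
        dihedral_terms = as_terms(p$dihedral_terms),
        const = p$const %||% 0)
    },
    stop("parameter error: unknown potential_type", call. = FALSE))
  list(reagent = obj$reagent, type = obj$potential_type, params = params)
}

#' @rdname read_potential_json
#' @param reagent reagent name recorded in the file.
#' @param type one of `"lorentz"`, `"statistical"`, `"mdbased"`.
#' @param params the matching parameter object.
#' @export
write_potential_json <- function(path, reagent, type, params) {
  p <- unclass(params)
  if (type == "mdbased") {
    strip <- function(m) `dimnames<-`(m, NULL)
    p$dist_terms <- strip(p$dist_terms)
    p$angle_terms_i <- strip(p$angle_terms_i)
    p$angle_terms_j <- strip(p$angle_terms_j)
    p$dihedral_terms <- strip(p$dihedral_terms)
  }
  jsonlite::write_json(
    list(schema_version = 1, reagent = reagent, potential_type = type,
         params = p),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
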