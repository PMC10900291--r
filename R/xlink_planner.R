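#' Construct a cross-link set
#'
#' A cross-link set is a data frame with one row per link: residue pair
#' (author numbering), reagent name, and an identification confidence in
#' [0, 1].  Duplicate unordered (i, j, reagent) triples and self-links are
#' rejected.
#'
#' @param i,j integer vectors of author residue numbers.
#' @param reagent character vector of reagent names (recycled).
#' @param confidence numeric vector in [0, 1] (recycled), default 1.
#' @param protein_id identifier attached to the set.
#' @return data frame of class `xlink_set`.
#' @export
xlink_set <- function(i, j, reagent = "BS3", confidence = 1,
                      protein_id = "") {
  n <- length(i)
  stopifnot(length(j) == n)
  df <- data.frame(i = as.integer(i), j = as.integer(j),
                   reagent = rep_len(as.character(reagent), n),
                   confidence = rep_len(as.numeric(confidence), n))
  if (any(df$i == df$j)) stop("self-link: i == j not allowed", call. = FALSE)
  if (any(df$confidence < 0 | df$confidence > 1)) {
    stop("confidence must lie in [0, 1]", call. = FALSE)
  }
  key <- paste(pmin(df$i, df$j), pmax(df$i, df$j), df$reagent)
  if (anyDuplicated(key)) stop("duplicate cross-link(s) in set", call. = FALSE)
  attr(df, "protein_id") <- protein_id
  class(df) <- c("xlink_set", "data.frame")
  df
}

#' Topological length of cross-links
#'
#' The topological length of a link between residues i and j is the residue
#' index difference |j - i| (default); the alternative loop-size convention
#' |j - i| + 1 counts both end residues of the closed loop.
#'
#' @param set an [xlink_set()] (or any data frame with `i`, `j`).
#' @param convention `"index_diff"` (default) or `"loop_size"`.
#' @return integer vector of per-link lengths.
#' @export
topological_length <- function(set, convention = c("index_diff", "loop_size")) {
  convention <- match.arg(convention)
  L <- abs(set$j - set$i)
  if (convention == "loop_size") L <- L + 1L
  as.integer(L)
}

#' Sum of topological lengths of a cross-link set
#'
#' @inheritParams topological_length
#' @return integer, 0 for an empty set.
#' @export
sigma_L <- function(set, convention = c("index_diff", "loop_size")) {
  if (is.null(set) || nrow(set) == 0) return(0L)
  sum(topological_length(set, convention))
}

#' Predict the model-improvement capacity of a cross-link set
#'
#' A cross-link set whose sum of topological lengths exceeds 150 (strictly)
#' is classified as high-capacity: in restrained coarse-grained modeling
#' such sets consistently improve model quality, because they pin down many
#' or long-range contacts that force-field errors would otherwise distort.
#' Sets at or below the threshold are low-capacity; they can still help when
#' the few links happen to define the fold topology.
#'
#' @param set an [xlink_set()].
#' @param threshold strict classification threshold, default 150.
#' @param convention passed to [sigma_L()].
#' @return list with `class` (`"high-capacity"`/`"low-capacity"`),
#'   `sigma_L`, `n_links`, `max_L`.
#' @export
predict_improvement <- function(set, threshold = 150,
                                convention = "index_diff") {
  sl <- sigma_L(set, convention)
  n <- if (is.null(set)) 0L else nrow(set)
  list(class = if (sl > threshold) "high-capacity" else "low-capacity",
       sigma_L = sl, n_links = n,
       max_L = if (n > 0) max(topological_length(set, convention)) else 0L)
}

#' Relative side-chain accessibility on the coarse-grained sphere model
#'
#' Shrake-Rupley-style accessibility computed directly on the two-sphere
#' representation: each residue contributes an alpha-carbon sphere and a
#' side-chain sphere; test points on the probe-inflated side-chain sphere
#' are counted accessible when outside every other site's probe-inflated
#' sphere.  The value is normalized by the accessibility of the same
#' residue isolated from the rest of the chain (its own alpha-carbon sphere
#' only), approximating a fully extended reference.
#'
#' @param chain a [cg_chain()].
#' @param probe probe radius (angstrom), default 1.4.
#' @param r_ca,r_sc site sphere radii (angstrom), defaults 2.2 and 3.0.
#' @param n_points number of test points per sphere (Fibonacci lattice),
#'   default 128.
#' @return numeric vector of relative accessibilities in [0, 1], one per
#'   residue.
#' @export
cg_exposure <- function(chain, probe = 1.4, r_ca = 2.2, r_sc = 3.0,
                        n_points = 128) {
  n <- n_res(chain)
  pts <- fibonacci_sphere(n_points)
  centers <- rbind(chain$ca, chain$sc)
  radii <- c(rep(r_ca + probe, n), rep(r_sc + probe, n))
  rel <- numeric(n)
  for (k in seq_len(n)) {
    test <- sweep(pts * (r_sc + probe), 2, chain$sc[k, ], `+`)
    own_ca <- rowSums(sweep(test, 2, chain$ca[k, ], `-`)^2) <
      (r_ca + probe)^2 - 1e-9
    occluders <- setdiff(seq_len(2 * n), c(k + n))
    buried <- own_ca
    for (o in occluders) {
      if (o == k) next  # own CA already handled
      d2 <- rowSums(sweep(test, 2, centers[o, ], `-`)^2)
      buried <- buried | d2 < radii[o]^2 - 1e-9
    }
    denom <- sum(!own_ca)
    rel[k] <- if (denom == 0) 0 else sum(!buried) / denom
  }
  rel
}

fibonacci_sphere <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Enumerate cross-linkable residue pairs of a structure
#'
#' A residue pair is cross-linkable by a reagent when (a) the residue types
#' form an allowed pair for the reagent, (b) the side-chain-center distance
#' does not exceed the reagent's upper contact boundary `d_u`, and (c) both
#' side chains are surface-exposed (relative CG-sphere accessibility at or
#' above the threshold).
#'
#' @param chain a [cg_chain()].
#' @param reagent a [reagent_spec()].
#' @param exposure_threshold minimum relative accessibility, default 0.2.
#' @param exposure optional precomputed [cg_exposure()] vector (saves
#'   recomputation when planning several reagents).
#' @return an [xlink_set()] (possibly empty) with confidence 1.
#' @export
find_crosslinkable_pairs <- function(chain, reagent, exposure_threshold = 0.2,
                                     exposure = NULL) {
  stopifnot(inherits(reagent, "reagent_spec"))
  n <- n_res(chain)
  if (is.null(exposure)) exposure <- cg_exposure(chain)
  ok_res <- exposure >= exposure_threshold
  pairs_i <- integer(); pairs_j <- integer()
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      if (!pair_allowed(reagent, chain$aa[a], chain$aa[b])) next
      if (!(ok_res[a] && ok_res[b])) next
      d <- vec_norm(chain$sc[b, ] - chain$sc[a, ])
      if (d > reagent$d_u) next
      pairs_i <- c(pairs_i, chain$resno[a])
      pairs_j <- c(pairs_j, chain$resno[b])
    }
  }
  if (length(pairs_i) == 0) {
    message("no cross-linkable pairs for reagent ", reagent$name)
    return(xlink_set(integer(), integer(), character(), numeric()))
  }
  xlink_set(pairs_i, pairs_j, reagent$name, 1)
}

#' Violation census of a cross-link set against a structure
#'
#' For every link, the alpha-carbon distance in the (reference) structure is
#' compared with the maximum alpha-carbon span of the reagent
#' (`d_u + 2 * sc_reach`); the excess is their difference.  Links whose
#' excess is greater than a margin could only have been captured through
#' large fluctuations or distortion of the structure and are, from the
#' modeling point of view, false restraints — they are counted, never
#' deleted.
#'
#' @param chain a [cg_chain()] (typically the reference structure).
#' @param set an [xlink_set()].
#' @param margins census margins in angstrom, default `c(5, 10)`.
#' @param reagents named list of [reagent_spec()]s, default
#'   [reagent_presets()].
#' @return object of class `violation_report`: `per_link` data frame (i, j,
#'   reagent, ca_distance, max_length, excess), `counts` named integer
#'   vector (`n_total`, `n_over_<margin>` per margin), `margins`, and
#'   `unresolved` (links excluded because a residue is absent).
#' @export
violation_report <- function(chain, set, margins = c(5, 10),
                             reagents = reagent_presets()) {
  resolvable <- set$i %in% chain$resno & set$j %in% chain$resno
  unresolved <- set[!resolvable, , drop = FALSE]
  if (nrow(unresolved) > 0) {
    warning(sprintf("%d link(s) with unresolvable residue(s) excluded",
                    nrow(unresolved)))
  }
  use <- set[resolvable, , drop = FALSE]
  nr <- nrow(use)
  per <- data.frame(i = use$i, j = use$j, reagent = use$reagent,
                    ca_distance = rep(NA_real_, nr),
                    max_length = rep(NA_real_, nr),
                    excess = rep(NA_real_, nr))
  for (k in seq_len(nrow(use))) {
    spec <- reagents[[use$reagent[k]]]
    if (is.null(spec)) stop("unknown reagent '", use$reagent[k], "'",
                            call. = FALSE)
    per$ca_distance[k] <- ca_distance(chain, use$i[k], use$j[k])
    per$max_length[k] <- spec$max_ca_span
    per$excess[k] <- per$ca_distance[k] - per$max_length[k]
  }
  counts <- c(n_total = nrow(per),
              vapply(margins, function(m) sum(per$excess > m), integer(1)))
  names(counts)[-1] <- paste0("n_over_", margins)
  structure(list(per_link = per, counts = counts, margins = margins,
                 unresolved = unresolved),
            class = "violation_report")
}

#' @export
print.violation_report <- function(x, ...) {
  cat(sprintf("violation report: %d link(s)\n", x$counts[["n_total"]]))
  for (m in x$margins) {
    cat(sprintf("  excess > %g angstrom: %d\n", m,
                x$counts[[paste0("n_over_", m)]]))
  }
  invisible(x)
}

#' Read and write cross-link tables (TSV)
#'
#' Dialect: tab-separated with header `protein res_i res_j reagent
#' confidence` (confidence optional, default 1.0); author residue
#' numbering.  Malformed rows are rejected with their line number.
#'
#' @param path TSV file path.
#' @return `read_xlinks`: an [xlink_set()]; the protein id is taken from the
#'   first row.
#' @export
read_xlinks <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("protein", "res_i", "res_j", "reagent")
  if (!all(need %in% names(df))) {
    stop("cross-link table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (is.null(df$confidence)) df$confidence <- 1.0
  for (r in seq_len(nrow(df))) {
    line <- r + 1  # header is line 1
    i <- suppressWarnings(as.integer(df$res_i[r]))
    j <- suppressWarnings(as.integer(df$res_j[r]))
    if (is.na(i) || is.na(j)) {
      stop(sprintf("malformed row at line %d: non-integer residue index", line),
           call. = FALSE)
    }
    if (i == j) {
      stop(sprintf("malformed row at line %d: i == j (%d)", line, i),
           call. = FALSE)
    }
    conf <- suppressWarnings(as.numeric(df$confidence[r]))
    if (is.na(conf) || conf < 0 || conf > 1) {
      stop(sprintf("malformed row at line %d: confidence outside [0, 1]", line),
           call. = FALSE)
    }
  }
  xlink_set(as.integer(df$res_i), as.integer(df$res_j), df$reagent,
            as.numeric(df$confidence), protein_id = df$protein[1])
}

#' @rdname read_xlinks
#' @param set an [xlink_set()].
#' @export
write_xlinks <- function(set, path) {
  df <- data.frame(protein = attr(set, "protein_id") %||% "",
                   res_i = set$i, res_j = set$j, reagent = set$reagent,
                   confidence = set$confidence)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
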