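#' Coarse-grained two-center chain representation
#'
#' A `cg_chain` stores, for every residue of a single protein chain, the
#' alpha-carbon position and the side-chain heavy-atom centroid (the
#' "side-chain center", SC).  This two-center-per-residue representation is
#' the geometry on which all cross-link restraints in this package act.
#'
#' Conventions: glycine has no side-chain heavy atoms, so its SC coincides
#' with the alpha carbon; alanine's SC is its C-beta.  Author (PDB) residue
#' numbering is preserved for cross-link matching; positional 0-based offsets
#' are only used internally.
#'
#' @param resno integer vector of author residue numbers, strictly increasing.
#' @param aa character vector of one-letter amino-acid codes.
#' @param ca n x 3 numeric matrix of alpha-carbon coordinates (angstrom).
#' @param sc n x 3 numeric matrix of side-chain-center coordinates (angstrom).
#' @param chain_id single chain identifier string.
#' @return an object of class `cg_chain`.
#' @export
cg_chain <- function(resno, aa, ca, sc, chain_id = "A") {
  ca <- as.matrix(ca)
  sc <- as.matrix(sc)
  n <- length(resno)
  stopifnot(n >= 1, length(aa) == n, nrow(ca) == n, nrow(sc) == n,
            ncol(ca) == 3, ncol(sc) == 3)
  if (n > 1 && any(diff(resno) <= 0)) {
    stop("residue numbering must be strictly increasing along the chain")
  }
  if (n > 1) {
    dca <- sqrt(rowSums((ca[-1, , drop = FALSE] - ca[-n, , drop = FALSE])^2))
    bad <- which(dca <= 2.0 | dca >= 4.5)
    if (length(bad) > 0) {
      warning(sprintf(
        "%d consecutive Ca-Ca distance(s) outside (2.0, 4.5) angstrom (e.g. %.2f at position %d)",
        length(bad), dca[bad[1]], bad[1]))
    }
  }
  structure(
    list(resno = as.integer(resno), aa = as.character(aa),
         ca = unname(ca), sc = unname(sc), chain_id = chain_id),
    class = "cg_chain")
}

#' @export
print.cg_chain <- function(x, ...) {
  cat(sprintf("cg_chain: %d residues, chain '%s', resno %d..%d\n",
              length(x$resno), x$chain_id, x$resno[1], x$resno[length(x$resno)]))
  invisible(x)
}

#' Number of residues in a coarse-grained chain
#' @param chain a `cg_chain`.
#' @return integer residue count.
#' @export
n_res <- function(chain) length(chain$resno)

# author resno -> internal position; errors listing unresolvable indices
res_index <- function(chain, resno) {
  idx <- match(resno, chain$resno)
  if (anyNA(idx)) {
    stop("mapping error: residue number(s) not in chain: ",
         paste(resno[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  idx
}

backbone_atoms <- c("N", "CA", "C", "O", "OXT")

#' Read an all-atom PDB structure into the coarse-grained representation
#'
#' Parses a PDB file (via \pkg{bio3d}) and reduces one protein chain of one
#' model to alpha-carbon plus side-chain-centroid coordinates.  The
#' side-chain center is the centroid of all heavy atoms beyond the backbone
#' (C-beta and outward); residues with no side-chain heavy atoms fall back to
#' the glycine convention (SC at the alpha carbon), with a warning for
#' non-glycine residues.  Residues lacking an alpha carbon are skipped with a
#' warning.  Alternate locations are resolved by the reader's first-altloc
#' rule; insertion-coded residues are dropped with a warning if they would
#' break strict numbering.
#'
#' @param path PDB file path.
#' @param chain_id chain identifier to extract (default first chain found).
#' @param model_index 1-based model number for multi-model files.
#' @return a [cg_chain()].
#' @export
read_structure <- function(path, chain_id = NULL, model_index = 1) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  if (is.null(chain_id)) chain_id <- at$chain[1]
  if (!chain_id %in% at$chain) {
    stop("chain not found: '", chain_id, "'", call. = FALSE)
  }
  n_models <- nrow(pdb$xyz)
  if (model_index < 1 || model_index > n_models) {
    stop(sprintf("model_index %d out of range (file has %d model(s))",
                 model_index, n_models), call. = FALSE)
  }
  xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)

  keep <- at$chain == chain_id & at$type == "ATOM" &
    !(toupper(at$elesy) %in% c("H", "D"))
  at <- at[keep, , drop = FALSE]
  xyz <- xyz[keep, , drop = FALSE]
  if (nrow(at) == 0) stop("chain not found: no ATOM records in chain '",
                          chain_id, "'", call. = FALSE)

  key <- paste(at$resno, at$insert %||% "", sep = "|")
  ord <- order(match(key, unique(key)))  # file order preserved
  groups <- split(seq_len(nrow(at)), factor(key, levels = unique(key)))

  res_list <- lapply(groups, function(rows) {
    sub <- at[rows, , drop = FALSE]
    co <- xyz[rows, , drop = FALSE]
    ca_row <- which(sub$elety == "CA")
    if (length(ca_row) == 0) {
      warning(sprintf("residue %s %s has no CA atom; skipped",
                      sub$resid[1], sub$resno[1]))
      return(NULL)
    }
    ca <- co[ca_row[1], ]
    side <- which(!(sub$elety %in% backbone_atoms))
    aa1 <- bio3d::aa321(sub$resid[1])
    if (length(side) == 0) {
      if (!identical(aa1, "G")) {
        warning(sprintf(
          "residue %s %s has no side-chain heavy atoms; SC set to CA",
          sub$resid[1], sub$resno[1]))
      }
      sc <- ca
    } else {
      sc <- colMeans(co[side, , drop = FALSE])
    }
    list(resno = sub$resno[1], aa = aa1, ca = ca, sc = sc)
  })
  res_list <- Filter(Negate(is.null), res_list)
  res_list <- Filter(function(r) r$aa != "X", res_list)  # non-standard skipped
  if (length(res_list) == 0) stop("no standard amino-acid residues with CA in chain",
                                  call. = FALSE)
  resno <- vapply(res_list, `[[`, integer(1), "resno")
  dup <- duplicated(resno)
  if (any(dup)) {
    warning(sprintf("%d insertion-coded duplicate residue number(s) dropped",
                    sum(dup)))
    res_list <- res_list[!dup]
    resno <- resno[!dup]
  }
  cg_chain(
    resno = resno,
    aa = vapply(res_list, `[[`, character(1), "aa"),
    ca = do.call(rbind, lapply(res_list, `[[`, "ca")),
    sc = do.call(rbind, lapply(res_list, `[[`, "sc")),
    chain_id = chain_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cross-link anchor point on the Ca -> SC axis
#'
#' The cross-link is attached not at the side-chain center but at an anchor
#' point located on the line from the alpha carbon through the side-chain
#' center, at distance `d_X` from the alpha carbon.  Offsets larger than
#' |SC - Ca| place the anchor beyond the side-chain center, which is allowed.
#'
#' @param ca,sc 3-vectors: alpha-carbon and side-chain-center positions.
#' @param d_X anchor offset from the alpha carbon along the axis (angstrom).
#' @param fallback_axis optional unit 3-vector used when |sc - ca| = 0
#'   (glycine); without it a zero-length axis is an error.
#' @return 3-vector anchor position.
#' @export
anchor_point <- function(ca, sc, d_X, fallback_axis = NULL) {
  if (d_X == 0) return(ca)
  axis <- sc - ca
  if (vec_norm(axis) == 0) {
    if (is.null(fallback_axis)) stop("degenerate axis", call. = FALSE)
    axis <- fallback_axis
  }
  ca + d_X * unit_vec(axis)
}

#' Cross-link internal-coordinate geometry between two residues
#'
#' Computes the five internal coordinates on which the MD-based cross-link
#' potentials depend: the anchor-anchor distance d(Xi,Xj), the two planar
#' angles Ca_i-Xi-Xj and Ca_j-Xj-Xi, and the Ca_i-Xi-Xj-Ca_j virtual-bond
#' dihedral (right-handed, reported in (-pi, pi]).  When either angle triple
#' is collinear the dihedral is undefined and reported as `NA`; the distance
#' and angles are still returned.
#'
#' @param chain a [cg_chain()].
#' @param i,j author residue numbers of the linked residues.
#' @param d_Xi,d_Xj anchor offsets from the respective alpha carbons
#'   (angstrom).
#' @return an object of class `xl_geometry`: list with `d` (anchor-anchor
#'   distance), `theta_i`, `theta_j`, `gamma` (radians; `NA` if degenerate),
#'   `d_Xi`, `d_Xj`.
#' @export
xlink_geometry <- function(chain, i, j, d_Xi, d_Xj) {
  if (i == j) stop("i and j must differ", call. = FALSE)
  pi_ <- res_index(chain, i)
  pj_ <- res_index(chain, j)
  ca_i <- chain$ca[pi_, ]; sc_i <- chain$sc[pi_, ]
  ca_j <- chain$ca[pj_, ]; sc_j <- chain$sc[pj_, ]
  xi <- anchor_point(ca_i, sc_i, d_Xi)
  xj <- anchor_point(ca_j, sc_j, d_Xj)
  safe_angle <- function(a, b, c) {
    if (vec_norm(a - b) < 1e-8 || vec_norm(c - b) < 1e-8) return(NA_real_)
    angle_at(a, b, c)
  }
  structure(list(
    d = vec_norm(xj - xi),
    theta_i = safe_angle(ca_i, xi, xj),
    theta_j = safe_angle(ca_j, xj, xi),
    gamma = torsion(ca_i, xi, xj, ca_j),
    d_Xi = d_Xi, d_Xj = d_Xj), class = "xl_geometry")
}

#' Pairwise distances and backbone virtual-bond dihedral
#'
#' `sc_distance` and `ca_distance` return the Euclidean distance between the
#' side-chain centers / alpha carbons of residues `i` and `j` (author
#' numbering).  `backbone_dihedral` returns the virtual-bond dihedral defined
#' by the four consecutive alpha carbons starting at residue `i`, in
#' (-pi, pi].
#'
#' @param chain a [cg_chain()].
#' @param i,j author residue numbers.
#' @return distance in angstrom, or dihedral in radians.
#' @export
sc_distance <- function(chain, i, j) {
  p <- res_index(chain, c(i, j))
  vec_norm(chain$sc[p[2], ] - chain$sc[p[1], ])
}

#' @rdname sc_distance
#' @export
ca_distance <- function(chain, i, j) {
  p <- res_index(chain, c(i, j))
  vec_norm(chain$ca[p[2], ] - chain$ca[p[1], ])
}

#' @rdname sc_distance
#' @export
backbone_dihedral <- function(chain, i) {
  p <- res_index(chain, i)
  if (p + 3 > n_res(chain)) {
    stop("index error: backbone dihedral needs residues i..i+3", call. = FALSE)
  }
  torsion(chain$ca[p, ], chain$ca[p + 1, ], chain$ca[p + 2, ], chain$ca[p + 3, ])
}

#' Write a coarse-grained chain as a minimal PDB file
#'
#' Emits one CA record per residue plus one side-chain pseudo-atom named
#' `SC` (skipped for glycine, whose SC coincides with CA), suitable for
#' visualization.  Not intended for round-tripping through
#' [read_structure()]; the fixture writer [write_toy_pdb()] serves that
#' purpose.
#'
#' @param chain a [cg_chain()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cg_pdb <- function(chain, path) {
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  aa3 <- vapply(chain$aa, bio3d::aa123, character(1))
  for (k in seq_len(n_res(chain))) {
    serial <- serial + 1L
    writeLines(pdb_atom_line(serial, "CA", aa3[k], chain$chain_id,
                             chain$resno[k], chain$ca[k, ], "C"), con)
    if (chain$aa[k] != "G") {
      serial <- serial + 1L
      writeLines(pdb_atom_line(serial, "SC", aa3[k], chain$chain_id,
                               chain$resno[k], chain$sc[k, ], "C"), con)
    }
  }
  writeLines("TER", con)
  writeLines("END", con)
  invisible(path)
}

pdb_atom_line <- function(serial, name, resid, chain, resno, xyz, elem) {
  name_fmt <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name_fmt, resid, chain, resno,
          xyz[1], xyz[2], xyz[3], 1.00, 0.00, elem)
}

#' Apply a rigid motion to a coarse-grained chain
#'
#' @param chain a [cg_chain()].
#' @param rotation 3 x 3 rotation matrix.
#' @param translation 3-vector (angstrom).
#' @return transformed `cg_chain`.
#' @export
transform_chain <- function(chain, rotation = diag(3), translation = c(0, 0, 0)) {
  chain$ca <- sweep(chain$ca %*% t(rotation), 2, translation, `+`)
  chain$sc <- sweep(chain$sc %*% t(rotation), 2, translation, `+`)
  chain
}
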