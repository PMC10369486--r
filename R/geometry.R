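# Torsion geometry: signed dihedrals (IUPAC right-hand convention) and
# internal-coordinate atom placement (NeRF), the two primitives behind both
# Chi extraction and the synthetic peptide builder.

.cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

.vnorm <- function(v) sqrt(sum(v * v))

#' Normalize an angle into (-180, +180]
#'
#' The trans boundary is reported as +180, never -180, so that a single
#' representative exists for the trans state.
#'
#' @param x angle(s) in degrees.
#' @return angle(s) in `(-180, 180]`.
#' @export
normalize_angle <- function(x) {
  out <- ((x + 180) %% 360) - 180
  out[out <= -180 + 1e-12] <- 180
  # map values that landed exactly on -180 by floating error
  out[abs(out + 180) < 1e-9] <- 180
  out
}

#' Signed dihedral angle of four points
#'
#' Right-hand (IUPAC) sign convention: the cis arrangement is 0 degrees and
#' trans is reported as +180.
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinate vectors (Angstrom).
#' @return torsion in degrees, in `(-180, 180]`.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  if (.vnorm(n1) < 1e-10 || .vnorm(n2) < 1e-10) {
    stop("undefined torsion: three consecutive points are collinear")
  }
  b2u <- b2 / .vnorm(b2)
  m1 <- .cross3(n1, b2u)
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  normalize_angle(ang)
}

#' Place an atom from internal coordinates
#'
#' Given three reference positions `a`, `b`, `c`, returns the position `d`
#' such that `|c-d| = bond_length`, the angle b-c-d equals `bond_angle` and
#' the dihedral a-b-c-d equals `torsion` (NeRF construction).
#'
#' @param a,b,c numeric length-3 reference positions.
#' @param bond_length distance c-d in Angstrom (> 0).
#' @param bond_angle angle b-c-d in degrees, in (0, 180).
#' @param torsion dihedral a-b-c-d in degrees.
#' @return numeric length-3 position of the new atom.
#' @export
place_atom <- function(a, b, c, bond_length, bond_angle, torsion) {
  stopifnot(bond_length > 0, bond_angle > 0, bond_angle < 180)
  bc <- c - b
  nbc <- .vnorm(bc)
  ab <- b - a
  n <- .cross3(ab, bc)
  if (nbc < 1e-10 || .vnorm(n) < 1e-10) {
    stop("cannot place atom: reference frame is degenerate (collinear points)")
  }
  bcu <- bc / nbc
  nu <- n / .vnorm(n)
  mu <- .cross3(nu, bcu)
  th <- bond_angle * pi / 180
  ph <- torsion * pi / 180
  d2 <- bond_length * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  c + d2[1] * bcu + d2[2] * mu + d2[3] * nu
}

#' Load the per-amino-acid Chi torsion atom definitions
#'
#' Standard IUPAC atom quadruples per residue type, shipped as the versioned
#' fixture `chi_definitions.tsv`. ALA and GLY have no Chi angles; ARG is
#' defined through Chi4 only (the guanidinium Chi5 is excluded from the
#' analysis).
#'
#' @param path optional path to an alternative definitions table.
#' @return data frame with columns `aa`, `chi`, `a1`..`a4`, `symmetric`
#'   (logical: terminal torsion of a two-fold symmetric branch).
#' @export
chi_definitions <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "chi_definitions.tsv", package = "rotaudit")
  }
  defs <- utils::read.delim(path, stringsAsFactors = FALSE)
  defs$symmetric <- as.logical(defs$symmetric)
  defs
}

#' Number of Chi angles per amino acid
#' @param aa three-letter amino-acid code(s).
#' @param defs Chi definition table from [chi_definitions()].
#' @return integer vector (0 for ALA/GLY).
#' @export
n_chi <- function(aa, defs = chi_definitions()) {
  tab <- table(factor(defs$aa, levels = unique(defs$aa)))
  out <- as.integer(tab[aa])
  out[is.na(out)] <- 0L
  out
}

#' Compute the Chi torsion vector of one residue
#'
#' @param res_atoms data frame of the residue's atoms with columns `name`,
#'   `x`, `y`, `z` (one row per atom, names unique).
#' @param aa three-letter code of the residue.
#' @param defs Chi definition table.
#' @return list with `values` (degrees, `NA` where atoms are missing) and
#'   `defined` (logical mask). ALA/GLY return zero-length vectors.
#' @export
compute_chis <- function(res_atoms, aa, defs = chi_definitions()) {
  rows <- defs[defs$aa == aa, , drop = FALSE]
  k <- nrow(rows)
  if (k == 0L) {
    return(list(values = numeric(0), defined = logical(0)))
  }
  values <- rep(NA_real_, k)
  defined <- rep(FALSE, k)
  pos <- function(nm) {
    i <- match(nm, res_atoms$name)
    if (is.na(i)) NULL else c(res_atoms$x[i], res_atoms$y[i], res_atoms$z[i])
  }
  for (j in seq_len(k)) {
    ps <- lapply(unlist(rows[j, c("a1", "a2", "a3", "a4")]), pos)
    if (!any(vapply(ps, is.null, logical(1)))) {
      values[j] <- dihedral(ps[[1]], ps[[2]], ps[[3]], ps[[4]])
      defined[j] <- TRUE
    }
  }
  list(values = values, defined = defined)
}

# Atom-name sets a residue must resolve for all its torsion computations:
# its own backbone torsion atoms (N, CA, C) plus every side-chain Chi atom.
.torsion_atom_names <- function(aa, defs = chi_definitions()) {
  rows <- defs[defs$aa == aa, , drop = FALSE]
  unique(c("N", "CA", "C", unlist(rows[, c("a1", "a2", "a3", "a4")],
                                  use.names = FALSE)))
}
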