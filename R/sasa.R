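# Solvent accessible surface area (Shrake-Rupley sphere sampling),
# accessibility binning, and secondary-structure ingestion.

#' Deterministic quasi-uniform points on the unit sphere
#'
#' Fibonacci (golden-section) spiral; deterministic, so repeated runs give
#' byte-identical accessibility values.
#'
#' @param n number of points.
#' @return `n x 3` matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-element van der Waals radii table
#' @param path optional alternative `radii.tsv`.
#' @return named numeric vector (Angstrom).
#' @export
vdw_radii <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "radii.tsv", package = "rotaudit")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(tab$radius, tab$element)
}

#' Per-residue solvent accessible surface area
#'
#' Shrake-Rupley sampling: each atom's sphere (vdW radius + probe) is
#' covered with `n_points` quasi-uniform points; points falling inside any
#' neighbouring atom's probe-expanded sphere are occluded. Residue ACC is
#' the sum over the residue's atoms.
#'
#' @param structure a `rotaudit_structure` (heavy atoms).
#' @param probe probe radius in Angstrom (default 1.4, water).
#' @param n_points sample points per atom (default 960).
#' @param radii named per-element radius vector, see [vdw_radii()].
#' @return data frame (`chain`, `seq_id`, `ins`, `aa`, `acc`) with
#'   attributes `method = "internal_sr"` and `probe_radius`.
#' @export
shrake_rupley_acc <- function(structure, probe = 1.4, n_points = 960,
                              radii = vdw_radii()) {
  a <- structure$atom
  unknown <- setdiff(unique(a$element), names(radii))
  if (length(unknown)) {
    stop("no van der Waals radius for element(s): ",
         paste(unknown, collapse = ", "))
  }
  r <- unname(radii[a$element]) + probe
  xyz <- as.matrix(a[, c("x", "y", "z")])
  n <- nrow(xyz)
  pts <- sphere_points(n_points)
  area <- numeric(n)
  maxr <- max(r)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (r[i] + maxr)^2 & d2 > 1e-12)
    nb <- nb[sqrt(d2[nb]) < r[i] + r[nb]]
    p <- sweep(pts * r[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(free)) break
      dj <- (p[free, 1] - xyz[j, 1])^2 + (p[free, 2] - xyz[j, 2])^2 +
        (p[free, 3] - xyz[j, 3])^2
      free[free] <- dj > r[j]^2
    }
    # twin atoms at identical coordinates bury each other completely
    if (any(d2 <= 1e-12 & seq_len(n) != i)) free[] <- FALSE
    area[i] <- 4 * pi * r[i]^2 * mean(free)
  }
  key <- paste(a$chain, a$seq_id, a$ins, sep = "|")
  ri <- .residue_index(structure)
  acc <- vapply(ri$key, function(k) sum(area[key == k]), numeric(1))
  out <- data.frame(ri[, c("chain", "seq_id", "ins", "aa")],
                    acc = unname(acc), stringsAsFactors = FALSE)
  attr(out, "method") <- "internal_sr"
  attr(out, "probe_radius") <- probe
  out
}

#' Convert an accessibility score to contacting water molecules
#'
#' One water molecule corresponds to about 9.65 Angstrom^2 of accessible
#' surface.
#'
#' @param acc accessibility in Angstrom^2 (non-negative).
#' @return approximate number of water molecules (real-valued).
#' @export
acc_to_waters <- function(acc) {
  if (any(acc < 0, na.rm = TRUE)) stop("negative accessibility")
  acc / 9.65
}

#' Accessibility category
#'
#' `zero` (ACC = 0), `low` (0, 50], `medium` (50, 100], `high` (> 100)
#' Angstrom^2.
#'
#' @param acc accessibility in Angstrom^2 (vectorized, non-negative).
#' @return factor with levels zero/low/medium/high.
#' @export
acc_category <- function(acc) {
  if (any(acc < 0, na.rm = TRUE)) stop("negative accessibility")
  cut(acc, breaks = c(-Inf, 0, 50, 100, Inf),
      labels = c("zero", "low", "medium", "high"))
}

#' Accessibility bin label
#'
#' 20-Angstrom^2 bins labelled by their lower limit (left-closed), covering
#' 0 to 320; larger values fall into the `">320"` overflow bin.
#'
#' @param acc accessibility in Angstrom^2 (vectorized).
#' @param width bin width (default 20).
#' @param cap upper limit of the binned range (default 320).
#' @return character bin labels (`"0"`, `"20"`, ..., `">320"`).
#' @export
acc_bin <- function(acc, width = 20, cap = 320) {
  lab <- as.character(pmin(floor(acc / width) * width, cap))
  lab[acc >= cap] <- paste0(">", cap)
  lab
}

#' Parse classic DSSP output
#'
#' @param file path to a classic (text) DSSP output file.
#' @return data frame `chain`, `seq_id`, `ins`, `ss` (8-category code with
#'   blank mapped to `"C"`), `acc` (DSSP accessibility).
#' @export
parse_dssp <- function(file) {
  lines <- readLines(file, warn = FALSE)
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) == 0) stop("not a classic DSSP file: ", file)
  body <- lines[(hdr[1] + 1):length(lines)]
  body <- body[nchar(body) >= 38 & substr(body, 14, 14) != "!"]
  data.frame(
    chain = trimws(substr(body, 12, 12)),
    seq_id = as.integer(substr(body, 6, 10)),
    ins = trimws(substr(body, 11, 11)),
    ss = ifelse(trimws(substr(body, 17, 17)) == "", "C",
                substr(body, 17, 17)),
    acc = as.numeric(substr(body, 35, 38)),
    stringsAsFactors = FALSE)
}

#' Per-residue secondary structure codes
#'
#' When a DSSP output file is supplied its 8-category codes (H, B, E, G, I,
#' T, S, blank = C) are aligned to the structure's residues. Without DSSP a
#' coarse phi/psi fallback assigns `H` (both angles within 30 degrees of
#' the ideal alpha helix -57/-47), `E` (within 30 degrees of -120/+120) or
#' `C`; the result then carries attribute `approximate = TRUE`.
#'
#' @param structure a `rotaudit_structure`.
#' @param dssp_file optional path to classic DSSP output for this structure.
#' @return data frame `chain`, `seq_id`, `ins`, `aa`, `ss`.
#' @export
ingest_secondary_structure <- function(structure, dssp_file = NULL) {
  ri <- .residue_index(structure)
  if (!is.null(dssp_file)) {
    d <- parse_dssp(dssp_file)
    i <- match(paste(ri$chain, ri$seq_id, ri$ins),
               paste(d$chain, d$seq_id, d$ins))
    if (any(is.na(i))) {
      stop("DSSP output does not cover ", sum(is.na(i)),
           " residue(s) of structure ", structure$id)
    }
    out <- data.frame(ri[, c("chain", "seq_id", "ins", "aa")],
                      ss = d$ss[i], stringsAsFactors = FALSE)
    attr(out, "approximate") <- FALSE
    return(out)
  }
  bb <- backbone_torsions(structure)
  near <- function(x, m) !is.na(x) & circular_distance(x, m) <= 30
  ss <- rep("C", nrow(ri))
  ss[near(bb$phi, -57) & near(bb$psi, -47)] <- "H"
  ss[near(bb$phi, -120) & near(bb$psi, 120)] <- "E"
  out <- data.frame(ri[, c("chain", "seq_id", "ins", "aa")], ss = ss,
                    stringsAsFactors = FALSE)
  attr(out, "approximate") <- TRUE
  out
}

#' Backbone phi/psi torsions
#'
#' @param structure a `rotaudit_structure`.
#' @return data frame `chain`, `seq_id`, `ins`, `aa`, `phi`, `psi` (degrees,
#'   `NA` at chain termini or where atoms are missing).
#' @export
backbone_torsions <- function(structure) {
  ri <- .residue_index(structure)
  a <- structure$atom
  key <- paste(a$chain, a$seq_id, a$ins, sep = "|")
  getp <- function(k, nm) {
    i <- which(key == k & a$name == nm)
    if (length(i) != 1) NULL else c(a$x[i], a$y[i], a$z[i])
  }
  phi <- psi <- rep(NA_real_, nrow(ri))
  for (i in seq_len(nrow(ri))) {
    N <- getp(ri$key[i], "N"); CA <- getp(ri$key[i], "CA")
    C <- getp(ri$key[i], "C")
    if (is.null(N) || is.null(CA) || is.null(C)) next
    if (i > 1 && ri$chain[i - 1] == ri$chain[i]) {
      Cp <- getp(ri$key[i - 1], "C")
      if (!is.null(Cp)) phi[i] <- dihedral(Cp, N, CA, C)
    }
    if (i < nrow(ri) && ri$chain[i + 1] == ri$chain[i]) {
      Nn <- getp(ri$key[i + 1], "N")
      if (!is.null(Nn)) psi[i] <- dihedral(N, CA, C, Nn)
    }
  }
  data.frame(ri[, c("chain", "seq_id", "ins", "aa")], phi = phi, psi = psi,
             stringsAsFactors = FALSE)
}
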