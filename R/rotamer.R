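# Discretized rotamer classification.
#
# A side chain is assigned to a canonical class when every Chi angle lies
# within +/-30 degrees of that class's mode vector; conformations outside
# all bins are "off". Generic modes are p = +65, t = 180, m = -65 (the plus
# bin mirrors the minus interval [-95, -35]; trans wraps across +/-180).
# Terminal torsions of two-fold symmetric branches (ASP Chi2, GLU Chi3,
# PHE/TYR Chi2) are compared with 180-degree periodicity, matching the
# IUPAC-IUB folding of those angles into (-90, +90].

#' Circular distance between two angles
#'
#' `180 - |(|x - y| mod 360) - 180|`: the shorter arc between two angles,
#' in `[0, 180]`.
#'
#' @param x,y angles in degrees (vectorized).
#' @return absolute angular separation in degrees.
#' @export
circular_distance <- function(x, y) {
  180 - abs(abs(x - y) %% 360 - 180)
}

# separation under an arbitrary period (180 for symmetric branches)
.circ_dist_period <- function(x, y, period = 360) {
  d <- abs(x - y) %% period
  pmin(d, period - d)
}

#' The canonical rotamer bin model
#'
#' @param path optional path to an alternative `bin_model.json`.
#' @return list with generic modes `p`, `t`, `m` and the bin `halfwidth`.
#' @export
bin_model <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "bin_model.json", package = "rotaudit")
  }
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Load the per-amino-acid rotamer class inventory
#'
#' The canonical class list per amino acid (label plus one mode per Chi
#' index) with reference occurrence counts, transcribed from the reference
#' census of quality-filtered crystal structures; "off" rows carry the off
#' counts and no modes.
#'
#' @param path optional path to an alternative `rotamer_inventory.tsv`.
#' @return data frame with columns `aa`, `label`, `mode1`..`mode4`, `weight`.
#' @export
rotamer_inventory <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "rotamer_inventory.tsv", package = "rotaudit")
  }
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# per-chi periods for one amino acid (360, or 180 on a symmetric terminal)
.chi_periods <- function(aa, defs = chi_definitions()) {
  rows <- defs[defs$aa == aa, , drop = FALSE]
  ifelse(rows$symmetric, 180, 360)
}

#' Classify a Chi vector into a rotamer class
#'
#' A class qualifies when every per-angle deviation from its mode vector is
#' at most `halfwidth` (30 degrees); among qualifying classes the one with
#' the smallest maximum deviation wins (ties: smallest deviation sum, then
#' inventory order). Conformations qualifying for no class are `"off"`.
#' Proline is dispatched to [classify_pro()]. Undefined Chi angles (missing
#' atoms) refuse classification and return `NA`.
#'
#' @param aa three-letter code (must have at least one Chi angle).
#' @param chis numeric vector of Chi angles in degrees.
#' @param inventory inventory table from [rotamer_inventory()].
#' @param bins bin model from [bin_model()].
#' @param defs Chi definition table.
#' @return class label string (`"off"` possible), or `NA` if any Chi is
#'   undefined.
#' @export
classify_rotamer <- function(aa, chis, inventory = rotamer_inventory(),
                             bins = bin_model(), defs = chi_definitions()) {
  k <- n_chi(aa, defs)
  if (k == 0L) stop("amino acid ", aa, " has no Chi angles to classify")
  chis <- chis[seq_len(k)]
  if (any(is.na(chis))) return(NA_character_)
  if (aa == "PRO") return(classify_pro(chis[1]))
  cls <- inventory[inventory$aa == aa & inventory$label != "off", , drop = FALSE]
  if (nrow(cls) == 0) stop("no inventory classes for ", aa)
  modes <- as.matrix(cls[, paste0("mode", seq_len(k)), drop = FALSE])
  periods <- .chi_periods(aa, defs)
  dev <- matrix(NA_real_, nrow(cls), k)
  for (j in seq_len(k)) {
    dev[, j] <- .circ_dist_period(chis[j], modes[, j], periods[j])
  }
  ok <- rowSums(dev <= bins$halfwidth) == k
  if (!any(ok)) return("off")
  cand <- which(ok)
  maxdev <- apply(dev[cand, , drop = FALSE], 1, max)
  cand <- cand[maxdev == min(maxdev)]
  if (length(cand) > 1) {
    sumdev <- rowSums(dev[cand, , drop = FALSE])
    cand <- cand[sumdev == min(sumdev)]
  }
  cls$label[cand[1]]
}

#' Classify a proline ring pucker from Chi1
#'
#' Chi1 within 30 degrees of +30 is "Cg endo", within 30 degrees of -30 is
#' "Cg exo" (the boundary Chi1 = 0, equidistant from both centers, is
#' assigned exo); anything else is "off".
#'
#' @param chi1 proline Chi1 in degrees.
#' @return `"Cg endo"`, `"Cg exo"` or `"off"` (`NA` input returns `NA`).
#' @export
classify_pro <- function(chi1) {
  if (is.na(chi1)) return(NA_character_)
  if (abs(chi1) > 60) return("off")
  if (chi1 > 0) "Cg endo" else "Cg exo"
}

#' Side-chain-length group of an amino acid
#'
#' Group I has Chi1 only (CYS, SER, THR, VAL); group II Chi1-Chi2; group
#' III Chi1-Chi3 (GLN, GLU, MET); group IV Chi1-Chi4 (LYS, ARG). ALA and
#' GLY have no side-chain torsions and map to `"none"`.
#'
#' @param aa three-letter code(s).
#' @return character vector in `{"I","II","III","IV","none"}`.
#' @export
assign_group <- function(aa) {
  grp <- c(CYS = "I", SER = "I", THR = "I", VAL = "I",
           ASN = "II", ASP = "II", HIS = "II", ILE = "II", LEU = "II",
           PHE = "II", PRO = "II", TRP = "II", TYR = "II",
           GLN = "III", GLU = "III", MET = "III",
           LYS = "IV", ARG = "IV",
           ALA = "none", GLY = "none")
  bad <- setdiff(unique(aa), names(grp))
  if (length(bad)) stop("unknown amino acid code(s): ", paste(bad, collapse = ", "))
  unname(grp[aa])
}

#' Rotamer census over a set of residue records
#'
#' Per amino acid: canonical and off counts with percentages, plus a grand
#' totals row. ALA and GLY (no rotamer) contribute to totals only.
#'
#' @param records residue-record data frame with columns `aa` and `rotamer`
#'   (label or `NA`), e.g. from [residue_records()].
#' @return data frame with columns `aa`, `canonical`, `canonical_pct`,
#'   `off`, `off_pct`, `total`.
#' @export
rotamer_census <- function(records) {
  if (nrow(records) == 0) {
    return(data.frame(aa = character(0), canonical = integer(0),
                      canonical_pct = numeric(0), off = integer(0),
                      off_pct = numeric(0), total = integer(0)))
  }
  aas <- sort(unique(records$aa))
  rows <- lapply(aas, function(a) {
    r <- records[records$aa == a, , drop = FALSE]
    cls <- r$rotamer[!is.na(r$rotamer)]
    off <- sum(cls == "off")
    can <- sum(cls != "off")
    data.frame(aa = a, canonical = can,
               canonical_pct = if (can + off > 0) 100 * can / (can + off) else NA_real_,
               off = off,
               off_pct = if (can + off > 0) 100 * off / (can + off) else NA_real_,
               total = nrow(r))
  })
  out <- do.call(rbind, rows)
  tot <- data.frame(aa = "total", canonical = sum(out$canonical),
                    canonical_pct = 100 * sum(out$canonical) /
                      max(1, sum(out$canonical) + sum(out$off)),
                    off = sum(out$off),
                    off_pct = 100 * sum(out$off) /
                      max(1, sum(out$canonical) + sum(out$off)),
                    total = sum(out$total))
  rbind(out, tot)
}
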