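# IUPAC-IUB symmetric-branch nomenclature handling.
#
# For the two-fold symmetric branches (ASP carboxylate, GLU carboxylate,
# PHE/TYR ring) the branch torsion is only defined modulo 180 degrees;
# IUPAC-IUB rules pick the representative in (-90, +90]. Records violating
# the rule are counted, corrected on the angle level, and (for PHE/TYR)
# fixable on the record level by swapping the CD1/CD2 and CE1/CE2 names.

#' Index of the symmetric terminal torsion, if any
#'
#' ASP's symmetric branch (OD1/OD2) is its Chi2 and GLU's (OE1/OE2) its
#' Chi3; PHE and TYR rings are their Chi2. `verbatim_indices = TRUE`
#' selects ASP Chi1 / GLU Chi2 instead (a published variant of the rule
#' whose indices are inconsistent with the named rotamer classes used
#' here).
#'
#' @param aa three-letter code.
#' @param verbatim_indices use the ASP-Chi1/GLU-Chi2 variant.
#' @return integer Chi index, or `NA` for amino acids without a symmetric
#'   terminal branch.
#' @export
symmetric_chi_index <- function(aa, verbatim_indices = FALSE) {
  idx <- if (verbatim_indices) {
    c(ASP = 1L, GLU = 2L, PHE = 2L, TYR = 2L)
  } else {
    c(ASP = 2L, GLU = 3L, PHE = 2L, TYR = 2L)
  }
  if (!aa %in% names(idx)) return(NA_integer_)
  unname(idx[aa])
}

# fold one angle into (-90, +90] by a 180-degree rotation when needed
.fold_symmetric <- function(t) {
  ifelse(!is.na(t) & (t > 90 | t <= -90), normalize_angle(t + 180), t)
}

#' Correct the symmetric terminal torsion of a Chi vector
#'
#' Maps the terminal symmetric-branch torsion into `(-90, +90]` by a
#' 180-degree rotation when it lies in `[-180, -90]` or `(+90, +180]`;
#' other angles are untouched. Idempotent. Amino acids without a symmetric
#' branch are returned unchanged with attribute `noop = TRUE`.
#'
#' @param aa three-letter code.
#' @param chis numeric Chi vector in degrees.
#' @param verbatim_indices see [symmetric_chi_index()].
#' @return corrected Chi vector.
#' @export
correct_symmetric_chi <- function(aa, chis, verbatim_indices = FALSE) {
  i <- symmetric_chi_index(aa, verbatim_indices)
  if (is.na(i) || length(chis) < i) {
    attr(chis, "noop") <- TRUE
    return(chis)
  }
  chis[i] <- .fold_symmetric(chis[i])
  chis
}

#' Audit and fix swapped ring-atom names in PHE/TYR residues
#'
#' When the raw Chi2 of a PHE or TYR lies outside `(-90, +90]`, the CD1/CD2
#' and CE1/CE2 names in the record are switched (coordinates untouched),
#' after which the recomputed Chi2 satisfies the IUPAC-IUB rule.
#'
#' @param structure a `rotaudit_structure`.
#' @return list with elements `structure` (names fixed) and `report` (one
#'   row per PHE/TYR residue: raw Chi2, `swap_applied`, `audit_error` when
#'   ring atoms were missing).
#' @export
fix_ring_names <- function(structure) {
  defs <- chi_definitions()
  ri <- .residue_index(structure)
  ring <- ri[ri$aa %in% c("PHE", "TYR"), , drop = FALSE]
  rep_rows <- list()
  a <- structure$atom
  key <- paste(a$chain, a$seq_id, a$ins, sep = "|")
  for (i in seq_len(nrow(ring))) {
    sel <- which(key == ring$key[i])
    res <- a[sel, , drop = FALSE]
    chis <- compute_chis(res, ring$aa[i], defs)
    chi2 <- chis$values[2]
    swap <- FALSE
    audit_error <- is.na(chi2)
    if (!audit_error && (chi2 > 90 || chi2 <= -90)) {
      nm <- a$name[sel]
      pairs <- list(c("CD1", "CD2"), c("CE1", "CE2"))
      for (p in pairs) {
        i1 <- which(nm == p[1]); i2 <- which(nm == p[2])
        if (length(i1) == 1 && length(i2) == 1) {
          nm[c(i1, i2)] <- c(p[2], p[1])
        }
      }
      a$name[sel] <- nm
      swap <- TRUE
    }
    rep_rows[[i]] <- data.frame(chain = ring$chain[i], seq_id = ring$seq_id[i],
                                ins = ring$ins[i], aa = ring$aa[i],
                                raw_chi2 = chi2, swap_applied = swap,
                                audit_error = audit_error,
                                stringsAsFactors = FALSE)
  }
  structure$atom <- a
  list(structure = structure,
       report = if (length(rep_rows)) do.call(rbind, rep_rows) else
         data.frame(chain = character(0), seq_id = integer(0),
                    ins = character(0), aa = character(0),
                    raw_chi2 = numeric(0), swap_applied = logical(0),
                    audit_error = logical(0)))
}

#' Census of invalid symmetric-branch nomenclature
#'
#' For ASP, GLU, PHE and TYR: the percentage of residues whose raw terminal
#' symmetric torsion violates `(-90, +90]`, over a set of structures.
#'
#' @param structures list of `rotaudit_structure` objects.
#' @param verbatim_indices see [symmetric_chi_index()].
#' @return data frame with columns `aa`, `n`, `invalid`, `percent_invalid`
#'   (residues whose terminal torsion could not be computed are excluded
#'   from `n`).
#' @export
nomenclature_census <- function(structures, verbatim_indices = FALSE) {
  defs <- chi_definitions()
  tally <- stats::setNames(rep(0L, 4), c("ASP", "GLU", "PHE", "TYR"))
  bad <- tally
  for (s in structures) {
    ri <- .residue_index(s)
    ri <- ri[ri$aa %in% names(tally), , drop = FALSE]
    a <- s$atom
    key <- paste(a$chain, a$seq_id, a$ins, sep = "|")
    for (i in seq_len(nrow(ri))) {
      aa <- ri$aa[i]
      j <- symmetric_chi_index(aa, verbatim_indices)
      res <- a[key == ri$key[i], , drop = FALSE]
      tv <- compute_chis(res, aa, defs)$values[j]
      if (is.na(tv)) next
      tally[aa] <- tally[aa] + 1L
      if (tv > 90 || tv <= -90) bad[aa] <- bad[aa] + 1L
    }
  }
  data.frame(aa = names(tally), n = as.integer(tally),
             invalid = as.integer(bad),
             percent_invalid = ifelse(tally > 0, 100 * bad / tally, NA_real_),
             row.names = NULL)
}
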