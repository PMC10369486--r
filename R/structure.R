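# PDB structure model and quality filters.
#
# The internal model is a light S3 container: an atom table (one row per
# heavy atom of a standard residue) plus the crystallographic resolution.
# Reading and writing go through bio3d; the resolution is taken from the
# REMARK 2 record, which bio3d does not expose.

.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

#' Construct a structure object from an atom table
#'
#' @param atom data frame with columns `name`, `element`, `alt`, `aa`,
#'   `chain`, `seq_id`, `ins`, `x`, `y`, `z`, `occ`, `b`.
#' @param id structure identifier string.
#' @param resolution crystallographic resolution in Angstrom, or `NA`.
#' @return an object of class `rotaudit_structure`.
#' @export
new_structure <- function(atom, id = "structure", resolution = NA_real_) {
  needed <- c("name", "element", "alt", "aa", "chain", "seq_id", "ins",
              "x", "y", "z", "occ", "b")
  stopifnot(all(needed %in% names(atom)))
  if (any(!is.finite(as.matrix(atom[, c("x", "y", "z")])))) {
    stop("non-finite coordinates in atom table")
  }
  rownames(atom) <- NULL
  structure(list(id = id, atom = atom, resolution = resolution),
            class = "rotaudit_structure")
}

#' @export
print.rotaudit_structure <- function(x, ...) {
  cat(sprintf("<rotaudit_structure> %s: %d atoms, %d residues, %d chain(s), resolution %s\n",
              x$id, nrow(x$atom), nrow(unique(x$atom[, c("chain", "seq_id", "ins")])),
              length(unique(x$atom$chain)),
              if (is.na(x$resolution)) "NA" else sprintf("%.2f A", x$resolution)))
  invisible(x)
}

# unique residue keys, in file order
.residue_index <- function(structure) {
  a <- structure$atom
  key <- paste(a$chain, a$seq_id, a$ins, sep = "|")
  i <- !duplicated(key)
  data.frame(chain = a$chain[i], seq_id = a$seq_id[i], ins = a$ins[i],
             aa = a$aa[i], key = key[i], stringsAsFactors = FALSE)
}

.residue_atoms <- function(structure, chain, seq_id, ins) {
  a <- structure$atom
  a[a$chain == chain & a$seq_id == seq_id & a$ins == ins, , drop = FALSE]
}

#' Read a PDB file into a structure object
#'
#' Keeps ATOM records of the 20 standard amino acids from the first model;
#' HETATM records (waters, ions, ligands) are dropped, as are alternate
#' locations other than blank or 'A'. The resolution is parsed from the
#' REMARK 2 record when present.
#'
#' @param file path to a PDB-format text file.
#' @param id structure identifier; default the file base name.
#' @return a `rotaudit_structure`.
#' @export
read_pdb <- function(file, id = NULL) {
  lines <- readLines(file, warn = FALSE)
  if (length(lines) == 0 || !any(grepl("^(ATOM|HETATM)", lines))) {
    stop("no ATOM records found in '", file, "'")
  }
  # pre-validate fixed-column numeric fields so errors carry line numbers
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(is_atom)) {
    ln <- lines[i]
    if (nchar(ln) < 54) stop("malformed ATOM record at line ", i, ": too short")
    flds <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    if (any(is.na(suppressWarnings(as.numeric(flds))))) {
      stop("malformed ATOM record at line ", i, ": non-numeric coordinates")
    }
  }
  res <- NA_real_
  rem <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(rem)) {
    tail <- sub("^REMARK   2 RESOLUTION\\.", "", rem[1])
    m <- regmatches(tail, regexpr("[0-9]+\\.?[0-9]*", tail))
    if (length(m)) res <- suppressWarnings(as.numeric(m))
  }
  pdb <- bio3d::read.pdb(file, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  a <- pdb$atom
  keep <- a$type == "ATOM" & a$resid %in% .AA3 & (is.na(a$alt) | a$alt == "A")
  a <- a[keep, , drop = FALSE]
  if (nrow(a) == 0) stop("no standard-residue ATOM records in '", file, "'")
  elem <- trimws(a$elesy)
  miss <- is.na(elem) | elem == ""
  elem[miss] <- substr(trimws(a$elety[miss]), 1, 1)
  atom <- data.frame(
    name = trimws(a$elety), element = elem,
    alt = ifelse(is.na(a$alt), "", a$alt),
    aa = a$resid, chain = ifelse(is.na(a$chain), "A", a$chain),
    seq_id = a$resno, ins = ifelse(is.na(a$insert), "", a$insert),
    x = a$x, y = a$y, z = a$z, occ = a$o, b = a$b,
    stringsAsFactors = FALSE)
  if (is.null(id)) id <- sub("\\.pdb$", "", basename(file))
  new_structure(atom, id = id, resolution = res)
}

#' Write a structure object to a PDB file
#'
#' Emits fixed-column ATOM records (plus a REMARK 2 resolution record when
#' the structure carries one); `read_pdb()` of the output reproduces atom
#' names, coordinates (3 decimals), occupancies and B-factors.
#'
#' @param structure a `rotaudit_structure`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_pdb <- function(structure, file) {
  a <- structure$atom
  if (any(nchar(a$name) > 4)) {
    stop("atom name longer than 4 characters: ",
         paste(unique(a$name[nchar(a$name) > 4]), collapse = ", "))
  }
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  bio3d::write.pdb(pdb = NULL, file = tmp,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(a)),
                   resno = a$seq_id, resid = a$aa, insert = a$ins,
                   eleno = seq_len(nrow(a)), elety = a$name,
                   chain = a$chain, o = a$occ, b = a$b, elesy = a$element)
  body <- readLines(tmp, warn = FALSE)
  hdr <- character(0)
  if (!is.na(structure$resolution)) {
    hdr <- sprintf("REMARK   2 RESOLUTION. %7.2f ANGSTROMS.", structure$resolution)
  }
  writeLines(c(hdr, body), file)
  invisible(file)
}

.filter_report <- function(kept, reason, flags) {
  out <- list(structure_kept = kept, reason = reason,
              residues_total = nrow(flags),
              residues_retained = sum(flags$flag == "retained"),
              per_residue_flags = flags)
  class(out) <- "rotaudit_filter_report"
  out
}

#' @export
print.rotaudit_filter_report <- function(x, ...) {
  cat(sprintf("<filter report> kept=%s (%s); residues %d/%d retained\n",
              x$structure_kept, x$reason, x$residues_retained, x$residues_total))
  invisible(x)
}

#' Structure-level quality filter
#'
#' Retains single-chain structures whose resolution is strictly better than
#' `max_resolution`. An absent resolution fails the filter unless the
#' resolution check is disabled.
#'
#' @param structure a `rotaudit_structure`.
#' @param max_resolution cutoff in Angstrom; structures with
#'   `resolution < max_resolution` pass (default 2.0).
#' @param require_single_chain reject multi-chain structures (default TRUE).
#' @param require_resolution when FALSE, skip the resolution check (for
#'   synthetic or resolution-less inputs).
#' @return a filter report.
#' @export
filter_structure <- function(structure, max_resolution = 2.0,
                             require_single_chain = TRUE,
                             require_resolution = TRUE) {
  ri <- .residue_index(structure)
  flags <- data.frame(ri[, c("chain", "seq_id", "ins", "aa")],
                      flag = "retained", stringsAsFactors = FALSE)
  if (require_single_chain && length(unique(structure$atom$chain)) > 1) {
    flags$flag <- "excluded"
    return(.filter_report(FALSE, "multi_chain", flags))
  }
  if (require_resolution &&
      (is.na(structure$resolution) || structure$resolution >= max_resolution)) {
    flags$flag <- "excluded"
    return(.filter_report(FALSE, "low_resolution", flags))
  }
  .filter_report(TRUE, "kept", flags)
}

#' Residue-level quality filter
#'
#' A residue is retained only if every atom participating in any of its
#' torsion computations (backbone N, CA, C plus all side-chain Chi atoms)
#' is present with B-factor at or below `max_bfactor` and occupancy at
#' least `required_occupancy`.
#'
#' @param structure a `rotaudit_structure`.
#' @param torsion_atom_sets optional named list (aa -> character vector of
#'   atom names); defaults to the sets implied by [chi_definitions()].
#' @param max_bfactor B-factor cutoff in Angstrom^2 (default 40).
#' @param required_occupancy minimum occupancy (default 1.0, i.e. full).
#' @return a filter report whose per-residue flags are one of `retained`,
#'   `missing_atoms`, `bad_bfactor`, `bad_occupancy`.
#' @export
filter_residues <- function(structure, torsion_atom_sets = NULL,
                            max_bfactor = 40, required_occupancy = 1.0) {
  defs <- chi_definitions()
  if (is.null(torsion_atom_sets)) {
    torsion_atom_sets <- lapply(stats::setNames(nm = .AA3), .torsion_atom_names,
                                defs = defs)
  }
  ri <- .residue_index(structure)
  a <- structure$atom
  key <- paste(a$chain, a$seq_id, a$ins, sep = "|")
  flag <- character(nrow(ri))
  for (i in seq_len(nrow(ri))) {
    need <- torsion_atom_sets[[ri$aa[i]]]
    sel <- key == ri$key[i]
    hit <- match(need, a$name[sel])
    if (any(is.na(hit))) {
      flag[i] <- "missing_atoms"
    } else if (any(a$b[sel][hit] > max_bfactor)) {
      flag[i] <- "bad_bfactor"
    } else if (any(a$occ[sel][hit] < required_occupancy - 1e-9)) {
      flag[i] <- "bad_occupancy"
    } else {
      flag[i] <- "retained"
    }
  }
  flags <- data.frame(ri[, c("chain", "seq_id", "ins", "aa")], flag = flag,
                      stringsAsFactors = FALSE)
  .filter_report(TRUE, "kept", flags)
}
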