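# Shared fixture builders. Everything is generated in code at test time;
# no binary data ships with the package.

# A 5-residue hand-written PDB text (includes a water that must be dropped).
five_residue_pdb <- function(path = tempfile(fileext = ".pdb"),
                             resolution = "REMARK   2 RESOLUTION.    1.80 ANGSTROMS.") {
  lines <- c(
    resolution,
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00 11.00           C",
    "ATOM      3  C   ALA A   1      12.759   7.095  -4.987  1.00 12.00           C",
    "ATOM      4  O   ALA A   1      13.344   7.561  -5.968  1.00 12.50           O",
    "ATOM      5  CB  ALA A   1      10.529   6.291  -4.107  0.50 13.00           C",
    "ATOM      6  N   GLY A   2      13.034   7.441  -3.735  1.00 10.00           N",
    "ATOM      7  CA  GLY A   2      14.091   8.391  -3.431  1.00 10.00           C",
    "ATOM      8  C   GLY A   2      15.427   7.921  -3.993  1.00 10.00           C",
    "ATOM      9  N   SER A   3      16.432   8.789  -3.934  1.00 10.00           N",
    "ATOM     10  CA  SER A   3      17.768   8.470  -4.430  1.00 10.00           C",
    "ATOM     11  C   SER A   3      18.832   9.441  -3.929  1.00 10.00           C",
    "ATOM     12  OG  SER A   3      17.804   8.437  -5.855  1.00 10.00           O",
    "ATOM     13  CB  SER A   3      18.137   7.060  -3.975  1.00 10.00           C",
    "ATOM     14  N   VAL A   4      20.089   9.005  -3.935  1.00 10.00           N",
    "ATOM     15  CA  VAL A   4      21.222   9.822  -3.509  1.00 10.00           C",
    "ATOM     16  C   VAL A   4      22.521   9.043  -3.681  1.00 10.00           C",
    "ATOM     17  N   LEU A   5      23.636   9.729  -3.442  1.00 10.00           N",
    "ATOM     18  CA  LEU A   5      24.965   9.133  -3.553  1.00 10.00           C",
    "ATOM     19  C   LEU A   5      25.986  10.088  -2.959  1.00 10.00           C",
    "HETATM   20  O   HOH A 101      30.000   5.000  -3.000  1.00 20.00           O",
    "TER",
    "END")
  writeLines(lines, path)
  path
}

# Build one residue's atoms at prescribed Chi angles, as a bare atom table
# (used to probe classification and nomenclature without a whole chain).
single_residue_structure <- function(aa, chis, b = 20, occ = 1) {
  cfg <- generator_config(n_residues = 1, seed = 1, sequence = aa,
                          b_factor_mean = b, b_factor_sd = 0)
  gen <- build_peptide(cfg)
  a <- gen$structure$atom
  k <- n_chi(aa)
  if (k > 0) {
    tmpl <- sidechain_templates()
    pos <- lapply(stats::setNames(nm = a$name), function(nm) {
      j <- match(nm, a$name); c(a$x[j], a$y[j], a$z[j])
    })
    sc <- rotaudit:::.build_sidechain(aa, c(chis, rep(NA, 4 - length(chis))),
                                      pos[c("N", "CA", "C", "O", "CB")], tmpl)
    for (nm in names(sc)) {
      j <- match(nm, a$name)
      a[j, c("x", "y", "z")] <- as.list(sc[[nm]])
    }
  }
  a$b <- b
  a$occ <- occ
  new_structure(a, id = paste0("single_", aa), resolution = 1.5)
}

# measured Chi vector of the first residue of a structure
measured_chis <- function(structure, aa) {
  compute_chis(structure$atom, aa)$values
}

# a paired synthetic data set shared by several tests (lazy, built once)
shared_pair <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- generator_config(n_residues = 120, seed = 2024, id = "shared")
      gen <- build_peptide(cfg)
      prd <- mock_predict(gen$structure, gen$ledger, epsilon0 = 0.3, seed = 2025)
      orec <- residue_records(gen$structure, acc_points = 120)
      prec <- residue_records(prd$structure, compute_acc = FALSE)
      cache <<- list(gen = gen, prd = prd, orec = orec, prec = prec,
                     cmp = pair_structures(orec, prec, "mock"))
    }
    cache
  }
})

# classic DSSP data line with the fields the parser reads
dssp_line <- function(idx, resno, chain, aa1, ss, acc) {
  sprintf("%-34s%4d", sprintf("%5d%5d %1s %1s  %1s", idx, resno, chain, aa1, ss), acc)
}

dssp_file_for <- function(structure, ss_codes, accs = NULL) {
  ri <- structure$atom[!duplicated(structure$atom$seq_id), ]
  if (is.null(accs)) accs <- rep(50L, nrow(ri))
  aa1 <- substr(ri$aa, 1, 1)
  path <- tempfile(fileext = ".dssp")
  writeLines(c("==== Secondary Structure Definition; synthetic ====",
               "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC",
               mapply(dssp_line, seq_len(nrow(ri)), ri$seq_id, ri$chain,
                      aa1, ss_codes, accs)),
             path)
  path
}
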