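# Synthetic peptide generator and mock side-chain predictor.
#
# Structures are built by sequential internal-coordinate (NeRF) placement
# with idealized bond lengths and angles; side chains are attached at
# prescribed Chi angles drawn from the rotamer inventory, so every residue
# carries exact ground truth. No steric relaxation is performed: the
# analyses under test are purely geometric and deterministic construction
# is worth more than physical realism.

.BB <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
            ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
            ang_ca_c_o = 120.5, omega = 180,
            cb_len = 1.53, cb_ang = 110.5, cb_torsion = -122.9)

.BACKBONE_PRESETS <- list(helix = c(phi = -57, psi = -47),
                          strand = c(phi = -120, psi = 120),
                          coil = c(phi = -75, psi = 145))

#' Load the side-chain internal-coordinate templates
#' @param path optional alternative `sidechain_templates.tsv`.
#' @return data frame `aa`, `atom`, `a`, `b`, `c`, `length`, `angle`,
#'   `chi` (index or `NA`), `offset` (degrees).
#' @export
sidechain_templates <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "sidechain_templates.tsv", package = "rotaudit")
  }
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Configuration for the synthetic peptide generator
#'
#' Defaults emulate the quality-filtered crystal-structure conditions the
#' audit targets: amino-acid composition and per-class sampling weights
#' proportional to the reference census (so canonical/off mixes match the
#' observed rotamer distribution), B-factors well inside the <= 40 A^2
#' filter, full occupancies, and a nominal 1.5 A resolution so
#' structure-level filters pass.
#'
#' @param n_residues chain length.
#' @param seed integer seed; mandatory, every build is reproducible.
#' @param backbone `"helix"`, `"strand"`, `"coil"`, or a character vector
#'   (one preset per residue).
#' @param sequence optional fixed vector of three-letter codes (overrides
#'   composition sampling).
#' @param aa_weights named weights for composition sampling (default:
#'   reference census totals).
#' @param class_weights optional named list aa -> named weight vector over
#'   inventory labels (including `"off"`); default: census counts.
#' @param b_factor_mean,b_factor_sd B-factor distribution (clamped to
#'   stay below the default filter cutoff unless corrupted).
#' @param occupancy_corruption per-residue probability of setting one
#'   torsion-set atom's occupancy to 0.5.
#' @param bfactor_corruption per-residue probability of setting one
#'   torsion-set atom's B-factor to 60 A^2.
#' @param swap_rate per-residue probability (ASP/GLU/PHE/TYR only) of
#'   writing the symmetric-branch atom names swapped, i.e. an IUPAC-IUB
#'   nomenclature violation.
#' @param resolution synthetic resolution metadata (default 1.5 A).
#' @param id structure identifier.
#' @return a `rotaudit_generator_config` list.
#' @export
generator_config <- function(n_residues = 150, seed, backbone = "helix",
                             sequence = NULL, aa_weights = NULL,
                             class_weights = NULL, b_factor_mean = 20,
                             b_factor_sd = 5, occupancy_corruption = 0,
                             bfactor_corruption = 0, swap_rate = 0,
                             resolution = 1.5, id = "synthetic") {
  if (missing(seed)) stop("a seed is mandatory for reproducible generation")
  cfg <- list(n_residues = n_residues, seed = as.integer(seed),
              backbone = backbone, sequence = sequence,
              aa_weights = aa_weights, class_weights = class_weights,
              b_factor_mean = b_factor_mean, b_factor_sd = b_factor_sd,
              occupancy_corruption = occupancy_corruption,
              bfactor_corruption = bfactor_corruption,
              swap_rate = swap_rate, resolution = resolution, id = id)
  class(cfg) <- "rotaudit_generator_config"
  cfg
}

# default per-aa class weights from the inventory counts
.default_class_weights <- function(inventory) {
  sp <- split(inventory, inventory$aa)
  lapply(sp, function(d) stats::setNames(d$weight, d$label))
}

# sample a Chi vector for a class label (canonical: mode +/- 15 uniform;
# off: one Chi pushed > 31 degrees away from every mode at that index)
.sample_chis <- function(aa, label, inventory, defs) {
  k <- n_chi(aa, defs)
  if (aa == "PRO") {
    if (label == "off") {
      chi1 <- sample(c(-1, 1), 1) * stats::runif(1, 62, 178)
    } else {
      chi1 <- (if (label == "Cg endo") 30 else -30) + stats::runif(1, -15, 15)
    }
    return(c(chi1, normalize_angle(-chi1), rep(NA_real_, 2)))
  }
  cls <- inventory[inventory$aa == aa & inventory$label != "off", , drop = FALSE]
  modes <- as.matrix(cls[, paste0("mode", seq_len(k)), drop = FALSE])
  periods <- .chi_periods(aa, defs)
  if (label != "off") {
    m <- modes[match(label, cls$label), ]
    return(c(normalize_angle(m + stats::runif(k, -15, 15)),
             rep(NA_real_, 4 - k)))
  }
  base <- modes[sample(nrow(modes), 1), ]
  chis <- normalize_angle(base + stats::runif(k, -15, 15))
  j <- sample.int(k, 1)
  repeat {
    cand <- stats::runif(1, -180, 180)
    if (min(.circ_dist_period(cand, modes[, j], periods[j])) > 31) break
  }
  chis[j] <- normalize_angle(cand)
  c(chis, rep(NA_real_, 4 - k))
}

# place side-chain atoms for one residue from the template table;
# returns a data frame name/x/y/z (positions keyed by atom name)
.build_sidechain <- function(aa, chis, bbpos, tmpl) {
  rows <- tmpl[tmpl$aa == aa, , drop = FALSE]
  pos <- bbpos  # named list: N, CA, C, CB already present
  out <- list()
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    tors <- if (is.na(r$chi)) r$offset else chis[r$chi] + r$offset
    p <- place_atom(pos[[r$a]], pos[[r$b]], pos[[r$c]],
                    r$length, r$angle, tors)
    pos[[r$atom]] <- p
    out[[r$atom]] <- p
  }
  out
}

.element_of <- function(name) substr(name, 1, 1)

#' Build a synthetic all-atom peptide with known ground truth
#'
#' @param config a [generator_config()].
#' @param inventory,defs,tmpl fixture tables (defaults: shipped fixtures).
#' @return list with `structure` (a `rotaudit_structure`) and `ledger`
#'   (one row per residue: true class, prescribed Chi angles, corruption
#'   and name-swap flags).
#' @export
build_peptide <- function(config, inventory = rotamer_inventory(),
                          defs = chi_definitions(), tmpl = sidechain_templates()) {
  set.seed(config$seed)
  n <- config$n_residues
  census <- utils::read.delim(system.file("extdata", "reference_census.tsv",
                                          package = "rotaudit"))
  aa_w <- config$aa_weights
  if (is.null(aa_w)) aa_w <- stats::setNames(census$total, census$aa)
  seq_aa <- config$sequence
  if (is.null(seq_aa)) {
    seq_aa <- sample(names(aa_w), n, replace = TRUE, prob = aa_w)
  } else {
    n <- length(seq_aa)
  }
  preset <- config$backbone
  if (length(preset) == 1) preset <- rep(preset, n)
  phis <- vapply(preset, function(p) .BACKBONE_PRESETS[[p]]["phi"], numeric(1))
  psis <- vapply(preset, function(p) .BACKBONE_PRESETS[[p]]["psi"], numeric(1))
  cw <- config$class_weights
  if (is.null(cw)) cw <- .default_class_weights(inventory)

  atoms <- list()
  ledger <- list()
  Nprev <- CAprev <- Cprev <- NULL
  for (i in seq_len(n)) {
    aa <- seq_aa[i]
    if (i == 1) {
      N <- c(0, 0, 0); CA <- c(.BB$n_ca, 0, 0)
      C <- place_atom(c(0, 1, 0), N, CA, .BB$ca_c, .BB$ang_n_ca_c, -60)
    } else {
      N <- place_atom(Nprev, CAprev, Cprev, .BB$c_n, .BB$ang_ca_c_n, psis[i - 1])
      CA <- place_atom(CAprev, Cprev, N, .BB$n_ca, .BB$ang_c_n_ca, .BB$omega)
      C <- place_atom(Cprev, N, CA, .BB$ca_c, .BB$ang_n_ca_c, phis[i])
    }
    O <- place_atom(N, CA, C, .BB$c_o, .BB$ang_ca_c_o,
                    normalize_angle(psis[i] + 180))
    pos <- list(N = N, CA = CA, C = C, O = O)
    if (aa != "GLY") {
      pos$CB <- place_atom(C, N, CA, .BB$cb_len, .BB$cb_ang, .BB$cb_torsion)
    }
    k <- n_chi(aa, defs)
    label <- NA_character_
    chis <- rep(NA_real_, 4)
    if (k > 0) {
      w <- cw[[aa]]
      label <- sample(names(w), 1, prob = w)
      chis <- .sample_chis(aa, label, inventory, defs)
      sc <- .build_sidechain(aa, chis, pos, tmpl)
      pos <- c(pos, sc[setdiff(names(sc), names(pos))])
    }
    swap <- FALSE
    if (config$swap_rate > 0 && aa %in% c("ASP", "GLU", "PHE", "TYR") &&
        stats::runif(1) < config$swap_rate) {
      swaps <- switch(aa,
                      ASP = list(c("OD1", "OD2")),
                      GLU = list(c("OE1", "OE2")),
                      list(c("CD1", "CD2"), c("CE1", "CE2")))
      nm <- names(pos)
      for (p in swaps) {
        nm[match(p, names(pos))] <- rev(p)
      }
      names(pos) <- nm
      swap <- TRUE
    }
    nm <- names(pos)
    atoms[[i]] <- data.frame(
      name = nm, element = .element_of(nm), alt = "", aa = aa, chain = "A",
      seq_id = i, ins = "",
      x = vapply(pos, `[`, numeric(1), 1),
      y = vapply(pos, `[`, numeric(1), 2),
      z = vapply(pos, `[`, numeric(1), 3),
      occ = 1,
      b = pmin(pmax(stats::rnorm(length(pos), config$b_factor_mean,
                                 config$b_factor_sd), 2), 39.5),
      stringsAsFactors = FALSE)
    ledger[[i]] <- data.frame(chain = "A", seq_id = i, aa = aa,
                              true_class = label,
                              chi1 = chis[1], chi2 = chis[2],
                              chi3 = chis[3], chi4 = chis[4],
                              swap_applied = swap, occ_corrupted = FALSE,
                              b_corrupted = FALSE, stringsAsFactors = FALSE)
    Nprev <- N; CAprev <- CA; Cprev <- C
  }
  atom <- do.call(rbind, atoms)
  led <- do.call(rbind, ledger)
  # metadata corruption for filter testing: hit atoms that participate in
  # torsion computations so the residue filter is guaranteed to trip
  for (i in seq_len(n)) {
    tset <- .torsion_atom_names(seq_aa[i], defs)
    sel <- which(atom$seq_id == i & atom$name %in% tset)
    if (config$occupancy_corruption > 0 &&
        stats::runif(1) < config$occupancy_corruption) {
      atom$occ[sample(sel, 1)] <- 0.5
      led$occ_corrupted[i] <- TRUE
    }
    if (config$bfactor_corruption > 0 &&
        stats::runif(1) < config$bfactor_corruption) {
      atom$b[sample(sel, 1)] <- 60
      led$b_corrupted[i] <- TRUE
    }
  }
  rownames(atom) <- NULL
  list(structure = new_structure(atom, id = config$id,
                                 resolution = config$resolution),
       ledger = led)
}

#' Repack side chains with a known confusion process
#'
#' Emulates an external side-chain packing program: per residue, with
#' probability `eps = plogis(qlogis(epsilon0) + acc_slope * ACC)`, the side
#' chain is rebuilt at a different inventory class (uniform over the
#' alternatives, `"off"` included); the backbone is untouched. An amino
#' acid with a single canonical class whose confusion is drawn is forced to
#' `"off"`. Every action is recorded in the returned ledger.
#'
#' @param structure a structure from [build_peptide()].
#' @param ledger its truth ledger.
#' @param epsilon0 baseline confusion probability in `[0, 1]`.
#' @param acc_slope logit-scale accessibility dependence per Angstrom^2
#'   (0 disables the ACC computation).
#' @param seed integer seed for the confusion draws.
#' @param inventory,defs,tmpl fixture tables.
#' @param acc_points Shrake-Rupley points when `acc_slope != 0`.
#' @return list with `structure` (repacked) and `ledger` (columns
#'   `predicted_class` and `action` added).
#' @export
mock_predict <- function(structure, ledger, epsilon0, acc_slope = 0, seed,
                         inventory = rotamer_inventory(),
                         defs = chi_definitions(),
                         tmpl = sidechain_templates(), acc_points = 480) {
  if (missing(seed)) stop("a seed is mandatory for reproducible prediction")
  set.seed(as.integer(seed))
  acc <- NULL
  if (acc_slope != 0) {
    ap <- shrake_rupley_acc(structure, n_points = acc_points)
    acc <- stats::setNames(ap$acc, paste(ap$chain, ap$seq_id, ap$ins, sep = "|"))
  }
  atom <- structure$atom
  keep_bb <- c("N", "CA", "C", "O", "CB")
  ledger$predicted_class <- ledger$true_class
  ledger$action <- ifelse(is.na(ledger$true_class), "no_sidechain", "kept")
  for (i in seq_len(nrow(ledger))) {
    if (is.na(ledger$true_class[i])) next
    aa <- ledger$aa[i]
    eps <- stats::plogis(stats::qlogis(epsilon0) +
                           (if (is.null(acc)) 0 else
                             acc_slope * acc[[paste("A", ledger$seq_id[i], "", sep = "|")]]))
    if (stats::runif(1) >= eps) next
    labels <- c(inventory$label[inventory$aa == aa & inventory$label != "off"], "off")
    alt <- setdiff(labels, ledger$true_class[i])
    new_label <- if (length(alt) == 0) "off" else
      if (length(alt) == 1) alt else sample(alt, 1)
    chis <- .sample_chis(aa, new_label, inventory, defs)
    sel <- which(atom$seq_id == ledger$seq_id[i] & atom$chain == ledger$chain[i])
    res <- atom[sel, , drop = FALSE]
    bbpos <- lapply(stats::setNames(nm = intersect(keep_bb, res$name)),
                    function(nm) {
                      j <- match(nm, res$name)
                      c(res$x[j], res$y[j], res$z[j])
                    })
    sc <- .build_sidechain(aa, chis, bbpos, tmpl)
    sc <- sc[setdiff(names(sc), keep_bb)]
    drop <- sel[!res$name %in% keep_bb]
    keep <- res[res$name %in% keep_bb, , drop = FALSE]
    newrows <- if (length(sc)) {
      data.frame(name = names(sc), element = .element_of(names(sc)),
                 alt = "", aa = aa, chain = ledger$chain[i],
                 seq_id = ledger$seq_id[i], ins = "",
                 x = vapply(sc, `[`, numeric(1), 1),
                 y = vapply(sc, `[`, numeric(1), 2),
                 z = vapply(sc, `[`, numeric(1), 3),
                 occ = 1, b = 20, stringsAsFactors = FALSE)
    } else NULL
    atom <- rbind(atom[seq_len(nrow(atom)) < min(sel), , drop = FALSE],
                  keep, newrows,
                  atom[seq_len(nrow(atom)) > max(sel), , drop = FALSE])
    ledger$predicted_class[i] <- new_label
    ledger$action[i] <- paste0("confused:", new_label)
  }
  rownames(atom) <- NULL
  list(structure = new_structure(atom, id = structure$id,
                                 resolution = structure$resolution),
       ledger = ledger)
}

#' Write a paired original/predicted fixture with its truth table
#'
#' @param config a [generator_config()].
#' @param epsilon0,acc_slope confusion parameters for [mock_predict()].
#' @param dir output directory (created if needed).
#' @param predictor_seed seed for the confusion draws (default
#'   `config$seed + 1`).
#' @return list with `original`, `predicted`, `truth` file paths and the
#'   `ledger` data frame.
#' @export
make_paired_fixture <- function(config, epsilon0 = 0.25, acc_slope = 0,
                                dir, predictor_seed = config$seed + 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gen <- build_peptide(config)
  prd <- mock_predict(gen$structure, gen$ledger, epsilon0 = epsilon0,
                      acc_slope = acc_slope, seed = predictor_seed)
  paths <- list(original = file.path(dir, "original.pdb"),
                predicted = file.path(dir, "predicted.pdb"),
                truth = file.path(dir, "truth.tsv"))
  write_pdb(gen$structure, paths$original)
  write_pdb(prd$structure, paths$predicted)
  utils::write.table(prd$ledger, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  c(paths, list(ledger = prd$ledger))
}
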