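# Residue-by-residue comparison of original and repacked structures and
# the decomposed error statistics: rotamer-class errors, per-Chi angular
# errors at a 30-degree cut-off, breakdowns by amino acid / accessibility /
# secondary structure / protein size, per-class prediction confidence, top
# error transitions, and the ACC-by-rotamer-class ANOVA with Tukey post hoc
# comparisons.

#' Build the per-residue analysis table for one structure
#'
#' Runs the residue-level stages in order: optional ring-name audit/fix,
#' residue quality filter, Chi extraction, symmetric-branch correction,
#' rotamer classification, accessibility, secondary structure, side-chain
#' group.
#'
#' @param structure a `rotaudit_structure`.
#' @param inventory,bins,defs fixture tables.
#' @param fix_names audit and fix swapped PHE/TYR ring names first.
#' @param max_bfactor,required_occupancy residue filter thresholds.
#' @param compute_acc compute Shrake-Rupley accessibility.
#' @param acc_points sampling points per atom.
#' @param dssp_file optional classic DSSP output for this structure.
#' @return data frame, one row per residue: `structure_id`, `chain`,
#'   `seq_id`, `ins`, `aa`, `group`, `n_chi`, `chi1`..`chi4` (corrected),
#'   `rotamer` (`NA` when refused), `retained`, `filter_flag`, `acc`, `ss`,
#'   `n_residues`.
#' @export
residue_records <- function(structure, inventory = rotamer_inventory(),
                            bins = bin_model(), defs = chi_definitions(),
                            fix_names = TRUE, max_bfactor = 40,
                            required_occupancy = 1.0, compute_acc = TRUE,
                            acc_points = 960, dssp_file = NULL) {
  if (fix_names) structure <- fix_ring_names(structure)$structure
  fr <- filter_residues(structure, max_bfactor = max_bfactor,
                        required_occupancy = required_occupancy)
  flags <- fr$per_residue_flags
  a <- structure$atom
  key <- paste(a$chain, a$seq_id, a$ins, sep = "|")
  n <- nrow(flags)
  chim <- matrix(NA_real_, n, 4,
                 dimnames = list(NULL, paste0("chi", 1:4)))
  rot <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    aa <- flags$aa[i]
    k <- n_chi(aa, defs)
    if (k == 0L) next
    res <- a[key == paste(flags$chain[i], flags$seq_id[i], flags$ins[i],
                          sep = "|"), , drop = FALSE]
    ch <- compute_chis(res, aa, defs)
    vals <- correct_symmetric_chi(aa, ch$values)
    chim[i, seq_len(k)] <- vals
    if (flags$flag[i] == "retained" && all(ch$defined)) {
      rot[i] <- classify_rotamer(aa, vals, inventory, bins, defs)
    }
  }
  acc <- rep(NA_real_, n)
  if (compute_acc) {
    ap <- shrake_rupley_acc(structure, n_points = acc_points)
    acc <- ap$acc[match(paste(flags$chain, flags$seq_id, flags$ins),
                        paste(ap$chain, ap$seq_id, ap$ins))]
  }
  ssd <- ingest_secondary_structure(structure, dssp_file)
  ss <- ssd$ss[match(paste(flags$chain, flags$seq_id, flags$ins),
                     paste(ssd$chain, ssd$seq_id, ssd$ins))]
  data.frame(structure_id = structure$id, flags[, c("chain", "seq_id", "ins", "aa")],
             group = assign_group(flags$aa),
             n_chi = n_chi(flags$aa, defs), chim,
             rotamer = rot, retained = flags$flag == "retained",
             filter_flag = flags$flag, acc = acc, ss = ss,
             n_residues = n, stringsAsFactors = FALSE)
}

#' Pair original and predicted residue records
#'
#' One comparison row per residue retained and classified in both tables;
#' unmatched residues are reported in the `"unmatched"` attribute, never
#' compared. Per-Chi deviations use the circular difference of the
#' nomenclature-corrected angles; a deviation above 30 degrees marks a Chi
#' error, and any class-label difference marks a rotamer (class) error.
#'
#' @param original,predicted data frames from [residue_records()], keyed
#'   identically (same structure id, chain, numbering).
#' @param program_tag label of the predicting program.
#' @return comparison data frame.
#' @export
pair_structures <- function(original, predicted, program_tag = "mock") {
  k_o <- paste(original$structure_id, original$chain, original$seq_id,
               original$ins, sep = "|")
  k_p <- paste(predicted$structure_id, predicted$chain, predicted$seq_id,
               predicted$ins, sep = "|")
  common <- intersect(k_o, k_p)
  io <- match(common, k_o); ip <- match(common, k_p)
  mism <- original$aa[io] != predicted$aa[ip]
  if (any(mism)) {
    stop("amino-acid mismatch at paired key(s): ",
         paste(utils::head(common[mism], 3), collapse = ", "))
  }
  use <- original$retained[io] & predicted$retained[ip] &
    !is.na(original$rotamer[io]) & !is.na(predicted$rotamer[ip])
  io2 <- io[use]; ip2 <- ip[use]
  dev <- matrix(NA_real_, length(io2), 4,
                dimnames = list(NULL, paste0("dev", 1:4)))
  for (j in 1:4) {
    cj <- paste0("chi", j)
    dev[, j] <- ifelse(is.na(original[[cj]][io2]) | is.na(predicted[[cj]][ip2]),
                       NA_real_,
                       circular_distance(original[[cj]][io2], predicted[[cj]][ip2]))
  }
  err <- dev > 30
  colnames(err) <- paste0("err", 1:4)
  out <- data.frame(
    structure_id = original$structure_id[io2], chain = original$chain[io2],
    seq_id = original$seq_id[io2], ins = original$ins[io2],
    aa = original$aa[io2], group = original$group[io2],
    n_chi = original$n_chi[io2],
    original_class = original$rotamer[io2],
    predicted_class = predicted$rotamer[ip2],
    class_error = original$rotamer[io2] != predicted$rotamer[ip2],
    dev, err,
    acc = original$acc[io2], ss = original$ss[io2],
    n_residues = original$n_residues[io2],
    program_tag = program_tag, stringsAsFactors = FALSE)
  only_o <- setdiff(k_o, k_p)
  only_p <- setdiff(k_p, k_o)
  unmatched <- data.frame(
    side = c(rep("original", length(only_o)), rep("predicted", length(only_p))),
    key = c(only_o, only_p), stringsAsFactors = FALSE)
  attr(out, "unmatched") <- unmatched
  out
}

# long per-Chi view of a comparison table
.chi_long <- function(cmp) {
  do.call(rbind, lapply(1:4, function(j) {
    keep <- !is.na(cmp[[paste0("dev", j)]])
    if (!any(keep)) return(NULL)
    data.frame(cmp[keep, c("aa", "group", "acc", "ss", "n_residues",
                           "program_tag")],
               chi = j, deviation = cmp[[paste0("dev", j)]][keep],
               error = cmp[[paste0("err", j)]][keep],
               stringsAsFactors = FALSE)
  }))
}

.metric_frame <- function(comparisons, metric) {
  if (metric == "chi") {
    d <- .chi_long(comparisons)
    data.frame(aa = d$aa, error = d$error, acc = d$acc, ss = d$ss,
               group = d$group, n_residues = d$n_residues, chi = d$chi,
               stringsAsFactors = FALSE)
  } else {
    data.frame(aa = comparisons$aa, error = comparisons$class_error,
               acc = comparisons$acc, ss = comparisons$ss,
               group = comparisons$group,
               n_residues = comparisons$n_residues, chi = NA_integer_,
               stringsAsFactors = FALSE)
  }
}

#' Percentage of prediction errors per amino acid
#'
#' Errors for an amino acid divided by its number of records (the mean of
#' the dichotomized error variable), as a percentage; includes an
#' `"overall"` row.
#'
#' @param comparisons table from [pair_structures()].
#' @param metric `"class"` (rotamer-class identity) or `"chi"` (per-angle
#'   30-degree dichotomization; the unit is then one Chi angle).
#' @return data frame `aa`, `n`, `errors`, `percent`.
#' @export
error_rate_by_aa <- function(comparisons, metric = c("class", "chi")) {
  metric <- match.arg(metric)
  d <- .metric_frame(comparisons, metric)
  agg <- stats::aggregate(error ~ aa, data = d,
                          FUN = function(x) c(n = length(x), e = sum(x)))
  out <- data.frame(aa = agg$aa, n = agg$error[, "n"],
                    errors = agg$error[, "e"],
                    percent = 100 * agg$error[, "e"] / agg$error[, "n"])
  rbind(out, data.frame(aa = "overall", n = nrow(d), errors = sum(d$error),
                        percent = 100 * mean(d$error)))
}

#' Percentage contribution of each amino acid to all errors
#'
#' @inheritParams error_rate_by_aa
#' @return data frame `aa`, `errors`, `percent` (sums to 100).
#' @export
contribution_by_aa <- function(comparisons, metric = c("class", "chi")) {
  metric <- match.arg(metric)
  d <- .metric_frame(comparisons, metric)
  tot <- sum(d$error)
  if (tot == 0) {
    out <- data.frame(aa = character(0), errors = integer(0),
                      percent = numeric(0))
    attr(out, "note") <- "no errors"
    return(out)
  }
  agg <- stats::aggregate(error ~ aa, data = d, FUN = sum)
  agg <- agg[agg$error > 0, , drop = FALSE]
  data.frame(aa = agg$aa, errors = agg$error,
             percent = 100 * agg$error / tot)
}

#' Error rates stratified by solvent accessibility
#'
#' Rates per 20-Angstrom^2 accessibility bin and per category (zero / low /
#' medium / high); empty strata are absent rather than zero. Bins beyond
#' 220 Angstrom^2 are flagged as potentially low-count.
#'
#' @inheritParams error_rate_by_aa
#' @param per_chi additionally stratify the `"chi"` metric by Chi index.
#' @return list with data frames `by_bin` and `by_category`.
#' @export
error_rate_by_acc <- function(comparisons, metric = c("class", "chi"),
                              per_chi = FALSE) {
  metric <- match.arg(metric)
  d <- .metric_frame(comparisons, metric)
  d <- d[!is.na(d$acc), , drop = FALSE]
  d$bin <- acc_bin(d$acc)
  d$category <- as.character(acc_category(d$acc))
  grp_bin <- if (per_chi && metric == "chi") c("chi", "bin") else "bin"
  agg1 <- stats::aggregate(d$error, by = d[grp_bin],
                           FUN = function(x) c(n = length(x), e = sum(x)))
  by_bin <- data.frame(agg1[grp_bin], n = agg1$x[, "n"],
                       errors = agg1$x[, "e"],
                       percent = 100 * agg1$x[, "e"] / agg1$x[, "n"])
  num <- suppressWarnings(as.numeric(sub(">", "", by_bin$bin)))
  by_bin$low_count_flag <- num > 220
  ord1 <- if (per_chi && metric == "chi") by_bin$chi else rep(0L, nrow(by_bin))
  by_bin <- by_bin[order(ord1, num), ]
  rownames(by_bin) <- NULL
  grp_cat <- if (per_chi && metric == "chi") c("chi", "category") else "category"
  agg2 <- stats::aggregate(d$error, by = d[grp_cat],
                           FUN = function(x) c(n = length(x), e = sum(x)))
  by_category <- data.frame(agg2[grp_cat], n = agg2$x[, "n"],
                            errors = agg2$x[, "e"],
                            percent = 100 * agg2$x[, "e"] / agg2$x[, "n"])
  ord <- match(by_category$category, c("zero", "low", "medium", "high"))
  ord1 <- if (per_chi && metric == "chi") by_category$chi else rep(0L, nrow(by_category))
  by_category <- by_category[order(ord1, ord), ]
  rownames(by_category) <- NULL
  list(by_bin = by_bin, by_category = by_category)
}

#' Prediction accuracy by stratum
#'
#' Percent of correctly predicted rotamer classes per secondary-structure
#' code, protein-size bin (residue count, bins of `size_bin`) or side-chain
#' group.
#'
#' @param comparisons table from [pair_structures()].
#' @param stratum one of `"secondary_structure"`, `"protein_size"`,
#'   `"group"`.
#' @param size_bin width of the protein-size bins (default 100 residues).
#' @return data frame `stratum`, `n`, `correct`, `accuracy` (percent).
#' @export
accuracy_by_stratum <- function(comparisons,
                                stratum = c("secondary_structure",
                                            "protein_size", "group"),
                                size_bin = 100) {
  stratum <- match.arg(stratum)
  s <- switch(stratum,
              secondary_structure = comparisons$ss,
              protein_size = as.character(floor(comparisons$n_residues / size_bin) * size_bin),
              group = comparisons$group)
  agg <- stats::aggregate(!comparisons$class_error, by = list(stratum = s),
                          FUN = function(x) c(n = length(x), ok = sum(x)))
  data.frame(stratum = agg$stratum, n = agg$x[, "n"],
             correct = agg$x[, "ok"],
             accuracy = 100 * agg$x[, "ok"] / agg$x[, "n"])
}

#' Per-class prediction confidence
#'
#' For every original class of every amino acid: the percentage of its
#' records predicted as the same class, per program and macro-averaged
#' across programs.
#'
#' @param comparisons table from [pair_structures()] (possibly several
#'   programs row-bound).
#' @return data frame `aa`, `class`, one `conf_<tag>` column per program,
#'   `confidence` (macro average), `n` (records per program summed).
#' @export
confidence_by_class <- function(comparisons) {
  tags <- unique(comparisons$program_tag)
  base <- unique(comparisons[, c("aa", "original_class")])
  base <- base[order(base$aa, base$original_class), , drop = FALSE]
  names(base) <- c("aa", "class")
  conf <- matrix(NA_real_, nrow(base), length(tags),
                 dimnames = list(NULL, paste0("conf_", tags)))
  ntot <- numeric(nrow(base))
  for (t in seq_along(tags)) {
    ct <- comparisons[comparisons$program_tag == tags[t], , drop = FALSE]
    for (i in seq_len(nrow(base))) {
      sel <- ct$aa == base$aa[i] & ct$original_class == base$class[i]
      if (!any(sel)) next
      conf[i, t] <- 100 * mean(ct$predicted_class[sel] == base$class[i])
      ntot[i] <- ntot[i] + sum(sel)
    }
  }
  data.frame(base, conf, confidence = rowMeans(conf, na.rm = TRUE),
             n = ntot, stringsAsFactors = FALSE)
}

#' Most frequent error transitions for one amino acid
#'
#' Transitions among erroneous pairs, labelled "original to predicted",
#' ranked by count (ties broken lexicographically by label).
#'
#' @param comparisons table from [pair_structures()].
#' @param aa three-letter code.
#' @param n number of transitions to return (default 10).
#' @return data frame `rank`, `transition`, `count` (empty when the amino
#'   acid has no errors).
#' @export
top_transitions <- function(comparisons, aa, n = 10) {
  d <- comparisons[comparisons$aa == aa & comparisons$class_error, , drop = FALSE]
  if (nrow(d) == 0) {
    return(data.frame(rank = integer(0), transition = character(0),
                      count = integer(0)))
  }
  lab <- paste(d$original_class, "to", d$predicted_class)
  tab <- table(lab)
  ord <- order(-as.integer(tab), names(tab))
  top <- utils::head(ord, n)
  data.frame(rank = seq_along(top), transition = names(tab)[top],
             count = as.integer(tab)[top], stringsAsFactors = FALSE)
}

#' One-way ANOVA of accessibility across rotamer classes
#'
#' @param records residue records (original structures) from
#'   [residue_records()], with accessibility computed.
#' @param aa three-letter code.
#' @return list `F`, `p`, `df_between`, `df_within`, `n_classes`.
#' @export
anova_acc_by_class <- function(records, aa) {
  d <- records[records$aa == aa & !is.na(records$rotamer) &
                 !is.na(records$acc), , drop = FALSE]
  counts <- table(d$rotamer)
  counts <- counts[counts >= 2]
  if (length(counts) < 2) {
    stop("degenerate grouping for ", aa,
         ": need at least two classes with at least two records each")
  }
  d <- d[d$rotamer %in% names(counts), , drop = FALSE]
  fit <- stats::aov(acc ~ rotamer, data = transform(d, rotamer = factor(rotamer)))
  s <- summary(fit)[[1]]
  list(F = s[["F value"]][1], p = s[["Pr(>F)"]][1],
       df_between = s[["Df"]][1], df_within = s[["Df"]][2],
       n_classes = length(counts))
}

#' Family size for the across-amino-acid Tukey adjustment
#'
#' Number of distinct class pairs over all amino acids, off class included:
#' `sum(choose(k_aa, 2))` where `k_aa` counts inventory classes plus off.
#'
#' @param inventory inventory table from [rotamer_inventory()].
#' @return integer (963 for the shipped inventory).
#' @export
tukey_family_size <- function(inventory = rotamer_inventory()) {
  k <- table(inventory$aa)
  as.integer(sum(choose(k, 2)))
}

#' Scale a post hoc p-value by the family size
#'
#' Bonferroni-style scaling of a per-amino-acid Tukey p-value to the full
#' family of class pairs, capped at 1.
#'
#' @param p raw p-value(s).
#' @param family_size number of comparisons in the family.
#' @return adjusted p-value(s).
#' @export
adjust_p <- function(p, family_size = tukey_family_size()) {
  pmin(1, p * family_size)
}

#' Tukey HSD of accessibility between rotamer classes
#'
#' All-pairs Tukey honest-significant-difference comparisons of mean
#' accessibility across the rotamer classes (off included) of one amino
#' acid, with the raw studentized-range p-value additionally scaled by the
#' across-amino-acid family size. Significance requires the adjusted
#' p-value below `alpha`. Classes with a single record are dropped with a
#' note.
#'
#' @param records residue records with accessibility.
#' @param aa three-letter code.
#' @param family_size comparisons in the full family (default: derived from
#'   the shipped inventory, 963).
#' @param alpha significance level (default 0.05).
#' @return data frame `aa`, `pair`, `difference`, `ci_low`, `ci_high`,
#'   `p_raw`, `p_adjusted`, `significant`, `correlation` (for pairs
#'   involving off: `off_higher_acc` / `off_lower_acc`, else `n/a`);
#'   attribute `dropped` lists singleton classes.
#' @export
tukey_hsd <- function(records, aa, family_size = tukey_family_size(),
                      alpha = 0.05) {
  d <- records[records$aa == aa & !is.na(records$rotamer) &
                 !is.na(records$acc), , drop = FALSE]
  counts <- table(d$rotamer)
  dropped <- names(counts)[counts < 2]
  d <- d[!d$rotamer %in% dropped, , drop = FALSE]
  if (length(unique(d$rotamer)) < 2) {
    stop("fewer than two usable classes for ", aa)
  }
  fit <- stats::aov(acc ~ rotamer, data = transform(d, rotamer = factor(rotamer)))
  tk <- stats::TukeyHSD(fit, conf.level = 0.95)$rotamer
  pairs <- rownames(tk)
  means <- tapply(d$acc, d$rotamer, mean)
  first <- sub("-.*$", "", pairs)
  second <- sub("^[^-]*-", "", pairs)
  # pair labels are "B-A" with difference mean(B) - mean(A)
  corr <- rep("n/a", length(pairs))
  has_off <- first == "off" | second == "off"
  off_minus_other <- ifelse(first == "off", tk[, "diff"], -tk[, "diff"])
  corr[has_off] <- ifelse(off_minus_other[has_off] > 0,
                          "off_higher_acc", "off_lower_acc")
  out <- data.frame(aa = aa, pair = pairs, difference = tk[, "diff"],
                    ci_low = tk[, "lwr"], ci_high = tk[, "upr"],
                    p_raw = tk[, "p adj"],
                    p_adjusted = adjust_p(tk[, "p adj"], family_size),
                    stringsAsFactors = FALSE)
  out$significant <- out$p_adjusted < alpha
  out$correlation <- corr
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}
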