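# Synthetic peptide generator and mock predictor.

test_that("built structures realize the prescribed Chi angles", {
  cfg <- generator_config(n_residues = 60, seed = 42)
  gen <- build_peptide(cfg)
  a <- gen$structure$atom
  worst <- 0
  pro_worst <- 0
  for (i in seq_len(nrow(gen$ledger))) {
    aa <- gen$ledger$aa[i]
    k <- n_chi(aa)
    if (k == 0) next
    got <- compute_chis(a[a$seq_id == i, ], aa)$values
    want <- as.numeric(gen$ledger[i, paste0("chi", seq_len(k))])
    err <- max(circular_distance(got, want))
    if (aa == "PRO") pro_worst <- max(pro_worst, err) else worst <- max(worst, err)
  }
  expect_lt(worst, 1e-4)
  expect_lt(pro_worst, 1)
  # an all-LEU helix prescribed mt measures (-65, 180) everywhere
  cfg2 <- generator_config(n_residues = 20, seed = 43,
                           sequence = rep("LEU", 20),
                           class_weights = list(LEU = c(mt = 1)))
  gen2 <- build_peptide(cfg2)
  for (i in 1:20) {
    got <- compute_chis(gen2$structure$atom[gen2$structure$atom$seq_id == i, ],
                        "LEU")$values
    expect_lt(circular_distance(got[1], gen2$ledger$chi1[i]), 1e-4)
    expect_lt(circular_distance(got[2], gen2$ledger$chi2[i]), 1e-4)
    expect_equal(classify_rotamer("LEU", got), "mt")
  }
})

test_that("generation is deterministic and corruption rates are honoured", {
  cfg <- generator_config(n_residues = 50, seed = 9, occupancy_corruption = 0.2)
  f1 <- tempfile(fileext = ".pdb"); f2 <- tempfile(fileext = ".pdb")
  write_pdb(build_peptide(cfg)$structure, f1)
  write_pdb(build_peptide(cfg)$structure, f2)
  expect_identical(readLines(f1), readLines(f2))

  # corrupted-occupancy fraction tracks the configured rate (3 binomial SE)
  cfg2 <- generator_config(n_residues = 600, seed = 10,
                           occupancy_corruption = 0.1)
  gen <- build_peptide(cfg2)
  rep <- filter_residues(gen$structure)
  frac_bad <- 1 - rep$residues_retained / rep$residues_total
  expect_lt(abs(frac_bad - 0.1), 3 * sqrt(0.1 * 0.9 / 600))
  expect_equal(rep$per_residue_flags$flag == "bad_occupancy",
               gen$ledger$occ_corrupted)
})

test_that("mock predictor honours the confusion probability limits", {
  cfg <- generator_config(n_residues = 80, seed = 12)
  gen <- build_peptide(cfg)
  keep <- mock_predict(gen$structure, gen$ledger, epsilon0 = 0, seed = 1)
  expect_true(all(keep$ledger$action %in% c("kept", "no_sidechain")))
  expect_identical(keep$structure$atom, gen$structure$atom)

  flip <- mock_predict(gen$structure, gen$ledger, epsilon0 = 1, seed = 1)
  has_chi <- !is.na(flip$ledger$true_class)
  expect_true(all(grepl("^confused", flip$ledger$action[has_chi])))
  expect_true(all(flip$ledger$predicted_class[has_chi] !=
                    flip$ledger$true_class[has_chi]))
  # and the rebuilt structures classify as the confused-to labels
  rec <- residue_records(flip$structure, compute_acc = FALSE)
  m <- merge(rec[!is.na(rec$rotamer), ],
             flip$ledger[, c("seq_id", "predicted_class")], by = "seq_id")
  expect_equal(m$rotamer, m$predicted_class)
})

test_that("different seeds vary the confusions but not the marginal rate", {
  cfg <- generator_config(n_residues = 500, seed = 13)
  gen <- build_peptide(cfg)
  p1 <- mock_predict(gen$structure, gen$ledger, epsilon0 = 0.25, seed = 1)
  p2 <- mock_predict(gen$structure, gen$ledger, epsilon0 = 0.25, seed = 2)
  c1 <- grepl("^confused", p1$ledger$action)
  c2 <- grepl("^confused", p2$ledger$action)
  expect_false(identical(which(c1), which(c2)))
  n <- sum(!is.na(gen$ledger$true_class))
  se <- sqrt(0.25 * 0.75 / n)
  expect_lt(abs(mean(c1[!is.na(gen$ledger$true_class)]) - 0.25), 3 * se)
  expect_lt(abs(mean(c2[!is.na(gen$ledger$true_class)]) - 0.25), 3 * se)
})

test_that("paired fixtures feed the pipeline and reproduce their ledger", {
  dir <- tempfile("fix")
  cfg <- generator_config(n_residues = 8, seed = 21,
                          sequence = c("LEU", "VAL", "SER", "ASN", "LYS",
                                       "PHE", "GLY", "MET"))
  fx <- make_paired_fixture(cfg, epsilon0 = 0.5, dir = dir)
  expect_true(all(file.exists(unlist(fx[c("original", "predicted", "truth")]))))
  o <- residue_records(read_pdb(fx$original, id = "p"), acc_points = 120)
  p <- residue_records(read_pdb(fx$predicted, id = "p"), compute_acc = FALSE)
  cmp <- pair_structures(o, p, "mock")
  truth <- utils::read.delim(fx$truth)
  m <- merge(cmp, truth, by = "seq_id")
  expect_equal(m$class_error, grepl("^confused", m$action))
  expect_equal(m$original_class, m$true_class)
})
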