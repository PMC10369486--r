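# Pairing, error decompositions, confidence, transitions, statistics.

test_that("identical structures compare with zero errors and deviations", {
  pair <- shared_pair()
  cmp <- pair_structures(pair$orec, pair$orec, "self")
  expect_true(all(!cmp$class_error))
  devs <- unlist(cmp[, paste0("dev", 1:4)])
  expect_true(all(devs[!is.na(devs)] < 1e-9))
})

test_that("comparison flags match the mock predictor's ledger exactly", {
  pair <- shared_pair()
  cmp <- pair$cmp
  led <- pair$prd$ledger
  m <- merge(cmp, led, by = "seq_id")
  expect_gt(nrow(m), 50)
  expect_equal(m$original_class, m$true_class)
  expect_equal(m$predicted_class.x, m$predicted_class.y)
  expect_equal(m$class_error, grepl("^confused", m$action))
  # a class error implies at least one Chi deviation beyond the bin reach;
  # identical labels keep both conformations inside the same bins, so no
  # per-angle deviation can exceed twice the halfwidth
  errs <- cmp[, paste0("err", 1:4)]
  for (i in which(!cmp$class_error & cmp$original_class != "off")) {
    devs <- unlist(cmp[i, paste0("dev", 1:4)])
    expect_true(all(devs <= 60 + 1e-9, na.rm = TRUE))
  }
  # aa mismatch at the same key is an error
  bad <- pair$prec
  bad$aa[1] <- if (bad$aa[1] == "GLY") "ALA" else "GLY"
  expect_error(pair_structures(pair$orec, bad), "mismatch")
})

test_that("error rates and contributions decompose as ratios of counts", {
  mk <- function(aa, err) data.frame(
    structure_id = "s", chain = "A", seq_id = seq_along(aa), ins = "",
    aa = aa, group = assign_group(aa), n_chi = n_chi(aa),
    original_class = "x", predicted_class = ifelse(err, "y", "x"),
    class_error = err, dev1 = ifelse(err, 90, 0), dev2 = NA_real_,
    dev3 = NA_real_, dev4 = NA_real_, err1 = err, err2 = NA, err3 = NA,
    err4 = NA, acc = 50, ss = "H", n_residues = 100, program_tag = "mock",
    stringsAsFactors = FALSE)
  cmp <- mk(c(rep("LYS", 10), rep("ARG", 5)),
            c(rep(TRUE, 4), rep(FALSE, 6), TRUE, rep(FALSE, 4)))
  er <- error_rate_by_aa(cmp)
  expect_equal(er$percent[er$aa == "LYS"], 40)
  expect_equal(er$percent[er$aa == "ARG"], 20)
  expect_equal(er$percent[er$aa == "overall"], 100 * 5 / 15)

  co <- contribution_by_aa(cmp)
  expect_equal(co$percent[co$aa == "LYS"], 80)
  expect_equal(co$percent[co$aa == "ARG"], 20)
  expect_equal(sum(co$percent), 100)

  none <- mk("LYS", FALSE)
  expect_equal(error_rate_by_aa(none)$percent, c(0, 0))
  expect_equal(nrow(contribution_by_aa(none)), 0)

  # contributions over many amino acids still sum to 100
  pair <- shared_pair()
  if (sum(pair$cmp$class_error) > 0) {
    expect_equal(sum(contribution_by_aa(pair$cmp)$percent), 100,
                 tolerance = 1e-9)
  }
})

test_that("accessibility strata report rates only where cases exist", {
  cmp <- data.frame(
    aa = "LYS", group = "IV", n_chi = 4L, original_class = "mttt",
    predicted_class = c("mttt", "tttt", "mttt", "mttt"),
    class_error = c(FALSE, TRUE, FALSE, FALSE),
    dev1 = c(0, 90, 0, 0), dev2 = NA_real_, dev3 = NA_real_, dev4 = NA_real_,
    err1 = c(FALSE, TRUE, FALSE, FALSE), err2 = NA, err3 = NA, err4 = NA,
    acc = c(105, 110, 30, 250), ss = "H", n_residues = 100,
    program_tag = "mock", structure_id = "s", chain = "A",
    seq_id = 1:4, ins = "", stringsAsFactors = FALSE)
  res <- error_rate_by_acc(cmp)
  expect_equal(res$by_bin$percent[res$by_bin$bin == "100"], 50)
  expect_equal(res$by_bin$percent[res$by_bin$bin == "20"], 0)
  expect_false("60" %in% res$by_bin$bin)  # empty bin absent, not zero
  expect_true(res$by_bin$low_count_flag[res$by_bin$bin == "240"])
  expect_equal(res$by_category$percent[res$by_category$category == "high"],
               100 / 3, tolerance = 1e-9)
  expect_false("zero" %in% res$by_category$category)
})

test_that("stratified accuracy complements the error rate", {
  pair <- shared_pair()
  acc_ss <- accuracy_by_stratum(pair$cmp, "secondary_structure")
  expect_true(all(acc_ss$accuracy >= 0 & acc_ss$accuracy <= 100))
  overall_err <- error_rate_by_aa(pair$cmp)
  err_all <- overall_err$percent[overall_err$aa == "overall"]
  pooled <- sum(acc_ss$correct) / sum(acc_ss$n) * 100
  expect_equal(pooled + err_all, 100, tolerance = 1e-9)
  one <- accuracy_by_stratum(pair$cmp[pair$cmp$ss == pair$cmp$ss[1], ],
                             "secondary_structure")
  expect_equal(nrow(one), 1)
  sz <- accuracy_by_stratum(pair$cmp, "protein_size")
  expect_equal(sz$stratum, "100")  # 120-residue chain falls in the 100 bin
})

test_that("per-class confidence is the diagonal of the confusion", {
  cmp <- data.frame(
    aa = "LYS", original_class = c(rep("mttt", 4), "tttt"),
    predicted_class = c("mttt", "mttt", "mttt", "tttt", "tttt"),
    class_error = c(FALSE, FALSE, FALSE, TRUE, FALSE),
    program_tag = "mock", stringsAsFactors = FALSE)
  cf <- confidence_by_class(cmp)
  expect_equal(cf$confidence[cf$class == "mttt"], 75)
  expect_equal(cf$confidence[cf$class == "tttt"], 100)

  pair <- shared_pair()
  perfect <- pair_structures(pair$orec, pair$orec, "self")
  cfp <- confidence_by_class(perfect)
  expect_true(all(cfp$confidence == 100))

  # two programs: macro average of per-program diagonals
  two <- rbind(cmp, transform(cmp, program_tag = "other",
                              predicted_class = "mttt",
                              class_error = original_class != "mttt"))
  cft <- confidence_by_class(two)
  expect_equal(cft$conf_mock[cft$class == "mttt"], 75)
  expect_equal(cft$conf_other[cft$class == "mttt"], 100)
  expect_equal(cft$confidence[cft$class == "mttt"], 87.5)
})

test_that("top transitions rank by count with lexicographic ties", {
  cmp <- data.frame(
    aa = "VAL",
    original_class = c(rep("m", 5), rep("p", 3), "t", "t"),
    predicted_class = c(rep("t", 5), rep("t", 3), "m", "p"),
    class_error = TRUE, program_tag = "mock", stringsAsFactors = FALSE)
  tt <- top_transitions(cmp, "VAL")
  expect_equal(tt$transition[1:2], c("m to t", "p to t"))
  expect_equal(tt$count[1:2], c(5, 3))
  # tie 1/1 resolved lexicographically
  expect_equal(tt$transition[3:4], c("t to m", "t to p"))
  expect_equal(nrow(top_transitions(cmp, "LEU")), 0)
  expect_equal(nrow(top_transitions(cmp, "VAL", n = 2)), 2)
})

test_that("ANOVA matches a sum-of-squares oracle and separates groups", {
  mkrec <- function(cls, acc) data.frame(
    structure_id = "s", chain = "A", seq_id = seq_along(cls), ins = "",
    aa = "LEU", group = "II", n_chi = 2L, chi1 = -65, chi2 = 180,
    chi3 = NA_real_, chi4 = NA_real_, rotamer = cls, retained = TRUE,
    filter_flag = "retained", acc = acc, ss = "H", n_residues = 30,
    stringsAsFactors = FALSE)
  # textbook 3-group toy data against a hand-computed oracle
  cls <- rep(c("mt", "tp", "off"), each = 5)
  acc <- c(12, 15, 11, 14, 13, 22, 25, 21, 27, 24, 40, 44, 39, 43, 42)
  got <- anova_acc_by_class(mkrec(cls, acc), "LEU")
  grand <- mean(acc)
  ssb <- sum(tapply(acc, cls, function(g) length(g) * (mean(g) - grand)^2))
  ssw <- sum(unlist(tapply(acc, cls, function(g) (g - mean(g))^2)))
  F_oracle <- (ssb / 2) / (ssw / 12)
  expect_equal(got$F, F_oracle, tolerance = 1e-8)
  expect_equal(got$df_between, 2)
  expect_equal(got$df_within, 12)
  # separation limit: identical values per group, different means
  sep <- anova_acc_by_class(mkrec(rep(c("mt", "tp"), each = 4),
                                  rep(c(10, 60), each = 4)), "LEU")
  expect_gt(sep$F, 1e10)
  expect_lt(sep$p, 1e-12)
  expect_error(anova_acc_by_class(mkrec("mt", 10), "LEU"), "degenerate")
})

test_that("Tukey results carry the family-scaled adjustment", {
  expect_equal(tukey_family_size(), 963L)
  expect_equal(adjust_p(1.67e-5, 963), 1.67e-5 * 963)
  expect_equal(adjust_p(0.5, 963), 1)
  set.seed(61)
  mkrec <- function(cls, acc) data.frame(
    structure_id = "s", chain = "A", seq_id = seq_along(cls), ins = "",
    aa = "LEU", group = "II", n_chi = 2L, chi1 = -65, chi2 = 180,
    chi3 = NA_real_, chi4 = NA_real_, rotamer = cls, retained = TRUE,
    filter_flag = "retained", acc = acc, ss = "H", n_residues = 30,
    stringsAsFactors = FALSE)
  cls <- rep(c("mt", "tp", "off"), each = 20)
  acc <- c(rnorm(20, 20, 5), rnorm(20, 22, 5), rnorm(20, 80, 5))
  tk <- tukey_hsd(mkrec(cls, acc), "LEU")
  expect_equal(tk$p_adjusted, pmin(1, tk$p_raw * 963))
  expect_true(all(tk$ci_low <= tk$difference & tk$difference <= tk$ci_high))
  expect_true(all(tk$p_adjusted >= tk$p_raw))
  expect_equal(tk$significant, tk$p_adjusted < 0.05)
  off_rows <- grepl("(^off-)|(-off$)", tk$pair)
  expect_true(all(tk$correlation[off_rows] == "off_higher_acc"))
  expect_true(all(tk$correlation[!off_rows] == "n/a"))
  # equal means: difference near 0, CI spans 0
  acc2 <- rep(rnorm(20, 30, 4), 2)
  tk2 <- tukey_hsd(mkrec(rep(c("mt", "tp"), each = 20), c(acc2)), "LEU")
  expect_true(tk2$ci_low < 0 & tk2$ci_high > 0)
  # singleton classes are dropped with a note
  tk3 <- tukey_hsd(mkrec(c(cls, "pp"), c(acc, 50)), "LEU")
  expect_equal(attr(tk3, "dropped"), "pp")
  expect_false(any(grepl("pp", tk3$pair)))
})

test_that("null ANOVA p-values hold the nominal type-I rate", {
  set.seed(71)
  mkrec <- function(cls, acc) data.frame(
    structure_id = "s", chain = "A", seq_id = seq_along(cls), ins = "",
    aa = "LEU", group = "II", n_chi = 2L, chi1 = -65, chi2 = 180,
    chi3 = NA_real_, chi4 = NA_real_, rotamer = cls, retained = TRUE,
    filter_flag = "retained", acc = acc, ss = "H", n_residues = 30,
    stringsAsFactors = FALSE)
  cls <- rep(c("mt", "tp", "off"), each = 10)
  hits <- 0
  nsim <- 1000
  for (i in seq_len(nsim)) {
    p <- anova_acc_by_class(mkrec(cls, rnorm(30, 50, 10)), "LEU")$p
    if (p < 0.05) hits <- hits + 1
  }
  expect_lt(abs(hits / nsim - 0.05), 0.015)
})
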