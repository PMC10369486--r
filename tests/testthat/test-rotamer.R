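# Discretized rotamer classification.

test_that("circular distance satisfies its identities", {
  expect_equal(circular_distance(10, -10), 20)
  expect_equal(circular_distance(170, -170), 20)
  set.seed(41)
  x <- runif(200, -720, 720); y <- runif(200, -720, 720)
  expect_equal(circular_distance(x, x), rep(0, 200))
  expect_equal(circular_distance(x, y), circular_distance(y, x))
  expect_true(all(circular_distance(x, y) >= 0 & circular_distance(x, y) <= 180))
  expect_equal(circular_distance(x + 360, y), circular_distance(x, y))
})

test_that("classification reproduces canonical labels and the off rule", {
  expect_equal(classify_rotamer("LEU", c(-65, 180)), "mt")
  expect_equal(classify_rotamer("ASN", c(-65, -20)), "m-20")
  expect_equal(classify_rotamer("LEU", c(0, 180)), "off")
  expect_equal(classify_rotamer("LYS", c(-65, 180, 180, 180)), "mttt")
  # the generic m bin is [-95, -35]; t wraps across +/-180
  expect_equal(classify_rotamer("CYS", -95), "m")
  expect_equal(classify_rotamer("CYS", -34), "off")
  expect_equal(classify_rotamer("CYS", c(150)), "t")
  expect_equal(classify_rotamer("CYS", c(-150)), "t")
  expect_equal(classify_rotamer("CYS", c(-149)), "off")
  # invariance under adding full turns
  expect_equal(classify_rotamer("LEU", c(-65 + 360, 180 - 720)), "mt")
  # undefined Chi refuses classification
  expect_true(is.na(classify_rotamer("LEU", c(-65, NA))))
  # overlapping named bins resolve to the nearest mode
  expect_equal(classify_rotamer("ASP", c(65, 5)), "p-10")
  expect_equal(classify_rotamer("ASP", c(65, 25)), "p30")
  # symmetric terminal torsions classify with 180-degree periodicity:
  # a corrected +80 is the image of -100, 15 degrees from the m-85 mode
  expect_equal(classify_rotamer("PHE", c(-65, 80)), "m-85")
})

test_that("proline puckers split on Chi1 with the documented tie-break", {
  expect_equal(classify_pro(30), "Cg endo")
  expect_equal(classify_pro(-30), "Cg exo")
  expect_equal(classify_pro(75), "off")
  expect_equal(classify_pro(0), "Cg exo")
  expect_equal(classify_rotamer("PRO", c(25, -25)), "Cg endo")
})

test_that("classification equals an independent qualification scan", {
  # independent oracle: a class qualifies iff every per-Chi deviation from
  # its mode is <= 30 (half-period for symmetric terminals); off iff none
  # qualifies, otherwise the returned label must be a qualifying class
  # minimizing the maximum deviation
  inv <- rotamer_inventory()
  defs <- chi_definitions()
  oracle_dev <- function(aa, chis) {
    cls <- inv[inv$aa == aa & inv$label != "off", ]
    k <- length(chis)
    per <- rotaudit:::.chi_periods(aa, defs)
    dv <- sapply(seq_len(k), function(j) {
      d <- abs(chis[j] - cls[[paste0("mode", j)]]) %% per[j]
      pmin(d, per[j] - d)
    })
    dv <- matrix(dv, nrow = nrow(cls))
    rownames(dv) <- cls$label
    dv
  }
  set.seed(52)
  for (aa in setdiff(unique(inv$aa), "PRO")) {
    k <- n_chi(aa)
    pts <- matrix(runif(200 * k, -180, 180), ncol = k)
    for (i in seq_len(nrow(pts))) {
      chis <- pts[i, ]
      dv <- oracle_dev(aa, chis)
      qual <- rownames(dv)[apply(dv <= 30, 1, all)]
      got <- classify_rotamer(aa, chis)
      if (length(qual) == 0) {
        expect_equal(got, "off", info = paste(aa, toString(round(chis))))
      } else {
        expect_true(got %in% qual)
        expect_equal(max(dv[got, ]), min(apply(dv[qual, , drop = FALSE], 1, max)),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("side-chain-length groups are assigned by Chi count", {
  expect_equal(assign_group("MET"), "III")
  expect_equal(assign_group("ARG"), "IV")
  expect_equal(assign_group("GLY"), "none")
  expect_equal(assign_group(c("CYS", "ASN", "GLN", "LYS")),
               c("I", "II", "III", "IV"))
  expect_error(assign_group("XYZ"), "unknown")
  # group sizes match the Chi arity of the definitions table
  for (aa in unique(chi_definitions()$aa)) {
    expect_equal(assign_group(aa), c("I", "II", "III", "IV")[n_chi(aa)])
  }
})

test_that("the census conserves counts and recovers a known class mix", {
  pair <- shared_pair()
  cen <- rotamer_census(pair$orec)
  body <- cen[cen$aa != "total", ]
  expect_equal(body$canonical + body$off,
               sapply(body$aa, function(a) {
                 sum(!is.na(pair$orec$rotamer[pair$orec$aa == a]))
               }), ignore_attr = TRUE)
  tot <- cen[cen$aa == "total", ]
  expect_equal(tot$canonical, sum(body$canonical))
  expect_equal(tot$off, sum(body$off))
  expect_equal(rotamer_census(pair$orec[0, ]),
               rotamer_census(pair$orec[0, ]))
  expect_equal(nrow(rotamer_census(pair$orec[0, ])), 0)
  # classified labels equal the generator's ledger exactly
  led <- pair$gen$ledger
  m <- merge(pair$orec[!is.na(pair$orec$rotamer), ],
             led[, c("seq_id", "true_class")], by = "seq_id")
  expect_equal(m$rotamer, m$true_class)
  # off percentage: known mix fully recovered
  expect_equal(sum(m$rotamer == "off"),
               sum(led$true_class[led$seq_id %in% m$seq_id] == "off"))
})
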