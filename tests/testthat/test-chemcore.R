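test_that("formula parsing reads Hill-style formulas and rejects bad input", {
  expect_equal(parse_formula("C15H10O6"), c(C = 15L, H = 10L, O = 6L))
  expect_equal(parse_formula("H2O"), c(H = 2L, O = 1L))
  expect_equal(parse_formula("CHBr3")[["Br"]], 3L)
  expect_error(parse_formula("C15X5"), "unknown element")
  expect_error(parse_formula("C0H2"), "count")
  expect_error(parse_formula(""), "non-empty")
})

test_that("monoisotopic masses match flavonoid reference values and an independent oracle", {
  # flavonol backbones, literature monoisotopic masses
  expect_equal(monoisotopic_mass("C15H10O6"), 286.0477, tolerance = 1e-4)
  expect_equal(monoisotopic_mass("C15H10O7"), 302.0427, tolerance = 1e-4)
  expect_equal(monoisotopic_mass(integer()), 0)
  for (f in c("C15H10O5", "C21H20O11", "C6H10O5", "C24H22O8", "C15H16O6")) {
    expect_equal(monoisotopic_mass(f), oracle_mass(f), tolerance = 1e-6)
  }
})

test_that("mass is additive over formula combination", {
  a <- parse_formula("C15H10O6")
  b <- parse_formula("C6H10O5")
  expect_equal(monoisotopic_mass(combine_formulas(a, b)),
               monoisotopic_mass(a) + monoisotopic_mass(b))
  expect_equal(format_formula(combine_formulas("C15H10O6", "C6H10O5")),
               "C21H20O11")
})

test_that("adduct m/z arithmetic reproduces negative-mode reference ions", {
  kae <- monoisotopic_mass("C15H10O6")
  que <- monoisotopic_mass("C15H10O7")
  expect_equal(adduct_mz(kae, "[M-H]-"), 285.0405, tolerance = 1e-4)
  expect_equal(adduct_mz(que, "[M+FA]-"), 347.0409, tolerance = 1e-4)
  expect_equal(adduct_mz(kae, "[2M-H]-"), 571.0882, tolerance = 1e-4)
  expect_equal(adduct_mz(kae, "[M-2H]2-"),
               (kae - 2 * 1.007276) / 2, tolerance = 1e-4)
  expect_error(adduct_mz(-1, "[M-H]-"), "positive")
  expect_error(adduct_mz(100, "[M+XYZ]"), "unknown adduct")
})

test_that("ppm error is signed, zero at equality, antisymmetric in the numerator", {
  expect_equal(ppm_error(300.0272, 300.02755), -1.17, tolerance = 0.01)
  expect_equal(ppm_error(353.0673, 353.06668), 1.76, tolerance = 0.01)
  expect_equal(ppm_error(500, 500), 0)
  x <- 400.1234; y <- 400.1300
  expect_equal(ppm_error(x, y) * y, -ppm_error(y, x) * x)
  expect_error(ppm_error(100, 0), "positive")
})

test_that("O-glycoside cleavage yields the heterolytic/homolytic pair", {
  for (case in list(list("C15H10O6", c(285.0405, 284.0326)),
                    list("C15H10O7", c(301.0354, 300.0276)),
                    list("C15H10O5", c(269.0455, 268.0377)))) {
    fr <- o_glycoside_fragments(monoisotopic_mass(case[[1]]), "X")
    expect_equal(fr$mz, case[[2]], tolerance = 1e-4)
    expect_equal(fr$cleavage, c("heterolytic-O", "homolytic-O"))
    # radical ion is one hydrogen atom below the even-electron ion
    expect_equal(fr$mz[1] - fr$mz[2], 1.007825, tolerance = 1e-4)
  }
  expect_error(o_glycoside_fragments(0), "positive")
})

test_that("C-glycoside fragments retain etenol/C3H4O2 residue combinations", {
  api <- monoisotopic_mass("C15H10O5")
  one <- c_glycoside_fragments(api, 1, "Apigenin")
  expect_equal(sort(one$mz), c(311.0561, 341.0666), tolerance = 1e-4)
  two <- c_glycoside_fragments(api, 2, "Apigenin")
  expect_equal(sort(two$mz), c(353.0667, 383.0772, 413.0877),
               tolerance = 1e-4)
  expect_true(all(two$cleavage == "C-residue"))
  expect_match(two$label[1], "di-etenol")
  expect_error(c_glycoside_fragments(api, 0), "1 or 2")
  expect_error(c_glycoside_fragments(api, 3), "1 or 2")
})

test_that("fragment database enumerates 7 records per aglycone with paired cleavages", {
  one <- build_fragment_db(data.frame(name = "Kaempferol",
                                      formula = "C15H10O6"))
  expect_equal(nrow(one), 7L)
  expect_equal(sum(one$cleavage %in% c("heterolytic-O", "homolytic-O")), 2L)
  expect_equal(sum(one$cleavage == "C-residue"), 5L)

  db <- build_fragment_db()
  # deterministic ordering
  expect_equal(db, dplyr::arrange(db, aglycone, mz))
  # heterolytic - homolytic = one hydrogen atom, for every aglycone
  for (a in unique(db$aglycone)) {
    sub <- db[db$aglycone == a, ]
    d <- sub$mz[sub$cleavage == "heterolytic-O"] -
      sub$mz[sub$cleavage == "homolytic-O"]
    expect_equal(d, 1.007825, tolerance = 1e-4)
  }
  # every fragment lies below its lightest possible glycoside precursor
  # (pentosyl residues, one per sugar the fragment implies)
  pentosyl <- monoisotopic_mass("C5H8O4")
  aglys <- default_aglycones()
  for (i in seq_len(nrow(aglys))) {
    sub <- db[db$aglycone == aglys$name[i], ]
    base <- adduct_mz(monoisotopic_mass(aglys$formula[i]), "[M-H]-")
    n_sugars <- ifelse(sub$residue_mass == 0, 1,
                       ifelse(sub$residue_mass < 80, 1, 2))
    expect_true(all(sub$mz < base + n_sugars * pentosyl))
  }
  expect_error(build_fragment_db(data.frame()), "non-empty")
  expect_error(build_fragment_db(data.frame(name = "bad", formula = "Xx9")),
               "bad")
})

test_that("neutral loss is conserved and rejects inverted arguments", {
  expect_equal(neutral_loss(463.0869, 301.0319), 162.0550, tolerance = 1e-4)
  expect_equal(neutral_loss(563.1420, 353.0673), 210.0747, tolerance = 1e-4)
  expect_error(neutral_loss(300, 300), "below")
  withr::with_seed(7, {
    p <- runif(50, 300, 900)
    f <- p - runif(50, 10, 250)
    expect_equal(neutral_loss(p, f) + f, p)
  })
})

test_that("sugar dictionary masses agree with their formulas and match losses", {
  sug <- sugar_losses()
  for (i in seq_len(nrow(sug))) {
    expect_equal(sug$loss[i], oracle_mass(sug$formula[i]), tolerance = 1e-4)
  }
  expect_equal(match_sugar(162.0550)$name[1], "hexose")
  m <- match_sugar(279.1105, radical = TRUE)
  expect_equal(m$name[1], "deoxyhexosyl-pentose")
  expect_equal(nrow(match_sugar(500.0)), 0L)
  expect_error(match_sugar(162, tol = 0), "positive")
  expect_error(match_sugar(-1), "positive")
})
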