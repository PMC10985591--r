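ms1_toy_table <- function(mz, rt = 2.5) {
  tibble::tibble(row_id = seq_along(mz), mz = mz, rt = rt)
}

test_that("MS1 search finds adduct matches and ranks by ppm", {
  db <- tibble::tibble(
    name = c("Quercetin hexoside", "Kaempferol hexoside"),
    mass = c(464.0955, 448.1006), formula = c("C21H20O12", "C21H20O11"),
    rt = 10, rt_wildcard = TRUE, class = "flavonol", source = "toy")
  hits <- search_ms1(ms1_toy_table(463.0869), db)
  expect_true("Quercetin hexoside" %in% hits$name)
  expect_equal(hits$adduct[hits$name == "Quercetin hexoside"][1], "[M-H]-")
  expect_equal(nrow(search_ms1(ms1_toy_table(999.999), db)), 0L)
  expect_error(search_ms1(ms1_toy_table(463.0869), db[0, ]), "empty")

  # isobars 1 mDa apart: both returned, closer ppm first
  iso <- tibble::tibble(name = c("far", "near"),
                        mass = c(464.0965, 464.0955),
                        formula = NA_character_, rt = 10,
                        rt_wildcard = TRUE, class = "other", source = "toy")
  both <- search_ms1(ms1_toy_table(463.0882), iso)
  expect_equal(nrow(both), 2L)
  expect_equal(both$name, c("near", "far"))
  expect_equal(both$rank, 1:2)
})

test_that("MS1 search results are stable under database row permutation", {
  db <- tibble::tibble(name = letters[1:4],
                       mass = 464.0955 + c(0, 0.001, 0.002, 50),
                       formula = NA_character_, rt = 10, rt_wildcard = TRUE,
                       class = "other", source = "toy")
  a <- search_ms1(ms1_toy_table(463.0882), db)
  b <- search_ms1(ms1_toy_table(463.0882), db[c(3, 1, 4, 2), ])
  expect_equal(a, b)
})

test_that("MS2 search annotates aglycone fragments at paper-scale mass accuracy", {
  fragdb <- build_fragment_db()
  het <- search_ms2(ms1_toy_table(285.0386), fragdb)
  expect_true("Kaempferol [M-H]-" %in% het$label)
  expect_equal(het$ppm[het$label == "Kaempferol [M-H]-"], -6.5,
               tolerance = 0.2)
  hom <- search_ms2(ms1_toy_table(284.0321), fragdb)
  expect_true("Kaempferol [M-H].-" %in% hom$label)
  expect_equal(nrow(search_ms2(ms1_toy_table(150.0), fragdb)), 0L)
  expect_error(search_ms2(ms1_toy_table(285.04), fragdb[0, ]), "empty")
})

test_that("precursor-fragment linking requires co-elution and shape agreement", {
  tr <- gauss_trace(2.0)
  ms1 <- toy_aligned_row(1L, 463.0882, 2.0, tr, height = 1e4)
  ms2 <- toy_aligned_row(1L, 301.0354, 2.0,
                         dplyr::mutate(tr, intensity = intensity * 0.5),
                         height = 5e3, level = 2L)
  link <- link_precursor_fragment(ms1, ms2)
  expect_equal(nrow(link), 1L)
  expect_equal(link$correlation, 1, tolerance = 1e-6)
  expect_equal(link$neutral_loss, 463.0882 - 301.0354)
  expect_equal(link$intensity_ratio, 0.5, tolerance = 1e-6)

  # 0.2 min apart with a 0.04 min tolerance: not linked
  ms2_far <- toy_aligned_row(1L, 301.0354, 2.2, gauss_trace(2.2), level = 2L)
  expect_equal(nrow(link_precursor_fragment(ms1, ms2_far, rt_tol = 0.04)), 0L)

  # noisy co-eluting pair still correlates well above the 0.8 threshold
  withr::with_seed(31, {
    noisy <- gauss_trace(2.0)
    noisy$intensity <- noisy$intensity * 0.4 +
      stats::rnorm(nrow(noisy), 0, 300)
    noisy$intensity[noisy$intensity < 0] <- 0
  })
  ms2_noisy <- toy_aligned_row(1L, 301.0354, 2.0, noisy, level = 2L)
  link2 <- link_precursor_fragment(ms1, ms2_noisy, min_corr = 0.8)
  expect_equal(nrow(link2), 1L)
  expect_gt(link2$correlation, 0.85)

  # fragment stronger than precursor: linked but flagged, with a warning
  ms2_big <- toy_aligned_row(1L, 301.0354, 2.0,
                             dplyr::mutate(tr, intensity = intensity * 2),
                             height = 2e4, level = 2L)
  expect_warning(big <- link_precursor_fragment(ms1, ms2_big),
                 "more intense")
  expect_true(big$fragment_above_precursor)
})

test_that("neutral-loss assignment reproduces representative annotation calls", {
  mk_pair <- function(ms1_mz, ms2_mz) {
    tibble::tibble(ms1_row = 1L, ms2_row = 1L, ms1_mz = ms1_mz,
                   ms2_mz = ms2_mz, rt = 2.5, delta_rt = 0,
                   correlation = 0.99, intensity_ratio = 0.5,
                   neutral_loss = ms1_mz - ms2_mz,
                   fragment_above_precursor = FALSE)
  }
  ann <- function(label, aglycone, cleavage, residue = 0) {
    tibble::tibble(row_id = 1L, mz = 0, rt = 2.5, label = label,
                   aglycone = aglycone, cleavage = cleavage,
                   residue_mass = residue, mz_theo = 0, ppm = 0, rank = 1L,
                   class = "flavonol")
  }
  # quercetin hexoside via heterolytic cleavage
  g1 <- assign_glycoside(mk_pair(463.0869, 301.0319),
                         ann("Quercetin [M-H]-", "Quercetin",
                             "heterolytic-O"))
  expect_equal(g1$bond, "O")
  expect_equal(g1$report, "Quercetin O-hexoside")

  # radical kaempferol aglycone with a 279.111 Da loss
  g2 <- assign_glycoside(mk_pair(563.1426, 284.0321),
                         ann("Kaempferol [M-H].-", "Kaempferol",
                             "homolytic-O"))
  expect_equal(g2$report, "Kaempferol O-deoxyhexosyl-pentoside")

  # apigenin di-C-glycoside: loss decomposes as 90 + 120
  g3 <- assign_glycoside(mk_pair(563.1420, 353.0673),
                         ann("Apigenin-di-etenol [M-H]-", "Apigenin",
                             "C-residue", residue = 84.0211))
  expect_equal(g3$bond, "C")
  expect_true(grepl("di-C-hexoside", g3$sugar) &&
                grepl("C-hexoside-C-pentoside", g3$sugar))

  # unmatched loss is reported numerically, unclassified
  g4 <- assign_glycoside(mk_pair(463.0869, 280.00),
                         ann("Quercetin [M-H]-", "Quercetin",
                             "heterolytic-O"))
  expect_equal(g4$bond, "unclassified")
  expect_match(g4$sugar, "loss 183")
  expect_error(assign_glycoside(mk_pair(400, 300),
                                ann("x", "X", "heterolytic-O")[0, ]),
               "no MS2 annotations")
})

test_that("a glycoside call never carries both bond types and keeps loss conservation", {
  g <- cohort_result()$res$glycosides
  expect_gt(nrow(g), 0L)
  expect_equal(g$neutral_loss, g$ms1_mz - g$ms2_mz)
  expect_true(all(g$bond %in% c("O", "C", "unclassified")))
  expect_true(all(g$cleavage[g$bond == "O"] %in%
                    c("heterolytic-O", "homolytic-O")))
  expect_true(all(g$cleavage[g$bond == "C"] == "C-residue"))
})

test_that("Jaccard isomer scoring follows the set-overlap definition", {
  expect_equal(jaccard_isomer_score(c(1, 2, 3), list(a = c(1, 2, 3)))$jaccard,
               1)
  expect_equal(jaccard_isomer_score(c(1, 2), list(a = c(5, 6)))$jaccard, 0)
  s <- jaccard_isomer_score(c(100.1, 200.2, 300.3),
                            list(a = c(100.1, 200.2, 400.4)))
  expect_equal(s$jaccard, 0.5)
  ranked <- jaccard_isomer_score(c(100.1, 200.2, 300.3),
                                 list(worse = c(100.1, 555.5),
                                      better = c(100.1, 200.2, 300.3)))
  expect_equal(ranked$candidate, c("better", "worse"))
  expect_error(jaccard_isomer_score(numeric(), list(a = 1)), "observed")
  expect_error(jaccard_isomer_score(1, list()), "candidate")
})

test_that("backbone classification counts hits by sample, aglycone and class", {
  ann <- tibble::tibble(row_id = c(1L, 1L, 2L, 3L),
                        aglycone = c("Kaempferol", "Kaempferol",
                                     "Kaempferol", "Apigenin"),
                        class = c("flavonol", "flavonol", "flavonol",
                                  "flavone"))
  pooled <- classify_backbone(ann)
  expect_equal(sum(pooled$n_hits[pooled$class == "flavonol"]), 2L)
  expect_equal(sum(pooled$n_hits[pooled$class == "flavone"]), 1L)
  expect_equal(nrow(classify_backbone(ann[0, ])), 0L)
})
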