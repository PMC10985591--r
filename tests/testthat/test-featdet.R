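test_that("mass detection keeps peaks above the noise level, order preserved", {
  sp <- data.frame(mz = c(100, 200), intensity = c(100, 400))
  expect_equal(nrow(detect_masses(sp, 300)), 1L)
  expect_equal(nrow(detect_masses(sp, 500)), 0L)
  expect_equal(detect_masses(sp, 0), sp)
})

test_that("EIC building matches exhaustive grouping on separated toy ions", {
  ions <- data.frame(mz = c(285.040, 412.120, 550.300),
                     rt = c(0.3, 0.5, 0.7), sigma = 0.02,
                     height = c(2e4, 5e4, 1e4))
  run <- toy_run(ions, n_scans = 600)
  eics <- build_eics(run, 1)
  oracle <- oracle_eic_groups(run, 1)
  expect_equal(nrow(eics), length(oracle))
  for (g in oracle) {
    hit <- which(abs(eics$mz - mean(g)) < 0.005)
    expect_length(hit, 1L)
    # every grouped centroid sits in exactly that EIC's trace
    expect_equal(sort(eics$trace[[hit]]$mz), g)
  }
})

test_that("the consecutive-scan rule suppresses short traces", {
  # 5 consecutive scans above the floor -> one EIC; 4 scans -> none
  mk <- function(n) {
    pk <- data.frame(scan = seq_len(n), rt = (seq_len(n) - 1) * toy_dt,
                     ms_level = 1L, mz = 285.040 + c(-1, 1, -1, 1, 0)[seq_len(n)] * 0.001,
                     intensity = 9000)
    ms_run(pk, run_length = 1)
  }
  expect_equal(nrow(build_eics(mk(5), 1)), 1L)
  expect_equal(nrow(build_eics(mk(4), 1)), 0L)
})

test_that("co-eluting ions 0.05 Da apart give two EICs", {
  ions <- data.frame(mz = c(400.100, 400.150), rt = 0.4, sigma = 0.02,
                     height = 2e4)
  run <- toy_run(ions, n_scans = 500)
  eics <- build_eics(run, 1)
  expect_equal(nrow(eics), 2L)
  expect_equal(sort(eics$mz), c(400.100, 400.150), tolerance = 1e-6)
})

test_that("local-minimum resolving splits twin peaks and enforces the height floor", {
  cfg <- detection_config(1)
  single <- toy_run(data.frame(mz = 400.1, rt = 0.4, sigma = 0.02,
                               height = 1e4), n_scans = 500)
  f <- resolve_peaks(build_eics(single, 1), cfg, "toy")
  expect_equal(nrow(f), 1L)
  expect_equal(f$rt, 0.4, tolerance = toy_dt)
  expect_equal(f$height, 1e4, tolerance = 1e-2)

  # two Gaussians with a deep valley -> two features at the two apexes
  twin <- toy_run(data.frame(mz = 400.1, rt = c(0.35, 0.47), sigma = 0.02,
                             height = c(1e4, 1.2e4)), n_scans = 500)
  f2 <- resolve_peaks(build_eics(twin, 1), cfg, "toy")
  expect_equal(nrow(f2), 2L)
  expect_equal(sort(f2$rt), c(0.35, 0.47), tolerance = 2 * toy_dt)

  # a 5e3 peak fails the MS1 height minimum but passes the MS2 one
  weak_eic <- tibble::tibble(
    eic_id = 1L, mz = 400.1, ms_level = 1L, max_intensity = 5e3,
    trace = list(tibble::tibble(
      lscan = 1:61, scan = 1:61, rt = (0:60) * toy_dt, mz = 400.1,
      intensity = 5e3 * exp(-((0:60) * toy_dt - 0.05)^2 / (2 * 0.015^2)))))
  expect_equal(nrow(resolve_peaks(weak_eic, detection_config(1))), 0L)
  expect_equal(nrow(resolve_peaks(weak_eic, detection_config(2))), 1L)
})

test_that("peak area never exceeds EIC area and traces are sub-ranges", {
  run <- toy_run(data.frame(mz = 400.1, rt = c(0.35, 0.5), sigma = 0.02,
                            height = c(3e4, 2e4)), n_scans = 500)
  eics <- build_eics(run, 1)
  f <- resolve_peaks(eics, detection_config(1), "toy")
  tr <- eics$trace[[1]]
  total <- sum(diff(tr$rt) * (head(tr$intensity, -1) + tail(tr$intensity, -1)) / 2)
  expect_true(sum(f$area) <= total + 1e-9)
  for (i in seq_len(nrow(f))) {
    expect_true(all(f$trace[[i]]$lscan %in% tr$lscan))
    expect_true(all(diff(match(f$trace[[i]]$lscan, tr$lscan)) == 1))
  }
})

test_that("deisotoping collapses 13C satellites onto the most intense member", {
  cfg <- detection_config(1)
  base <- toy_feature("S1", 463.0882, 2.0, height = 5e4)
  iso1 <- toy_feature("S1", 463.0882 + 1.00336, 2.0, height = 1.2e4)
  iso2 <- toy_feature("S1", 463.0882 + 2 * 1.00336, 2.0, height = 2e3)
  out <- deisotope(dplyr::bind_rows(base, iso1, iso2), cfg)
  expect_equal(nrow(out), 1L)
  expect_equal(out$mz, 463.0882)

  # half-dalton spacing is a z=2 pattern: ignored at max charge 1
  pair <- dplyr::bind_rows(toy_feature("S1", 400.0, 1.0, 5e4),
                           toy_feature("S1", 400.5017, 1.0, 2e4))
  expect_equal(nrow(deisotope(pair, cfg)), 2L)

  # a singleton and a non-coeluting pair are untouched
  expect_equal(nrow(deisotope(base, cfg)), 1L)
  apart <- dplyr::bind_rows(toy_feature("S1", 400.0, 1.0, 5e4),
                            toy_feature("S1", 401.00336, 2.0, 2e4))
  expect_equal(nrow(deisotope(apart, cfg)), 2L)
})

test_that("deisotoping never removes the most intense member of a cluster", {
  cfg <- detection_config(1)
  withr::with_seed(11, {
    for (rep in 1:20) {
      n <- sample(2:4, 1)
      h <- sort(runif(n, 1e4, 1e5), decreasing = TRUE)
      feats <- dplyr::bind_rows(lapply(seq_len(n), function(k) {
        toy_feature("S1", 400 + (k - 1) * 1.00336 + runif(1, -1e-3, 1e-3),
                    1.0, h[k])
      }))
      out <- deisotope(feats, cfg)
      expect_true(max(h) %in% out$height)
    }
  })
})

test_that("alignment reproduces the optimal assignment on a 3-sample toy set", {
  cfg <- detection_config(1)
  withr::with_seed(5, {
    centers <- tibble::tibble(center = 1:15,
                              mz = seq(300, 800, length.out = 15),
                              rt = rep(seq(1, 5, length.out = 5), 3))
    feats <- dplyr::bind_rows(lapply(c("S1", "S2", "S3"), function(s) {
      present <- sort(sample(15, 12))
      dplyr::bind_cols(
        center = present,
        dplyr::bind_rows(lapply(present, function(i) {
          toy_feature(s, centers$mz[i] + runif(1, -1e-3, 1e-3),
                      centers$rt[i] + runif(1, -0.01, 0.01))
        })))
    }))
    aligned <- align_features(dplyr::select(feats, -"center"), cfg)
    # oracle: features sharing a generating center must share a row
    key <- dplyr::bind_rows(lapply(seq_len(nrow(aligned)), function(r) {
      m <- aligned$members[[r]]
      tibble::tibble(row = r, sample_id = m$sample_id, mz = m$mz)
    }))
    key <- dplyr::left_join(key, dplyr::select(feats, "center", "sample_id", "mz"),
                            by = c("sample_id", "mz"))
    expect_equal(nrow(aligned), length(unique(feats$center)))
    expect_true(all(tapply(key$center, key$row,
                           function(x) length(unique(x)) == 1L)))
  })
})

test_that("alignment is identity for one sample and keeps distant features apart", {
  cfg <- detection_config(1)
  f1 <- dplyr::bind_rows(toy_feature("S1", 400.0, 1.0),
                         toy_feature("S1", 500.0, 2.0))
  one <- align_features(f1, cfg)
  expect_equal(nrow(one), 2L)
  expect_equal(one$n_samples, c(1L, 1L))

  # identical duplicate sample: every row gains a second member
  f2 <- dplyr::mutate(f1, sample_id = "S2")
  two <- align_features(dplyr::bind_rows(f1, f2), cfg)
  expect_equal(two$n_samples, c(2L, 2L))

  # 0.02 Da apart exceeds the 0.007 join tolerance
  g2 <- dplyr::mutate(f1, sample_id = "S2", mz = mz + 0.02)
  sep <- align_features(dplyr::bind_rows(f1, g2), cfg)
  expect_equal(nrow(sep), 4L)
})

test_that("alignment is invariant to sample order up to row ordering", {
  cfg <- detection_config(1)
  f <- dplyr::bind_rows(
    toy_feature("S1", 400.0, 1.0), toy_feature("S1", 500.0, 2.0),
    toy_feature("S2", 400.001, 1.01), toy_feature("S2", 500.002, 2.01))
  a <- align_features(split(f, f$sample_id), cfg)
  b <- align_features(rev(split(f, f$sample_id)), cfg)
  expect_equal(a$mz, b$mz, tolerance = 1e-9)
  expect_equal(a$n_samples, b$n_samples)
})

test_that("gap filling integrates genuine raw peaks and rejects thin or absent signal", {
  cfg <- detection_config(1)
  f1 <- dplyr::bind_rows(toy_feature("S1", 400.0, 0.4),
                         toy_feature("S1", 500.0, 0.6))
  aligned <- align_features(f1, cfg)
  # S2's raw data holds a genuine peak at 400 only
  run2 <- toy_run(data.frame(mz = 400.0, rt = 0.4, sigma = 0.01,
                             height = 3e3), n_scans = 500, sample_id = "S2")
  filled <- gap_fill(aligned, list(S1 = run2[0, ], S2 = run2), cfg)
  m400 <- filled$members[[which(abs(filled$mz - 400) < 0.01)]]
  expect_true("S2" %in% m400$sample_id)
  expect_true(m400$gap_filled[m400$sample_id == "S2"])
  m500 <- filled$members[[which(abs(filled$mz - 500) < 0.01)]]
  expect_false("S2" %in% m500$sample_id)

  # three scans of signal stay empty under the 4-scan minimum
  thin <- ms_run(data.frame(scan = 238:240, rt = (237:239) * toy_dt,
                            ms_level = 1L, mz = 400.0, intensity = 3e3),
                 sample_id = "S3", run_length = 1)
  filled3 <- gap_fill(aligned, list(S3 = thin), cfg)
  m400b <- filled3$members[[which(abs(filled3$mz - 400) < 0.01)]]
  expect_false("S3" %in% m400b$sample_id)
})

test_that("feature detection is deterministic", {
  sp <- spike_spec("Kaempferol", "C15H10O6", "hexose", "O", rt = 0.5,
                   height = 4e4, sample_id = "S1")
  sim <- simulate_run(sp, run_length = 1, seed = 9)
  a <- detect_features(sim$run, 1)
  b <- detect_features(sim$run, 1)
  expect_identical(a, b)
})

test_that("spiked MS1 features well above the height floor are always recovered", {
  withr::with_seed(21, {
    spikes <- dplyr::bind_rows(lapply(1:5, function(i) {
      spike_spec(c("Kaempferol", "Quercetin", "Apigenin", "Naringenin",
                   "Taxifolin")[i],
                 c("C15H10O6", "C15H10O7", "C15H10O5", "C15H12O5",
                   "C15H12O7")[i],
                 "hexose", "O", rt = 0.3 + 0.3 * i,
                 height = runif(1, 2e4, 8e4), sample_id = "S1")
    }))
  })
  sim <- simulate_run(spikes, run_length = 2, seed = 13)
  f <- detect_features(sim$run, 1)
  cfg <- detection_config(1)
  for (i in seq_len(nrow(spikes))) {
    hit <- f[abs(f$rt - spikes$rt[i]) < 0.05 &
               abs(f$mz - spikes$precursor_mz[i]) < 0.01, ]
    expect_equal(nrow(hit), 1L)
    expect_lt(abs(hit$mz - spikes$precursor_mz[i]),
              mz_window(hit$mz, cfg$mz_tol_abs, cfg$mz_tol_ppm))
  }
})
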