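# In-code fixtures: toy single-level runs with hand-placed ion traces, and
# brute-force oracles for EIC grouping and cross-sample alignment on small
# instances.

# dt: scan period in minutes (default 10 Hz)
toy_dt <- 0.1 / 60

# Build an ms_run from ion definitions. `ions` is a data frame with columns
# mz, rt (apex, min), sigma (min), height; every ion contributes a Gaussian
# trace sampled on the scan grid (points above `floor` kept).
toy_run <- function(ions, n_scans = 600, level = 1, dt = toy_dt,
                    floor = 0, sample_id = "toy") {
  rt <- (seq_len(n_scans) - 1) * dt
  rows <- lapply(seq_len(nrow(ions)), function(i) {
    y <- ions$height[i] * exp(-(rt - ions$rt[i])^2 / (2 * ions$sigma[i]^2))
    keep <- which(y > floor & y > 1)
    data.frame(scan = keep, rt = rt[keep], ms_level = level,
               mz = ions$mz[i], intensity = y[keep])
  })
  pk <- do.call(rbind, rows)
  # co-eluting ions at identical m/z stack up in the detector
  pk <- stats::aggregate(intensity ~ scan + rt + ms_level + mz, pk, sum)
  pk <- pk[order(pk$scan, pk$mz), ]
  ms_run(pk, sample_id = sample_id, run_length = n_scans * dt)
}

# Exhaustive EIC grouping oracle for instances whose ions are separated by
# far more than the m/z window: clusters are gaps > window in sorted m/z.
oracle_eic_groups <- function(run, level, window = 0.005, noise = 300) {
  pk <- run[run$ms_level == level & run$intensity > noise, ]
  mzs <- sort(pk$mz)
  if (!length(mzs)) return(list())
  brk <- c(0, cumsum(diff(mzs) > window))
  split(mzs, brk)
}

# Feature stub for alignment tests
toy_feature <- function(sample_id, mz, rt, height = 1e4) {
  tibble::tibble(sample_id = sample_id, ms_level = 1L, mz = mz, rt = rt,
                 height = height, area = height * 0.05, rt_min = rt - 0.05,
                 rt_max = rt + 0.05, n_scans = 10L, eic_id = 1L,
                 trace = list(tibble::tibble(
                   lscan = 1:5, scan = 1:5,
                   rt = rt + seq(-0.02, 0.02, length.out = 5), mz = mz,
                   intensity = height * exp(-seq(-2, 2, length.out = 5)^2))))
}

# aligned-table row holding hand-made traces, for linking tests
toy_aligned_row <- function(row_id, mz, rt, trace, sample_id = "S1",
                            height = max(trace$intensity), level = 1L) {
  tibble::tibble(
    row_id = row_id, ms_level = level, mz = mz, rt = rt, n_samples = 1L,
    members = list(tibble::tibble(
      sample_id = sample_id, mz = mz, rt = rt, height = height,
      area = 1, gap_filled = FALSE, trace = list(trace))))
}

gauss_trace <- function(rt0, sigma = 0.02, height = 1e4, span = 4,
                        dt = toy_dt) {
  rt <- seq(rt0 - span * sigma, rt0 + span * sigma, by = dt)
  tibble::tibble(rt = rt, intensity = height * exp(-(rt - rt0)^2 / (2 * sigma^2)))
}

.cohort_cache <- new.env(parent = emptyenv())

# full cohort pipeline result, computed once per test run
cohort_result <- function() {
  if (is.null(.cohort_cache$res)) {
    fx <- cohort_fixture()
    agl <- default_aglycones()
    fragdb <- build_fragment_db(agl[agl$name %in% unique(fx$spikes$aglycone), ])
    .cohort_cache$res <- suppressWarnings(
      run_pipeline(fx$runs, truth_compound_db(fx$spikes), fragdb,
                   out_dir = NULL))
    .cohort_cache$fx <- fx
  }
  list(res = .cohort_cache$res, spikes = .cohort_cache$fx$spikes,
       runs = .cohort_cache$fx$runs)
}

# deterministic three-sample cohort used by several integration tests
cohort_fixture <- function(seed = 42) {
  spikes <- demo_cohort_spikes(n_samples = 3, seed = seed)
  sims <- lapply(split(spikes, spikes$sample_id), function(sp) {
    simulate_run(sp, run_length = 10,
                 seed = 100 + match(sp$sample_id[1], sort(unique(spikes$sample_id))),
                 sample_id = sp$sample_id[1])
  })
  list(spikes = spikes, runs = lapply(sims, `[[`, "run"))
}
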