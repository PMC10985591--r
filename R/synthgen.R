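# Synthetic DIA-run generator with ground truth: co-eluting Gaussian
# precursor/fragment peaks, 13C isotope satellites and uniform noise, so the
# whole pipeline is testable without instrument data.

#' Specify a spiked glycoside
#'
#' Builds one spike row from an aglycone and a sugar assignment: the
#' precursor [M - H]- m/z, the diagnostic fragment m/z values and their
#' yields, and the annotation string the pipeline is expected to produce.
#' O-glycosides fragment into the heterolytic and homolytic bare aglycone;
#' C-glycosides into residue-modified aglycones.
#'
#' @param aglycone Aglycone name (capitalised, e.g. `"Quercetin"`).
#' @param formula Aglycone molecular formula.
#' @param sugar Sugar name from [sugar_losses()] for O-glycosides
#'   (`"hexose"`, `"pentose"`, ...), or for C-glycosides one of
#'   `"C-hexoside"`, `"C-pentoside"`, `"di-C-hexoside-pentoside"`.
#' @param bond `"O"` or `"C"`.
#' @param rt Apex retention time, minutes.
#' @param height Precursor apex intensity.
#' @param sample_id Sample the spike elutes in.
#' @param rt_sigma Gaussian peak width (sd), minutes.
#' @param yields Fragment yields as fractions of the precursor height,
#'   recycled over the fragment list.
#' @param class Flavonoid class tag.
#' @return One-row tibble; see [simulate_run()].
#' @export
spike_spec <- function(aglycone, formula, sugar, bond, rt, height,
                       sample_id = "sample", rt_sigma = 0.02,
                       yields = c(0.6, 0.35), class = "other") {
  agly_mass <- monoisotopic_mass(formula)
  sug_tab <- sugar_losses()
  if (bond == "O") {
    entry <- sug_tab[sug_tab$name == sugar & sug_tab$bond == "O", ]
    if (nrow(entry) != 1L) stop("unknown O-sugar: ", sugar, call. = FALSE)
    neutral <- agly_mass + entry$loss
    comp <- combine_formulas(formula, entry$formula)
    frag <- o_glycoside_fragments(agly_mass, aglycone)
    expected <- paste(aglycone, entry$label)
  } else if (bond == "C") {
    residues <- switch(sugar,
      "C-hexoside" = "C6H10O5",
      "C-pentoside" = "C5H8O4",
      "di-C-hexoside-pentoside" = c("C6H10O5", "C5H8O4"),
      stop("unknown C-sugar spec: ", sugar, call. = FALSE))
    comp <- Reduce(combine_formulas, residues, parse_formula(formula))
    neutral <- monoisotopic_mass(comp)
    frag <- c_glycoside_fragments(agly_mass, length(residues), aglycone)
    expected <- paste(aglycone, switch(sugar,
      "C-hexoside" = "C-hexoside",
      "C-pentoside" = "C-pentoside",
      "di-C-hexoside-pentoside" = "C-hexoside-C-pentoside"))
  } else {
    stop("bond must be 'O' or 'C'", call. = FALSE)
  }
  if (any(yields > 1)) stop("fragment yields must be <= 1", call. = FALSE)
  if (height <= 0) stop("height must be positive", call. = FALSE)
  frag$yield <- rep_len(yields, nrow(frag))
  tibble::tibble(
    compound = paste(aglycone, sugar, sep = " "),
    aglycone = aglycone, class = class, bond = bond, sugar = sugar,
    formula = format_formula(comp), neutral_mass = neutral,
    precursor_mz = adduct_mz(neutral, "[M-H]-"),
    n_carbon = parse_formula(format_formula(comp))[["C"]],
    rt = rt, rt_sigma = rt_sigma, height = height, sample_id = sample_id,
    expected = expected, fragments = list(frag)
  )
}

#' Simulate a DIA run from spike specifications
#'
#' Generates alternating low-/high-energy (MS1/MS2) scans. Every spike
#' contributes a Gaussian elution profile to the MS1 channel, with an M+1
#' 13C satellite at +1.0033 Da and relative abundance 1.1% per carbon; its
#' fragments trace the identical profile in the MS2 channel, scaled by their
#' yields. Uniform random noise centroids are added at the noise floor and
#' all m/z values are perturbed by Gaussian ppm jitter. Reproducible under a
#' fixed seed.
#'
#' @param spikes Tibble of [spike_spec()] rows (one sample's worth).
#' @param run_length Run length, minutes.
#' @param scan_rate Scans per second per channel.
#' @param noise_floor Mean intensity of noise centroids; noise intensities
#'   are uniform on (0.5, 1.5) times the floor.
#' @param noise_peaks_per_scan Number of noise centroids per scan.
#' @param mz_jitter_ppm Gaussian m/z jitter sd, ppm.
#' @param seed Integer seed.
#' @param sample_id Sample identifier for the run.
#' @return List with `run` (an [ms_run()]) and `truth` (the spike tibble
#'   with the expected annotation strings).
#' @export
simulate_run <- function(spikes, run_length = 10, scan_rate = 10,
                         noise_floor = 200, noise_peaks_per_scan = 10,
                         mz_jitter_ppm = 3, seed = 1,
                         sample_id = spikes$sample_id[1]) {
  stopifnot(nrow(spikes) == 0L || all(spikes$rt <= run_length))
  n_cycles <- floor(run_length * 60 * scan_rate)
  dt <- 1 / scan_rate / 60   # cycle period, minutes
  rt1 <- (seq_len(n_cycles) - 1) * dt          # MS1 scan times
  rt2 <- rt1 + dt / 2                           # interleaved MS2 scans
  withr::with_seed(seed, {
    sig <- list()
    add_trace <- function(level, mz0, height, rt0, sigma, scan_rt, scan_off) {
      y <- height * exp(-(scan_rt - rt0)^2 / (2 * sigma^2))
      keep <- which(y > 1)
      if (!length(keep)) return(NULL)
      mz <- mz0 * (1 + stats::rnorm(length(keep), 0, mz_jitter_ppm * 1e-6))
      tibble::tibble(scan = 2L * keep - scan_off, rt = scan_rt[keep],
                     ms_level = level, mz = mz, intensity = y[keep])
    }
    for (i in seq_len(nrow(spikes))) {
      sp <- spikes[i, ]
      sig[[length(sig) + 1L]] <-
        add_trace(1L, sp$precursor_mz, sp$height, sp$rt, sp$rt_sigma, rt1, 1L)
      sig[[length(sig) + 1L]] <-
        add_trace(1L, sp$precursor_mz + mass_constants[["c13_delta"]],
                  sp$height * 0.011 * sp$n_carbon, sp$rt, sp$rt_sigma,
                  rt1, 1L)
      frag <- sp$fragments[[1]]
      for (j in seq_len(nrow(frag))) {
        sig[[length(sig) + 1L]] <-
          add_trace(2L, frag$mz[j], sp$height * frag$yield[j], sp$rt,
                    sp$rt_sigma, rt2, 0L)
      }
    }
    n_noise <- n_cycles * noise_peaks_per_scan
    noise <- tibble::tibble(
      scan = c(2L * sample.int(n_cycles, n_noise, replace = TRUE) - 1L,
               2L * sample.int(n_cycles, n_noise, replace = TRUE)),
      ms_level = rep(c(1L, 2L), each = n_noise),
      mz = stats::runif(2 * n_noise, 50, 1000),
      intensity = stats::runif(2 * n_noise, 0.5, 1.5) * noise_floor
    )
    cycle <- (noise$scan + 1L) %/% 2L
    noise$rt <- ifelse(noise$ms_level == 1L, rt1[cycle], rt2[cycle])
    peaks <- dplyr::bind_rows(c(sig, list(noise)))
    # collapse centroids closer than 1 mDa within a scan (detector merging)
    peaks <- peaks[order(peaks$scan, round(peaks$mz, 3), -peaks$intensity), ]
    key <- paste(peaks$scan, round(peaks$mz, 3))
    peaks <- peaks[!duplicated(key), ]
  })
  run <- ms_run(peaks, sample_id = sample_id, polarity = "negative",
                run_length = run_length)
  list(run = run, truth = spikes)
}

#' A reproducible multi-sample demonstration cohort
#'
#' Twenty distinct glycosylated flavonoids (O- and C-glycosides of
#' aglycones with unique masses) distributed over three samples, eluting
#' between 1.5 and 6 minutes with apex heights 2e4 to 1e5 -- the conditions
#' of a small plant-extract batch. Used by the end-to-end examples and the
#' package's own validation.
#'
#' @param n_samples Number of samples (default 3).
#' @param seed Seed controlling heights and retention times.
#' @return Tibble of spike rows across samples.
#' @export
demo_cohort_spikes <- function(n_samples = 3, seed = 42) {
  agly <- tibble::tribble(
    ~aglycone,    ~formula,   ~class,
    "Kaempferol", "C15H10O6", "flavonol",
    "Quercetin",  "C15H10O7", "flavonol",
    "Myricetin",  "C15H10O8", "flavonol",
    "Apigenin",   "C15H10O5", "flavone",
    "Naringenin", "C15H12O5", "flavanone",
    "Taxifolin",  "C15H12O7", "flavanonol"
  )
  combos <- tibble::tribble(
    ~aglycone,    ~sugar,                     ~bond,
    "Kaempferol", "hexose",                   "O",
    "Kaempferol", "pentose",                  "O",
    "Kaempferol", "deoxyhexose",              "O",
    "Kaempferol", "coumaroyl-deoxyhexose",    "O",
    "Quercetin",  "hexose",                   "O",
    "Quercetin",  "pentose",                  "O",
    "Quercetin",  "deoxyhexose",              "O",
    "Quercetin",  "deoxyhexosyl-pentose",     "O",
    "Myricetin",  "hexose",                   "O",
    "Myricetin",  "deoxyhexose",              "O",
    "Apigenin",   "C-hexoside",               "C",
    "Apigenin",   "C-pentoside",              "C",
    "Apigenin",   "di-C-hexoside-pentoside",  "C",
    "Naringenin", "hexose",                   "O",
    "Naringenin", "C-hexoside",               "C",
    "Taxifolin",  "hexose",                   "O",
    "Taxifolin",  "deoxyhexose",              "O",
    "Apigenin",   "hexose",                   "O",
    "Naringenin", "deoxyhexose",              "O",
    "Taxifolin",  "C-pentoside",              "C"
  )
  combos <- dplyr::left_join(combos, agly, by = "aglycone")
  withr::with_seed(seed, {
    n <- nrow(combos)
    rts <- sort(stats::runif(n, 1.5, 6))
    # keep apexes separated so co-elution links are unambiguous
    rts <- 1.5 + (rts - min(rts)) / diff(range(rts)) * 4.5
    rts <- seq(1.5, 6, length.out = n) + stats::runif(n, -0.05, 0.05)
    heights <- stats::runif(n, 2e4, 1e5)
    samples <- paste0("S", ((seq_len(n) - 1L) %% n_samples) + 1L)
    purrr::pmap_dfr(
      list(combos$aglycone, combos$formula, combos$sugar, combos$bond,
           combos$class, rts, heights, samples),
      function(a, f, s, b, cl, rt, h, sid) {
        spike_spec(a, f, s, b, rt = rt, height = h, sample_id = sid,
                   class = cl)
      })
  })
}

#' Compound database for a simulated cohort
#'
#' Collapses a spike truth table into MS1 compound records (the curated
#' database a profiling study would hold for its spiked compounds), with
#' wildcard retention times.
#'
#' @param truth Spike tibble from [simulate_run()] / [demo_cohort_spikes()].
#' @param run_length Run length in minutes (the RT wildcard value).
#' @return Compound-record tibble as from [read_compound_db()].
#' @export
truth_compound_db <- function(truth, run_length = 10) {
  db <- dplyr::distinct(truth, name = .data$compound,
                        mass = .data$neutral_mass, formula = .data$formula,
                        class = .data$class)
  db$rt <- run_length
  db$rt_wildcard <- TRUE
  db$source <- "simulated-truth"
  db[, c("name", "mass", "formula", "rt", "rt_wildcard", "class", "source")]
}

#' Compare pipeline annotations with simulation ground truth
#'
#' A spike counts as recovered when some glycoside annotation matches its
#' precursor m/z within `tol`, names its aglycone and bond type, and its
#' sugar call (any `" or "`-separated alternative) equals the expected
#' string. An annotation is correct when it is consistent with some spike
#' by the same rule; precision is computed over distinct
#' (precursor, aglycone, bond) claims.
#'
#' @param truth Spike tibble from the simulation.
#' @param annotations Glycoside-annotation tibble from [assign_glycoside()].
#' @param tol Precursor m/z matching tolerance, Da.
#' @return List with `spikes` (per-spike status tibble), `recall`,
#'   `precision`, `n_true`, `n_claims`.
#' @export
truth_compare <- function(truth, annotations, tol = 0.01) {
  compounds <- dplyr::distinct(truth, .data$compound, .data$aglycone,
                               .data$bond, .data$precursor_mz, .data$expected)
  ann_ok <- function(sp, ann) {
    if (abs(ann$ms1_mz - sp$precursor_mz) > tol) return(FALSE)
    if (!identical(ann$aglycone, sp$aglycone)) return(FALSE)
    if (!identical(ann$bond, sp$bond)) return(FALSE)
    alts <- paste(sp$aglycone, strsplit(ann$sugar, " or ", fixed = TRUE)[[1]])
    sp$expected %in% alts
  }
  matched <- vapply(seq_len(nrow(compounds)), function(i) {
    sp <- compounds[i, ]
    any(vapply(seq_len(nrow(annotations)), function(k) {
      ann_ok(sp, annotations[k, ])
    }, logical(1)))
  }, logical(1))
  claims <- dplyr::distinct(annotations, .data$ms1_row, .data$aglycone,
                            .data$bond, .keep_all = TRUE)
  correct <- vapply(seq_len(nrow(claims)), function(k) {
    any(vapply(seq_len(nrow(compounds)), function(i) {
      ann_ok(compounds[i, ], claims[k, ])
    }, logical(1)))
  }, logical(1))
  compounds$recovered <- matched
  list(
    spikes = compounds,
    recall = if (nrow(compounds)) mean(matched) else NA_real_,
    precision = if (nrow(claims)) mean(correct) else NA_real_,
    n_true = nrow(compounds), n_claims = nrow(claims)
  )
}
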