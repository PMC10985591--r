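# Feature detection, applied identically at MS1 and MS2 level: mass
# detection, EIC building, local-minimum peak resolving, 13C deisotoping,
# join alignment across samples, and gap filling.
#
# Running the same chromatographic machinery on the high-energy (MS2)
# channel as on the precursor channel is the central move of the pipeline:
# in DIA data every fragment traces out its own chromatographic peak, so
# fragments can be resolved, aligned and annotated as first-class features.

#' Detection configuration
#'
#' All tunable parameters of the feature-detection stack, with the defaults
#' used for the precursor (MS1) channel. The high-energy channel uses the
#' identical parameters except that the minimum absolute height is lowered
#' to 4e3 (fragment ions are weaker than their precursors). m/z tolerances
#' are "absolute-or-ppm": the effective window is the larger of the two at
#' the m/z in question.
#'
#' @param level MS level the configuration targets (1 or 2).
#' @param noise_level Centroid intensities at or below this are discarded.
#' @param min_consec_scans An EIC must span at least this many consecutive
#'   scans above `min_consec_intensity`.
#' @param min_consec_intensity Intensity floor for the consecutive-scan rule.
#' @param min_height Minimum apex intensity for an EIC / resolved peak.
#' @param mz_tol_abs,mz_tol_ppm EIC builder m/z tolerance.
#' @param chrom_threshold Baseline quantile: trace points below the
#'   `1 - chrom_threshold` intensity quantile of their EIC are baseline.
#' @param min_rt_range Minimum RT separation (minutes) for a local minimum
#'   to split two peaks.
#' @param top_edge_ratio Minimum apex / edge intensity ratio of a peak.
#' @param peak_duration Allowed peak duration range, minutes.
#' @param min_scans Minimum points per resolved peak.
#' @param iso_mz_tol_abs,iso_mz_tol_ppm,iso_rt_tol,max_charge 13C isotope
#'   filter tolerances and maximum charge.
#' @param align_mz_tol_abs,align_mz_tol_ppm,align_mz_weight,align_rt_tol,align_rt_weight
#'   Join-aligner tolerances and score weights.
#' @param gf_intensity_tol,gf_mz_tol_abs,gf_mz_tol_ppm,gf_rt_tol,gf_min_scans
#'   Gap-filling parameters: maximum relative deviation from a monotone
#'   flank, m/z and RT windows, and minimum contiguous scans.
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(level = 1,
                             noise_level = 3e2,
                             min_consec_scans = 5,
                             min_consec_intensity = 8e2,
                             min_height = if (level == 2) 4e3 else 8e3,
                             mz_tol_abs = 0.005, mz_tol_ppm = 10,
                             chrom_threshold = 0.85,
                             min_rt_range = 0.035,
                             top_edge_ratio = 1.8,
                             peak_duration = c(0, 2),
                             min_scans = 5,
                             iso_mz_tol_abs = 0.003, iso_mz_tol_ppm = 5,
                             iso_rt_tol = 0.05, max_charge = 1,
                             align_mz_tol_abs = 0.007, align_mz_tol_ppm = 12,
                             align_mz_weight = 3,
                             align_rt_tol = 0.045, align_rt_weight = 2,
                             gf_intensity_tol = 0.2,
                             gf_mz_tol_abs = 0.005, gf_mz_tol_ppm = 7,
                             gf_rt_tol = 0.04, gf_min_scans = 4) {
  cfg <- as.list(environment())
  num <- cfg[!(names(cfg) %in% "peak_duration")]
  if (any(vapply(num, function(x) !is.numeric(x) || any(x < 0), logical(1)))) {
    stop("detection parameters must be non-negative numbers", call. = FALSE)
  }
  tols <- c("mz_tol_abs", "iso_mz_tol_abs", "align_mz_tol_abs",
            "gf_mz_tol_abs", "align_rt_tol", "gf_rt_tol", "iso_rt_tol")
  if (any(unlist(cfg[tols]) <= 0)) {
    stop("tolerances must be positive", call. = FALSE)
  }
  structure(cfg, class = "detection_config")
}

#' Centroid mass detection
#'
#' Retains centroids with intensity above the noise level, order preserved.
#'
#' @param spectrum Data frame with `mz` and `intensity` columns.
#' @param noise Noise level; peaks with intensity <= `noise` are dropped.
#' @return The filtered spectrum.
#' @export
detect_masses <- function(spectrum, noise = 3e2) {
  spectrum[spectrum$intensity > noise, , drop = FALSE]
}

# longest run of consecutive integers in a sorted vector
.max_consecutive <- function(idx) {
  if (!length(idx)) return(0L)
  runs <- rle(cumsum(c(1L, diff(idx) != 1L)))
  max(runs$lengths)
}

#' Build extracted-ion chromatograms
#'
#' Deterministic, intensity-seeded greedy grouping of centroids across the
#' scans of one MS level. Seeds are taken in decreasing intensity order from
#' the centroids reaching the minimum absolute height; each seed opens an
#' m/z window (`max(mz_tol_abs, mz_tol_ppm)`) and collects the most intense
#' unassigned centroid per scan inside the window. An EIC is kept only if it
#' holds a run of at least `min_consec_scans` consecutive scans at or above
#' `min_consec_intensity`.
#'
#' @param run An [ms_run()].
#' @param level MS level to extract (1 or 2).
#' @param cfg A [detection_config()].
#' @return Tibble of EICs: `eic_id`, `mz` (intensity-weighted representative
#'   m/z), `ms_level`, `max_intensity`, `trace` list-column of per-scan
#'   tibbles (`lscan`, `scan`, `rt`, `mz`, `intensity`).
#' @export
build_eics <- function(run, level, cfg = detection_config(level)) {
  pk <- run[run$ms_level == level, ]
  if (nrow(pk) == 0L) {
    stop("run '", attr(run, "sample_id"), "' has no MS level ", level,
         " scans", call. = FALSE)
  }
  pk <- detect_masses(pk, cfg$noise_level)
  empty <- tibble::tibble(eic_id = integer(), mz = numeric(),
                          ms_level = integer(), max_intensity = numeric(),
                          trace = list())
  if (nrow(pk) == 0L) return(empty)
  scans <- sort(unique(run$scan[run$ms_level == level]))
  ord <- order(pk$mz)
  mz <- pk$mz[ord]; int <- pk$intensity[ord]
  lscan <- match(pk$scan[ord], scans); rt <- pk$rt[ord]
  n <- length(mz)
  assigned <- logical(n)
  seeds <- which(int >= cfg$min_height)
  seeds <- seeds[order(-int[seeds], mz[seeds])]
  traces <- list(); reps <- numeric(); maxi <- numeric(); k <- 0L
  for (s in seeds) {
    if (assigned[s]) next
    win <- mz_window(mz[s], cfg$mz_tol_abs, cfg$mz_tol_ppm)
    lo <- findInterval(mz[s] - win, mz) + 1L
    hi <- findInterval(mz[s] + win, mz)
    cand <- lo:hi
    cand <- cand[!assigned[cand]]
    if (!length(cand)) next
    # most intense unassigned centroid per scan
    cand <- cand[order(-int[cand])]
    cand <- cand[!duplicated(lscan[cand])]
    assigned[cand] <- TRUE
    cand <- cand[order(lscan[cand])]
    strong <- lscan[cand][int[cand] >= cfg$min_consec_intensity]
    if (.max_consecutive(strong) < cfg$min_consec_scans) next
    k <- k + 1L
    traces[[k]] <- tibble::tibble(lscan = lscan[cand], scan = pk$scan[ord][cand],
                                  rt = rt[cand], mz = mz[cand],
                                  intensity = int[cand])
    reps[k] <- sum(mz[cand] * int[cand]) / sum(int[cand])
    maxi[k] <- max(int[cand])
  }
  if (k == 0L) return(empty)
  out <- tibble::tibble(eic_id = seq_len(k), mz = reps,
                        ms_level = as.integer(level), max_intensity = maxi,
                        trace = traces)
  dplyr::arrange(out, .data$mz)
}

# split one contiguous trace segment at qualified local minima
.split_at_minima <- function(seg, min_rt_range) {
  n <- nrow(seg)
  if (n < 3L) return(list(seg))
  y <- seg$intensity; rt <- seg$rt
  splits <- integer()
  for (i in 2:(n - 1)) {
    if (y[i] > y[i - 1] || y[i] > y[i + 1]) next
    inwin <- which(abs(rt - rt[i]) <= min_rt_range)
    if (y[i] > min(y[inwin])) next
    # require genuinely higher signal on both sides of the minimum
    left <- which(rt < rt[i] - min_rt_range / 2)
    right <- which(rt > rt[i] + min_rt_range / 2)
    if (!length(left) || !length(right)) next
    if (max(y[left]) <= y[i] || max(y[right]) <= y[i]) next
    if (length(splits) && rt[i] - rt[splits[length(splits)]] < min_rt_range) next
    splits <- c(splits, i)
  }
  if (!length(splits)) return(list(seg))
  bounds <- c(1L, splits, n)
  lapply(seq_len(length(bounds) - 1L), function(j) {
    seg[bounds[j]:bounds[j + 1L], , drop = FALSE]
  })
}

.trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Resolve chromatographic peaks from EICs
#'
#' Local-minimum resolver in the retention-time dimension. Points below the
#' `1 - chrom_threshold` intensity quantile of the EIC are treated as
#' baseline; the remaining contiguous segments are split at local minima
#' separated by at least `min_rt_range`, and each candidate peak is kept if
#' it reaches the minimum absolute height, its apex/edge ratio is at least
#' `top_edge_ratio`, its duration falls within `peak_duration`, and it spans
#' at least `min_scans` points.
#'
#' @param eics EIC tibble from [build_eics()].
#' @param cfg A [detection_config()].
#' @param sample_id Sample identifier stamped on the features.
#' @return Tibble of features: `sample_id`, `ms_level`, `mz`, `rt`, `height`,
#'   `area` (trapezoidal, intensity x minutes), `rt_min`, `rt_max`,
#'   `n_scans`, `eic_id`, `trace` list-column.
#' @export
resolve_peaks <- function(eics, cfg = detection_config(), sample_id = "sample") {
  empty <- tibble::tibble(sample_id = character(), ms_level = integer(),
                          mz = numeric(), rt = numeric(), height = numeric(),
                          area = numeric(), rt_min = numeric(),
                          rt_max = numeric(), n_scans = integer(),
                          eic_id = integer(), trace = list())
  if (nrow(eics) == 0L) return(empty)
  feats <- purrr::pmap(eics, function(eic_id, mz, ms_level, max_intensity,
                                      trace) {
    tr <- trace[order(trace$lscan), ]
    base <- stats::quantile(tr$intensity, 1 - cfg$chrom_threshold,
                            names = FALSE)
    keep <- tr$intensity >= base
    if (!any(keep)) return(NULL)
    # above-baseline segments; a single missing scan does not break a peak,
    # only an RT gap larger than the local-minimum search range does
    grp <- cumsum(c(1L, (diff(tr$rt) > cfg$min_rt_range |
                           diff(keep) != 0L)))[keep]
    segs <- split(tr[keep, , drop = FALSE], grp)
    segs <- unlist(lapply(segs, .split_at_minima, cfg$min_rt_range),
                   recursive = FALSE)
    rows <- lapply(segs, function(seg) {
      apex <- which.max(seg$intensity)
      height <- seg$intensity[apex]
      if (height < cfg$min_height) return(NULL)
      if (nrow(seg) < cfg$min_scans) return(NULL)
      dur <- seg$rt[nrow(seg)] - seg$rt[1]
      if (dur < cfg$peak_duration[1] || dur > cfg$peak_duration[2]) return(NULL)
      edge <- max(seg$intensity[1], seg$intensity[nrow(seg)], 1e-9)
      if (height / edge < cfg$top_edge_ratio) return(NULL)
      tibble::tibble(
        sample_id = sample_id, ms_level = as.integer(ms_level),
        mz = sum(seg$mz * seg$intensity) / sum(seg$intensity),
        rt = seg$rt[apex], height = height,
        area = .trapz(seg$rt, seg$intensity),
        rt_min = seg$rt[1], rt_max = seg$rt[nrow(seg)],
        n_scans = nrow(seg), eic_id = eic_id, trace = list(seg)
      )
    })
    dplyr::bind_rows(rows)
  })
  out <- dplyr::bind_rows(feats)
  if (nrow(out) == 0L) return(empty)
  dplyr::arrange(out, .data$mz, .data$rt)
}

#' Remove 13C isotope satellites
#'
#' Features whose m/z lie 1.00335/z above a co-eluting, more intense feature
#' (z up to `max_charge`), within the isotope m/z and RT tolerances and with
#' monotonically decreasing intensity along the series, are collapsed onto
#' the most intense member.
#'
#' @param features Feature tibble from one sample and MS level.
#' @param cfg A [detection_config()].
#' @return The feature tibble with isotope satellites removed.
#' @export
deisotope <- function(features, cfg = detection_config()) {
  n <- nrow(features)
  if (n <= 1L) return(features)
  ord <- order(features$mz)
  f <- features[ord, ]
  drop <- logical(n)
  for (i in seq_len(n - 1L)) {
    for (z in seq_len(cfg$max_charge)) {
      target <- f$mz[i] + mass_constants[["c13_delta"]] / z
      tol <- mz_window(f$mz[i], cfg$iso_mz_tol_abs, cfg$iso_mz_tol_ppm)
      j <- which(abs(f$mz - target) <= tol &
                   abs(f$rt - f$rt[i]) <= cfg$iso_rt_tol &
                   f$height <= f$height[i])
      j <- setdiff(j, i)
      if (length(j)) drop[j] <- TRUE
    }
  }
  f[!drop, ]
}

#' Detect features on one DIA channel
#'
#' Convenience wrapper: EIC building, local-minimum resolving and
#' deisotoping on one MS level of a run.
#'
#' @param run An [ms_run()].
#' @param level MS level (1 or 2).
#' @param cfg A [detection_config()]; defaults to the level-appropriate one.
#' @return Feature tibble (see [resolve_peaks()]).
#' @export
detect_features <- function(run, level, cfg = detection_config(level)) {
  eics <- build_eics(run, level, cfg)
  feats <- resolve_peaks(eics, cfg, sample_id = attr(run, "sample_id"))
  deisotope(feats, cfg)
}

#' Align feature lists across samples
#'
#' Master-list greedy join alignment. The first sample's features found the
#' master rows; each further sample's features are scored against rows
#' within both tolerances with
#' `mz_weight * (1 - |dmz|/mz_tol) + rt_weight * (1 - |drt|/rt_tol)`,
#' highest score first (ties by smaller |dmz|, then input order); unmatched
#' features start new rows. Consensus m/z and RT are member means.
#'
#' @param feature_tables A list of per-sample feature tibbles, or one tibble
#'   covering several `sample_id`s.
#' @param cfg A [detection_config()].
#' @return Aligned tibble: `row_id`, `ms_level`, `mz`, `rt`, `n_samples`,
#'   `members` list-column of per-sample member tibbles (`sample_id`, `mz`,
#'   `rt`, `height`, `area`, `gap_filled`, `trace`).
#' @export
align_features <- function(feature_tables, cfg = detection_config()) {
  if (is.data.frame(feature_tables)) {
    feature_tables <- split(feature_tables, feature_tables$sample_id)
  }
  feature_tables <- feature_tables[vapply(feature_tables, nrow, integer(1)) >= 0]
  if (!length(feature_tables)) stop("no feature tables", call. = FALSE)
  as_member <- function(f) {
    tibble::tibble(sample_id = f$sample_id, mz = f$mz, rt = f$rt,
                   height = f$height, area = f$area, gap_filled = FALSE,
                   trace = f$trace)
  }
  first <- feature_tables[[1]]
  rows <- lapply(seq_len(nrow(first)), function(i) as_member(first[i, ]))
  row_mz <- first$mz; row_rt <- first$rt
  lvl <- if (nrow(first)) first$ms_level[1] else NA_integer_
  for (ft in feature_tables[-1]) {
    if (nrow(ft) == 0L) next
    cand <- NULL
    if (length(rows)) {
      cand <- tidyr::crossing(fi = seq_len(nrow(ft)), ri = seq_along(rows))
      dmz <- abs(ft$mz[cand$fi] - row_mz[cand$ri])
      drt <- abs(ft$rt[cand$fi] - row_rt[cand$ri])
      mz_tol <- mz_window(row_mz[cand$ri], cfg$align_mz_tol_abs,
                          cfg$align_mz_tol_ppm)
      ok <- dmz <= mz_tol & drt <= cfg$align_rt_tol
      cand <- cand[ok, ]
      if (nrow(cand)) {
        cand$score <- cfg$align_mz_weight * (1 - dmz[ok] / mz_tol[ok]) +
          cfg$align_rt_weight * (1 - drt[ok] / cfg$align_rt_tol)
        cand$dmz <- dmz[ok]
        cand <- cand[order(-cand$score, cand$dmz, cand$fi), ]
      }
    }
    used_f <- logical(nrow(ft)); used_r <- logical(length(rows))
    if (!is.null(cand) && nrow(cand)) {
      for (i in seq_len(nrow(cand))) {
        fi <- cand$fi[i]; ri <- cand$ri[i]
        if (used_f[fi] || used_r[ri]) next
        used_f[fi] <- TRUE; used_r[ri] <- TRUE
        rows[[ri]] <- dplyr::bind_rows(rows[[ri]], as_member(ft[fi, ]))
        row_mz[ri] <- mean(rows[[ri]]$mz)
        row_rt[ri] <- mean(rows[[ri]]$rt)
      }
    }
    for (fi in which(!used_f)) {
      rows[[length(rows) + 1L]] <- as_member(ft[fi, ])
      row_mz[length(rows)] <- ft$mz[fi]
      row_rt[length(rows)] <- ft$rt[fi]
    }
  }
  out <- tibble::tibble(
    row_id = seq_along(rows), ms_level = lvl,
    mz = row_mz, rt = row_rt,
    n_samples = vapply(rows, nrow, integer(1)),
    members = rows
  )
  out <- dplyr::arrange(out, .data$mz, .data$rt)
  out$row_id <- seq_len(nrow(out))
  out
}

#' Fill alignment gaps from raw data
#'
#' For every (row, sample) cell left empty by alignment, raw centroids of
#' the sample's run are re-integrated within the row's m/z and RT windows.
#' A fill is accepted only if at least `gf_min_scans` contiguous scans form
#' a unimodal profile whose flanks deviate from monotone by at most the
#' relative `gf_intensity_tol`. Filled members are flagged `gap_filled`.
#'
#' @param table Aligned tibble from [align_features()].
#' @param runs Named list of [ms_run()]s keyed by sample id (or a list whose
#'   runs carry sample ids).
#' @param cfg A [detection_config()].
#' @param level MS level to integrate; defaults to the table's level.
#' @return The aligned tibble with filled members added.
#' @export
gap_fill <- function(table, runs, cfg = detection_config(),
                     level = table$ms_level[1]) {
  if (is.null(names(runs))) {
    names(runs) <- vapply(runs, attr, character(1), "sample_id")
  }
  all_samples <- names(runs)
  for (i in seq_len(nrow(table))) {
    mem <- table$members[[i]]
    missing <- setdiff(all_samples, mem$sample_id)
    for (s in missing) {
      run <- runs[[s]]
      pk <- run[run$ms_level == level, ]
      win <- mz_window(table$mz[i], cfg$gf_mz_tol_abs, cfg$gf_mz_tol_ppm)
      pk <- pk[abs(pk$mz - table$mz[i]) <= win &
                 abs(pk$rt - table$rt[i]) <= cfg$gf_rt_tol, ]
      if (nrow(pk) < cfg$gf_min_scans) next
      scans <- sort(unique(run$scan[run$ms_level == level]))
      pk$lscan <- match(pk$scan, scans)
      pk <- pk[order(pk$lscan, -pk$intensity), ]
      pk <- pk[!duplicated(pk$lscan), ]
      # maximal contiguous block containing the most intense point
      grp <- cumsum(c(1L, diff(pk$lscan) != 1L))
      blk <- pk[grp == grp[which.max(pk$intensity)], ]
      if (nrow(blk) < cfg$gf_min_scans) next
      apex <- which.max(blk$intensity)
      lft <- blk$intensity[seq_len(apex)]
      rgt <- blk$intensity[apex:nrow(blk)]
      mono_up <- all(diff(lft) >= -cfg$gf_intensity_tol * utils::head(lft, -1))
      mono_dn <- all(diff(rgt) <= cfg$gf_intensity_tol * utils::head(rgt, -1))
      if (!mono_up || !mono_dn) next
      fill <- tibble::tibble(
        sample_id = s,
        mz = sum(blk$mz * blk$intensity) / sum(blk$intensity),
        rt = blk$rt[apex], height = max(blk$intensity),
        area = .trapz(blk$rt, blk$intensity), gap_filled = TRUE,
        trace = list(blk[, c("lscan", "scan", "rt", "mz", "intensity")])
      )
      table$members[[i]] <- dplyr::bind_rows(mem, fill)
      mem <- table$members[[i]]
    }
    table$n_samples[i] <- nrow(table$members[[i]])
  }
  table
}

#' Widen an aligned table to per-sample intensity columns
#'
#' @param table Aligned tibble from [align_features()].
#' @param value Member column to spread (default `"height"`).
#' @return Tibble with one `intensity_<sample>` (and `gapfilled_<sample>`)
#'   column per sample; absent cells are 0.
#' @export
aligned_wide <- function(table, value = "height") {
  long <- tidyr::unnest(
    dplyr::select(table, "row_id", "ms_level", "mz", "rt", "members"),
    "members", names_sep = "_")
  base <- dplyr::select(table, "row_id", "ms_level", "mz", "rt")
  vals <- tidyr::pivot_wider(
    dplyr::select(long, "row_id", sample_id = "members_sample_id",
                  value = paste0("members_", value)),
    names_from = "sample_id", values_from = "value",
    names_prefix = "intensity_", values_fill = 0)
  gf <- tidyr::pivot_wider(
    dplyr::select(long, "row_id", sample_id = "members_sample_id",
                  gap_filled = "members_gap_filled"),
    names_from = "sample_id", values_from = "gap_filled",
    names_prefix = "gapfilled_", values_fill = FALSE)
  dplyr::left_join(dplyr::left_join(base, vals, by = "row_id"), gf,
                   by = "row_id")
}

#' Per-sample intensity matrix of an aligned table
#'
#' @param table Aligned tibble.
#' @param value Member column to use (default `"height"`).
#' @return Numeric matrix, rows = aligned features, columns = samples.
#' @export
aligned_intensity_matrix <- function(table, value = "height") {
  wide <- aligned_wide(table, value)
  cols <- grep("^intensity_", names(wide), value = TRUE)
  m <- as.matrix(wide[cols])
  colnames(m) <- sub("^intensity_", "", cols)
  rownames(m) <- wide$row_id
  m
}
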