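# DIA run container and mzML reading/writing (via mzR).
#
# An MS run is a tibble of centroided peaks in long form -- one row per
# centroid, columns (scan, rt, ms_level, mz, intensity) -- with the sample
# identifier, polarity and run length (minutes) held as attributes. Low- and
# high-energy DIA channels are encoded as MS levels 1 and 2, the convention
# used by Waters-to-mzML converters for alternating-energy acquisitions;
# level-2 scans carry no precursor isolation metadata.

#' Construct an MS run from a peak table
#'
#' @param peaks Data frame with columns `scan` (integer scan index), `rt`
#'   (minutes), `ms_level` (1 or 2), `mz`, `intensity`. m/z must be strictly
#'   increasing within each scan; retention time non-decreasing with scan
#'   index.
#' @param sample_id Sample identifier.
#' @param polarity `"negative"` or `"positive"`.
#' @param run_length Run length in minutes.
#' @return A tibble of class `ms_run`.
#' @export
ms_run <- function(peaks, sample_id = "sample", polarity = "negative",
                   run_length = 10) {
  peaks <- tibble::as_tibble(peaks)
  req <- c("scan", "rt", "ms_level", "mz", "intensity")
  if (!all(req %in% names(peaks))) {
    stop("peak table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  peaks <- peaks[order(peaks$scan, peaks$mz), req]
  if (nrow(peaks)) {
    if (any(peaks$intensity < 0)) stop("negative intensities", call. = FALSE)
    if (any(peaks$rt < 0)) stop("negative retention times", call. = FALSE)
    by_scan <- split(peaks$mz, peaks$scan)
    if (any(vapply(by_scan, function(x) any(diff(x) <= 0), logical(1)))) {
      stop("m/z must be strictly increasing within a spectrum", call. = FALSE)
    }
    rt_scan <- vapply(split(peaks$rt, peaks$scan), `[`, numeric(1), 1L)
    if (any(diff(rt_scan) < 0)) {
      stop("retention time must be non-decreasing with scan index",
           call. = FALSE)
    }
  }
  structure(peaks,
            class = c("ms_run", class(peaks)),
            sample_id = sample_id, polarity = polarity,
            run_length = run_length)
}

#' @export
print.ms_run <- function(x, ...) {
  cat(sprintf("<ms_run> sample '%s', %s mode, %.3g min, %d scans, %d peaks\n",
              attr(x, "sample_id"), attr(x, "polarity"),
              attr(x, "run_length"),
              length(unique(x$scan)), nrow(x)))
  for (lv in sort(unique(x$ms_level))) {
    cat(sprintf("  MS%d: %d scans\n", lv, length(unique(x$scan[x$ms_level == lv]))))
  }
  invisible(x)
}

#' One-line summary of an MS run
#'
#' @param x An `ms_run`.
#' @param ... Unused.
#' @return One-row tibble: sample, polarity, run length, scan and peak counts
#'   per MS level.
#' @export
glance.ms_run <- function(x, ...) {
  tibble::tibble(
    sample_id = attr(x, "sample_id"),
    polarity = attr(x, "polarity"),
    run_length = attr(x, "run_length"),
    n_scans_ms1 = length(unique(x$scan[x$ms_level == 1])),
    n_scans_ms2 = length(unique(x$scan[x$ms_level == 2])),
    n_peaks = nrow(x)
  )
}

#' Read a centroided DIA run from mzML
#'
#' Reads an mzML file into the long peak-table representation. Alternating
#' low/high-energy DIA channels are expected as MS levels 1 and 2; a run with
#' only one level is read with a warning (MS2-dependent stages will refuse
#' it). Profile-mode spectra are an error.
#'
#' @param path Path to an mzML file.
#' @param sample_id Sample identifier; defaults to the file name.
#' @return An [ms_run()] tibble.
#' @export
read_mzml <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.mzML$", "", basename(path), ignore.case = TRUE)
  }
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh))
  hdr <- mzR::header(fh)
  if (nrow(hdr) == 0L) stop("empty mzML file: ", path, call. = FALSE)
  if (any(!is.na(hdr$centroided) & !hdr$centroided)) {
    stop("profile-mode spectra in ", path, "; centroided data required",
         call. = FALSE)
  }
  pk <- mzR::peaks(fh)
  if (is.matrix(pk)) pk <- list(pk)
  n <- vapply(pk, nrow, integer(1))
  peaks <- tibble::tibble(
    scan = rep(hdr$seqNum, n),
    rt = rep(hdr$retentionTime, n) / 60,
    ms_level = rep(hdr$msLevel, n),
    mz = unlist(lapply(pk, function(m) m[, 1]), use.names = FALSE),
    intensity = unlist(lapply(pk, function(m) m[, 2]), use.names = FALSE)
  )
  levels_seen <- sort(unique(hdr$msLevel))
  if (!all(c(1, 2) %in% levels_seen)) {
    warning("mzML file ", basename(path), " carries MS level(s) ",
            paste(levels_seen, collapse = ", "),
            " only; not a two-channel DIA run", call. = FALSE)
  }
  polarity <- if (all(hdr$polarity == 1, na.rm = TRUE)) "positive" else "negative"
  ms_run(peaks, sample_id = sample_id, polarity = polarity,
         run_length = max(hdr$retentionTime / 60, 0))
}

.empty_mzml_header <- function() {
  data.frame(
    seqNum = integer(), acquisitionNum = integer(), msLevel = integer(),
    polarity = integer(), peaksCount = integer(), totIonCurrent = numeric(),
    retentionTime = numeric(), basePeakMZ = numeric(),
    basePeakIntensity = numeric(), collisionEnergy = numeric(),
    ionisationEnergy = numeric(), lowMZ = numeric(), highMZ = numeric(),
    precursorScanNum = integer(), precursorMZ = numeric(),
    precursorCharge = integer(), precursorIntensity = numeric(),
    mergedScan = integer(), mergedResultScanNum = integer(),
    mergedResultStartScanNum = integer(), mergedResultEndScanNum = integer(),
    injectionTime = numeric(), filterString = character(),
    spectrumId = character(), centroided = logical(),
    ionMobilityDriftTime = numeric(), isolationWindowTargetMZ = numeric(),
    isolationWindowLowerOffset = numeric(),
    isolationWindowUpperOffset = numeric(),
    scanWindowLowerLimit = numeric(), scanWindowUpperLimit = numeric())
}

#' Write an MS run to mzML
#'
#' Writes a standard-conformant centroided mzML file; numeric payloads (RT,
#' level, m/z, intensity) round-trip through [read_mzml()] to within 1e-6.
#'
#' @param run An [ms_run()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mzml <- function(run, path) {
  stopifnot(inherits(run, "ms_run"))
  scans <- sort(unique(run$scan))
  idx <- match(run$scan, scans)
  pk <- lapply(seq_along(scans), function(i) {
    sub <- run[idx == i, ]
    cbind(mz = sub$mz, intensity = sub$intensity)
  })
  first <- match(seq_along(scans), idx)
  rt_s <- run$rt[first] * 60
  lvl <- as.integer(run$ms_level[first])
  pol <- if (identical(attr(run, "polarity"), "positive")) 1L else 0L
  n <- length(scans)
  np <- vapply(pk, nrow, integer(1))
  if (n == 0L) {
    hdr <- .empty_mzml_header()
    if (file.exists(path)) unlink(path)
    mzR::writeMSData(list(), path, header = hdr, outformat = "mzml")
    return(invisible(path))
  }
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = lvl,
    polarity = pol, peaksCount = np,
    totIonCurrent = vapply(pk, function(m) sum(m[, 2]), numeric(1)),
    retentionTime = rt_s,
    basePeakMZ = vapply(pk, function(m) if (nrow(m)) m[which.max(m[, 2]), 1] else 0, numeric(1)),
    basePeakIntensity = vapply(pk, function(m) if (nrow(m)) max(m[, 2]) else 0, numeric(1)),
    collisionEnergy = ifelse(lvl == 2L, 30, 0), ionisationEnergy = 0,
    lowMZ = vapply(pk, function(m) if (nrow(m)) min(m[, 1]) else 0, numeric(1)),
    highMZ = vapply(pk, function(m) if (nrow(m)) max(m[, 1]) else 0, numeric(1)),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)), centroided = TRUE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_
  )
  if (file.exists(path)) unlink(path)
  mzR::writeMSData(pk, path, header = hdr, outformat = "mzml")
  invisible(path)
}
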