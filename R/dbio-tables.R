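# CSV dialects for compound / fragment databases and feature tables.
#
# Databases are comma-separated, UTF-8, header row required. Column naming
# varies between curated sources, so every reader takes an explicit
# column-name mapping. A record whose retention time equals the configured
# run length is an RT wildcard: the compound elutes "anywhere", the curators'
# convention for entries without measured retention times.

#' Read an MS1 compound database
#'
#' @param path CSV file path.
#' @param columns Named character vector mapping the internal fields `name`,
#'   `mass`, `formula`, `rt` to the file's column names.
#' @param run_length Run length in minutes; records with `rt == run_length`
#'   are flagged as RT wildcards.
#' @param class_map Optional named character vector mapping compound names to
#'   flavonoid classes, or the name of a class column in the file.
#' @param source Database name recorded on every row.
#' @param mass_tol_ppm Records whose mass disagrees with their formula by
#'   more than this are rejected (with row numbers). Default 5 ppm.
#' @return Tibble of compound records: `name`, `mass`, `formula`, `rt`,
#'   `rt_wildcard`, `class`, `source`, plus any unmapped columns passed
#'   through untouched.
#' @export
read_compound_db <- function(path,
                             columns = c(name = "name", mass = "neutral_mass",
                                         formula = "formula", rt = "rt"),
                             run_length = 10, class_map = NULL,
                             source = basename(path), mass_tol_ppm = 5) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(unname(columns), names(raw))
  if (length(missing_cols)) {
    stop("mapped column(s) absent from ", basename(path), ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    name = as.character(raw[[columns[["name"]]]]),
    mass = suppressWarnings(as.numeric(raw[[columns[["mass"]]]])),
    formula = as.character(raw[[columns[["formula"]]]]),
    rt = suppressWarnings(as.numeric(raw[[columns[["rt"]]]]))
  )
  if (any(is.na(out$mass))) {
    stop("unparseable mass in row(s) ",
         paste(which(is.na(out$mass)), collapse = ", "), call. = FALSE)
  }
  if (any(out$mass <= 0)) {
    stop("non-positive mass in row(s) ",
         paste(which(out$mass <= 0), collapse = ", "), call. = FALSE)
  }
  have_formula <- !is.na(out$formula) & nzchar(out$formula)
  calc <- rep(NA_real_, nrow(out))
  calc[have_formula] <- vapply(out$formula[have_formula], function(f) {
    tryCatch(monoisotopic_mass(f), error = function(e) NA_real_)
  }, numeric(1))
  bad <- have_formula & !is.na(calc) &
    abs(ppm_error(out$mass, calc)) > mass_tol_ppm
  if (any(bad)) {
    stop("mass/formula mismatch (> ", mass_tol_ppm, " ppm) in row(s) ",
         paste(which(bad), collapse = ", "), " of ", basename(path),
         call. = FALSE)
  }
  out$rt_wildcard <- !is.na(out$rt) & abs(out$rt - run_length) < 1e-9
  out$class <- if (is.null(class_map)) {
    "other"
  } else if (length(class_map) == 1L && class_map %in% names(raw)) {
    as.character(raw[[class_map]])
  } else {
    unname(ifelse(out$name %in% names(class_map), class_map[out$name], "other"))
  }
  out$source <- source
  extra <- setdiff(names(raw), unname(columns))
  extra <- setdiff(extra, names(out))
  dplyr::bind_cols(out, raw[extra])
}

#' Write an aglycone fragment database
#'
#' Writes fragment records from [build_fragment_db()] in the same CSV
#' dialect read back by [read_fragment_db()]: fragment label, m/z on the
#' deprotonated basis, wildcard retention time, plus the aglycone, cleavage
#' class and retained-residue columns.
#'
#' @param records Fragment-record tibble.
#' @param path Output CSV path.
#' @param run_length Wildcard RT written for every row (minutes).
#' @return `path`, invisibly.
#' @export
write_fragment_db <- function(records, path, run_length = 10) {
  cols <- c("label", "mz", "aglycone", "cleavage", "residue_mass")
  if (nrow(records) == 0L) {
    records <- tibble::tibble(label = character(), mz = numeric(),
                              aglycone = character(), cleavage = character(),
                              residue_mass = numeric())
  }
  out <- records[intersect(c(cols, "class"), names(records))]
  out$rt <- if (nrow(out)) run_length else numeric()
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read an aglycone fragment database
#'
#' @param path CSV path written by [write_fragment_db()] (or any CSV with a
#'   compatible column mapping).
#' @param columns Mapping of the internal fields `label`, `mz`, `rt` to file
#'   columns.
#' @param run_length Run length for the RT wildcard convention.
#' @return Tibble of fragment records; `aglycone`, `cleavage`,
#'   `residue_mass` and `class` columns are carried through when present.
#' @export
read_fragment_db <- function(path,
                             columns = c(label = "label", mz = "mz", rt = "rt"),
                             run_length = 10) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(unname(columns), names(raw))
  if (length(missing_cols)) {
    stop("mapped column(s) absent from ", basename(path), ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    label = as.character(raw[[columns[["label"]]]]),
    mz = as.numeric(raw[[columns[["mz"]]]]),
    rt = as.numeric(raw[[columns[["rt"]]]])
  )
  out$rt_wildcard <- !is.na(out$rt) & abs(out$rt - run_length) < 1e-9
  extra <- setdiff(names(raw), unname(columns))
  dplyr::bind_cols(out, raw[extra])
}

#' Write an aligned feature table to CSV
#'
#' One row per consensus feature with per-sample intensity columns
#' (`intensity_<sample>`); gap-filled cells are marked in matching
#' `gapfilled_<sample>` columns.
#'
#' @param table Aligned feature tibble from [align_features()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  wide <- aligned_wide(table)
  readr::write_csv(wide, path, progress = FALSE)
  invisible(path)
}
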