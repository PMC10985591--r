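# Orchestration: the five-step DIA profiling workflow (base-peak
# chromatograms, independent MS1/MS2 feature detection, database search,
# precursor-fragment linking, reports), with YAML-configurable parameters.

#' Pipeline configuration
#'
#' Bundles the per-level detection configurations, search tolerances,
#' adduct set and linking parameters, optionally overridden from a YAML
#' file whose keys mirror the parameter names of [detection_config()],
#' [search_ms1()] and [link_precursor_fragment()].
#'
#' @param yaml Optional path to a YAML file with sections `ms1`, `ms2`,
#'   `search` and `link`.
#' @param seed Seed recorded for any simulation step.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(yaml = NULL, seed = 1) {
  cfg <- list(
    ms1 = detection_config(1),
    ms2 = detection_config(2),
    search = list(tol_abs = 0.005, tol_ppm = 5),
    link = list(rt_tol = 0.045, min_corr = 0.8),
    sugar_tol = 0.01,
    blank_ratio = 1 / 3,
    seed = seed
  )
  if (!is.null(yaml)) {
    over <- yaml::read_yaml(yaml)
    problems <- character()
    for (lev in intersect(c("ms1", "ms2"), names(over))) {
      unknown <- setdiff(names(over[[lev]]), names(cfg[[lev]]))
      if (length(unknown)) {
        problems <- c(problems, paste0(lev, ": unknown parameter(s) ",
                                       paste(unknown, collapse = ", ")))
      } else {
        cfg[[lev]][names(over[[lev]])] <- over[[lev]]
      }
    }
    for (sec in intersect(c("search", "link"), names(over))) {
      unknown <- setdiff(names(over[[sec]]), names(cfg[[sec]]))
      if (length(unknown)) {
        problems <- c(problems, paste0(sec, ": unknown parameter(s) ",
                                       paste(unknown, collapse = ", ")))
      } else {
        cfg[[sec]][names(over[[sec]])] <- over[[sec]]
      }
    }
    if ("seed" %in% names(over)) cfg$seed <- over$seed
    if (length(problems)) {
      stop("configuration problems:\n  ", paste(problems, collapse = "\n  "),
           call. = FALSE)
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full DIA flavonoid-profiling pipeline
#'
#' Detects features independently on both DIA channels of every run, aligns
#' them across samples, gap-fills, searches the MS1 compound and MS2
#' aglycone databases, links fragments to co-eluting precursors by peak
#' shape, assigns glycosyl neutral losses, and writes feature tables, a
#' precursor/fragment annotation table, backbone counts and figures.
#'
#' @param runs List of [ms_run()]s, or character paths to mzML files.
#' @param compound_db MS1 compound records ([read_compound_db()]).
#' @param fragment_db MS2 fragment records ([build_fragment_db()]).
#' @param out_dir Output directory; created if needed. `NULL` writes
#'   nothing.
#' @param config A [pipeline_config()].
#' @param blanks Optional character vector of sample ids to treat as
#'   blanks: aligned MS1 rows whose blank intensity reaches `blank_ratio`
#'   of the maximum sample intensity are dropped, and blanks are excluded
#'   from reports.
#' @return List with `ms1`, `ms2` (aligned tables), `ms1_annotations`,
#'   `ms2_annotations`, `links`, `glycosides`, `backbone_counts`,
#'   `ratio_table`.
#' @export
run_pipeline <- function(runs, compound_db, fragment_db, out_dir = NULL,
                         config = pipeline_config(), blanks = character()) {
  if (is.character(runs)) {
    missing_files <- runs[!file.exists(runs)]
    if (length(missing_files)) {
      stop("missing input file(s): ", paste(missing_files, collapse = ", "),
           call. = FALSE)
    }
    runs <- lapply(runs, read_mzml)
  }
  names(runs) <- vapply(runs, attr, character(1), "sample_id")
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  save_plot <- function(p, name, width = 7, height = 5) {
    if (!is.null(out_dir)) {
      ggplot2::ggsave(file.path(out_dir, name), p, width = width,
                      height = height, dpi = 500)
    }
  }

  # steps 1-2: per-level base peak chromatograms
  for (r in runs) {
    bpi <- bpi_chromatogram(r)
    save_plot(attr(bpi, "plot"),
              paste0("bpi_", attr(r, "sample_id"), ".png"))
  }

  message("detecting features on ", length(runs), " run(s)")
  f1 <- lapply(runs, detect_features, level = 1, cfg = config$ms1)
  f2 <- lapply(runs, detect_features, level = 2, cfg = config$ms2)
  ms1 <- gap_fill(align_features(f1, config$ms1), runs, config$ms1, level = 1)
  ms2 <- gap_fill(align_features(f2, config$ms2), runs, config$ms2, level = 2)

  # step 3: blank overview -- drop rows dominated by blank signal
  if (length(blanks)) {
    keep <- vapply(seq_len(nrow(ms1)), function(i) {
      mem <- ms1$members[[i]]
      bl <- max(c(0, mem$height[mem$sample_id %in% blanks]))
      smp <- max(c(0, mem$height[!mem$sample_id %in% blanks]))
      smp > 0 && bl < config$blank_ratio * smp
    }, logical(1))
    ms1 <- ms1[keep, ]
    ms1$members <- lapply(ms1$members, function(m) {
      m[!m$sample_id %in% blanks, ]
    })
    ms2$members <- lapply(ms2$members, function(m) {
      m[!m$sample_id %in% blanks, ]
    })
    ms2 <- ms2[vapply(ms2$members, nrow, integer(1)) > 0, ]
  }

  message("searching databases (", nrow(ms1), " MS1 / ", nrow(ms2),
          " MS2 features)")
  ann1 <- search_ms1(ms1, compound_db, tol_abs = config$search$tol_abs,
                     tol_ppm = config$search$tol_ppm)
  ann2 <- search_ms2(ms2, fragment_db, tol_abs = config$search$tol_abs,
                     tol_ppm = config$search$tol_ppm)

  links <- link_precursor_fragment(ms1, ms2, ms2_rows = unique(ann2$row_id),
                                   rt_tol = config$link$rt_tol,
                                   min_corr = config$link$min_corr)
  glyco <- if (nrow(links) && nrow(ann2)) {
    assign_glycoside(links, ann2, tol = config$sugar_tol)
  } else {
    tibble::tibble(ms1_row = integer(), aglycone = character(),
                   bond = character(), sugar = character(),
                   report = character())
  }

  counts <- classify_backbone(ann2, ms2)
  ratios <- if (nrow(counts)) class_ratio_table(counts) else
    tibble::tibble(sample_id = character(), n_flavone = integer(),
                   n_flavonol = integer(), ratio = numeric())

  if (!is.null(out_dir)) {
    write_feature_table(ms1, file.path(out_dir, "features_ms1.csv"))
    write_feature_table(ms2, file.path(out_dir, "features_ms2.csv"))
    readr::write_csv(ann1, file.path(out_dir, "annotations_ms1.csv"),
                     progress = FALSE)
    readr::write_csv(ann2, file.path(out_dir, "annotations_ms2.csv"),
                     progress = FALSE)
    readr::write_csv(annotation_table(glyco, ann1),
                     file.path(out_dir, "glycoside_annotations.csv"),
                     progress = FALSE)
    readr::write_csv(counts, file.path(out_dir, "backbone_counts.csv"),
                     progress = FALSE)
    readr::write_csv(ratios, file.path(out_dir, "class_ratios.csv"),
                     progress = FALSE)
    if (nrow(counts)) save_plot(backbone_stack(counts), "backbone_stack.png")
    if (length(runs) - length(blanks) >= 2 && nrow(ms1) >= 2) {
      save_plot(autoplot(sample_correlation(ms1)), "sample_correlation.png")
    }
  }
  list(ms1 = ms1, ms2 = ms2, ms1_annotations = ann1, ms2_annotations = ann2,
       links = links, glycosides = glyco, backbone_counts = counts,
       ratio_table = ratios)
}

#' Final annotation table in reporting layout
#'
#' One row per linked precursor-fragment pair: retention time, MS1 m/z and
#' its precursor candidate list (all database names within tolerance,
#' `"; "`-joined -- positional isomers are deliberately not resolved), ppm
#' errors, MS2 m/z and aglycone label, neutral loss and the bond/sugar
#' call. MS2 aglycone features without a linked precursor can be appended
#' as orphan rows with empty precursor columns.
#'
#' @param glycosides Tibble from [assign_glycoside()].
#' @param ms1_annotations Tibble from [search_ms1()].
#' @return Report tibble.
#' @export
annotation_table <- function(glycosides, ms1_annotations) {
  if (nrow(glycosides) == 0L) {
    return(tibble::tibble(rt = numeric(), ms1_mz = numeric(),
                          precursor_candidates = character(),
                          ms1_ppm = numeric(), ms2_mz = numeric(),
                          aglycone = character(), neutral_loss = numeric(),
                          bond = character(), sugar = character(),
                          report = character()))
  }
  prec <- dplyr::summarise(
    dplyr::group_by(ms1_annotations, .data$row_id),
    precursor_candidates = paste(unique(.data$name), collapse = "; "),
    ms1_ppm = .data$ppm[1], .groups = "drop")
  out <- dplyr::left_join(glycosides, prec,
                          by = c(ms1_row = "row_id"))
  dplyr::select(out, rt = "rt", ms1_mz = "ms1_mz",
                precursor_candidates = "precursor_candidates",
                ms1_ppm = "ms1_ppm", ms2_mz = "ms2_mz",
                aglycone = "aglycone", neutral_loss = "neutral_loss",
                bond = "bond", sugar = "sugar", report = "report")
}
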