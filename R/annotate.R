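# Annotation: MS1 database search with adducts, MS2 aglycone search,
# precursor-fragment linking by co-elution and peak shape, neutral-loss
# sugar assignment, O-/C-glycosylation classification, and Jaccard isomer
# scoring.

#' Search an MS1 feature table against a compound database
#'
#' Every (record, adduct) combination whose computed m/z falls within the
#' tolerance of a feature m/z becomes a candidate annotation, ranked per
#' feature by absolute ppm error. A record whose retention time is the
#' wildcard matches at any RT; otherwise the RT difference must stay within
#' `rt_tol`.
#'
#' @param table Aligned MS1 tibble from [align_features()].
#' @param db Compound records (see [read_compound_db()]).
#' @param adducts Adduct table, default [default_adducts()].
#' @param tol_abs,tol_ppm Search tolerance ("0.005 m/z or 5 ppm").
#' @param rt_tol RT tolerance (minutes) for non-wildcard records.
#' @return Annotation tibble: `row_id`, `mz`, `rt`, `name`, `adduct`,
#'   `mz_theo`, `ppm`, `rank`, `class`, `source`.
#' @export
search_ms1 <- function(table, db, adducts = default_adducts(),
                       tol_abs = 0.005, tol_ppm = 5, rt_tol = 0.1) {
  if (!is.data.frame(db) || nrow(db) == 0L) {
    stop("empty compound database", call. = FALSE)
  }
  if (!"rt_wildcard" %in% names(db)) db$rt_wildcard <- TRUE
  if (!"class" %in% names(db)) db$class <- "other"
  if (!"source" %in% names(db)) db$source <- "db"
  cand <- tidyr::crossing(
    dplyr::select(table, "row_id", "mz", "rt"),
    tidyr::crossing(
      dplyr::select(db, name = "name", mass = "mass", db_rt = "rt",
                    rt_wildcard = "rt_wildcard", class = "class",
                    source = "source"),
      dplyr::select(adducts, adduct = "name", delta = "delta",
                    charge = "charge", n_mol = "n_mol")
    )
  )
  cand$mz_theo <- (cand$n_mol * cand$mass + cand$delta) / abs(cand$charge)
  win <- mz_window(cand$mz_theo, tol_abs, tol_ppm)
  keep <- abs(cand$mz - cand$mz_theo) <= win &
    (cand$rt_wildcard | is.na(cand$db_rt) | abs(cand$rt - cand$db_rt) <= rt_tol)
  cand <- cand[keep, ]
  cand$ppm <- ppm_error(cand$mz, cand$mz_theo)
  cand <- dplyr::arrange(cand, .data$row_id, abs(.data$ppm), .data$name,
                         .data$adduct)
  cand <- dplyr::mutate(dplyr::group_by(cand, .data$row_id),
                        rank = dplyr::row_number())
  dplyr::select(dplyr::ungroup(cand), "row_id", "mz", "rt", "name", "adduct",
                "mz_theo", "ppm", "rank", "class", "source")
}

#' Search an MS2 feature table against an aglycone fragment database
#'
#' Fragment database m/z values are already on the deprotonated-ion basis,
#' so matching is direct, with the same "absolute or ppm" tolerance rule as
#' the MS1 search.
#'
#' @param table Aligned MS2 tibble.
#' @param fragdb Fragment records from [build_fragment_db()] (or
#'   [read_fragment_db()]).
#' @param tol_abs,tol_ppm Search tolerance.
#' @return Annotation tibble: `row_id`, `mz`, `rt`, `label`, `aglycone`,
#'   `cleavage`, `residue_mass`, `mz_theo`, `ppm`, `rank` (and `class` when
#'   present in the database).
#' @export
search_ms2 <- function(table, fragdb, tol_abs = 0.005, tol_ppm = 5) {
  if (!is.data.frame(fragdb) || nrow(fragdb) == 0L) {
    stop("empty fragment database", call. = FALSE)
  }
  keep_cols <- intersect(c("label", "mz", "aglycone", "cleavage",
                           "residue_mass", "class"), names(fragdb))
  cand <- tidyr::crossing(
    dplyr::select(table, "row_id", feat_mz = "mz", rt = "rt"),
    dplyr::rename(fragdb[keep_cols], mz_theo = "mz")
  )
  win <- mz_window(cand$mz_theo, tol_abs, tol_ppm)
  cand <- cand[abs(cand$feat_mz - cand$mz_theo) <= win, ]
  cand$ppm <- ppm_error(cand$feat_mz, cand$mz_theo)
  cand <- dplyr::arrange(cand, .data$row_id, abs(.data$ppm), .data$label)
  cand <- dplyr::mutate(dplyr::group_by(cand, .data$row_id),
                        rank = dplyr::row_number())
  dplyr::rename(dplyr::ungroup(cand), mz = "feat_mz")
}

# Pearson correlation of two chromatographic traces on a shared RT grid
.shape_correlation <- function(tr1, tr2) {
  lo <- max(min(tr1$rt), min(tr2$rt))
  hi <- min(max(tr1$rt), max(tr2$rt))
  if (hi <= lo) return(NA_real_)
  grid <- sort(unique(c(tr1$rt[tr1$rt >= lo & tr1$rt <= hi],
                        tr2$rt[tr2$rt >= lo & tr2$rt <= hi])))
  if (length(grid) < 4L) return(NA_real_)
  y1 <- stats::approx(tr1$rt, tr1$intensity, xout = grid)$y
  y2 <- stats::approx(tr2$rt, tr2$intensity, xout = grid)$y
  if (stats::sd(y1) == 0 || stats::sd(y2) == 0) return(NA_real_)
  stats::cor(y1, y2)
}

#' Link MS2 fragment features to MS1 precursor features
#'
#' For every MS2 row (optionally restricted to annotated rows), MS1 rows at
#' higher m/z within the RT tolerance are scored by peak-shape similarity:
#' the Pearson correlation of the two traces interpolated to a shared RT
#' grid, computed in the shared sample with the most intense precursor.
#' Pairs at or above `min_corr` are kept. Pairs where the fragment is more
#' intense than its precursor are flagged (`fragment_above_precursor`) with
#' a soft warning, not discarded.
#'
#' @param ms1,ms2 Aligned tibbles for the two levels, from the same samples.
#' @param ms2_rows Optional vector of MS2 `row_id`s to link (e.g. annotated
#'   ones); default all.
#' @param rt_tol Co-elution tolerance in minutes.
#' @param min_corr Minimum shape correlation.
#' @return Linked-pair tibble: `ms1_row`, `ms2_row`, `ms1_mz`, `ms2_mz`,
#'   `rt`, `delta_rt`, `correlation`, `intensity_ratio`, `neutral_loss`,
#'   `fragment_above_precursor`.
#' @export
link_precursor_fragment <- function(ms1, ms2, ms2_rows = NULL,
                                    rt_tol = 0.045, min_corr = 0.8) {
  if (is.null(ms2_rows)) ms2_rows <- ms2$row_id
  out <- list()
  for (j in which(ms2$row_id %in% ms2_rows)) {
    cand <- which(ms1$mz > ms2$mz[j] & abs(ms1$rt - ms2$rt[j]) <= rt_tol)
    for (i in cand) {
      mem1 <- ms1$members[[i]]; mem2 <- ms2$members[[j]]
      shared <- intersect(mem1$sample_id, mem2$sample_id)
      if (!length(shared)) next
      m1 <- mem1[mem1$sample_id %in% shared, ]
      s <- m1$sample_id[which.max(m1$height)]
      tr1 <- mem1$trace[[match(s, mem1$sample_id)]]
      tr2 <- mem2$trace[[match(s, mem2$sample_id)]]
      rho <- .shape_correlation(tr1, tr2)
      if (is.na(rho) || rho < min_corr) next
      h1 <- mem1$height[match(s, mem1$sample_id)]
      h2 <- mem2$height[match(s, mem2$sample_id)]
      out[[length(out) + 1L]] <- tibble::tibble(
        ms1_row = ms1$row_id[i], ms2_row = ms2$row_id[j],
        ms1_mz = ms1$mz[i], ms2_mz = ms2$mz[j],
        rt = ms2$rt[j], delta_rt = ms1$rt[i] - ms2$rt[j],
        correlation = rho, intensity_ratio = h2 / h1,
        neutral_loss = ms1$mz[i] - ms2$mz[j],
        fragment_above_precursor = h2 > h1
      )
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    return(tibble::tibble(ms1_row = integer(), ms2_row = integer(),
                          ms1_mz = numeric(), ms2_mz = numeric(),
                          rt = numeric(), delta_rt = numeric(),
                          correlation = numeric(), intensity_ratio = numeric(),
                          neutral_loss = numeric(),
                          fragment_above_precursor = logical()))
  }
  if (any(res$fragment_above_precursor)) {
    warning(sum(res$fragment_above_precursor),
            " linked pair(s) have fragment more intense than precursor",
            call. = FALSE)
  }
  res
}

# partial cross-ring losses per C-bound sugar and their sugar options
.c_partials <- function() {
  tibble::tibble(
    loss = c(monoisotopic_mass("C2H4O2"), monoisotopic_mass("C3H6O3"),
             monoisotopic_mass("C4H8O4")),
    options = list("pentoside", c("hexoside", "pentoside"), "hexoside")
  )
}

.sugar_multiset_string <- function(sugars) {
  sugars <- sort(sugars)
  if (length(sugars) == 1L) return(paste0("C-", sugars))
  if (length(unique(sugars)) == 1L) {
    prefix <- c("di", "tri")[length(sugars) - 1L]
    return(paste0(prefix, "-C-", sugars[1]))
  }
  paste(paste0("C-", sugars), collapse = "-")
}

# decompose a C-glycoside neutral loss into n_sugars partial losses
.decompose_c_loss <- function(loss, n_sugars, tol) {
  p <- .c_partials()
  idx <- seq_len(nrow(p))
  combos <- if (n_sugars == 1L) {
    lapply(idx, function(i) i)
  } else {
    unlist(lapply(idx, function(i) lapply(idx[idx >= i], function(j) c(i, j))),
           recursive = FALSE)
  }
  hits <- character()
  for (cc in combos) {
    if (abs(sum(p$loss[cc]) - loss) > tol) next
    opts <- expand.grid(p$options[cc], stringsAsFactors = FALSE)
    strs <- unique(apply(opts, 1, function(r) {
      .sugar_multiset_string(unlist(r, use.names = FALSE))
    }))
    hits <- c(hits, strs)
  }
  unique(hits)
}

#' Assign glycosidic bond type and sugar from a neutral loss
#'
#' For each linked precursor-fragment pair carrying an MS2 aglycone
#' annotation, the neutral loss (MS1 m/z minus MS2 m/z) is interpreted:
#' bond type O when the fragment is the bare (or radical) aglycone and the
#' loss matches an intact glycosyl entry (with a hydrogen-atom correction
#' for the radical); bond type C when the fragment retains sugar residues
#' and the loss decomposes into per-sugar partial losses (60.0211 /
#' 90.0317 / 120.0423 Da). Unmatched losses are reported numerically with
#' bond type `"unclassified"`.
#'
#' @param pairs Linked-pair tibble from [link_precursor_fragment()].
#' @param ms2_annotations MS2 annotation tibble from [search_ms2()];
#'   joined on `ms2_row` / `row_id`.
#' @param sugars Sugar dictionary, see [sugar_losses()].
#' @param tol Loss-matching tolerance in Da.
#' @return Glycoside-annotation tibble: pair columns plus `aglycone`,
#'   `cleavage`, `bond`, `sugar` (best candidate), `sugar_candidates`
#'   (all, `"; "`-joined), `sugar_delta`, `report` (e.g.
#'   `"Quercetin O-hexoside"`), and `class` when present.
#' @export
assign_glycoside <- function(pairs, ms2_annotations, sugars = sugar_losses(),
                             tol = 0.01) {
  ann <- dplyr::rename(ms2_annotations, ms2_row = "row_id")
  need <- intersect(c("ms2_row", "label", "aglycone", "cleavage",
                      "residue_mass", "class"), names(ann))
  joined <- dplyr::inner_join(pairs, ann[need], by = "ms2_row",
                              relationship = "many-to-many")
  if (nrow(joined) == 0L) {
    stop("no MS2 annotations on the linked pairs", call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(joined)), function(k) {
    x <- joined[k, ]
    loss <- x$neutral_loss
    bond <- "unclassified"
    sugar <- sugar_all <- sprintf("loss %.4f Da", loss)
    delta <- NA_real_
    if (x$cleavage %in% c("heterolytic-O", "homolytic-O")) {
      m <- match_sugar(loss, radical = x$cleavage == "homolytic-O",
                       tol = tol, sugars = sugars[sugars$bond == "O", ])
      if (nrow(m)) {
        bond <- "O"
        sugar <- m$label[1]
        sugar_all <- paste(m$label, collapse = "; ")
        delta <- m$delta[1]
      }
    } else if (x$cleavage == "C-residue") {
      # one sugar retains 42 or 72 Da; two sugars retain 84 to 144 Da
      n_sugars <- if (x$residue_mass < 80) 1L else 2L
      strs <- .decompose_c_loss(loss, n_sugars, tol)
      if (length(strs)) {
        bond <- "C"
        sugar <- paste(strs, collapse = " or ")
        sugar_all <- sugar
        delta <- NA_real_
      }
    }
    tibble::tibble(
      x[intersect(c("ms1_row", "ms2_row", "ms1_mz", "ms2_mz", "rt",
                    "delta_rt", "correlation", "intensity_ratio",
                    "neutral_loss", "fragment_above_precursor"), names(x))],
      aglycone = x$aglycone, cleavage = x$cleavage,
      class = if ("class" %in% names(x)) x$class else NA_character_,
      bond = bond, sugar = sugar, sugar_candidates = sugar_all,
      sugar_delta = delta,
      report = if (bond == "unclassified") {
        paste0(x$aglycone, " glycoside (", sugar, ")")
      } else {
        paste(x$aglycone, sugar)
      }
    )
  })
  dplyr::bind_rows(rows)
}

#' Jaccard similarity scoring of fragment sets
#'
#' Scores each candidate's theoretical fragment m/z set against the observed
#' set: matched / (observed + candidate - matched), a fragmentation-pattern
#' similarity used to discriminate isobaric aglycone isomers.
#'
#' @param observed Numeric vector of observed fragment m/z.
#' @param candidates Named list of theoretical fragment m/z vectors.
#' @param tol Matching tolerance in Da.
#' @return Tibble `candidate`, `n_matched`, `n_union`, `jaccard`, ranked
#'   descending.
#' @export
jaccard_isomer_score <- function(observed, candidates, tol = 0.01) {
  if (!length(observed)) stop("empty observed fragment set", call. = FALSE)
  if (!length(candidates)) stop("empty candidate set", call. = FALSE)
  out <- purrr::imap_dfr(candidates, function(theo, nm) {
    matched <- sum(vapply(theo, function(t) any(abs(observed - t) <= tol),
                          logical(1)))
    uni <- length(observed) + length(theo) - matched
    tibble::tibble(candidate = nm, n_matched = matched, n_union = uni,
                   jaccard = matched / uni)
  })
  dplyr::arrange(out, dplyr::desc(.data$jaccard), .data$candidate)
}

#' Per-sample backbone counts by aglycone and flavonoid class
#'
#' Counts annotated features per sample, aglycone and class. A feature is
#' counted once per aglycone (heterolytic and homolytic hits of the same
#' aglycone on one feature are one backbone hit); a sample holds the hit if
#' the feature has a member (detected or gap-filled) in that sample.
#'
#' @param annotations MS2 annotation tibble from [search_ms2()] carrying a
#'   `class` column.
#' @param table The aligned table the annotations refer to; supplies the
#'   per-sample membership. When omitted, counts are pooled under sample
#'   `"all"`.
#' @return Tibble `sample_id`, `aglycone`, `class`, `n_hits`.
#' @export
classify_backbone <- function(annotations, table = NULL) {
  if (nrow(annotations) == 0L) {
    return(tibble::tibble(sample_id = character(), aglycone = character(),
                          class = character(), n_hits = integer()))
  }
  uniq <- dplyr::distinct(annotations, .data$row_id, .data$aglycone,
                          .data$class)
  if (is.null(table)) {
    uniq$sample_id <- "all"
  } else {
    mem <- dplyr::select(table, "row_id", "members")
    mem <- tidyr::unnest(mem, "members", names_sep = "_")
    mem <- dplyr::distinct(mem, .data$row_id,
                           sample_id = .data$members_sample_id)
    uniq <- dplyr::inner_join(uniq, mem, by = "row_id",
                              relationship = "many-to-many")
  }
  dplyr::count(uniq, .data$sample_id, .data$aglycone, .data$class,
               name = "n_hits")
}
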