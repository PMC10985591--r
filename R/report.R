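# Summary analytics and figures: flavone:flavonol ratio, backbone
# distributions, sample correlation heatmap, database-overlap counts.

#' Flavone-to-flavonol ratio
#'
#' The chemophenetic index: flavone-backbone hit count divided by
#' flavonol-backbone hit count.
#'
#' @param flavone,flavonol Non-negative hit counts; `flavonol` must be > 0.
#' @return The ratio (scale-invariant in the two counts).
#' @examples
#' flavone_flavonol_ratio(60, 125) # 0.48
#' @export
flavone_flavonol_ratio <- function(flavone, flavonol) {
  if (any(flavonol <= 0)) {
    stop("flavone:flavonol ratio is undefined when the flavonol count is 0",
         call. = FALSE)
  }
  flavone / flavonol
}

#' Per-sample flavone:flavonol ratios from backbone counts
#'
#' @param counts Backbone-count tibble from [classify_backbone()].
#' @return Tibble `sample_id`, `n_flavone`, `n_flavonol`, `ratio` (NA where
#'   a sample has no flavonol hits), plus an `"overall"` row.
#' @export
class_ratio_table <- function(counts) {
  per <- dplyr::summarise(
    dplyr::group_by(counts, .data$sample_id),
    n_flavone = sum(.data$n_hits[.data$class == "flavone"]),
    n_flavonol = sum(.data$n_hits[.data$class == "flavonol"]),
    .groups = "drop")
  overall <- tibble::tibble(sample_id = "overall",
                            n_flavone = sum(per$n_flavone),
                            n_flavonol = sum(per$n_flavonol))
  out <- dplyr::bind_rows(per, overall)
  out$ratio <- ifelse(out$n_flavonol > 0, out$n_flavone / out$n_flavonol, NA)
  out
}

#' Pairwise sample correlation of feature profiles
#'
#' Pearson (or Spearman) correlation of `log10(1 + intensity)` sample
#' vectors over all aligned rows. Constant-intensity samples have no
#' defined correlation and are excluded with a warning.
#'
#' @param table Aligned tibble with at least 2 samples.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Symmetric correlation matrix with unit diagonal, class
#'   `flav_cor`.
#' @export
sample_correlation <- function(table, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  m <- log10(1 + aligned_intensity_matrix(table))
  if (ncol(m) < 2L) stop("need at least 2 samples", call. = FALSE)
  const <- apply(m, 2, stats::sd) == 0
  if (any(const)) {
    warning("excluding constant-intensity sample(s): ",
            paste(colnames(m)[const], collapse = ", "), call. = FALSE)
    m <- m[, !const, drop = FALSE]
    if (ncol(m) < 2L) stop("fewer than 2 non-constant samples", call. = FALSE)
  }
  structure(stats::cor(m, method = method), class = c("flav_cor", "matrix"))
}

#' Heatmap of a sample correlation matrix
#'
#' @param x A correlation matrix from [sample_correlation()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @method autoplot flav_cor
autoplot.flav_cor <- function(x, ...) {
  df <- tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(unclass(x)), sample_a = rownames(x)),
    -"sample_a", names_to = "sample_b", values_to = "r")
  ggplot2::ggplot(df, ggplot2::aes(.data$sample_a, .data$sample_b,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0,
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r",
                  title = "Feature-profile correlation") +
    ggplot2::theme_minimal()
}

#' Overlap counts of two hit sets
#'
#' Partition counts of two sets of consensus m/z values, each rounded to
#' `digits` decimals before comparison.
#'
#' @param hits_a,hits_b Numeric vectors of m/z hits.
#' @param digits Rounding used for set membership (default 4).
#' @return Tibble with one row: `only_a`, `only_b`, `shared`.
#' @export
venn_counts <- function(hits_a, hits_b, digits = 4) {
  a <- unique(round(hits_a, digits))
  b <- unique(round(hits_b, digits))
  tibble::tibble(only_a = length(setdiff(a, b)),
                 only_b = length(setdiff(b, a)),
                 shared = length(intersect(a, b)))
}

#' Stacked-bar figure of backbone distributions
#'
#' @param counts Backbone-count tibble from [classify_backbone()].
#' @param by Stack by `"class"` (default) or `"aglycone"`.
#' @return A ggplot object; the underlying tibble is attached as attribute
#'   `"data"` and per-sample bar totals equal the per-sample hit sums.
#' @export
backbone_stack <- function(counts, by = c("class", "aglycone")) {
  by <- match.arg(by)
  if (nrow(counts) == 0L) stop("no backbone counts", call. = FALSE)
  agg <- dplyr::summarise(
    dplyr::group_by(counts, .data$sample_id, .data[[by]]),
    n_hits = sum(.data$n_hits), .groups = "drop")
  p <- ggplot2::ggplot(agg, ggplot2::aes(.data$sample_id, .data$n_hits,
                                         fill = .data[[by]])) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "annotated backbone hits", fill = by,
                  title = "Flavonoid backbone distribution") +
    ggplot2::theme_minimal()
  attr(p, "data") <- agg
  p
}

#' Base-peak intensity chromatogram
#'
#' The per-scan maximum intensity trace of one MS level, the view used to
#' compare the precursor and fragment channels of a DIA run.
#'
#' @param run An [ms_run()].
#' @param level MS level, or `NULL` for all levels (faceted).
#' @return Tibble `ms_level`, `scan`, `rt`, `bpi` with a `plot` attribute.
#' @export
bpi_chromatogram <- function(run, level = NULL) {
  pk <- if (is.null(level)) run else run[run$ms_level == level, ]
  bpi <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(pk), .data$ms_level, .data$scan),
    rt = .data$rt[1], bpi = max(.data$intensity), .groups = "drop")
  p <- ggplot2::ggplot(bpi, ggplot2::aes(.data$rt, .data$bpi)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ms_level, ncol = 1, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "retention time (min)", y = "base-peak intensity",
                  title = attr(run, "sample_id")) +
    ggplot2::theme_minimal()
  attr(bpi, "plot") <- p
  bpi
}
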