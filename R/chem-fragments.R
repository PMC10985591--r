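# In-silico glycoside fragment generation and the glycosyl neutral-loss
# dictionary.
#
# O-glycosides release the intact glycosyl residue, leaving either the
# even-electron deprotonated aglycone [Agly - H]- (heterolytic cleavage) or
# the radical anion [Agly - 2H].- one hydrogen atom lower (homolytic
# cleavage). C-glycosides never release the bare aglycone: cross-ring sugar
# cleavage leaves a partial residue on the fragment, here 42.0106 Da (C2H2O,
# "etenol", from a 120.0423 Da loss off a hexosyl or a 90.0317 Da loss off a
# pentosyl residue) or 72.0211 Da (C3H4O2, from a 90.0317 Da loss off a
# hexosyl residue). Fragment m/z values are expressed on the deprotonated
# [M - H]- basis throughout.

.residue_etenol <- 42.01056468   # C2H2O retained on a C-glycoside fragment
.residue_c3h4o2 <- 72.02112936   # C3H4O2 retained on a C-glycoside fragment

.residue_name <- function(mass) {
  if (abs(mass - .residue_etenol) < 1e-3) "etenol" else "propenediol"
}

#' O-glycoside aglycone fragments
#'
#' For an aglycone of neutral monoisotopic mass M, returns the two diagnostic
#' fragments of O-glycosidic cleavage: the heterolytic deprotonated aglycone
#' at M - 1.007276 and the homolytic radical anion one hydrogen atom
#' (1.007825 Da) below it.
#'
#' @param mass Aglycone neutral monoisotopic mass, Da (> 0).
#' @param name Aglycone name used in fragment labels.
#' @return Tibble with columns `aglycone`, `label`, `mz`, `cleavage`
#'   (`"heterolytic-O"` / `"homolytic-O"`), `residue_mass` (0 for the bare
#'   aglycone).
#' @examples
#' o_glycoside_fragments(286.0477, "Kaempferol")
#' @export
o_glycoside_fragments <- function(mass, name = "aglycone") {
  if (!is.finite(mass) || mass <= 0) {
    stop("aglycone mass must be positive", call. = FALSE)
  }
  het <- mass - mass_constants[["proton"]]
  hom <- het - mass_constants[["hydrogen"]]
  tibble::tibble(
    aglycone = name,
    label = paste0(name, c(" [M-H]-", " [M-H].-")),
    mz = c(het, hom),
    cleavage = c("heterolytic-O", "homolytic-O"),
    residue_mass = 0
  )
}

#' C-glycoside modified-aglycone fragments
#'
#' Each C-bound sugar leaves a retained residue of 42.0106 Da (C2H2O) or
#' 72.0211 Da (C3H4O2) on the fragment. Fragments are the deprotonated
#' aglycone plus every distinct residue-sum for exactly `n_sugars` sugars.
#'
#' @param mass Aglycone neutral monoisotopic mass, Da (> 0).
#' @param n_sugars Number of C-bound sugars, 1 or 2.
#' @param name Aglycone name used in fragment labels.
#' @return Tibble in the same shape as [o_glycoside_fragments()], cleavage
#'   class `"C-residue"`, ordered by m/z.
#' @examples
#' c_glycoside_fragments(270.0528, 2, "Apigenin")
#' @export
c_glycoside_fragments <- function(mass, n_sugars, name = "aglycone") {
  if (!is.finite(mass) || mass <= 0) {
    stop("aglycone mass must be positive", call. = FALSE)
  }
  if (!n_sugars %in% c(1L, 2L)) {
    stop("`n_sugars` must be 1 or 2", call. = FALSE)
  }
  residues <- c(.residue_etenol, .residue_c3h4o2)
  combos <- if (n_sugars == 1L) {
    lapply(residues, function(r) r)
  } else {
    list(c(residues[1], residues[1]),
         c(residues[1], residues[2]),
         c(residues[2], residues[2]))
  }
  sums <- vapply(combos, sum, numeric(1))
  keep <- !duplicated(round(sums, 4))
  combos <- combos[keep]
  sums <- sums[keep]
  labels <- vapply(combos, function(cc) {
    nm <- vapply(cc, .residue_name, character(1))
    cnt <- table(nm)
    part <- ifelse(cnt == 2, paste0("di-", names(cnt)), names(cnt))
    paste0(name, "-", paste(part, collapse = "-"), " [M-H]-")
  }, character(1))
  out <- tibble::tibble(
    aglycone = name,
    label = labels,
    mz = mass - mass_constants[["proton"]] + sums,
    cleavage = "C-residue",
    residue_mass = sums
  )
  dplyr::arrange(out, .data$mz)
}

#' Default flavonoid aglycones
#'
#' The aglycone panel used to generate the MS2 fragment database: kaempferol
#' and its isomers datiscetin and luteolin, quercetin, catechin/epicatechin,
#' apigenin, taxifolin, naringenin and myricetin, with formulas and flavonoid
#' class tags.
#'
#' @return Tibble with columns `name`, `formula`, `class`.
#' @export
default_aglycones <- function() {
  tibble::tribble(
    ~name,         ~formula,   ~class,
    "Kaempferol",  "C15H10O6", "flavonol",
    "Datiscetin",  "C15H10O6", "flavonol",
    "Luteolin",    "C15H10O6", "flavone",
    "Quercetin",   "C15H10O7", "flavonol",
    "Myricetin",   "C15H10O8", "flavonol",
    "Apigenin",    "C15H10O5", "flavone",
    "Catechin",    "C15H14O6", "flavan-3-ol",
    "Epicatechin", "C15H14O6", "flavan-3-ol",
    "Taxifolin",   "C15H12O7", "flavanonol",
    "Naringenin",  "C15H12O5", "flavanone"
  )
}

#' Build an aglycone fragment database
#'
#' Generates, for every aglycone, the O-cleavage pair and all distinct
#' C-residue fragments for one and two sugars (7 records per aglycone),
#' labelled with aglycone name and cleavage class and ordered by
#' (aglycone, m/z).
#'
#' @param aglycones Data frame with columns `name` and `formula` (and
#'   optionally `class`, carried through). Defaults to
#'   [default_aglycones()].
#' @return Tibble of fragment records: `aglycone`, `label`, `mz`,
#'   `cleavage`, `residue_mass`, plus `class` when supplied.
#' @export
build_fragment_db <- function(aglycones = default_aglycones()) {
  if (!is.data.frame(aglycones) || nrow(aglycones) == 0L) {
    stop("`aglycones` must be a non-empty data frame", call. = FALSE)
  }
  stopifnot(all(c("name", "formula") %in% names(aglycones)))
  recs <- purrr::pmap(aglycones, function(name, formula, ...) {
    mass <- tryCatch(monoisotopic_mass(formula), error = function(e) {
      stop("aglycone '", name, "': ", conditionMessage(e), call. = FALSE)
    })
    frag <- dplyr::bind_rows(
      o_glycoside_fragments(mass, name),
      c_glycoside_fragments(mass, 1L, name),
      c_glycoside_fragments(mass, 2L, name)
    )
    extra <- list(...)
    if (!is.null(extra$class)) frag$class <- extra$class
    frag
  })
  dplyr::arrange(dplyr::bind_rows(recs), .data$aglycone, .data$mz)
}

#' Neutral loss between a precursor and a fragment
#'
#' @param precursor_mz,fragment_mz m/z values with
#'   `precursor_mz > fragment_mz`. Vectorised.
#' @return Neutral loss in Da.
#' @examples
#' neutral_loss(463.0869, 301.0319) # 162.0550, an O-hexose
#' @export
neutral_loss <- function(precursor_mz, fragment_mz) {
  if (any(fragment_mz >= precursor_mz)) {
    stop("fragment m/z must be below precursor m/z", call. = FALSE)
  }
  precursor_mz - fragment_mz
}

#' Glycosyl neutral-loss dictionary
#'
#' Sugar moieties recognised in neutral-loss assignment. O-type entries are
#' intact glycosyl residues (sugar minus water, e.g. hexose 162.0528 Da);
#' C-type entries are the partial cross-ring losses 60.0211 / 90.0317 /
#' 120.0423 Da plus the named 210.0739 Da di-C combination (90 + 120).
#' Acylated deoxyhexose entries cover coumaroyl decorations.
#'
#' @return Tibble with columns `name`, `label` (the reporting suffix, e.g.
#'   `"O-hexoside"`), `loss` (Da), `formula`, `bond` (`"O"`/`"C"`), `acyl`.
#' @export
sugar_losses <- function() {
  tab <- tibble::tribble(
    ~name,                      ~label,                          ~formula,    ~bond, ~acyl,
    "hexose",                   "O-hexoside",                    "C6H10O5",   "O",   FALSE,
    "pentose",                  "O-pentoside",                   "C5H8O4",    "O",   FALSE,
    "deoxyhexose",              "O-deoxyhexoside",               "C6H10O4",   "O",   FALSE,
    "deoxyhexosyl-pentose",     "O-deoxyhexosyl-pentoside",      "C11H18O8",  "O",   FALSE,
    "coumaroyl-deoxyhexose",    "O-coumaroyl-deoxyhexoside",     "C15H16O6",  "O",   TRUE,
    "di-coumaroyl-deoxyhexose", "O-di-coumaroyl-deoxyhexoside",  "C24H22O8",  "O",   TRUE,
    "C-partial-60",             "C-pentoside",                   "C2H4O2",    "C",   FALSE,
    "C-partial-90",             "C-hexoside or C-pentoside",     "C3H6O3",    "C",   FALSE,
    "C-partial-120",            "C-hexoside",                    "C4H8O4",    "C",   FALSE,
    "di-C-90+120",              "di-C-hexoside or C-hexoside-C-pentoside", "C7H14O7", "C", FALSE
  )
  tab$loss <- unname(vapply(tab$formula, monoisotopic_mass, numeric(1)))
  tab[, c("name", "label", "loss", "formula", "bond", "acyl")]
}

#' Match an observed neutral loss against the sugar dictionary
#'
#' For a radical (homolytic) fragment the expected loss is the glycosyl mass
#' plus one hydrogen atom (1.007825 Da), since the neutral carries the
#' homolytically transferred hydrogen.
#'
#' @param loss Observed neutral loss, Da (> 0).
#' @param radical Was the fragment the radical aglycone ion?
#' @param tol Matching tolerance in Da (> 0). Default 0.01.
#' @param sugars Dictionary tibble, see [sugar_losses()].
#' @return Tibble of matching entries with `expected_loss` and `delta`
#'   (observed - expected) columns, ordered by `abs(delta)`.
#' @examples
#' match_sugar(162.0550)
#' match_sugar(279.1105, radical = TRUE)
#' @export
match_sugar <- function(loss, radical = FALSE, tol = 0.01,
                        sugars = sugar_losses()) {
  if (!is.finite(tol) || tol <= 0) stop("`tol` must be positive", call. = FALSE)
  if (!is.finite(loss) || loss <= 0) {
    stop("`loss` must be positive", call. = FALSE)
  }
  sugars$expected_loss <- sugars$loss +
    if (isTRUE(radical)) mass_constants[["hydrogen"]] else 0
  sugars$delta <- loss - sugars$expected_loss
  out <- sugars[abs(sugars$delta) <= tol, ]
  dplyr::arrange(out, abs(.data$delta))
}

#' Build an MS1 glycoside compound database
#'
#' Enumerates aglycone x O-sugar combinations into compound records (neutral
#' mass = aglycone + glycosyl residue), the same shape returned by
#' [read_compound_db()]. Retention time is the wildcard (run length).
#'
#' @param aglycones Tibble with `name`, `formula`, `class`.
#' @param sugars Sugar dictionary; only O-type entries are used.
#' @param run_length Chromatographic run length in minutes (RT wildcard).
#' @param source Database name tag.
#' @return Tibble of compound records: `name`, `mass`, `formula`, `rt`,
#'   `rt_wildcard`, `class`, `source`.
#' @export
build_glycoside_db <- function(aglycones = default_aglycones(),
                               sugars = sugar_losses(),
                               run_length = 10, source = "generated") {
  sug <- sugars[sugars$bond == "O", ]
  combos <- tidyr::crossing(
    dplyr::select(aglycones, agly_name = "name", agly_formula = "formula",
                  class = "class"),
    dplyr::select(sug, sugar = "name", sugar_label = "label",
                  sugar_formula = "formula")
  )
  purrr::pmap_dfr(combos, function(agly_name, agly_formula, class, sugar,
                                   sugar_label, sugar_formula) {
    comp <- combine_formulas(agly_formula, sugar_formula)
    tibble::tibble(
      name = paste(agly_name, sugar_label),
      mass = monoisotopic_mass(comp),
      formula = format_formula(comp),
      rt = run_length,
      rt_wildcard = TRUE,
      class = class,
      source = source
    )
  })
}
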