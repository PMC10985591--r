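# Exact-mass arithmetic: formulas, monoisotopic masses, adducts, ppm errors.

# Monoisotopic (most abundant isotope) masses, Da. CODATA/NIST values.
.element_masses <- c(
  C  = 12.0000000,
  H  = 1.00782503,
  O  = 15.99491462,
  N  = 14.00307401,
  S  = 31.97207100,
  P  = 30.97376163,
  F  = 18.99840316,
  Cl = 34.96885268,
  Br = 78.91833760,
  I  = 126.90447300,
  Na = 22.98976928,
  K  = 38.96370649
)

#' Physical mass constants used in ion arithmetic
#'
#' Proton and hydrogen-atom monoisotopic masses in Da. Deprotonation uses the
#' proton mass; a homolytic hydrogen-atom loss uses the hydrogen-atom mass
#' (the 0.000549 Da electron difference between the two is what separates an
#' even-electron fragment from its radical counterpart). The electron mass is
#' otherwise ignored in adduct arithmetic, which reproduces routine
#' negative-mode metabolomics annotation to well under 0.1 ppm at m/z 300.
#'
#' @format Named numeric vector with entries `proton`, `hydrogen`,
#'   `c13_delta` (the 13C-12C spacing used in deisotoping).
#' @export
mass_constants <- c(
  proton    = 1.00727647,
  hydrogen  = 1.00782503,
  c13_delta = 1.00335484
)

#' Parse a molecular formula into element counts
#'
#' Parses a Hill-style molecular formula (e.g. `"C15H10O6"`) into a named
#' integer vector of element counts. Element symbols are case-sensitive;
#' unknown symbols and explicit zero counts are errors.
#'
#' @param formula Single character string, e.g. `"C15H10O6"`.
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C15H10O6")
#' parse_formula("H2O")
#' @export
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || is.na(formula) ||
      !nzchar(formula)) {
    stop("`formula` must be a single non-empty string", call. = FALSE)
  }
  rx <- "([A-Z][a-z]?)([0-9]*)"
  m <- gregexpr(rx, formula, perl = TRUE)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula)) {
    stop("cannot parse formula: ", formula, call. = FALSE)
  }
  sym <- sub(rx, "\\1", toks)
  cnt <- sub(rx, "\\2", toks)
  cnt <- ifelse(cnt == "", 1L, suppressWarnings(as.integer(cnt)))
  bad <- setdiff(sym, names(.element_masses))
  if (length(bad)) {
    stop("unknown element symbol(s) in '", formula, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(is.na(cnt)) || any(cnt <= 0L)) {
    stop("zero or unreadable element count in formula: ", formula,
         call. = FALSE)
  }
  counts <- tapply(cnt, sym, sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  # Hill order: C, H, then alphabetical
  ord <- order(match(names(out), c("C", "H"), nomatch = 3L), names(out))
  out[ord]
}

#' Combine element-count vectors
#'
#' Adds the element counts of two parsed formulas (see [parse_formula()]),
#' e.g. an aglycone plus a glycosyl residue.
#'
#' @param a,b Named integer vectors of element counts, or formula strings.
#' @return Named integer vector of the combined counts, Hill-ordered.
#' @export
combine_formulas <- function(a, b) {
  a <- if (is.character(a)) parse_formula(a) else a
  b <- if (is.character(b)) parse_formula(b) else b
  all_sym <- union(names(a), names(b))
  out <- vapply(all_sym, function(s) {
    sum(a[s], b[s], na.rm = TRUE)
  }, integer(1))
  ord <- order(match(names(out), c("C", "H"), nomatch = 3L), names(out))
  out[ord]
}

#' Format element counts as a Hill-order formula string
#'
#' @param comp Named integer vector of element counts.
#' @return A formula string such as `"C21H20O11"`.
#' @export
format_formula <- function(comp) {
  comp <- comp[comp > 0]
  ord <- order(match(names(comp), c("C", "H"), nomatch = 3L), names(comp))
  comp <- comp[ord]
  paste0(names(comp), ifelse(comp == 1L, "", comp), collapse = "")
}

#' Monoisotopic mass of a composition or formula
#'
#' Sums the most-abundant-isotope masses of every atom. An empty composition
#' has mass 0.
#'
#' @param x A formula string or a named integer vector from [parse_formula()].
#' @return Monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("C15H10O6") # kaempferol, 286.0477
#' @export
monoisotopic_mass <- function(x) {
  if (is.character(x)) x <- parse_formula(x)
  if (length(x) == 0L) return(0)
  bad <- setdiff(names(x), names(.element_masses))
  if (length(bad)) {
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  sum(.element_masses[names(x)] * as.numeric(x))
}

#' Negative-mode adduct definitions
#'
#' The adduct set used for MS1 database search: deprotonated, chloride,
#' bromide and formate attachment, each as the single molecule and the
#' 2M dimer, plus the doubly deprotonated ion (charge 2). `delta` is the
#' mass added to `n_mol` neutral molecules; `charge` is signed.
#'
#' @return Tibble with columns `name`, `delta`, `charge`, `n_mol`.
#' @export
default_adducts <- function() {
  base <- tibble::tribble(
    ~name,       ~delta,                           ~charge,
    "[M-H]-",    -mass_constants[["proton"]],      -1L,
    "[M+Cl]-",   .element_masses[["Cl"]],          -1L,
    "[M+Br]-",   .element_masses[["Br"]],          -1L,
    # formate: formic acid attachment minus a proton
    "[M+FA]-",   monoisotopic_mass("CH2O2") - mass_constants[["proton"]], -1L
  )
  dimers <- base
  dimers$name <- sub("\\[M", "[2M", dimers$name)
  out <- dplyr::bind_rows(
    dplyr::mutate(base, n_mol = 1L),
    dplyr::mutate(dimers, n_mol = 2L),
    tibble::tibble(name = "[M-2H]2-",
                   delta = -2 * mass_constants[["proton"]],
                   charge = -2L, n_mol = 1L)
  )
  tibble::as_tibble(out)
}

#' m/z of an adduct ion
#'
#' `m/z = (n_mol * M + delta) / |charge|`. Deprotonation subtracts the proton
#' mass 1.007276 Da.
#'
#' @param mass Neutral monoisotopic mass in Da (> 0). Vectorised.
#' @param adduct One row of an adduct table (see [default_adducts()]), or an
#'   adduct name to look up there.
#' @return m/z values.
#' @examples
#' adduct_mz(286.0477, "[M-H]-") # kaempferol, 285.0405
#' @export
adduct_mz <- function(mass, adduct = "[M-H]-") {
  if (any(!is.finite(mass)) || any(mass <= 0)) {
    stop("neutral mass must be positive and finite", call. = FALSE)
  }
  if (is.character(adduct)) {
    tab <- default_adducts()
    hit <- tab[tab$name == adduct, ]
    if (nrow(hit) != 1L) stop("unknown adduct name: ", adduct, call. = FALSE)
    adduct <- hit
  }
  (adduct$n_mol * mass + adduct$delta) / abs(adduct$charge)
}

#' Signed mass error in parts per million
#'
#' `1e6 * (observed - theoretical) / theoretical`.
#'
#' @param observed,theoretical m/z values; `theoretical` must be > 0.
#'   Vectorised.
#' @return Signed ppm error.
#' @examples
#' ppm_error(300.0272, 300.02755)
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(!is.finite(theoretical)) || any(theoretical <= 0)) {
    stop("theoretical m/z must be positive", call. = FALSE)
  }
  1e6 * (observed - theoretical) / theoretical
}

#' Absolute m/z tolerance window
#'
#' MZmine-style "x m/z or y ppm" tolerance: the effective half-window is the
#' maximum of the absolute and the relative component at the given m/z.
#'
#' @param mz m/z at which the window is evaluated.
#' @param tol_abs Absolute component in Da.
#' @param tol_ppm Relative component in ppm.
#' @return Half-window width in Da.
#' @export
mz_window <- function(mz, tol_abs, tol_ppm) {
  pmax(tol_abs, mz * tol_ppm * 1e-6)
}
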