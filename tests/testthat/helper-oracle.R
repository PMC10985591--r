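# Independent oracle for exact-mass arithmetic: its own isotope-mass table
# (typed from the NIST atomic mass compilation, more digits than the
# package's) and its own formula walker, kept deliberately separate from the
# implementation under test.

oracle_isotopes <- c(
  H = 1.00782503207, C = 12.0, N = 14.0030740048, O = 15.99491461956,
  P = 30.97376163, S = 31.97207100, Cl = 34.96885268, Br = 78.9183371,
  Na = 22.9897692809, K = 38.96370668
)
oracle_proton <- 1.00727646688
oracle_hydrogen <- 1.00782503207

# character-scanning formula parser, no shared code with the package
oracle_mass <- function(formula) {
  chars <- strsplit(formula, "")[[1]]
  total <- 0
  i <- 1
  n <- length(chars)
  while (i <= n) {
    sym <- chars[i]; i <- i + 1
    if (i <= n && grepl("[a-z]", chars[i])) {
      sym <- paste0(sym, chars[i]); i <- i + 1
    }
    digits <- ""
    while (i <= n && grepl("[0-9]", chars[i])) {
      digits <- paste0(digits, chars[i]); i <- i + 1
    }
    cnt <- if (digits == "") 1 else as.integer(digits)
    if (!sym %in% names(oracle_isotopes)) stop("oracle: unknown ", sym)
    total <- total + oracle_isotopes[[sym]] * cnt
  }
  total
}

# expected O-cleavage fragment pair from first principles
oracle_o_pair <- function(formula) {
  het <- oracle_mass(formula) - oracle_proton
  c(het = het, hom = het - oracle_hydrogen)
}

# expected C-residue fragments for 1..2 sugars
oracle_c_frags <- function(formula, n_sugars) {
  r <- c(oracle_mass("C2H2O"), oracle_mass("C3H4O2"))
  base <- oracle_mass(formula) - oracle_proton
  sums <- if (n_sugars == 1) r else
    unique(round(c(2 * r[1], r[1] + r[2], 2 * r[2]), 6))
  sort(base + sums)
}
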