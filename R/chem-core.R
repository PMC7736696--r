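# Exact-mass chemistry: elemental formulas, peptide/glycan assembly, m/z,
# and theoretical isotope patterns by per-element convolution.

# Monoisotopic masses and isotope tables, IUPAC 2021 atomic properties.
# Isotope offsets are nucleon-number differences from the lightest isotope;
# fine structure within an offset is collapsed (see isotope_pattern()).
.ELEMENTS <- list(
  C = list(mono = 12.0,           iso = list(offsets = c(0L, 1L),
            masses = c(12.0, 13.003354835), abund = c(0.9893, 0.0107))),
  H = list(mono = 1.0078250319,   iso = list(offsets = c(0L, 1L),
            masses = c(1.0078250319, 2.0141017781), abund = c(0.999885, 0.000115))),
  N = list(mono = 14.0030740052,  iso = list(offsets = c(0L, 1L),
            masses = c(14.0030740052, 15.0001088989), abund = c(0.99636, 0.00364))),
  O = list(mono = 15.9949146221,  iso = list(offsets = c(0L, 1L, 2L),
            masses = c(15.9949146221, 16.9991315650, 17.9991596129),
            abund = c(0.99757, 0.00038, 0.00205))),
  S = list(mono = 31.97207069,    iso = list(offsets = c(0L, 1L, 2L, 4L),
            masses = c(31.97207069, 32.97145890, 33.96786701, 35.96708069),
            abund = c(0.9499, 0.0075, 0.0425, 0.0001)))
)

#' Mass of a proton (Da), for protonated-adduct m/z arithmetic
#' @export
PROTON_MASS <- 1.007276466

#' Average isotope spacing (Da) used for envelope detection and extraction
#'
#' The mean mass gap between successive isotopologues of a peptide-like
#' molecule; centroid m/z of isotope k at charge z is taken as
#' mono m/z + k * 1.00336 / z.
#' @export
ISOTOPE_SPACING <- 1.00336

# Amino acid residue formulas (monomer minus water), 20 standard residues.
.AA_FORMULAS <- list(
  G = c(C = 2, H = 3, N = 1, O = 1),
  A = c(C = 3, H = 5, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2),
  P = c(C = 5, H = 7, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1),
  T = c(C = 4, H = 7, N = 1, O = 2),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1),
  I = c(C = 6, H = 11, N = 1, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2),
  D = c(C = 4, H = 5, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2),
  K = c(C = 6, H = 12, N = 2, O = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1),
  F = c(C = 9, H = 9, N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1),
  Y = c(C = 9, H = 9, N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1)
)

# Glycan residue formulas (monosaccharide minus water).
.GLYCAN_RESIDUES <- list(
  H = c(C = 6, H = 10, O = 5),            # hexose
  N = c(C = 8, H = 13, N = 1, O = 5),     # N-acetylhexosamine
  F = c(C = 6, H = 10, O = 4),            # deoxyhexose (fucose)
  S = c(C = 11, H = 17, N = 1, O = 8)     # N-acetylneuraminic acid
)

# Named modifications: delta formulas applied on top of the peptide backbone.
.MODIFICATIONS <- list(
  carbamidomethyl = c(C = 2, H = 3, N = 1, O = 1),   # C[+57]
  met_oxidation   = c(O = 1),                        # M[+16]
  cys_oxidation   = c(O = 1),                        # +15.9949 on CAM-Cys
  formylation     = c(C = 1, O = 1)                  # +27.9949, formic acid adduct
)

## ---- elemental formulas ----------------------------------------------------

#' Parse an elemental formula string
#'
#' @param x formula like `"C2H5O2NS"` (counts default to 1).
#' @return named integer vector of element counts.
#' @examples
#' formula_parse("C2H5O2NS")
#' @export
formula_parse <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (!nzchar(x)) return(integer(0))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", x, perl = TRUE)[[1]]
  toks <- regmatches(x, list(m))[[1]]
  if (sum(nchar(toks)) != nchar(x))
    stop("malformed formula: ", x)
  el <- sub("[0-9]*$", "", toks)
  n <- as.integer(ifelse(grepl("[0-9]+$", toks), sub("^[A-Za-z]+", "", toks), "1"))
  out <- tapply(n, el, sum)
  storage.mode(out) <- "integer"
  out[out > 0L]
}

#' Combine elemental formulas
#'
#' Element-wise addition of `n` copies of `f2` onto `f1`; negative `n`
#' subtracts, and subtraction below zero for any element is an error.
#'
#' @param f1,f2 named integer vectors of element counts.
#' @param n integer multiplier for `f2`.
#' @return named integer vector.
#' @export
formula_add <- function(f1, f2, n = 1L) {
  els <- union(names(f1), names(f2))
  out <- setNames(integer(length(els)), els)
  out[names(f1)] <- out[names(f1)] + f1
  out[names(f2)] <- out[names(f2)] + as.integer(n) * f2
  if (any(out < 0L))
    stop("formula subtraction yields negative count for: ",
         paste(els[out < 0L], collapse = ", "))
  out[out > 0L]
}

#' Monoisotopic mass of an elemental formula
#'
#' @param formula named integer vector (as from [formula_parse()]) or a
#'   formula string.
#' @return mass in Da.
#' @examples
#' formula_mass("C2H5O2NS")  # 107.0041, oxidized carbamidomethyl-Cys loss
#' @export
formula_mass <- function(formula) {
  if (is.character(formula)) formula <- formula_parse(formula)
  if (length(formula) == 0L) return(0)
  unknown <- setdiff(names(formula), names(.ELEMENTS))
  if (length(unknown))
    stop("unknown element(s): ", paste(unknown, collapse = ", "))
  sum(vapply(names(formula), function(e) .ELEMENTS[[e]]$mono, 0) * formula)
}

## ---- glycan compositions ---------------------------------------------------

#' Parse a glycan composition in HxNyFzSw shorthand
#'
#' Counts of hexose (H), N-acetylhexosamine (N), deoxyhexose/fucose (F) and
#' N-acetylneuraminic acid (S). `"H5N4F1S1"` is 5 Hex, 4 HexNAc, 1 Fuc,
#' 1 NeuAc. Absent monosaccharides get count 0; the empty string is the empty
#' composition (mass 0).
#'
#' @param x composition string.
#' @return named integer vector with names H, N, F, S.
#' @export
glycan_parse <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  out <- c(H = 0L, N = 0L, F = 0L, S = 0L)
  if (!nzchar(x)) return(out)
  m <- gregexpr("([HNFS])(-?[0-9]+)", x, perl = TRUE)[[1]]
  toks <- regmatches(x, list(m))[[1]]
  if (sum(nchar(toks)) != nchar(x))
    stop("malformed glycan composition: ", x)
  for (t in toks) out[substr(t, 1, 1)] <- out[substr(t, 1, 1)] + as.integer(substring(t, 2))
  out
}

#' Format a glycan composition back to HxNyFzSw shorthand
#'
#' Inverse of [glycan_parse()]: zero counts are omitted, so the round trip
#' is lossless on logical compositions.
#'
#' @param counts named integer vector (H, N, F, S).
#' @return composition string ("" for the empty composition).
#' @export
glycan_format <- function(counts) {
  counts <- glycan_counts(counts)
  nz <- counts != 0L
  paste0(names(counts)[nz], counts[nz], collapse = "")
}

# Normalize any representation to a full H/N/F/S count vector.
glycan_counts <- function(x) {
  if (is.character(x)) return(glycan_parse(x))
  out <- c(H = 0L, N = 0L, F = 0L, S = 0L)
  out[names(x)] <- as.integer(x)
  out
}

#' Is a glycan composition logical (all counts non-negative)?
#' @param x composition string or count vector.
#' @export
glycan_is_logical <- function(x) all(glycan_counts(x) >= 0L)

#' Elemental formula of a glycan composition (residue formulas)
#' @param x composition string or count vector.
#' @export
glycan_formula <- function(x) {
  counts <- glycan_counts(x)
  if (any(counts < 0L)) stop("illogical composition: ", glycan_format(counts))
  out <- integer(0)
  for (code in names(counts))
    if (counts[[code]] > 0L)
      out <- formula_add(out, .GLYCAN_RESIDUES[[code]], counts[[code]])
  out
}

#' Monoisotopic mass of a glycan composition (sum of residue masses)
#' @param x composition string or count vector.
#' @export
glycan_mass <- function(x) {
  counts <- glycan_counts(x)
  sum(counts * vapply(names(counts), function(code)
    formula_mass(.GLYCAN_RESIDUES[[code]]), 0))
}

## ---- building-block registry ----------------------------------------------

#' Monosaccharide building-block registry
#'
#' The mass deltas and per-block retention-time windows used to connect
#' glycopeptide features in the identification graph. Defaults: Hex
#' (162.0528 Da, 30 s), HexNAc (203.0794 Da, 30 s), the HexHexNAc composite
#' (365.1322 Da, 30 s) which bridges missing intermediates, Fuc (146.0579 Da,
#' 20 s) and NeuAc (291.0954 Da, 120 s). The `delta` columns give the glycan
#' count increment of traversing an edge of that block.
#'
#' @return data.frame with columns `code`, `name`, `formula`, `mass`,
#'   `rt_window`, `dH`, `dN`, `dF`, `dS`.
#' @export
block_registry <- function() {
  b <- data.frame(
    code = c("Hex", "HexNAc", "HexHexNAc", "Fuc", "NeuAc"),
    name = c("hexose", "N-acetylhexosamine", "hexose + N-acetylhexosamine",
             "deoxyhexose (fucose)", "N-acetylneuraminic acid"),
    formula = c("C6H10O5", "C8H13NO5", "C14H23NO10", "C6H10O4", "C11H17NO8"),
    rt_window = c(30, 30, 30, 20, 120),
    dH = c(1L, 0L, 1L, 0L, 0L),
    dN = c(0L, 1L, 1L, 0L, 0L),
    dF = c(0L, 0L, 0L, 1L, 0L),
    dS = c(0L, 0L, 0L, 0L, 1L),
    stringsAsFactors = FALSE
  )
  b$mass <- vapply(b$formula, formula_mass, 0, USE.NAMES = FALSE)
  b
}

#' Read a building-block registry from TSV
#'
#' Columns: `code`, `name`, `formula`, `rt_window`, `dH`, `dN`, `dF`, `dS`.
#' Residue masses are recomputed from the formulas.
#'
#' @param path TSV file.
#' @export
read_block_registry <- function(path) {
  b <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("code", "name", "formula", "rt_window", "dH", "dN", "dF", "dS")
  if (!all(need %in% names(b)))
    stop("block registry must have columns: ", paste(need, collapse = ", "))
  if (any(b$rt_window <= 0)) stop("rt_window must be > 0")
  b$mass <- vapply(b$formula, formula_mass, 0, USE.NAMES = FALSE)
  b
}

#' Residue mass of a registered building block
#' @param code block code, e.g. `"HexNAc"`.
#' @param blocks registry from [block_registry()].
#' @export
block_mass <- function(code, blocks = block_registry()) {
  i <- match(code, blocks$code)
  if (is.na(i)) stop("unknown building block: ", code)
  blocks$mass[i]
}

## ---- peptides and glycopeptides -------------------------------------------

#' Define a peptide backbone
#'
#' @param sequence amino-acid string (20 standard one-letter codes).
#' @param fixed_mods character vector of modification names from the
#'   registry (`carbamidomethyl`, `met_oxidation`, `cys_oxidation`,
#'   `formylation`); repeats apply the shift multiple times.
#' @param label cluster label (e.g. `"TPL"`, `"IgG1"`).
#' @return object of class `peptide`.
#' @export
peptide <- function(sequence, fixed_mods = character(0), label = sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  aa <- strsplit(sequence, "")[[1]]
  bad <- setdiff(aa, names(.AA_FORMULAS))
  if (length(bad)) stop("unknown residue(s): ", paste(unique(bad), collapse = ", "))
  bad_mod <- setdiff(fixed_mods, names(.MODIFICATIONS))
  if (length(bad_mod)) stop("unknown modification(s): ", paste(bad_mod, collapse = ", "))
  structure(list(sequence = sequence, fixed_mods = fixed_mods, label = label),
            class = "peptide")
}

#' Elemental formula of a peptide (residues + water + fixed modifications)
#' @param pep a [peptide()] or a plain sequence string.
#' @export
peptide_formula <- function(pep) {
  if (is.character(pep)) pep <- peptide(pep)
  f <- c(H = 2L, O = 1L)  # water
  for (a in strsplit(pep$sequence, "")[[1]])
    f <- formula_add(f, .AA_FORMULAS[[a]])
  for (m in pep$fixed_mods)
    f <- formula_add(f, .MODIFICATIONS[[m]])
  f
}

#' Monoisotopic neutral mass of a peptide
#' @inheritParams peptide_formula
#' @export
peptide_mass <- function(pep) formula_mass(peptide_formula(pep))

#' Elemental formula of a glycopeptide
#'
#' @param pep [peptide()] or sequence string.
#' @param glycan composition string or count vector.
#' @param extra_mods additional modification names applied on top.
#' @export
glycopeptide_formula <- function(pep, glycan = "", extra_mods = character(0)) {
  f <- peptide_formula(pep)
  f <- formula_add(f, glycan_formula(glycan))
  for (m in extra_mods) {
    if (!m %in% names(.MODIFICATIONS)) stop("unknown modification: ", m)
    f <- formula_add(f, .MODIFICATIONS[[m]])
  }
  f
}

#' Monoisotopic neutral mass of a glycopeptide
#'
#' Peptide backbone (residues + water + fixed mods) plus glycan residue
#' masses plus any extra modifications; additive in glycan counts and mods.
#'
#' @inheritParams glycopeptide_formula
#' @examples
#' m <- glycopeptide_mass("TPLTANITK", "H5N5F1S1")
#' mz(m, 3)  # 1074.4619
#' @export
glycopeptide_mass <- function(pep, glycan = "", extra_mods = character(0)) {
  if (is.character(pep)) pep <- peptide(pep)
  peptide_mass(pep) + glycan_mass(glycan) +
    sum(vapply(extra_mods, function(m) {
      if (!m %in% names(.MODIFICATIONS)) stop("unknown modification: ", m)
      formula_mass(.MODIFICATIONS[[m]])
    }, 0))
}

#' Mass-to-charge ratio of a protonated ion
#' @param neutral_mass neutral monoisotopic mass (Da).
#' @param charge positive integer charge (protons).
#' @export
mz <- function(neutral_mass, charge) {
  if (any(charge < 1)) stop("charge must be >= 1")
  (neutral_mass + charge * PROTON_MASS) / charge
}

#' Neutral mass from m/z and charge (inverse of [mz()])
#' @param x m/z value.
#' @param charge positive integer charge.
#' @export
neutral_mass <- function(x, charge) {
  if (any(charge < 1)) stop("charge must be >= 1")
  x * charge - charge * PROTON_MASS
}

#' Mass shift of a registered modification
#' @param name modification name.
#' @export
modification_mass <- function(name) {
  if (!name %in% names(.MODIFICATIONS)) stop("unknown modification: ", name)
  formula_mass(.MODIFICATIONS[[name]])
}

## ---- isotope patterns ------------------------------------------------------

# Aggregated isotope distribution of n atoms of one element on the integer
# offset grid, by binary-exponentiation convolution of the single-atom
# distribution.
.element_pattern <- function(element, n) {
  iso <- .ELEMENTS[[element]]$iso
  single <- numeric(max(iso$offsets) + 1L)
  single[iso$offsets + 1L] <- iso$abund
  single <- single / sum(single)
  out <- 1
  base <- single
  while (n > 0L) {
    if (n %% 2L == 1L) out <- convolve_trim(out, base)
    n <- n %/% 2L
    if (n > 0L) base <- convolve_trim(base, base)
  }
  out
}

# Linear convolution of two abundance vectors, trimming a negligible tail.
convolve_trim <- function(a, b, tail_tol = 1e-15) {
  out <- stats::convolve(a, rev(b), type = "open")
  out[out < 0] <- 0
  keep <- max(which(out > tail_tol), 1L)
  out[seq_len(keep)]
}

#' Theoretical isotope pattern of an elemental formula
#'
#' Relative isotopologue abundances aggregated per integer isotope offset
#' (0 = monoisotopic), computed by iterated convolution of per-element
#' isotope distributions. The returned pattern is the smallest prefix of
#' offsets whose summed fraction reaches `min_covered_fraction`; areas
#' integrated over that prefix are corrected downstream by dividing by
#' `covered_fraction`.
#'
#' @param formula element count vector or formula string.
#' @param min_covered_fraction minimal share of the full distribution to
#'   include, in (0, 1].
#' @return list with `offsets` (integer), `fractions` (abundances of the
#'   included isotopes, summing to `covered_fraction`) and `covered_fraction`.
#' @export
isotope_pattern <- function(formula, min_covered_fraction = 0.95) {
  if (is.character(formula)) formula <- formula_parse(formula)
  stopifnot(length(formula) > 0L,
            min_covered_fraction > 0, min_covered_fraction <= 1)
  unknown <- setdiff(names(formula), names(.ELEMENTS))
  if (length(unknown))
    stop("no isotope table for element(s): ", paste(unknown, collapse = ", "))
  full <- 1
  for (e in names(formula))
    if (formula[[e]] > 0L)
      full <- convolve_trim(full, .element_pattern(e, formula[[e]]))
  full <- full / sum(full)
  cum <- cumsum(full)
  k <- which(cum >= min_covered_fraction - 1e-12)[1]
  if (is.na(k)) k <- length(full)
  list(offsets = 0:(k - 1L),
       fractions = full[seq_len(k)],
       covered_fraction = cum[k])
}
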