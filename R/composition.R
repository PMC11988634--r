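# All 118 IUPAC element symbols, for recognising tokens; valence and mass
# coverage is narrower and checked separately.
.elementSymbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn",
  "Fr", "Ra", "Ac", "Th", "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf",
  "Es", "Fm", "Md", "No", "Lr", "Rf", "Db", "Sg", "Bh", "Hs", "Mt", "Ds",
  "Rg", "Cn", "Nh", "Fl", "Mc", "Lv", "Ts", "Og")

#' Construct a MolecularComposition
#'
#' @param elements named vector of atom counts (names are element symbols)
#' @param source free-text provenance, usually the formula that was parsed
#' @return a [MolecularComposition-class]
#' @examples
#' molecularComposition(c(H = 2, O = 1))
#' @export
molecularComposition <- function(elements, source = NA_character_) {
  el <- elements
  if (any(abs(el - round(el)) > 0)) stop("atom counts must be whole numbers")
  el <- stats::setNames(as.integer(round(el)), names(elements))
  unknown <- setdiff(names(el), .elementSymbols)
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  new("MolecularComposition", elements = el, source = as.character(source))
}

#' Parse a molecular formula
#'
#' Accepts a sequence of element-symbol/count tokens with optional
#' multi-digit counts (default 1) and one level of parenthesised groups,
#' e.g. `"C18H12Cl2N2O"` or `"CH3(CH2)2OH"`. Whitespace is ignored; repeated
#' element tokens are summed. Isotope brackets, charges and hydrate dots are
#' rejected explicitly.
#'
#' @param formula formula text
#' @return a [MolecularComposition-class]
#' @examples
#' parseFormula("C18H12Cl2N2O")
#' parseFormula("CH3(CH2)2OH")
#' @export
parseFormula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || is.na(formula))
    stop("formula must be a single character string")
  txt <- gsub("[[:space:]]+", "", formula)
  if (!nzchar(txt)) stop("formula is empty")
  if (grepl("[·.*]", txt))
    stop("hydrate/adduct separators are not supported in formula '", formula, "'")
  if (grepl("[][+-]", txt))
    stop("isotope brackets and charges are not supported in formula '", formula, "'")

  counts <- integer(0)
  add <- function(sym, n) {
    if (sym %in% names(counts)) counts[[sym]] <<- counts[[sym]] + n
    else counts[[sym]] <<- n
  }
  i <- 1L; nc <- nchar(txt)
  group <- NULL  # named integer vector while inside parentheses
  while (i <= nc) {
    ch <- substr(txt, i, i)
    if (ch == "(") {
      if (!is.null(group))
        stop("nested parentheses at position ", i, " in formula '", formula, "'")
      group <- integer(0)
      i <- i + 1L
    } else if (ch == ")") {
      if (is.null(group))
        stop("unbalanced ')' at position ", i, " in formula '", formula, "'")
      if (length(group) == 0L)
        stop("empty group at position ", i, " in formula '", formula, "'")
      i <- i + 1L
      mult <- 1L
      m <- regmatches(substr(txt, i, nc), regexpr("^[0-9]+", substr(txt, i, nc)))
      if (length(m)) {
        mult <- suppressWarnings(as.integer(m))
        if (is.na(mult) || mult < 1L)
          stop("malformed group count at position ", i, " in formula '", formula, "'")
        i <- i + nchar(m)
      }
      for (sym in names(group)) add(sym, group[[sym]] * mult)
      group <- NULL
    } else if (grepl("^[A-Z]", ch)) {
      tok <- regmatches(substr(txt, i, nc), regexpr("^[A-Z][a-z]*", substr(txt, i, nc)))
      if (!tok %in% .elementSymbols)
        stop("unknown element '", tok, "' at position ", i, " in formula '", formula, "'")
      i <- i + nchar(tok)
      n <- 1L
      m <- regmatches(substr(txt, i, nc), regexpr("^[0-9]+", substr(txt, i, nc)))
      if (length(m)) {
        n <- suppressWarnings(as.integer(m))
        if (is.na(n) || n < 1L)
          stop("malformed count after '", tok, "' at position ", i,
               " in formula '", formula, "'")
        i <- i + nchar(m)
      }
      if (is.null(group)) add(tok, n) else {
        if (tok %in% names(group)) group[[tok]] <- group[[tok]] + n
        else group[[tok]] <- n
      }
    } else {
      stop("unexpected character '", ch, "' at position ", i,
           " in formula '", formula, "'")
    }
  }
  if (!is.null(group))
    stop("unbalanced '(' in formula '", formula, "'")
  if (length(counts) == 0L) stop("formula '", formula, "' contains no elements")
  molecularComposition(counts, source = formula)
}

#' @describeIn canonicalFormula Hill string of a composition
#' @export
setMethod("canonicalFormula", "MolecularComposition", function(x) {
  el <- x@elements
  syms <- names(el)
  if ("C" %in% syms) {
    rest <- sort(setdiff(syms, c("C", "H")))
    ord <- c("C", intersect("H", syms), rest)
  } else {
    ord <- sort(syms)
  }
  paste0(vapply(ord, function(s)
    paste0(s, if (el[[s]] > 1L) el[[s]] else ""), character(1)), collapse = "")
})

#' @describeIn canonicalFormula parse then canonicalise a formula string
#' @export
setMethod("canonicalFormula", "character", function(x) canonicalFormula(parseFormula(x)))

#' @describeIn nAtoms atom count of a composition
#' @export
setMethod("nAtoms", "MolecularComposition", function(x) sum(x@elements))

#' @describeIn nAtoms atom count of a formula string
#' @export
setMethod("nAtoms", "character", function(x) nAtoms(parseFormula(x)))

#' Composition from a structure line notation (SMILES)
#'
#' Derives the molecular formula, including implicit hydrogens, from a
#' SMILES string. Requires the optional ChemmineOB backend; when it is not
#' installed, a capability error directs the user to supply a molecular
#' formula instead.
#'
#' @param lineNotation a single SMILES string
#' @return a [MolecularComposition-class]
#' @export
compositionFromStructure <- function(lineNotation) {
  if (!is.character(lineNotation) || length(lineNotation) != 1L ||
      is.na(lineNotation) || !nzchar(lineNotation))
    stop("lineNotation must be a single non-empty SMILES string")
  if (!requireNamespace("ChemmineOB", quietly = TRUE))
    stop("structure input requires the ChemmineOB package; ",
         "install it or supply a molecular formula instead")
  props <- tryCatch(
    ChemmineOB::prop_OB(ChemmineOB::forEachMol("SMILES", lineNotation, identity)),
    error = function(e) stop("invalid structure notation '", lineNotation,
                             "': ", conditionMessage(e), call. = FALSE))
  formula <- as.character(props$formula)
  if (is.null(formula) || !nzchar(formula))
    stop("could not derive a formula from structure notation '", lineNotation, "'")
  comp <- parseFormula(formula)
  comp@source <- lineNotation
  comp
}

#' Standard average atomic masses
#'
#' Current IUPAC standard atomic weights (conventional values, Da) for the
#' elements common in organic and agrochemical structures.
#'
#' @return an [AtomicMassTable-class]
#' @export
defaultAtomicMasses <- function() {
  new("AtomicMassTable", masses = c(
    H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
    Na = 22.990, Mg = 24.305, Si = 28.085, P = 30.974, S = 32.06,
    Cl = 35.45, K = 39.098, Ca = 40.078, Fe = 55.845, Zn = 65.38,
    Se = 78.971, Br = 79.904, I = 126.904))
}

#' @describeIn molecularWeight weight of a parsed composition
#' @export
setMethod("molecularWeight", "MolecularComposition", function(x, masses = defaultAtomicMasses()) {
  stopifnot(is(masses, "AtomicMassTable"))
  miss <- setdiff(names(x@elements), names(masses@masses))
  if (length(miss))
    stop("no atomic mass for element(s): ", paste(miss, collapse = ", "))
  sum(x@elements * masses@masses[names(x@elements)])
})

#' @describeIn molecularWeight weight of a formula string
#' @export
setMethod("molecularWeight", "character", function(x, masses = defaultAtomicMasses()) {
  molecularWeight(parseFormula(x), masses)
})

setMethod("show", "MolecularComposition", function(object) {
  cat("MolecularComposition:", canonicalFormula(object),
      sprintf("(%d atoms, %d elements)\n", sum(object@elements),
              length(object@elements)))
  if (!is.na(object@source) && !identical(object@source, canonicalFormula(object)))
    cat("  source:", object@source, "\n")
})
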