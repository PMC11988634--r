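#' Average quasi-valence number (AQVN)
#'
#' The atom-count-weighted mean of valence numbers over all atoms of a
#' molecule, \eqn{Z^* = (1/N) \sum_i n_i Z_i}. Defined for a parsed
#' [MolecularComposition-class] or directly for a formula string.
#'
#' @param x a MolecularComposition or a molecular formula string
#' @param valences a [ValenceTable-class]; defaults to [defaultValenceTable()]
#' @return the AQVN as a plain number (conventionally labelled Ry)
#' @examples
#' aqvn("C18H12Cl2N2O")   # 2.9143
#' @export
setGeneric("aqvn", function(x, valences = defaultValenceTable()) standardGeneric("aqvn"))

#' Sum of valence numbers over all atoms
#'
#' @param x a MolecularComposition or formula string
#' @param valences a [ValenceTable-class]
#' @return integer-valued sum \eqn{\sum_i n_i Z_i}
#' @export
setGeneric("quasiValenceSum",
           function(x, valences = defaultValenceTable()) standardGeneric("quasiValenceSum"))

#' Full AQVN/EIIP descriptor set for one compound
#'
#' @param x a MolecularComposition or formula string
#' @param valences a [ValenceTable-class]
#' @param id identifier carried into the result
#' @return a [DescriptorResult-class]
#' @export
setGeneric("describeCompound",
           function(x, valences = defaultValenceTable(), id = NA_character_)
             standardGeneric("describeCompound"))

#' Molecular weight from a composition
#'
#' @param x a MolecularComposition or formula string
#' @param masses an [AtomicMassTable-class]; defaults to [defaultAtomicMasses()]
#' @return average molecular weight in Da
#' @export
setGeneric("molecularWeight",
           function(x, masses = defaultAtomicMasses()) standardGeneric("molecularWeight"))

#' Total atom count of a composition
#' @param x a MolecularComposition or formula string
#' @return integer atom count N
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' Canonical Hill-notation formula string
#'
#' Carbon first, then hydrogen, then the remaining elements alphabetically;
#' when no carbon is present, all elements are ordered alphabetically.
#'
#' @param x a MolecularComposition or formula string
#' @return a single formula string
#' @export
setGeneric("canonicalFormula", function(x) standardGeneric("canonicalFormula"))

#' Initial reaction rate of a progress curve
#'
#' Ordinary least-squares slope of absorbance versus time over a window at
#' the start of the trace, reported in AU/min.
#'
#' @param curve a [ProgressCurve-class]
#' @param window length of the fitting window in seconds, measured from the
#'   first time point; NULL uses the whole trace
#' @return rate in AU/min (negative rates are allowed, with a warning)
#' @export
setGeneric("initialRate", function(curve, window = NULL) standardGeneric("initialRate"))

#' Blank-correct a plate
#'
#' Subtracts the point-wise mean absorbance trace of the blank wells from
#' every well on the plate. Applying the correction twice changes nothing.
#'
#' @param plate a [PlateAssay-class]
#' @return the corrected [PlateAssay-class]
#' @export
setGeneric("blankCorrect", function(plate) standardGeneric("blankCorrect"))

#' Analyze an inhibition plate end to end
#'
#' Blank-corrects initial rates, averages technical replicates, computes
#' percent inhibition against the uninhibited (negative-control) rate, and
#' fits the IC50 -- or reports a censored "IC50 > c_max" outcome when the
#' top tested concentration does not reach 50 percent inhibition.
#'
#' @param plate a [PlateAssay-class] with blank and negative-control wells
#' @param window initial-rate window in seconds (NULL = whole trace)
#' @param ... further arguments passed to [fitIC50()]
#' @return an [InhibitionResult-class]
#' @export
setGeneric("analyzePlate", function(plate, window = NULL, ...) standardGeneric("analyzePlate"))

#' Accessors for fitted inhibition results
#'
#' @param object an [InhibitionResult-class]
#' @return `ic50()`/`ic50SE()` the fitted IC50 and its standard error (uM),
#'   `hillSlope()` the Hill slope, `isCensored()` whether the result is a
#'   censored "IC50 > c_max" outcome, `inhibitionTable()` the
#'   per-concentration percent-inhibition table.
#' @name inhibition-accessors
NULL

#' @rdname inhibition-accessors
#' @export
setGeneric("ic50", function(object) standardGeneric("ic50"))
#' @rdname inhibition-accessors
#' @export
setGeneric("ic50SE", function(object) standardGeneric("ic50SE"))
#' @rdname inhibition-accessors
#' @export
setGeneric("hillSlope", function(object) standardGeneric("hillSlope"))
#' @rdname inhibition-accessors
#' @export
setGeneric("isCensored", function(object) standardGeneric("isCensored"))
#' @rdname inhibition-accessors
#' @export
setGeneric("inhibitionTable", function(object) standardGeneric("inhibitionTable"))

#' Accessors for plate assays
#'
#' @param object a [PlateAssay-class]
#' @return `curves()` the list of [ProgressCurve-class] objects, `wells()`
#'   the well identifiers, `conditions()` the [AssayConditions-class].
#' @name plate-accessors
NULL

#' @rdname plate-accessors
#' @export
setGeneric("curves", function(object) standardGeneric("curves"))
#' @rdname plate-accessors
#' @export
setGeneric("wells", function(object) standardGeneric("wells"))
#' @rdname plate-accessors
#' @export
setGeneric("conditions", function(object) standardGeneric("conditions"))
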