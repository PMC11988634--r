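#' @import methods
NULL

#' MolecularComposition: element-count multiset of one compound
#'
#' Holds the parsed elemental composition of a single molecule: a named
#' integer vector mapping IUPAC element symbols (case-sensitive) to atom
#' counts, plus the free text it was parsed from. This is the substrate of
#' the AQVN calculation: the counts are the \eqn{n_i}, the number of distinct
#' elements is \eqn{m}, and their sum is the total atom count \eqn{N}.
#'
#' @slot elements named integer vector; names are element symbols, values
#'   are counts (all >= 1, no duplicate names)
#' @slot source the input text the composition was derived from
#'
#' @seealso [parseFormula()], [describeCompound()]
#' @export
setClass("MolecularComposition",
  representation(elements = "integer", source = "character"),
  validity = function(object) {
    el <- object@elements
    if (length(el) < 1L) return("composition must contain at least one element")
    if (is.null(names(el)) || any(!nzchar(names(el))))
      return("all element counts must be named")
    if (anyDuplicated(names(el))) return("duplicate element symbols")
    if (any(is.na(el)) || any(el < 1L)) return("all counts must be >= 1")
    TRUE
  }
)

#' ValenceTable: element-to-valence-number map
#'
#' The \eqn{Z_i} convention used by the AQVN. The default table (see
#' [defaultValenceTable()]) assigns H:1, C:4, N:5, O:6, S:6, P:5 and 1 to
#' every halogen; users may supply their own table to explore other
#' conventions.
#'
#' @slot valences named numeric vector of positive valence numbers
#' @slot provenance a short label identifying the convention in use
#' @export
setClass("ValenceTable",
  representation(valences = "numeric", provenance = "character"),
  validity = function(object) {
    v <- object@valences
    if (length(v) < 1L) return("valence table is empty")
    if (is.null(names(v)) || any(!nzchar(names(v)))) return("valences must be named")
    if (anyDuplicated(names(v))) return("duplicate element symbols in valence table")
    if (any(!is.finite(v)) || any(v <= 0)) return("valence numbers must be positive")
    TRUE
  }
)

#' AtomicMassTable: element-to-average-atomic-mass map (Da)
#'
#' @slot masses named numeric vector of standard average atomic masses in Da
#' @export
setClass("AtomicMassTable",
  representation(masses = "numeric"),
  validity = function(object) {
    m <- object@masses
    if (is.null(names(m)) || anyDuplicated(names(m))) return("masses must have unique names")
    if (any(!is.finite(m)) || any(m <= 0)) return("all masses must be positive")
    req <- c("H", "C", "N", "O", "S", "P", "F", "Cl", "Br", "I")
    miss <- setdiff(req, names(m))
    if (length(miss))
      return(paste("mass table must cover at least H,C,N,O,S,P,F,Cl,Br,I; missing:",
                   paste(miss, collapse = ", ")))
    TRUE
  }
)

#' DescriptorResult: AQVN/EIIP descriptors for one compound
#'
#' @slot id compound identifier
#' @slot formula canonical Hill-notation formula
#' @slot aqvn average quasi-valence number (labelled Ry by convention)
#' @slot eiipSigned signed EIIP in Ry
#' @slot eiipAbs absolute EIIP in Ry
#' @slot nAtoms total atom count N
#' @slot quasiValenceSum the integer sum over atoms of valence numbers
#' @export
setClass("DescriptorResult",
  representation(id = "character", formula = "character", aqvn = "numeric",
                 eiipSigned = "numeric", eiipAbs = "numeric",
                 nAtoms = "integer", quasiValenceSum = "numeric"),
  validity = function(object) {
    if (!isTRUE(all.equal(object@eiipAbs, abs(object@eiipSigned))))
      return("eiipAbs must equal |eiipSigned|")
    if (object@nAtoms < 1L) return("nAtoms must be >= 1")
    if (abs(object@aqvn - object@quasiValenceSum / object@nAtoms) > 1e-12)
      return("aqvn must equal quasiValenceSum / nAtoms")
    TRUE
  }
)

#' AssayConditions: in-well conditions of the Ellman microplate protocol
#'
#' All concentrations are final in-well values. Defaults reproduce a common
#' 200 uL microplate geometry: 50 uL inhibitor dilution + 100 uL substrate/
#' chromogen mix (1 mM acetylthiocholine, 0.5 mM DTNB stocks) + 50 uL enzyme
#' (0.0075 U/mL stock), read at 405 nm at 25 C for 5 min.
#'
#' @slot substrateConc final acetylthiocholine concentration, mM
#' @slot chromogenConc final DTNB concentration, mM
#' @slot enzymeActivity final enzyme activity, U/mL (1 U = 1 umol/min)
#' @slot finalVolume final well volume, uL
#' @slot pathLength optical path length through the well, cm
#' @slot extinctionCoef TNB molar extinction coefficient at 405 nm, 1/(M cm)
#' @slot Km Michaelis constant for the substrate, mM
#' @slot duration kinetic read duration, s
#' @slot readInterval interval between reads, s
#' @export
setClass("AssayConditions",
  representation(substrateConc = "numeric", chromogenConc = "numeric",
                 enzymeActivity = "numeric", finalVolume = "numeric",
                 pathLength = "numeric", extinctionCoef = "numeric",
                 Km = "numeric", duration = "numeric", readInterval = "numeric"),
  validity = function(object) {
    vals <- c(object@substrateConc, object@chromogenConc, object@enzymeActivity,
              object@finalVolume, object@pathLength, object@extinctionCoef,
              object@Km, object@duration, object@readInterval)
    if (any(!is.finite(vals)) || any(vals <= 0))
      return("all assay condition values must be positive and finite")
    if (object@readInterval >= object@duration)
      return("readInterval must be smaller than duration")
    TRUE
  }
)

.curveRoles <- c("test", "blank", "positive-control", "negative-control")

#' ProgressCurve: one well's kinetic absorbance trace
#'
#' @slot well well identifier
#' @slot role one of "test", "blank", "positive-control", "negative-control"
#' @slot conc final in-well inhibitor concentration, uM
#' @slot times seconds from reaction start, strictly increasing, >= 0
#' @slot absorbance absorbance (AU) at 405 nm, one value per time point
#' @export
setClass("ProgressCurve",
  representation(well = "character", role = "character", conc = "numeric",
                 times = "numeric", absorbance = "numeric"),
  validity = function(object) {
    if (!object@role %in% .curveRoles)
      return(paste("role must be one of:", paste(.curveRoles, collapse = ", ")))
    if (length(object@times) < 3L) return("a progress curve needs >= 3 time points")
    if (length(object@times) != length(object@absorbance))
      return("times and absorbance must have equal length")
    if (any(object@times < 0) || any(diff(object@times) <= 0))
      return("times must be non-negative and strictly increasing")
    if (any(!is.finite(object@absorbance))) return("absorbance must be finite")
    if (length(object@conc) != 1L || is.na(object@conc) || object@conc < 0)
      return("conc must be a single non-negative value (uM)")
    TRUE
  }
)

#' PlateAssay: a set of progress curves with shared assay conditions
#'
#' @slot curves list of [ProgressCurve-class] objects
#' @slot conditions the [AssayConditions-class] the plate was run under
#' @slot corrected has the plate already been blank-corrected?
#' @slot truth for simulated plates, a list of ground-truth parameters
#'   (ki_uM, ic50_uM, mode, noise_sd_AU, seed); empty for real data
#' @export
setClass("PlateAssay",
  representation(curves = "list", conditions = "AssayConditions",
                 corrected = "logical", truth = "list"),
  validity = function(object) {
    if (!all(vapply(object@curves, is, logical(1), class2 = "ProgressCurve")))
      return("curves must all be ProgressCurve objects")
    wells <- vapply(object@curves, function(x) x@well, character(1))
    if (anyDuplicated(wells)) return("duplicate well identifiers")
    if (length(object@corrected) != 1L || is.na(object@corrected))
      return("corrected must be TRUE or FALSE")
    TRUE
  }
)

#' SimulationSpec: ground-truth parameters for a simulated inhibition plate
#'
#' Exactly one of the true IC50 or the true Ki must be given; the other is
#' derived through the Cheng-Prusoff relation appropriate for the chosen
#' inhibition mode.
#'
#' @slot ic50 true IC50, uM (NA if ki given)
#' @slot ki true inhibition constant, uM (NA if ic50 given)
#' @slot mode "competitive" or "noncompetitive"
#' @slot concentrations inhibitor concentration series, uM (non-negative)
#' @slot replicates technical replicates per concentration
#' @slot noiseSD additive Gaussian absorbance noise per read, AU
#' @slot seed integer seed; a fixed seed gives byte-identical plates
#' @slot baseline absorbance offset A0 common to all wells, AU
#' @slot conditions the [AssayConditions-class] to simulate under
#' @export
setClass("SimulationSpec",
  representation(ic50 = "numeric", ki = "numeric", mode = "character",
                 concentrations = "numeric", replicates = "integer",
                 noiseSD = "numeric", seed = "integer", baseline = "numeric",
                 conditions = "AssayConditions"),
  validity = function(object) {
    if (!object@mode %in% c("competitive", "noncompetitive"))
      return("mode must be 'competitive' or 'noncompetitive'")
    given <- c(ic50 = is.finite(object@ic50), ki = is.finite(object@ki))
    if (sum(given) != 1L) return("give exactly one of ic50 or ki (uM)")
    if (given["ic50"] && object@ic50 <= 0) return("ic50 must be positive")
    if (given["ki"] && object@ki <= 0) return("ki must be positive")
    if (length(object@concentrations) < 1L || any(object@concentrations < 0))
      return("concentrations must be non-negative (uM)")
    if (object@replicates < 1L) return("replicates must be >= 1")
    if (object@noiseSD < 0) return("noiseSD must be >= 0")
    TRUE
  }
)

#' InhibitionResult: percent-inhibition series and IC50 fit for one plate
#'
#' @slot inhibition data.frame with columns conc_uM, inhibition_pct, sd_pct, n
#' @slot ic50 fitted IC50, uM (NA when censored or not converged)
#' @slot ic50SE standard error of the IC50 from the fit covariance, uM
#' @slot hill fitted Hill slope
#' @slot residuals fit residuals (percent-inhibition scale)
#' @slot converged did the nonlinear fit converge?
#' @slot censored NA, or "gt:<c_max>" when the top tested concentration did
#'   not reach 50 percent inhibition (the "no activity" outcome)
#' @slot ki optional inhibition constant, uM; never computed here, carried
#'   only if supplied externally
#' @export
setClass("InhibitionResult",
  representation(inhibition = "data.frame", ic50 = "numeric", ic50SE = "numeric",
                 hill = "numeric", residuals = "numeric", converged = "logical",
                 censored = "character", ki = "numeric"),
  validity = function(object) {
    need <- c("conc_uM", "inhibition_pct")
    if (!all(need %in% names(object@inhibition)))
      return("inhibition table must have columns conc_uM and inhibition_pct")
    if (isTRUE(object@converged) && is.na(object@censored) &&
        (!is.finite(object@ic50) || object@ic50 <= 0))
      return("a converged, uncensored fit must carry a positive IC50")
    TRUE
  }
)
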