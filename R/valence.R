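#' Construct a ValenceTable
#'
#' @param valences named vector of positive valence numbers
#' @param provenance short label for the convention
#' @return a [ValenceTable-class]
#' @export
valenceTable <- function(valences, provenance = "user") {
  unknown <- setdiff(names(valences), .elementSymbols)
  if (length(unknown))
    stop("unknown element symbol(s) in valence table: ",
         paste(unknown, collapse = ", "))
  new("ValenceTable", valences = stats::setNames(as.numeric(valences), names(valences)),
      provenance = provenance)
}

#' The default EIIP valence-number convention
#'
#' The fixed, versioned table used by the AQVN/EIIP descriptor: H 1, C 4,
#' N 5, O 6, S 6, P 5 and 1 for each halogen (F, Cl, Br, I). Note the
#' halogen assignment: this convention counts the single bonding valence,
#' not the seven outer-shell electrons; it is the assignment under which
#' published AQVN values for halogenated pesticides reproduce. Supply a
#' custom [valenceTable()] to use a different convention.
#'
#' @return a [ValenceTable-class]
#' @examples
#' defaultValenceTable()
#' @export
defaultValenceTable <- function() {
  valenceTable(
    c(H = 1, C = 4, N = 5, O = 6, S = 6, P = 5, F = 1, Cl = 1, Br = 1, I = 1),
    provenance = "eiip-default-v1")
}

#' Read a valence table from a two-column CSV
#'
#' The file must have header columns `element,valence`; rows are validated
#' on load (known element symbols, positive numeric valences, no duplicates).
#'
#' @param path CSV file path
#' @return a [ValenceTable-class]
#' @export
readValenceTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("element", "valence") %in% names(df)))
    stop("valence table must have columns 'element' and 'valence'")
  if (anyDuplicated(df$element))
    stop("duplicate element in valence table: ",
         paste(unique(df$element[duplicated(df$element)]), collapse = ", "))
  v <- suppressWarnings(as.numeric(df$valence))
  if (any(is.na(v))) stop("non-numeric valence value(s) in ", path)
  valenceTable(stats::setNames(v, df$element), provenance = basename(path))
}

setMethod("show", "ValenceTable", function(object) {
  cat("ValenceTable [", object@provenance, "]\n", sep = "")
  print(object@valences)
})
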