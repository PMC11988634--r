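.lookupValences <- function(comp, valences) {
  stopifnot(is(valences, "ValenceTable"))
  miss <- setdiff(names(comp@elements), names(valences@valences))
  if (length(miss))
    stop("no valence number for element(s): ", paste(miss, collapse = ", "),
         " (table: ", valences@provenance, ")")
  valences@valences[names(comp@elements)]
}

#' @describeIn quasiValenceSum sum over a parsed composition
#' @export
setMethod("quasiValenceSum", "MolecularComposition", function(x, valences = defaultValenceTable()) {
  sum(x@elements * .lookupValences(x, valences))
})

#' @describeIn quasiValenceSum sum over a formula string
#' @export
setMethod("quasiValenceSum", "character", function(x, valences = defaultValenceTable()) {
  quasiValenceSum(parseFormula(x), valences)
})

#' @describeIn aqvn AQVN of a parsed composition
#' @export
setMethod("aqvn", "MolecularComposition", function(x, valences = defaultValenceTable()) {
  quasiValenceSum(x, valences) / sum(x@elements)
})

#' @describeIn aqvn AQVN of a formula string
#' @export
setMethod("aqvn", "character", function(x, valences = defaultValenceTable()) {
  aqvn(parseFormula(x), valences)
})

#' Electron-ion interaction potential (EIIP)
#'
#' Evaluates \eqn{EIIP = 0.25 (Z^*/2\pi) \sin(1.04 \pi Z^*)} (Ry), with the
#' sine argument in radians, at an average quasi-valence number \eqn{Z^*}.
#' The value is signed; descriptors conventionally report its absolute
#' value, which [describeCompound()] exposes alongside.
#'
#' @param zStar AQVN value(s), must be positive
#' @return signed EIIP in Ry, same length as `zStar`
#' @examples
#' eiip(aqvn("C48H72O14"))   # 0.0834
#' @export
eiip <- function(zStar) {
  if (!is.numeric(zStar) || any(!is.finite(zStar)))
    stop("zStar must be finite numeric")
  if (any(zStar <= 0)) stop("zStar must be positive")
  0.25 * (zStar / (2 * pi)) * sin(1.04 * pi * zStar)
}

#' @describeIn describeCompound descriptors of a parsed composition
#' @export
setMethod("describeCompound", "MolecularComposition",
  function(x, valences = defaultValenceTable(), id = NA_character_) {
    qvs <- quasiValenceSum(x, valences)
    n <- sum(x@elements)
    z <- qvs / n
    e <- eiip(z)
    new("DescriptorResult", id = as.character(id), formula = canonicalFormula(x),
        aqvn = z, eiipSigned = e, eiipAbs = abs(e),
        nAtoms = as.integer(n), quasiValenceSum = as.numeric(qvs))
  })

#' @describeIn describeCompound descriptors of a formula string
#' @export
setMethod("describeCompound", "character",
  function(x, valences = defaultValenceTable(), id = NA_character_) {
    describeCompound(parseFormula(x), valences, id = id)
  })

setMethod("show", "DescriptorResult", function(object) {
  cat("DescriptorResult",
      if (!is.na(object@id)) paste0("for ", object@id) else "", "\n")
  cat("  formula:           ", object@formula, "\n")
  cat("  atoms (N):         ", object@nAtoms, "\n")
  cat("  sum n_i Z_i:       ", format(object@quasiValenceSum), "\n")
  cat(sprintf("  AQVN:               %.4f Ry\n", object@aqvn))
  cat(sprintf("  EIIP (signed):      %.4f Ry\n", object@eiipSigned))
  cat(sprintf("  EIIP (absolute):    %.4f Ry\n", object@eiipAbs))
})

#' Compute descriptors for a whole compound table
#'
#' Takes a compound table as returned by [readCompoundTable()] (columns
#' `id`, `formula` and/or `smiles`) and computes one descriptor row per
#' input row, preserving input order. Rows that fail to parse are collected
#' in the `errors` attribute of the result -- never silently dropped -- and
#' reported with a warning.
#'
#' @param table data.frame with columns `id` and `formula` (or `smiles`)
#' @param valences a [ValenceTable-class]
#' @return data.frame with columns id, formula, n_atoms, quasi_valence_sum,
#'   aqvn, eiip_signed, eiip_abs; failed rows in `attr(result, "errors")`
#'   (a data.frame with columns row, id, message)
#' @export
batchDescribe <- function(table, valences = defaultValenceTable()) {
  stopifnot(is.data.frame(table))
  empty <- data.frame(id = character(), formula = character(),
                      n_atoms = integer(), quasi_valence_sum = numeric(),
                      aqvn = numeric(), eiip_signed = numeric(),
                      eiip_abs = numeric(), stringsAsFactors = FALSE)
  errs <- data.frame(row = integer(), id = character(), message = character(),
                     stringsAsFactors = FALSE)
  if (nrow(table) == 0L) {
    warning("empty compound table; returning empty descriptor table")
    attr(empty, "errors") <- errs
    return(empty)
  }
  if (!"id" %in% names(table)) stop("compound table must have an 'id' column")
  if (!any(c("formula", "smiles") %in% names(table)))
    stop("compound table must have a 'formula' or 'smiles' column")
  rows <- vector("list", nrow(table))
  for (i in seq_len(nrow(table))) {
    res <- tryCatch({
      comp <- if ("formula" %in% names(table) && !is.na(table$formula[i]) &&
                  nzchar(table$formula[i]))
        parseFormula(table$formula[i])
      else if ("smiles" %in% names(table) && !is.na(table$smiles[i]) &&
               nzchar(table$smiles[i]))
        compositionFromStructure(table$smiles[i])
      else stop("row has neither formula nor smiles")
      d <- describeCompound(comp, valences, id = table$id[i])
      data.frame(id = d@id, formula = d@formula, n_atoms = d@nAtoms,
                 quasi_valence_sum = d@quasiValenceSum, aqvn = d@aqvn,
                 eiip_signed = d@eiipSigned, eiip_abs = d@eiipAbs,
                 stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errs <- rbind(errs, data.frame(row = i, id = as.character(table$id[i]),
                                     message = conditionMessage(res),
                                     stringsAsFactors = FALSE))
    } else rows[[i]] <- res
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- empty
  rownames(out) <- NULL
  if (nrow(errs))
    warning(nrow(errs), " row(s) failed to parse; see attr(result, 'errors')")
  attr(out, "errors") <- errs
  out
}

#' Rank compounds by AQVN similarity to a reference
#'
#' Orders a descriptor table by the absolute AQVN difference to a reference
#' compound, ascending; ties are broken by id, lexicographically. Compounds
#' with near-identical AQVN are expected to show similar long-range
#' recognition behaviour, which motivates this screen.
#'
#' @param descriptors data.frame from [batchDescribe()] (needs id, aqvn)
#' @param referenceId id of the reference compound, must be present
#' @return data.frame with columns id, aqvn, delta_aqvn, ordered by
#'   ascending delta_aqvn; the reference id is kept in
#'   `attr(result, "reference")`
#' @export
rankByAqvn <- function(descriptors, referenceId) {
  stopifnot(is.data.frame(descriptors), all(c("id", "aqvn") %in% names(descriptors)))
  ref <- which(descriptors$id == referenceId)
  if (length(ref) != 1L)
    stop("reference id '", referenceId, "' not found exactly once in table")
  delta <- abs(descriptors$aqvn - descriptors$aqvn[ref])
  ord <- order(delta, descriptors$id, method = "radix")
  out <- data.frame(id = descriptors$id[ord], aqvn = descriptors$aqvn[ord],
                    delta_aqvn = delta[ord], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "reference") <- referenceId
  out
}
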