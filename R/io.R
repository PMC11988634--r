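.detectSep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a compound table (CSV or TSV)
#'
#' The file must have an `id` column and at least one of `formula` /
#' `smiles`; extra columns are preserved. The delimiter (comma or tab) is
#' auto-detected from the header line. Row numbers are retained in the
#' `row` column of error messages.
#'
#' @param path CSV/TSV file path
#' @return data.frame with at least columns id and formula (or smiles)
#' @export
readCompoundTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, sep = .detectSep(path), header = TRUE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "", check.names = TRUE)
  if (!"id" %in% names(df))
    stop("compound table must have columns: id and formula (or smiles); ",
         "found: ", paste(names(df), collapse = ", "))
  if (!any(c("formula", "smiles") %in% names(df)))
    stop("compound table must have a 'formula' or 'smiles' column; found: ",
         paste(names(df), collapse = ", "))
  dup <- unique(df$id[duplicated(df$id)])
  if (length(dup)) {
    rows <- which(df$id %in% dup)
    stop("duplicate compound id(s): ", paste(dup, collapse = ", "),
         " (rows ", paste(rows, collapse = ", "), ")")
  }
  ok <- rep(FALSE, nrow(df))
  if ("formula" %in% names(df)) ok <- ok | (!is.na(df$formula) & nzchar(df$formula))
  if ("smiles" %in% names(df)) ok <- ok | (!is.na(df$smiles) & nzchar(df$smiles))
  if (any(!ok))
    stop("row(s) ", paste(which(!ok), collapse = ", "),
         " have neither a formula nor a structure")
  df
}

#' Write a result table as CSV or JSON
#'
#' CSV output rounds the descriptor columns (aqvn, eiip_signed, eiip_abs,
#' delta_aqvn) to 4 decimals; JSON keeps full double precision. Both
#' serialisations carry identical columns.
#'
#' @param rows data.frame of results
#' @param path output file path, or "" for stdout
#' @param format "csv" or "json"
#' @return invisibly, the data.frame as written
#' @export
writeResults <- function(rows, path, format = c("csv", "json")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(rows))
  if (format == "csv") {
    out <- rows
    for (col in intersect(c("aqvn", "eiip_signed", "eiip_abs", "delta_aqvn"),
                          names(out)))
      out[[col]] <- round(out[[col]], 4)
    ok <- tryCatch({
      utils::write.csv(out, file = if (nzchar(path)) path else stdout(),
                       row.names = FALSE)
      TRUE
    }, error = function(e) e)
  } else {
    out <- rows
    txt <- jsonlite::toJSON(out, dataframe = "rows", digits = NA, na = "null")
    ok <- tryCatch({
      if (nzchar(path)) writeLines(txt, path) else cat(txt, "\n")
      TRUE
    }, error = function(e) e)
  }
  if (inherits(ok, "error"))
    stop("cannot write results to '", path, "': ", conditionMessage(ok))
  invisible(out)
}

#' Write a plate assay as long-format CSV
#'
#' Columns: `well,role,conc_uM,time_s,abs405`. For simulated plates the
#' ground-truth parameters can be written to a sidecar JSON file.
#'
#' @param plate a [PlateAssay-class]
#' @param path output CSV path
#' @param truthPath optional path for the ground-truth sidecar JSON
#' @return invisibly, `path`
#' @export
writePlate <- function(plate, path, truthPath = NULL) {
  stopifnot(is(plate, "PlateAssay"))
  rows <- do.call(rbind, lapply(plate@curves, function(cv)
    data.frame(well = cv@well, role = cv@role, conc_uM = cv@conc,
               time_s = cv@times, abs405 = cv@absorbance,
               stringsAsFactors = FALSE)))
  utils::write.csv(rows, path, row.names = FALSE)
  if (!is.null(truthPath)) {
    if (!length(plate@truth)) stop("plate carries no ground truth to write")
    jsonlite::write_json(plate@truth, truthPath, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a plate assay from long-format CSV
#'
#' Expects the header `well,role,conc_uM,time_s,abs405` (comma or tab
#' delimited). Rows are grouped by well; within each well, readings are
#' sorted by time.
#'
#' @param path CSV file path
#' @param conditions the [AssayConditions-class] the plate was run under
#' @return a [PlateAssay-class]
#' @export
readPlate <- function(path, conditions = assayConditions()) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, sep = .detectSep(path), header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("well", "role", "conc_uM", "time_s", "abs405")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("plate file must have columns ", paste(need, collapse = ","),
         "; missing: ", paste(miss, collapse = ", "))
  curvesList <- lapply(split(df, df$well), function(d) {
    d <- d[order(d$time_s), ]
    progressCurve(d$well[1], d$time_s, d$abs405, conc = d$conc_uM[1],
                  role = d$role[1])
  })
  names(curvesList) <- NULL
  new("PlateAssay", curves = curvesList, conditions = conditions,
      corrected = FALSE, truth = list())
}

#' Read assay conditions from a YAML file
#'
#' Recognised keys match the arguments of [assayConditions()]; unknown keys
#' are rejected with a message listing them.
#'
#' @param path YAML file path
#' @return an [AssayConditions-class]
#' @export
readAssayConditions <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(assayConditions))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown assay-condition key(s): ", paste(unknown, collapse = ", "),
         "; recognised keys: ", paste(known, collapse = ", "))
  do.call(assayConditions, vals)
}

#' The bundled reference-compound fixture
#'
#' A four-compound table (boscalid, abamectin B1A, abamectin B1B,
#' chlorantraniliprole) with their molecular formulas, shipped with the
#' package for examples and tests.
#'
#' @return data.frame with columns id and formula
#' @examples
#' batchDescribe(referenceCompounds())
#' @export
referenceCompounds <- function() {
  readCompoundTable(system.file("extdata", "reference_compounds.csv",
                                package = "eiipScreen", mustWork = TRUE))
}
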