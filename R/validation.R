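# Pluggable post-hoc validation of annotated accessions.
#
# A validator is a function (db, normalized_accession) -> one of
# "valid", "invalid", "unknown". Two built-ins are provided: a syntactic
# pass-through (every pattern-conformant accession is valid) and a
# table-backed lookup against user-supplied per-database accession lists,
# which emulates checking annotations against the live databases without
# any network dependency.

#' Syntactic pass-through validator
#'
#' Declares every annotation valid; [validate_annotations()] with this
#' validator is the identity on the annotation set.
#'
#' @return A validator function.
#' @export
validator_passthrough <- function() {
  function(db, accession) rep("valid", length(accession))
}

#' Table-backed validator
#'
#' Looks annotations up in a table of known accessions: listed pairs are
#' `valid`, unlisted accessions of a listed database are `invalid`, and
#' databases absent from the table entirely are `unknown` (the table makes
#' no claim about them).
#'
#' @param table A data frame with columns `db` and `accession`, or a path
#'   to a two-column TSV with those columns.
#' @return A validator function.
#' @export
validator_table <- function(table) {
  if (is.character(table)) {
    table <- readr::read_tsv(table, col_types = readr::cols(.default = "c"),
                             progress = FALSE)
  }
  stopifnot(all(c("db", "accession") %in% names(table)))
  known_dbs <- unique(table$db)
  keys <- paste(table$db, toupper(table$accession), sep = "\t")
  function(db, accession) {
    status <- rep("unknown", length(accession))
    covered <- db %in% known_dbs
    hit <- paste(db, toupper(accession), sep = "\t") %in% keys
    status[covered & hit] <- "valid"
    status[covered & !hit] <- "invalid"
    status
  }
}

#' Validate annotations
#'
#' Sets each annotation's `validation_status` from the validator verdict;
#' an `unknown` verdict maps to `unvalidated`. When
#' `config$drop_invalid` is `TRUE` (the default), annotations marked
#' invalid are removed, so they never inflate downstream counts. A
#' validator that errors leaves every annotation `unvalidated` with a
#' warning — a run never fails on validation.
#'
#' @param annotations Annotation tibble.
#' @param validator A validator function, e.g. [validator_passthrough()]
#'   or [validator_table()].
#' @param config [annotation_config()].
#' @return The annotations with `validation_status` set (and invalid rows
#'   dropped when configured).
#' @export
validate_annotations <- function(annotations,
                                 validator = validator_passthrough(),
                                 config = annotation_config()) {
  if (nrow(annotations) == 0L) {
    return(annotations)
  }
  verdict <- tryCatch(
    validator(annotations$db, annotations$normalized_accession),
    error = function(e) {
      warning("validator unavailable (", conditionMessage(e),
              "); annotations left unvalidated", call. = FALSE)
      rep("unknown", nrow(annotations))
    }
  )
  stopifnot(length(verdict) == nrow(annotations))
  verdict[!verdict %in% c("valid", "invalid")] <- "unvalidated"
  verdict[verdict == "unknown"] <- "unvalidated"
  annotations$validation_status <- verdict
  if (config$drop_invalid) {
    annotations <- annotations[annotations$validation_status != "invalid", ,
                               drop = FALSE]
  }
  annotations
}
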