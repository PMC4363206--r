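#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data
#' @importFrom stats rpois runif setNames
#' @importFrom utils head
NULL

# The ten supported databases, in overlap-resolution priority order
# (most specific / least collision-prone prefix first). OMIM ("[0-9]{6}")
# and PDBe ("[0-9][A-Z0-9]{3}") are the most collision-prone and rank last.
DB_PRIORITY <- c(
  "Ensembl", "ArrayExpress", "InterPro", "Pfam", "RefSeq",
  "RefSNP", "UniProt", "ENA", "OMIM", "PDBe"
)

# Databases whose accession prefixes are commonly written lower-case in
# running text (e.g. "rs12345", "ipr000001"): matched case-insensitively.
# ENA, UniProt, PDBe and OMIM bodies stay case-sensitive upper-case to
# limit false positives in prose.
CASE_INSENSITIVE_DBS <- c(
  "RefSNP", "RefSeq", "Ensembl", "InterPro", "Pfam", "ArrayExpress"
)

registry_rows <- function() {
  list(
    list(
      db = "ENA",
      patterns = c(
        "[A-Z][0-9]{5}", "[A-Z]{2}[0-9]{6}", "[A-Z]{3}[0-9]{5}",
        "[A-Z]{4}[0-9]{8,10}", "[A-Z]{5}[0-9]{7}"
      ),
      cues = c("genbank", "gen", "ddbj", "embl")
    ),
    list(
      db = "UniProt",
      patterns = c(
        "[A-NR-Z][0-9][A-Z][A-Z0-9][A-Z0-9][0-9]",
        "[OPQ][0-9][A-Z0-9][A-Z0-9][A-Z0-9][0-9]"
      ),
      cues = c("swissprot", "sprot", "uniprot")
    ),
    list(
      db = "PDBe",
      patterns = "[0-9][A-Z0-9]{3}",
      cues = "pdb"
    ),
    list(
      db = "InterPro",
      patterns = "IPR[0-9]{6}",
      cues = "interpro"
    ),
    list(
      db = "Pfam",
      patterns = "PF(AM)?[0-9]{5}",
      cues = c("hmm", "family", "pfam")
    ),
    list(
      db = "ArrayExpress",
      patterns = "E-[A-Z]{4}-[0-9]+",
      cues = "arrayexpress"
    ),
    list(
      db = "OMIM",
      patterns = "[0-9]{6}",
      cues = "omim"
    ),
    list(
      db = "Ensembl",
      patterns = "ENS[A-Z]*G[0-9]{11}",
      cues = "ensembl"
    ),
    list(
      db = "RefSeq",
      patterns = paste0(
        "(AC|AP|NC|NG|NM|NP|NR|NT|NW|NZ|XM|XP|XR|YP|ZP|NS)",
        "_([A-Z]{4})*[0-9]{6,9}(?:[.][0-9]+)?"
      ),
      cues = "refseq"
    ),
    list(
      db = "RefSNP",
      patterns = "RS[0-9]{5,9}",
      cues = "snp"
    )
  )
}

#' Extraction-pattern registry for the ten supported databases
#'
#' Returns the registry of accession-number extraction patterns and
#' contextual cue words, one row per database: ENA, UniProt, PDBe, InterPro,
#' Pfam, ArrayExpress, OMIM, Ensembl, RefSeq and RefSNP. Patterns are
#' anchored regular expressions describing the full accession token; cues
#' are lower-case keywords whose nearby presence licenses a pattern match as
#' a genuine database citation.
#'
#' @param db_subset Optional character vector of database identifiers; the
#'   registry is restricted to these. Unknown identifiers are an error.
#' @return A tibble with columns `db` (identifier), `patterns` (list column
#'   of regular-expression strings), `cues` (list column of lower-case cue
#'   words), `cue_required` (logical), `case_insensitive` (logical) and
#'   `priority` (integer rank used for overlap tie-breaking; 1 = highest).
#'   Rows are ordered by `priority`.
#' @examples
#' db_registry()
#' db_registry("Pfam")$patterns[[1]]
#' @export
db_registry <- function(db_subset = NULL) {
  rows <- registry_rows()
  reg <- tibble::tibble(
    db = vapply(rows, `[[`, character(1), "db"),
    patterns = lapply(rows, `[[`, "patterns"),
    cues = lapply(rows, `[[`, "cues")
  )
  reg$cue_required <- TRUE
  reg$case_insensitive <- reg$db %in% CASE_INSENSITIVE_DBS
  reg$priority <- match(reg$db, DB_PRIORITY)
  reg <- reg[order(reg$priority), , drop = FALSE]
  if (!is.null(db_subset)) {
    unknown <- setdiff(db_subset, reg$db)
    if (length(unknown) > 0L) {
      stop("unknown database: ", paste(unknown, collapse = ", "), call. = FALSE)
    }
    reg <- reg[reg$db %in% db_subset, , drop = FALSE]
  }
  validate_registry(reg)
  reg
}

validate_registry <- function(registry) {
  stopifnot(
    is.data.frame(registry),
    all(c("db", "patterns", "cues", "cue_required", "case_insensitive",
          "priority") %in% names(registry)),
    !anyDuplicated(registry$db),
    all(lengths(registry$cues) > 0L)
  )
  for (i in seq_len(nrow(registry))) {
    for (p in registry$patterns[[i]]) {
      # compilation check: stringr raises on an invalid expression
      stringr::str_detect("", stringr::regex(p))
    }
  }
  invisible(registry)
}

db_entry <- function(registry, db_id) {
  i <- match(db_id, registry$db)
  if (is.na(i)) {
    stop("unknown database: ", db_id, call. = FALSE)
  }
  registry[i, , drop = FALSE]
}

# Anchor a registry pattern so it must cover an entire string.
whole_token_regex <- function(pattern, case_insensitive) {
  stringr::regex(paste0("\\A(?:", pattern, ")\\z"),
                 ignore_case = case_insensitive)
}

#' Whole-token syntactic conformance
#'
#' Tests whether an entire token matches at least one extraction pattern of
#' the given database, under the registry's per-database case policy
#' (case-insensitive for RefSNP, RefSeq, Ensembl, InterPro, Pfam and
#' ArrayExpress; upper-case only for ENA, UniProt, PDBe and OMIM).
#'
#' @param db_id Database identifier (one of `db_registry()$db`).
#' @param token Character vector of candidate tokens (whole strings, no
#'   surrounding text).
#' @param registry Registry tibble, by default [db_registry()].
#' @return Logical vector, one element per token.
#' @examples
#' acc_conforms("InterPro", "IPR000001")
#' acc_conforms("UniProt", c("P09372", "p09372"))
#' @export
acc_conforms <- function(db_id, token, registry = db_registry()) {
  entry <- db_entry(registry, db_id)
  hit <- rep(FALSE, length(token))
  for (p in entry$patterns[[1]]) {
    hit <- hit | stringr::str_detect(
      token, whole_token_regex(p, entry$case_insensitive)
    )
  }
  hit & !is.na(token)
}

#' Canonical form of an accession
#'
#' Upper-cases the surface string and, for RefSeq, strips the optional
#' version suffix (".<digits>"), since databases key on the versionless
#' accession.
#'
#' @param db_id Database identifier.
#' @param surface Matched accession string(s).
#' @return Character vector of normalized accessions.
#' @examples
#' normalize_accession("RefSeq", "NM_000546.5")
#' normalize_accession("RefSNP", "rs12345")
#' @export
normalize_accession <- function(db_id, surface) {
  out <- toupper(surface)
  if (db_id == "RefSeq") {
    out <- sub("[.][0-9]+$", "", out)
  }
  out
}

#' Write a registry to a YAML config file
#'
#' One record per database (id, patterns, cues, cue_required,
#' case_insensitive, priority), so cue lists can be amended without code
#' changes and read back with [read_registry()].
#'
#' @param registry Registry tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  validate_registry(registry)
  recs <- lapply(seq_len(nrow(registry)), function(i) {
    list(
      db = registry$db[i],
      patterns = as.list(registry$patterns[[i]]),
      cues = as.list(registry$cues[[i]]),
      cue_required = registry$cue_required[i],
      case_insensitive = registry$case_insensitive[i],
      priority = registry$priority[i]
    )
  })
  yaml::write_yaml(recs, path)
  invisible(path)
}

#' Read a registry from a YAML config file
#'
#' @param path File written by [write_registry()] (or hand-edited in the
#'   same layout).
#' @return Registry tibble, ordered by priority.
#' @export
read_registry <- function(path) {
  recs <- yaml::read_yaml(path)
  reg <- tibble::tibble(
    db = vapply(recs, function(r) as.character(r$db), character(1)),
    patterns = lapply(recs, function(r) as.character(unlist(r$patterns))),
    cues = lapply(recs, function(r) as.character(unlist(r$cues))),
    cue_required = vapply(recs, function(r) isTRUE(r$cue_required), logical(1)),
    case_insensitive =
      vapply(recs, function(r) isTRUE(r$case_insensitive), logical(1)),
    priority = vapply(recs, function(r) as.integer(r$priority), integer(1))
  )
  reg <- reg[order(reg$priority), , drop = FALSE]
  validate_registry(reg)
  reg
}
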