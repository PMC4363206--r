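# Candidate finding, contextual-cue gating, overlap resolution.
#
# Offsets follow the 0-based half-open convention throughout: a candidate
# with start = s, end = e covers substr(text, s + 1, e) in R's 1-based
# indexing. Texts are expected to be whitespace-normalized flat character
# sequences (see normalize_ws()); the document readers normalize before
# annotation so spans are reproducible across readers.

#' Collapse whitespace runs to single spaces
#'
#' @param text Character vector.
#' @return Character vector with runs of whitespace replaced by one space
#'   and leading/trailing whitespace removed.
#' @export
normalize_ws <- function(text) {
  stringr::str_squish(text)
}

#' Annotation configuration
#'
#' @param cue_mode How far a contextual cue may sit from a candidate and
#'   still license it: `"window"` (within `cue_window` characters on either
#'   side, the default) or `"section"` (anywhere in the same text section).
#' @param cue_window Window half-width in characters (default 300).
#' @param drop_invalid Whether annotations a validator marks invalid are
#'   dropped from downstream counts (default `TRUE`).
#' @param source_code_exts File extensions treated as source code during
#'   supplementary-file triage.
#' @return A list of class `accminer_config`.
#' @export
annotation_config <- function(cue_mode = c("window", "section"),
                              cue_window = 300,
                              drop_invalid = TRUE,
                              source_code_exts = c(
                                ".c", ".cpp", ".h", ".py", ".pl", ".java",
                                ".r", ".m", ".sh", ".js"
                              )) {
  cue_mode <- match.arg(cue_mode)
  stopifnot(is.numeric(cue_window), length(cue_window) == 1L, cue_window > 0)
  structure(
    list(
      cue_mode = cue_mode,
      cue_window = as.integer(cue_window),
      drop_invalid = isTRUE(drop_invalid),
      source_code_exts = tolower(source_code_exts)
    ),
    class = "accminer_config"
  )
}

empty_candidates <- function() {
  tibble::tibble(
    db = character(), surface = character(),
    start = integer(), end = integer(),
    pattern_index = integer(), priority = integer()
  )
}

# A token match counts only when delimited by word boundaries: the
# characters flanking it must not be alphanumeric.
bounded_regex <- function(pattern, case_insensitive) {
  stringr::regex(
    paste0("(?<![A-Za-z0-9])(?:", pattern, ")(?![A-Za-z0-9])"),
    ignore_case = case_insensitive
  )
}

#' Find candidate accession mentions
#'
#' Applies every registry pattern to the text and returns all maximal
#' word-bounded matches. Overlapping candidates from different databases
#' may coexist at this stage; disambiguation happens later via cue gating
#' and overlap resolution.
#'
#' @param text A single character string.
#' @param registry Registry tibble from [db_registry()].
#' @return Tibble of candidates with columns `db`, `surface`, `start`,
#'   `end` (0-based half-open character offsets), `pattern_index` and
#'   `priority`, sorted by (`start`, `end`, `priority`).
#' @examples
#' find_candidates("accession P09372 from swissprot", db_registry())
#' @export
find_candidates <- function(text, registry = db_registry()) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    return(empty_candidates())
  }
  db <- character(0); start1 <- integer(0); end1 <- integer(0)
  pattern_index <- integer(0); priority <- integer(0)
  for (i in seq_len(nrow(registry))) {
    pats <- registry$patterns[[i]]
    for (j in seq_along(pats)) {
      loc <- stringr::str_locate_all(
        text, bounded_regex(pats[j], registry$case_insensitive[i])
      )[[1]]
      n <- nrow(loc)
      if (n == 0L) next
      db <- c(db, rep(registry$db[i], n))
      start1 <- c(start1, loc[, 1])
      end1 <- c(end1, loc[, 2])
      pattern_index <- c(pattern_index, rep(j, n))
      priority <- c(priority, rep(registry$priority[i], n))
    }
  }
  if (length(db) == 0L) {
    return(empty_candidates())
  }
  cand <- tibble::tibble(
    db = db,
    surface = stringr::str_sub(text, start1, end1),
    start = as.integer(start1 - 1L),
    end = as.integer(end1),
    pattern_index = pattern_index,
    priority = priority
  )
  # a span matched by several patterns of the same database is one candidate
  cand <- cand |>
    dplyr::arrange(.data$start, .data$end, .data$priority,
                   .data$pattern_index) |>
    dplyr::distinct(.data$db, .data$start, .data$end, .keep_all = TRUE)
  cand
}

locate_cues <- function(text, cues) {
  name <- character(0); start0 <- integer(0); end0 <- integer(0)
  for (cue in cues) {
    loc <- stringr::str_locate_all(
      text,
      stringr::regex(
        paste0("(?<![A-Za-z0-9])", escape_regex(cue), "(?![A-Za-z0-9])"),
        ignore_case = TRUE
      )
    )[[1]]
    n <- nrow(loc)
    if (n == 0L) next
    name <- c(name, rep(cue, n))
    start0 <- c(start0, loc[, 1] - 1L)
    end0 <- c(end0, loc[, 2])
  }
  data.frame(cue = name, start = as.integer(start0), end = as.integer(end0))
}

escape_regex <- function(x) {
  stringr::str_escape(x)
}

#' Gate candidates with contextual cues
#'
#' Keeps a candidate iff its database does not require a cue, or one of the
#' database's cue words occurs (case-insensitively, word-bounded) within
#' `config$cue_window` characters of the candidate span (`cue_mode =
#' "window"`) or anywhere in the text (`cue_mode = "section"`). A cue
#' occurrence overlapping the candidate span itself never licenses it. The
#' nearest licensing cue and its character distance are recorded.
#'
#' @param candidates Output of [find_candidates()] for this `text`.
#' @param text The source text the candidates were found in.
#' @param registry Registry tibble.
#' @param config [annotation_config()].
#' @return The retained candidates with `cue` and `cue_distance` columns
#'   (`NA` when the database does not require a cue and none is nearby).
#' @export
apply_context_filter <- function(candidates, text,
                                 registry = db_registry(),
                                 config = annotation_config()) {
  if (!config$cue_mode %in% c("window", "section")) {
    stop("unknown cue mode: ", config$cue_mode, call. = FALSE)
  }
  candidates$cue <- NA_character_
  candidates$cue_distance <- NA_integer_
  if (nrow(candidates) == 0L) {
    return(candidates)
  }
  keep <- rep(TRUE, nrow(candidates))
  for (db in unique(candidates$db)) {
    entry <- db_entry(registry, db)
    idx <- which(candidates$db == db)
    cue_loc <- locate_cues(text, entry$cues[[1]])
    for (i in idx) {
      s <- candidates$start[i]
      e <- candidates$end[i]
      # cue must lie outside the accession token (no self-licensing)
      outside <- cue_loc[cue_loc$end <= s | cue_loc$start >= e, , drop = FALSE]
      if (nrow(outside) > 0L) {
        gap <- ifelse(outside$end <= s, s - outside$end, outside$start - e)
        nearest <- which.min(gap)
        licensed <- if (config$cue_mode == "window") {
          gap[nearest] <= config$cue_window
        } else {
          TRUE
        }
        if (licensed) {
          candidates$cue[i] <- outside$cue[nearest]
          candidates$cue_distance[i] <- as.integer(gap[nearest])
        }
      }
      if (entry$cue_required && is.na(candidates$cue[i])) {
        keep[i] <- FALSE
      }
    }
  }
  candidates[keep, , drop = FALSE]
}

#' Resolve overlapping candidates
#'
#' Selects a pairwise non-overlapping subset of candidate spans. Among
#' overlapping candidates the winner has the smallest cue distance, then
#' the longest span, then the highest registry priority (lowest rank
#' number); remaining ties break on start offset and database name, so the
#' result is deterministic for a fixed input.
#'
#' @param candidates Cue-gated candidates (with `cue_distance`).
#' @return Non-overlapping candidates sorted by `start`.
#' @export
resolve_overlaps <- function(candidates) {
  if (nrow(candidates) <= 1L) {
    return(candidates)
  }
  dist <- candidates$cue_distance
  dist[is.na(dist)] <- Inf
  len <- candidates$end - candidates$start
  ord <- order(dist, -len, candidates$priority, candidates$start,
               candidates$db)
  kept <- integer(0)
  for (i in ord) {
    s <- candidates$start[i]
    e <- candidates$end[i]
    clash <- any(s < candidates$end[kept] & candidates$start[kept] < e)
    if (!clash) {
      kept <- c(kept, i)
    }
  }
  res <- candidates[sort(kept), , drop = FALSE]
  res[order(res$start, res$end), , drop = FALSE]
}

annotation_columns <- function(x) {
  x[, c("db", "surface", "start", "end", "pattern_index",
        "normalized_accession", "cue", "cue_distance", "section",
        "validation_status"), drop = FALSE]
}

empty_annotations <- function() {
  tibble::tibble(
    db = character(), surface = character(),
    start = integer(), end = integer(), pattern_index = integer(),
    normalized_accession = character(),
    cue = character(), cue_distance = integer(),
    section = character(), validation_status = character()
  )
}

#' Annotate a text section
#'
#' The full single-section pipeline: find candidates, gate them with
#' contextual cues, resolve overlaps, and lift the survivors to annotations
#' with normalized accessions and a section locator.
#'
#' @inheritParams apply_context_filter
#' @param section Section locator recorded on each annotation, `"BODY"` or
#'   `"SUPP:<filename>"`.
#' @return Annotation tibble sorted by `start`, with columns `db`,
#'   `surface`, `start`, `end`, `pattern_index`, `normalized_accession`,
#'   `cue`, `cue_distance`, `section`, `validation_status`
#'   (`"unvalidated"`).
#' @examples
#' annotate_text("the interpro domain IPR004839 was found")
#' @export
annotate_text <- function(text, registry = db_registry(),
                          config = annotation_config(), section = "BODY") {
  cand <- find_candidates(text, registry)
  cand <- apply_context_filter(cand, text, registry, config)
  cand <- resolve_overlaps(cand)
  if (nrow(cand) == 0L) {
    return(empty_annotations())
  }
  cand$normalized_accession <- vapply(
    seq_len(nrow(cand)),
    function(i) normalize_accession(cand$db[i], cand$surface[i]),
    character(1)
  )
  cand$section <- section
  cand$validation_status <- "unvalidated"
  annotation_columns(cand)
}

unique_pairs <- function(annotations) {
  annotations |>
    dplyr::distinct(.data$article_id, .data$db, .data$normalized_accession)
}

#' Annotate an article and its supplementary files
#'
#' Annotates the article body and each mineable supplementary text
#' independently, and derives the per-article sets of unique
#' (database, accession) pairs for body and supplementary data, which
#' downstream shared-citation counting uses.
#'
#' @param doc A document record from [parse_article_xml()] (with
#'   supplementary text already extracted, see [extract_supp_texts()]), or
#'   built programmatically with the same fields.
#' @param registry Registry tibble.
#' @param config [annotation_config()].
#' @return List with `annotations` (tibble with `article_id` plus the
#'   [annotate_text()] columns), `body_pairs` and `supp_pairs` (unique
#'   `(article_id, db, normalized_accession)` tibbles), and `skipped`
#'   (mineable manifest entries that had no extracted text).
#' @export
annotate_document <- function(doc, registry = db_registry(),
                              config = annotation_config()) {
  ann <- list()
  body <- annotate_text(doc$body_text %||% "", registry, config,
                        section = "BODY")
  if (nrow(body) > 0L) ann[["BODY"]] <- body
  skipped <- character(0)
  manifest <- doc$supp_manifest
  if (!is.null(manifest) && nrow(manifest) > 0L) {
    for (i in seq_len(nrow(manifest))) {
      if (!identical(manifest$triage[i], "mineable")) next
      txt <- manifest$text[i]
      if (is.na(txt)) {
        warning("no extracted text for mineable supplementary file ",
                manifest$filename[i], " (skipped)", call. = FALSE)
        skipped <- c(skipped, manifest$filename[i])
        next
      }
      a <- annotate_text(txt, registry, config,
                         section = paste0("SUPP:", manifest$filename[i]))
      if (nrow(a) > 0L) ann[[manifest$filename[i]]] <- a
    }
  }
  annotations <- if (length(ann) > 0L) {
    dplyr::bind_rows(ann)
  } else {
    empty_annotations()
  }
  annotations <- tibble::add_column(
    annotations, article_id = rep(doc$article_id, nrow(annotations)),
    .before = 1L
  )
  list(
    annotations = annotations,
    body_pairs = unique_pairs(
      annotations[annotations$section == "BODY", , drop = FALSE]
    ),
    supp_pairs = unique_pairs(
      annotations[startsWith(annotations$section, "SUPP:"), , drop = FALSE]
    ),
    skipped = skipped
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write annotations to TSV or JSON
#'
#' Serializes with a fixed column order (`article_id`, `section`, `db`,
#' `accession`, `normalized_accession`, `start`, `end`, `cue`,
#' `cue_distance`, `validation_status`) so outputs diff cleanly.
#'
#' @param annotations Annotation tibble that includes an `article_id`
#'   column (e.g. from [annotate_document()] or [annotate_corpus()]).
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  out <- tibble::tibble(
    article_id = annotations$article_id,
    section = annotations$section,
    db = annotations$db,
    accession = annotations$surface,
    normalized_accession = annotations$normalized_accession,
    start = annotations$start,
    end = annotations$end,
    cue = annotations$cue,
    cue_distance = annotations$cue_distance,
    validation_status = annotations$validation_status
  )
  if (format == "tsv") {
    readr::write_tsv(out, path, na = "")
  } else {
    jsonlite::write_json(out, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Annotate every document in a corpus
#'
#' @param docs List of document records (see [read_corpus()]).
#' @param registry Registry tibble.
#' @param config [annotation_config()].
#' @param validator Optional validator applied to the pooled annotations
#'   (see [validate_annotations()]).
#' @return List with `annotations` (pooled tibble), `body_pairs`,
#'   `supp_pairs` and `skipped` (named by article).
#' @export
annotate_corpus <- function(docs, registry = db_registry(),
                            config = annotation_config(),
                            validator = NULL) {
  per_doc <- lapply(docs, annotate_document, registry = registry,
                    config = config)
  annotations <- dplyr::bind_rows(lapply(per_doc, `[[`, "annotations"))
  if (nrow(annotations) == 0L) {
    annotations <- tibble::add_column(empty_annotations(),
                                      article_id = character(), .before = 1L)
  }
  if (!is.null(validator)) {
    annotations <- validate_annotations(annotations, validator, config)
  }
  skipped <- unlist(lapply(per_doc, `[[`, "skipped"))
  list(
    annotations = annotations,
    body_pairs = unique_pairs(
      annotations[annotations$section == "BODY", , drop = FALSE]
    ),
    supp_pairs = unique_pairs(
      annotations[startsWith(annotations$section, "SUPP:"), , drop = FALSE]
    ),
    skipped = skipped
  )
}
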