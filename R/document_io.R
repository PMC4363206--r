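# JATS-style article reading, supplementary-file triage and text extraction.
#
# Triage implements a three-step pre-processing of supplementary files:
# (1) files that are not easily text-convertible (image/audio/video MIME
# classes) are screened out; (2) text files unlikely to contain accession
# numbers (source code, by extension) are screened out; (3) text is
# extracted from the remainder with built-in adapters (TXT/CSV/TSV/HTML/XML)
# or user-registered adapters for binary formats (PDF/DOC/XLS).

TEXT_CONVERTIBLE_EXTS <- c(
  ".txt", ".csv", ".tsv", ".tab", ".xml", ".html", ".htm",
  ".pdf", ".doc", ".docx", ".xls", ".xlsx"
)

file_extension <- function(filename) {
  ext <- tolower(sub("^.*(\\.[A-Za-z0-9]+)$", "\\1", filename))
  ext[!grepl("\\.[A-Za-z0-9]+$", filename) | is.na(filename)] <- ""
  ext
}

#' Parse a JATS-style article XML file
#'
#' Reads the article identifier, publication year, body narrative and the
#' supplementary-material manifest. Body text concatenates the character
#' data of the `<body>` element (figure and table text included); the
#' reference list (`<ref-list>`) is excluded, since citation lists are full
#' of identifier-like tokens that are not database citations. Whitespace is
#' normalized so spans are reproducible.
#'
#' @param xml Path to an XML file, or an `xml_document`.
#' @return A list of class `document_record`: `article_id`, `pub_year`,
#'   `body_text`, and `supp_manifest`, a tibble with one row per
#'   `<supplementary-material>` link (`filename`, `mime_type`,
#'   `mime_subtype`, `extension`, `triage = NA`, `text = NA`).
#' @export
parse_article_xml <- function(xml) {
  doc <- tryCatch(
    if (inherits(xml, "xml_document")) xml else xml2::read_xml(xml),
    error = function(e) {
      stop("malformed XML in ",
           if (is.character(xml)) xml else "<document>", ": ",
           conditionMessage(e), call. = FALSE)
    }
  )
  article_id <- xml2::xml_text(
    xml2::xml_find_first(doc, ".//article-id")
  )
  if (is.na(article_id) || !nzchar(article_id)) {
    article_id <- "unknown"
  }
  year <- xml2::xml_text(
    xml2::xml_find_first(doc, ".//pub-date/year")
  )
  pub_year <- suppressWarnings(as.integer(year))

  body <- xml2::xml_find_first(doc, ".//body")
  if (inherits(body, "xml_missing")) {
    warning("article ", article_id, " has no <body>", call. = FALSE)
    body_text <- ""
  } else {
    body <- xml2::xml_new_root(body, .copy = TRUE)
    for (ref in xml2::xml_find_all(body, ".//ref-list")) {
      xml2::xml_remove(ref)
    }
    body_text <- normalize_ws(xml_text_with_spaces(xml2::xml_root(body)))
  }

  supp <- xml2::xml_find_all(doc, ".//supplementary-material")
  rows <- lapply(supp, function(node) {
    link <- node
    if (!xml2::xml_has_attr(node, "href") &&
        !xml2::xml_has_attr(node, "xlink:href")) {
      media <- xml2::xml_find_first(node, ".//media")
      if (!inherits(media, "xml_missing")) link <- media
    }
    href <- xml2::xml_attr(link, "href")
    if (is.na(href)) href <- xml2::xml_attr(link, "xlink:href")
    tibble::tibble(
      filename = href %||% NA_character_,
      mime_type = xml2::xml_attr(link, "mimetype"),
      mime_subtype = xml2::xml_attr(link, "mime-subtype")
    )
  })
  manifest <- if (length(rows) > 0L) {
    dplyr::bind_rows(rows)
  } else {
    tibble::tibble(filename = character(), mime_type = character(),
                   mime_subtype = character())
  }
  manifest$extension <- file_extension(manifest$filename)
  manifest$triage <- NA_character_
  manifest$triage_reason <- NA_character_
  manifest$text <- NA_character_

  structure(
    list(article_id = article_id, pub_year = pub_year,
         body_text = body_text, supp_manifest = manifest),
    class = "document_record"
  )
}

# xml2::xml_text runs adjacent element text together; insert separators so
# "<td>A</td><td>B</td>" does not fuse tokens across cell boundaries.
xml_text_with_spaces <- function(node) {
  texts <- xml2::xml_find_all(node, ".//text()")
  paste(xml2::xml_text(texts), collapse = " ")
}

#' Triage a supplementary-file manifest
#'
#' Labels every manifest entry with exactly one of `mineable`,
#' `excluded_media` (image/audio/video MIME class), `excluded_source_code`
#' (extension in `config$source_code_exts`) or `excluded_unconvertible`
#' (format not known to be text-convertible). MIME is trusted over
#' extension when both are present; extension is the fallback.
#'
#' @param manifest Manifest tibble from [parse_article_xml()].
#' @param config [annotation_config()] (supplies the source-code extension
#'   list).
#' @return The manifest with `triage` and `triage_reason` filled in.
#' @export
triage_supplementary <- function(manifest, config = annotation_config()) {
  if (nrow(manifest) == 0L) {
    return(manifest)
  }
  mime <- tolower(manifest$mime_type)
  ext <- tolower(manifest$extension)
  for (i in seq_len(nrow(manifest))) {
    if (!is.na(mime[i]) && mime[i] %in% c("image", "audio", "video")) {
      manifest$triage[i] <- "excluded_media"
      manifest$triage_reason[i] <- paste0("MIME class ", mime[i])
    } else if (!is.na(ext[i]) && ext[i] %in% config$source_code_exts) {
      manifest$triage[i] <- "excluded_source_code"
      manifest$triage_reason[i] <- paste0("source-code extension ", ext[i])
    } else if ((!is.na(mime[i]) && mime[i] == "text") ||
               (!is.na(ext[i]) && ext[i] %in% TEXT_CONVERTIBLE_EXTS)) {
      manifest$triage[i] <- "mineable"
      manifest$triage_reason[i] <- "text-convertible"
    } else {
      manifest$triage[i] <- "excluded_unconvertible"
      manifest$triage_reason[i] <- "unconvertible"
    }
  }
  manifest
}

default_adapters <- function() {
  strip_markup <- function(path) {
    doc <- xml2::read_html(path)
    xml_text_with_spaces(doc)
  }
  list(
    ".txt" = read_text_file,
    ".csv" = read_text_file,
    ".tsv" = read_text_file,
    ".tab" = read_text_file,
    ".html" = strip_markup,
    ".htm" = strip_markup,
    ".xml" = function(path) xml_text_with_spaces(xml2::read_xml(path))
  )
}

read_text_file <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  txt <- rawToChar(raw)
  if (!validUTF8(txt)) {
    # fall back to latin1 when the bytes are not valid UTF-8
    txt <- iconv(txt, from = "latin1", to = "UTF-8")
  }
  Encoding(txt) <- "UTF-8"
  txt
}

#' Extract text from one supplementary file
#'
#' Routes the file to a format adapter by extension. Built-in adapters
#' handle TXT/CSV/TSV/HTML/XML; binary formats (PDF/DOC/XLS) only have
#' adapters if the caller registers them. Any failure — no adapter,
#' unreadable bytes, adapter error — downgrades the entry to
#' `extraction_failed` instead of aborting the run.
#'
#' @param path Path to the file on disk.
#' @param extension Lower-case extension (with dot) used to pick the
#'   adapter; defaults to the path's extension.
#' @param adapters Named list mapping extension to `function(path) text`;
#'   merged over the built-ins.
#' @return List with `text` (character or `NA`) and `status`
#'   (`"ok"` or `"extraction_failed"`).
#' @export
extract_text <- function(path, extension = file_extension(path),
                         adapters = list()) {
  all_adapters <- utils::modifyList(default_adapters(), adapters)
  adapter <- all_adapters[[extension]]
  if (is.null(adapter) || !file.exists(path)) {
    return(list(text = NA_character_, status = "extraction_failed"))
  }
  txt <- tryCatch(
    normalize_ws(adapter(path)),
    error = function(e) NA_character_
  )
  if (is.na(txt)) {
    list(text = NA_character_, status = "extraction_failed")
  } else {
    list(text = txt, status = "ok")
  }
}

#' Extract text for all mineable files in a document record
#'
#' Runs triage if it has not been applied, then extracts text for every
#' mineable manifest entry from `supp_dir`, keyed by filename. Files whose
#' extraction fails are relabeled `extraction_failed`.
#'
#' @param doc `document_record` from [parse_article_xml()].
#' @param supp_dir Directory holding the supplementary files.
#' @param config [annotation_config()].
#' @param adapters Extra format adapters (see [extract_text()]).
#' @return The document record with manifest `triage` and `text` filled in.
#' @export
extract_supp_texts <- function(doc, supp_dir, config = annotation_config(),
                               adapters = list()) {
  manifest <- doc$supp_manifest
  if (any(is.na(manifest$triage))) {
    manifest <- triage_supplementary(manifest, config)
  }
  for (i in seq_len(nrow(manifest))) {
    if (!identical(manifest$triage[i], "mineable")) next
    res <- extract_text(file.path(supp_dir, manifest$filename[i]),
                        manifest$extension[i], adapters)
    if (res$status == "ok") {
      manifest$text[i] <- res$text
    } else {
      manifest$triage[i] <- "extraction_failed"
      manifest$triage_reason[i] <- "extraction failed"
    }
  }
  doc$supp_manifest <- manifest
  doc
}

#' Read a corpus directory
#'
#' Loads every `*.xml` article under `dir`, triages its manifest and
#' extracts supplementary text from the sibling `supp/` directory (or
#' `supp_dir` if given). The layout matches what [generate_corpus()]
#' writes.
#'
#' @param dir Corpus directory containing article XML files.
#' @param supp_dir Directory with supplementary files (default
#'   `file.path(dir, "supp")`).
#' @param config [annotation_config()].
#' @param adapters Extra format adapters.
#' @param min_year Articles published before this year are dropped
#'   (default 1990); articles with no year are kept.
#' @return List of `document_record`s, sorted by filename.
#' @export
read_corpus <- function(dir, supp_dir = file.path(dir, "supp"),
                        config = annotation_config(), adapters = list(),
                        min_year = 1990) {
  files <- sort(list.files(dir, pattern = "\\.xml$", full.names = TRUE))
  docs <- lapply(files, function(f) {
    doc <- parse_article_xml(f)
    extract_supp_texts(doc, supp_dir, config, adapters)
  })
  keep <- vapply(docs, function(d) {
    is.na(d$pub_year) || d$pub_year >= min_year
  }, logical(1))
  docs[keep]
}

#' Write a triage report
#'
#' @param docs List of document records (post-triage).
#' @param path Output TSV path.
#' @return Tibble written (`article_id`, `filename`, `mime_type`,
#'   `mime_subtype`, `extension`, `triage`, `triage_reason`), invisibly.
#' @export
write_triage_report <- function(docs, path) {
  rows <- lapply(docs, function(d) {
    m <- d$supp_manifest
    if (nrow(m) == 0L) return(NULL)
    tibble::tibble(
      article_id = d$article_id, filename = m$filename,
      mime_type = m$mime_type, mime_subtype = m$mime_subtype,
      extension = m$extension, triage = m$triage,
      triage_reason = m$triage_reason
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(
      article_id = character(), filename = character(),
      mime_type = character(), mime_subtype = character(),
      extension = character(), triage = character(),
      triage_reason = character()
    )
  }
  readr::write_tsv(out, path, na = "")
  invisible(out)
}
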