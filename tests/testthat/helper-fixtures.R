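# In-code fixtures shared across test files.

# The extraction patterns exactly as published, used as an independent
# whole-string oracle (kept separate from the package registry on
# purpose). The "[A-Z, 0-9]"-style classes are written out the same way
# the registry interprets them; the oracle applies them with base R.
printed_patterns <- list(
  ENA = c("[A-Z][0-9]{5}", "[A-Z]{2}[0-9]{6}", "[A-Z]{3}[0-9]{5}",
          "[A-Z]{4}[0-9]{8,10}", "[A-Z]{5}[0-9]{7}"),
  UniProt = c("[A-NR-Z][0-9][A-Z][A-Z0-9][A-Z0-9][0-9]",
              "[OPQ][0-9][A-Z0-9][A-Z0-9][A-Z0-9][0-9]"),
  PDBe = "[0-9][A-Z0-9]{3}",
  InterPro = "IPR[0-9]{6}",
  Pfam = "PF(AM)?[0-9]{5}",
  ArrayExpress = "E-[A-Z]{4}-[0-9]+",
  OMIM = "[0-9]{6}",
  Ensembl = "ENS[A-Z]*G[0-9]{11}",
  RefSeq = paste0("(AC|AP|NC|NG|NM|NP|NR|NT|NW|NZ|XM|XP|XR|YP|ZP|NS)",
                  "_([A-Z]{4})*[0-9]{6,9}(?:[.][0-9]+)?"),
  RefSNP = "RS[0-9]{5,9}"
)

# Oracle: does the whole upper-case token match any printed pattern?
oracle_conforms <- function(db, tokens) {
  hit <- rep(FALSE, length(tokens))
  for (p in printed_patterns[[db]]) {
    hit <- hit | grepl(paste0("^(?:", p, ")$"), tokens, perl = TRUE)
  }
  hit
}

random_tokens <- function(n, max_len = 16) {
  pool <- c(LETTERS, 0:9)
  vapply(sample(1:max_len, n, replace = TRUE), function(len) {
    paste(sample(pool, len, replace = TRUE), collapse = "")
  }, character(1))
}

# One-character mutation of a token (substitution at a random position).
mutate_token <- function(token) {
  pool <- c(LETTERS, 0:9)
  i <- sample.int(nchar(token), 1)
  old <- substr(token, i, i)
  repl <- sample(setdiff(pool, old), 1)
  paste0(substr(token, 1, i - 1), repl,
         substr(token, i + 1, nchar(token)))
}

# A hand-built document record (no XML involved).
make_doc <- function(article_id = "PMC0000001", body_text = "",
                     supp = NULL, pub_year = 2010L) {
  manifest <- if (is.null(supp)) {
    tibble::tibble(
      filename = character(), mime_type = character(),
      mime_subtype = character(), extension = character(),
      triage = character(), triage_reason = character(),
      text = character()
    )
  } else {
    tibble::tibble(
      filename = names(supp),
      mime_type = "text", mime_subtype = "plain",
      extension = accminer:::file_extension(names(supp)),
      triage = "mineable", triage_reason = "text-convertible",
      text = unname(unlist(supp))
    )
  }
  structure(
    list(article_id = article_id, pub_year = pub_year,
         body_text = body_text, supp_manifest = manifest),
    class = "document_record"
  )
}

# A minimal JATS-style article as an XML string.
jats_fixture <- function(article_id = "PMC1234567", year = 2008,
                         body = "some narrative text",
                         refs = NULL, supp = list()) {
  supp_xml <- paste(vapply(supp, function(s) {
    sprintf('<supplementary-material href="%s" mimetype="%s" mime-subtype="%s"/>',
            s$filename, s$mime, s$subtype)
  }, character(1)), collapse = "\n")
  ref_xml <- if (is.null(refs)) "" else {
    paste0("<ref-list><ref>", refs, "</ref></ref-list>")
  }
  paste0(
    '<?xml version="1.0"?><article><front>',
    '<article-id pub-id-type="pmcid">', article_id, "</article-id>",
    "<pub-date><year>", year, "</year></pub-date></front>",
    "<body><p>", body, "</p>", supp_xml, ref_xml, "</body></article>"
  )
}

# Annotation tibble built directly (for corpus statistics tests).
make_annotations <- function(article_id, section, db, accession) {
  tibble::tibble(
    article_id = article_id, section = section, db = db,
    surface = accession, start = 0L, end = nchar(accession),
    pattern_index = 1L, normalized_accession = toupper(accession),
    cue = "x", cue_distance = 1L, validation_status = "unvalidated"
  )
}
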