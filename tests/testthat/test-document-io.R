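test_that("JATS parsing extracts id, year, body and manifest", {
  xml <- jats_fixture(
    body = "body narrative with  extra   spaces",
    supp = list(
      list(filename = "tableS1.txt", mime = "text", subtype = "plain"),
      list(filename = "movie1.mp4", mime = "video", subtype = "mp4")
    )
  )
  doc <- parse_article_xml(xml2::read_xml(xml))
  expect_equal(doc$article_id, "PMC1234567")
  expect_equal(doc$pub_year, 2008L)
  expect_equal(doc$body_text, "body narrative with extra spaces")
  expect_equal(nrow(doc$supp_manifest), 2L)
  expect_equal(doc$supp_manifest$filename, c("tableS1.txt", "movie1.mp4"))
  expect_equal(doc$supp_manifest$mime_type, c("text", "video"))
  expect_equal(doc$supp_manifest$extension, c(".txt", ".mp4"))
})

test_that("reference lists are excluded from body text", {
  xml <- jats_fixture(body = "narrative interpro IPR000001",
                      refs = "citation with token AB123456")
  doc <- parse_article_xml(xml2::read_xml(xml))
  expect_match(doc$body_text, "IPR000001")
  expect_no_match(doc$body_text, "AB123456")
})

test_that("missing body warns, malformed XML and empty manifests behave", {
  xml <- '<article><front><article-id>PMC1</article-id></front></article>'
  expect_warning(doc <- parse_article_xml(xml2::read_xml(xml)), "no <body>")
  expect_equal(doc$body_text, "")
  expect_equal(nrow(doc$supp_manifest), 0L)

  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines("<article><unclosed>", bad)
  expect_error(parse_article_xml(bad), "malformed XML")
})

test_that("triage labels every entry with exactly one category", {
  manifest <- tibble::tibble(
    filename = c("code.c", "fig.png", "data.txt", "archive.zip",
                 "table.xls", "notes.bin"),
    mime_type = c("text", "image", "text", "application", NA, "text"),
    mime_subtype = c("plain", "png", "plain", "zip", NA, "octet"),
    extension = c(".c", ".png", ".txt", ".zip", ".xls", ".bin"),
    triage = NA_character_, triage_reason = NA_character_,
    text = NA_character_
  )
  out <- triage_supplementary(manifest, annotation_config())
  expect_equal(out$triage, c("excluded_source_code", "excluded_media",
                             "mineable", "excluded_unconvertible",
                             "mineable", "mineable"))
  # total function + conservation: one label each, counts add up
  expect_false(any(is.na(out$triage)))
  expect_equal(sum(table(out$triage)), nrow(manifest))
  # idempotent
  expect_equal(triage_supplementary(out, annotation_config()), out)
})

test_that("text extraction handles TSV, HTML and failures", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines("gene\taccession\ntp53\tNM_000546", tsv)
  res <- extract_text(tsv)
  expect_equal(res$status, "ok")
  expect_match(res$text, "NM_000546")

  html <- withr::local_tempfile(fileext = ".html")
  writeLines("<html><body><p>see <b>pfam</b> PF00001</p></body></html>", html)
  res2 <- extract_text(html)
  expect_equal(res2$status, "ok")
  expect_equal(res2$text, "see pfam PF00001")
  expect_no_match(res2$text, "<")

  pdf <- withr::local_tempfile(fileext = ".pdf")
  writeBin(as.raw(c(0x25, 0x50, 0x44, 0x46, 0x00, 0xff)), pdf)
  expect_equal(extract_text(pdf)$status, "extraction_failed")

  # a registered adapter takes over for binary formats
  res3 <- extract_text(pdf, adapters = list(".pdf" = function(p) "from adapter"))
  expect_equal(res3$text, "from adapter")
})

test_that("corpus reading wires triage and extraction together", {
  dir <- withr::local_tempdir()
  dir.create(file.path(dir, "supp"))
  writeLines("omim citation 123456 end",
             file.path(dir, "supp", "s1.txt"))
  writeLines("junk", file.path(dir, "supp", "code.py"))
  xml <- jats_fixture(
    article_id = "PMC42", body = "text",
    supp = list(
      list(filename = "s1.txt", mime = "text", subtype = "plain"),
      list(filename = "code.py", mime = "text", subtype = "x-python")
    )
  )
  writeLines(xml, file.path(dir, "PMC42.xml"))
  docs <- read_corpus(dir)
  expect_length(docs, 1L)
  m <- docs[[1]]$supp_manifest
  expect_equal(m$triage, c("mineable", "excluded_source_code"))
  expect_match(m$text[1], "123456")
  expect_true(is.na(m$text[2]))

  report <- write_triage_report(docs, file.path(dir, "triage.tsv"))
  expect_equal(nrow(report), 2L)
  expect_true(file.exists(file.path(dir, "triage.tsv")))
})

test_that("pre-1990 articles are filtered out of a corpus", {
  dir <- withr::local_tempdir()
  writeLines(jats_fixture(article_id = "PMC1", year = 1985),
             file.path(dir, "PMC1.xml"))
  writeLines(jats_fixture(article_id = "PMC2", year = 1995),
             file.path(dir, "PMC2.xml"))
  docs <- read_corpus(dir)
  expect_equal(vapply(docs, `[[`, character(1), "article_id"), "PMC2")
})
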