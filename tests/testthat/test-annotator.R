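test_that("find_candidates returns word-bounded matches from all databases", {
  expect_equal(nrow(find_candidates("")), 0L)

  cand <- find_candidates("accession P09372 from swissprot")
  expect_setequal(cand$db[cand$surface == "P09372"], c("UniProt", "ENA"))
  expect_equal(cand$start[1], 10L)
  expect_equal(cand$end[1], 16L)
  expect_equal(substr("accession P09372 from swissprot", 11, 16), "P09372")

  cand2 <- find_candidates("gene ENSG00000139618 here")
  expect_equal(cand2$db[cand2$db == "Ensembl"], "Ensembl")
  expect_equal(cand2$surface[cand2$db == "Ensembl"], "ENSG00000139618")

  # embedded in a longer alphanumeric run: not a candidate
  expect_false("InterPro" %in% find_candidates("xIPR000001")$db)
  expect_false("InterPro" %in% find_candidates("IPR0000012")$db)
})

test_that("cue gating keeps licensed candidates and drops the rest", {
  reg <- db_registry()
  cfg <- annotation_config()

  txt <- "the swissprot entry P09372 was studied"
  kept <- apply_context_filter(find_candidates(txt, reg), txt, reg, cfg)
  expect_true("UniProt" %in% kept$db)
  expect_false("ENA" %in% kept$db)
  expect_equal(kept$cue[kept$db == "UniProt"], "swissprot")

  # OMIM-shaped number with no cue anywhere
  txt2 <- "the number 123456 appears here"
  expect_equal(nrow(apply_context_filter(find_candidates(txt2, reg),
                                         txt2, reg, cfg)), 0L)

  # far cue: removed in window mode, kept in section mode
  txt3 <- paste0("pdb ", strrep("filler ", 700), "1ABC")
  expect_equal(nrow(annotate_text(txt3, reg, cfg)), 0L)
  sect <- annotate_text(txt3, reg, annotation_config(cue_mode = "section"))
  expect_equal(sect$db, "PDBe")

  expect_error(
    apply_context_filter(find_candidates(txt2, reg), txt2, reg,
                         list(cue_mode = "sentence", cue_window = 300)),
    "unknown cue mode"
  )
})

test_that("a cue inside the accession token does not license it", {
  reg <- db_registry()
  # "E-PFAM-12345" contains the word-bounded cue "pfam" within its own span
  txt <- "token E-PFAM-12345 stands alone"
  cand <- find_candidates(txt, reg)
  ae <- apply_context_filter(cand[cand$db == "ArrayExpress", , drop = FALSE],
                             txt, reg, annotation_config())
  expect_equal(nrow(ae), 0L)
  # with an external cue it is licensed
  txt2 <- "arrayexpress token E-PFAM-12345 stands alone"
  ann <- annotate_text(txt2, reg)
  expect_true("ArrayExpress" %in% ann$db)
  expect_equal(ann$cue[ann$db == "ArrayExpress"], "arrayexpress")
})

test_that("overlap resolution prefers nearer cues, then longer spans", {
  # same span, two databases: nearer cue wins
  txt <- paste0("swissprot entry P09372 ", strrep("pad ", 60), "genbank")
  ann <- annotate_text(txt)
  expect_equal(ann$db, "UniProt")

  # genbank cue closer: same span resolves to ENA instead
  txt2 <- paste0("genbank entry P09372 ", strrep("pad ", 60), "swissprot")
  expect_equal(annotate_text(txt2)$db, "ENA")

  # with no cues in play (cue_required off), longer span wins over nested
  reg2 <- db_registry()
  reg2$cue_required[] <- FALSE
  cfg <- annotation_config()
  txt3 <- "NM_123456"
  cand3 <- apply_context_filter(find_candidates(txt3, reg2), txt3, reg2, cfg)
  expect_setequal(cand3$db, c("RefSeq", "OMIM"))
  res3 <- resolve_overlaps(cand3)
  expect_equal(res3$db, "RefSeq")
  expect_equal(res3$surface, "NM_123456")

  # same span, same (absent) cue distance: registry priority decides
  txt5 <- "P09372"
  cand5 <- apply_context_filter(find_candidates(txt5, reg2), txt5, reg2, cfg)
  expect_setequal(cand5$db, c("UniProt", "ENA"))
  expect_equal(resolve_overlaps(cand5)$db, "UniProt")

  # identity on a single candidate; disjoint candidates both kept
  one <- find_candidates("IPR000001", db_registry("InterPro"))
  one$cue <- "interpro"; one$cue_distance <- 3L
  expect_equal(nrow(resolve_overlaps(one)), 1L)
  txt4 <- "interpro IPR000001 and pfam PF00001"
  expect_equal(nrow(annotate_text(txt4)), 2L)
})

test_that("annotate_text output is sorted, non-overlapping and conformant", {
  set.seed(21)
  reg <- db_registry()
  for (rep in 1:5) {
    dbs <- sample(reg$db, 4)
    blocks <- vapply(dbs, function(db) {
      paste("from", reg$cues[[match(db, reg$db)]][1], "entry",
            sample_accession(db), "listed .")
    }, character(1))
    txt <- paste(blocks, collapse = paste(rep("pad", 120), collapse = " "))
    ann <- annotate_text(txt)
    expect_equal(ann$start, sort(ann$start))
    if (nrow(ann) > 1) {
      expect_true(all(ann$start[-1] >= ann$end[-nrow(ann)]))
    }
    for (i in seq_len(nrow(ann))) {
      expect_true(acc_conforms(ann$db[i], ann$surface[i]))
      expect_equal(
        substr(txt, ann$start[i] + 1, ann$end[i]), ann$surface[i]
      )
    }
    # determinism
    expect_identical(ann, annotate_text(txt))
  }
})

test_that("annotate_document covers body and supplementary sections", {
  doc <- make_doc(body_text = "",
                  supp = list("s1.txt" = "pfam PF00001"))
  res <- annotate_document(doc)
  expect_equal(sum(res$annotations$section == "BODY"), 0L)
  expect_equal(res$annotations$section, "SUPP:s1.txt")
  expect_equal(res$annotations$normalized_accession, "PF00001")

  # same accession in body and supp appears in both unique-pair sets
  doc2 <- make_doc(body_text = "pfam PF00001 in text",
                   supp = list("s1.txt" = "pfam PF00001"))
  res2 <- annotate_document(doc2)
  expect_equal(nrow(res2$body_pairs), 1L)
  expect_equal(nrow(res2$supp_pairs), 1L)
  expect_equal(res2$body_pairs$normalized_accession,
               res2$supp_pairs$normalized_accession)

  # no mineable supp files -> empty supp annotations
  doc3 <- make_doc(body_text = "pfam PF00001 here")
  res3 <- annotate_document(doc3)
  expect_equal(nrow(res3$supp_pairs), 0L)

  # mineable manifest entry without extracted text -> warning + skip
  doc4 <- make_doc(supp = list("s1.txt" = "pfam PF00001"))
  doc4$supp_manifest$text <- NA_character_
  expect_warning(res4 <- annotate_document(doc4), "no extracted text")
  expect_equal(res4$skipped, "s1.txt")
  expect_equal(nrow(res4$annotations), 0L)
})

test_that("annotations serialize with a fixed column order", {
  doc <- make_doc(body_text = "interpro IPR004839 found",
                  supp = list("s1.tsv" = "pfam\tPF00001"))
  res <- annotate_document(doc)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_annotations(res$annotations, tsv, "tsv")
  header <- readLines(tsv, n = 1)
  expect_equal(
    header,
    paste("article_id", "section", "db", "accession",
          "normalized_accession", "start", "end", "cue", "cue_distance",
          "validation_status", sep = "\t")
  )
  js <- withr::local_tempfile(fileext = ".json")
  write_annotations(res$annotations, js, "json")
  parsed <- jsonlite::read_json(js)
  expect_length(parsed, nrow(res$annotations))
  expect_equal(parsed[[1]]$normalized_accession, "IPR004839")
})
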