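test_that("citation distribution counts mentions and shared unique pairs", {
  ann <- dplyr::bind_rows(
    # PMC1: two ENA supp mentions of the same accession + one body mention
    make_annotations("PMC1", c("SUPP:a.txt", "SUPP:a.txt", "BODY"),
                     "ENA", c("AB123456", "AB123456", "AB123456")),
    # PMC1: OMIM body only
    make_annotations("PMC1", "BODY", "OMIM", "123456"),
    # PMC2: ENA supp only
    make_annotations("PMC2", "SUPP:b.txt", "ENA", "CD654321"),
    # PMC2: RefSNP supp only (no body mentions anywhere)
    make_annotations("PMC2", "SUPP:b.txt", "RefSNP", "RS12345")
  )
  dist <- citation_distribution(ann)
  ena <- dist[dist$db == "ENA", ]
  expect_equal(ena$supp_count, 3L)   # mention counting, duplicates count
  expect_equal(ena$body_count, 1L)
  expect_equal(ena$shared_count, 1L) # unique (db, acc) pair shared in PMC1
  expect_equal(ena$ratio, 3)
  expect_equal(ena$shared_pct_raw, 100 / 3)

  omim <- dist[dist$db == "OMIM", ]
  expect_equal(omim$body_count, 1L)
  expect_equal(omim$supp_count, 0L)
  expect_equal(omim$ratio, 0)        # defined: body mentions exist

  snp <- dist[dist$db == "RefSNP", ]
  expect_equal(snp$supp_count, 1L)
  expect_equal(snp$body_count, 0L)
  expect_true(is.na(snp$ratio))      # undefined, not infinite

  # absent databases appear with zero counts; conservation holds
  expect_equal(nrow(dist), 10L)
  expect_equal(sum(dist$supp_count), sum(startsWith(ann$section, "SUPP:")))
  expect_equal(sum(dist$body_count), sum(ann$section == "BODY"))
})

test_that("derived ratio/shared columns recompute from published counts", {
  d <- derive_citation_stats(citation_counts())
  expect_equal(d$ratio[d$db == "Ensembl"], 1121.70)
  expect_equal(d$ratio[d$db == "RefSeq"], 886.96)
  expect_equal(d$shared_pct[d$db == "PDBe"], 1.42)
  expect_equal(d$shared_pct[d$db == "ArrayExpress"], 2.23)
  # ratio * body_count recovers supp_count exactly before rounding
  ok <- !is.na(d$ratio_raw)
  expect_equal(d$ratio_raw[ok] * d$body_count[ok], d$supp_count[ok])
})

test_that("empty corpora give zero rows and undefined ratios", {
  empty <- make_annotations(character(), character(), character(),
                            character())
  dist <- citation_distribution(empty)
  expect_equal(nrow(dist), 10L)
  expect_true(all(dist$supp_count == 0))
  expect_true(all(is.na(dist$ratio)))
  expect_error(top_fraction_concentration(empty, "ENA"), "no citations|no supplementary")
})

test_that("top-fraction concentration matches hand enumeration", {
  # 20 articles: one data dump with 81 supp citations, 19 with one each
  ids <- sprintf("PMC%02d", 1:20)
  ann <- dplyr::bind_rows(
    make_annotations(rep(ids[1], 81), "SUPP:a.txt", "ENA",
                     sprintf("AB%06d", 1:81)),
    make_annotations(ids[2:20], "SUPP:a.txt", "ENA",
                     sprintf("CD%06d", 2:20))
  )
  top5 <- top_fraction_concentration(ann, "ENA", 0.05)
  expect_equal(top5$n_articles, 20L)
  expect_equal(top5$pct_in_top, 81)

  # whole corpus: always 100
  expect_equal(top_fraction_concentration(ann, "ENA", 1)$pct_in_top, 100)

  # uniform counts: closed form 100 * ceil(f n) / n
  uni <- make_annotations(ids, "SUPP:a.txt", "OMIM",
                          sprintf("%06d", 100001:100020))
  expect_equal(top_fraction_concentration(uni, "OMIM", 0.05)$pct_in_top,
               100 * ceiling(0.05 * 20) / 20)

  # monotone non-decreasing in the fraction
  fr <- c(0.05, 0.1, 0.25, 0.5, 0.75, 1)
  pct <- vapply(fr, function(f) {
    top_fraction_concentration(ann, "ENA", f)$pct_in_top
  }, numeric(1))
  expect_true(all(diff(pct) >= 0))

  expect_error(top_fraction_concentration(ann, "ENA", 0), "fraction")
})

test_that("corpus breakdown computes counts against the right denominators", {
  docs <- list(
    make_doc("PMC1", body_text = "pfam PF00001",
             supp = list("a.txt" = "pfam PF00002")),
    make_doc("PMC2", body_text = "no citations here",
             supp = list("b.txt" = "also none")),
    make_doc("PMC3", body_text = "omim number 123456")
  )
  res <- annotate_corpus(docs)
  bd <- corpus_breakdown(docs, res$annotations)
  expect_equal(bd$n_articles_total, 3L)
  expect_equal(bd$n_with_mineable_supp, 2L)
  expect_equal(bd$n_files_mineable, 2L)
  expect_equal(bd$n_files_supp_cited, 1L)
  expect_equal(bd$n_body_cited, 2L)
  expect_equal(bd$n_both_body_and_supp, 1L)
  expect_equal(bd$pct_with_mineable_supp,
               accminer:::round_half_up(100 * 2 / 3))
  expect_equal(bd$pct_files_supp_cited, 50)

  # published corpus percentages recompute from stored counts
  cs <- corpus_summary_counts()
  pc <- function(q) {
    r <- cs[cs$quantity == q, ]
    100 * r$count / r$denominator
  }
  expect_equal(round(pc("articles_with_mineable_supp"), 1), 16.8)
  expect_equal(accminer:::round_half_up(pc("files_supp_cited")), 4.77)
  expect_equal(accminer:::round_half_up(pc("articles_both_body_and_supp")),
               0.82)
})

test_that("yearly averages cover articles with mineable supplementary data", {
  docs <- list(
    make_doc("PMC1", body_text = "pfam PF00001 and pfam PF00002",
             supp = list("a.txt" = "x"), pub_year = 2005L),
    make_doc("PMC2", body_text = "pfam PF00003 pfam PF00004 pfam PF00005 pfam PF00006",
             supp = list("b.txt" = "x"), pub_year = 2005L),
    # no mineable supp: excluded from the yearly series
    make_doc("PMC3", body_text = "pfam PF00007", pub_year = 2005L)
  )
  res <- annotate_corpus(docs)
  ya <- yearly_averages(docs, res$annotations)
  expect_equal(ya$year, 2005L)
  expect_equal(ya$n_articles, 2L)
  expect_equal(ya$mean_body, 3)   # counts {2, 4}
  expect_equal(ya$mean_supp, 0)

  # excluding the only cited database zeroes the body means
  ya2 <- yearly_averages(docs, res$annotations, exclude_db = "Pfam")
  expect_equal(ya2$mean_body, 0)
  expect_error(yearly_averages(docs, res$annotations, exclude_db = "Foo"),
               "unknown database")
})
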