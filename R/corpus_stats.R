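# Corpus-level citation statistics: body vs supplementary distributions,
# shared citations, top-fraction concentration, corpus breakdown and yearly
# averages.
#
# Counting conventions: distribution counts are mention-level (every
# accepted span counts once); shared citations are unique
# (db, normalized accession) pairs present in both the body and at least
# one supplementary file of the same article.

is_supp <- function(section) startsWith(section, "SUPP:")

#' Derive ratio and shared-percentage columns from citation counts
#'
#' Given per-database supplementary, body and shared counts, computes the
#' supplementary/body ratio and the shared percentage
#' (100 * shared / supplementary). Works on any count table, including
#' published reference counts.
#'
#' @param counts Tibble with columns `db`, `supp_count`, `body_count`,
#'   `shared_count`.
#' @return The input with `ratio`, `shared_pct` (rounded half-up to two
#'   decimals) and `ratio_raw`, `shared_pct_raw` columns appended. A zero
#'   body count yields an undefined (`NA`) ratio, not infinity.
#' @export
derive_citation_stats <- function(counts) {
  ratio_raw <- ifelse(counts$body_count > 0,
                      counts$supp_count / counts$body_count, NA_real_)
  shared_raw <- ifelse(counts$supp_count > 0,
                       100 * counts$shared_count / counts$supp_count,
                       NA_real_)
  dplyr::mutate(
    counts,
    ratio = round_half_up(ratio_raw),
    shared_pct = round_half_up(shared_raw),
    ratio_raw = ratio_raw,
    shared_pct_raw = shared_raw
  )
}

#' Per-database citation distribution
#'
#' One row per database: total mention counts in supplementary data and in
#' article bodies, their ratio, and shared citations — unique
#' (db, accession) pairs occurring in both the body and the supplementary
#' data of the same article, summed over articles — with the shared
#' percentage taken against the supplementary count.
#'
#' @param annotations Pooled annotation tibble with `article_id`,
#'   `section`, `db`, `normalized_accession` (e.g. from
#'   [annotate_corpus()]).
#' @param dbs Databases to report (default: the full registry, so absent
#'   databases appear with zero counts).
#' @return Tibble of per-database rows (see [derive_citation_stats()] for
#'   the derived columns), ordered by descending raw ratio.
#' @export
citation_distribution <- function(annotations, dbs = db_registry()$db) {
  base <- tibble::tibble(db = dbs)
  if (nrow(annotations) == 0L) {
    counts <- dplyr::mutate(base, supp_count = 0L, body_count = 0L,
                            shared_count = 0L)
    return(derive_citation_stats(counts))
  }
  supp <- annotations[is_supp(annotations$section), , drop = FALSE]
  body <- annotations[annotations$section == "BODY", , drop = FALSE]
  mention_counts <- function(x, col) {
    out <- dplyr::count(x, .data$db, name = col)
    out
  }
  shared <- dplyr::inner_join(
    dplyr::distinct(body[, c("article_id", "db", "normalized_accession")]),
    dplyr::distinct(supp[, c("article_id", "db", "normalized_accession")]),
    by = c("article_id", "db", "normalized_accession")
  ) |>
    dplyr::count(.data$db, name = "shared_count")
  counts <- base |>
    dplyr::left_join(mention_counts(supp, "supp_count"), by = "db") |>
    dplyr::left_join(mention_counts(body, "body_count"), by = "db") |>
    dplyr::left_join(shared, by = "db") |>
    dplyr::mutate(dplyr::across(
      c("supp_count", "body_count", "shared_count"),
      ~ tidyr::replace_na(.x, 0L)
    ))
  out <- derive_citation_stats(counts)
  out[order(-ifelse(is.na(out$ratio_raw), -Inf, out$ratio_raw), out$db), ,
      drop = FALSE]
}

#' Concentration of supplementary citations in the top articles
#'
#' Among articles with at least one supplementary citation of the given
#' database, ranks articles by their supplementary mention count
#' (descending, ties broken by article identifier) and reports what
#' percentage of the database's supplementary citations fall in the top
#' `fraction` of those articles (top `ceiling(fraction * n)` articles).
#'
#' @param annotations Pooled annotation tibble.
#' @param db_id Database identifier.
#' @param fraction Fraction of articles in (0, 1]; default 0.05.
#' @return Tibble with `db`, `n_articles`, `fraction`, `pct_in_top`.
#' @export
top_fraction_concentration <- function(annotations, db_id,
                                       fraction = 0.05) {
  stopifnot(length(fraction) == 1L, fraction > 0, fraction <= 1)
  supp <- annotations[is_supp(annotations$section) &
                        annotations$db == db_id, , drop = FALSE]
  if (nrow(supp) == 0L) {
    stop("no supplementary citations for database ", db_id, call. = FALSE)
  }
  per_article <- dplyr::count(supp, .data$article_id, name = "n")
  per_article <- per_article[order(-per_article$n, per_article$article_id), ,
                             drop = FALSE]
  n_articles <- nrow(per_article)
  n_top <- ceiling(fraction * n_articles)
  tibble::tibble(
    db = db_id,
    n_articles = n_articles,
    fraction = fraction,
    pct_in_top = 100 * sum(per_article$n[seq_len(n_top)]) /
      sum(per_article$n)
  )
}

#' Corpus-level breakdown counts and percentages
#'
#' Computes the corpus summary: how many articles have mineable
#' supplementary data, how many article bodies contain database citations,
#' how many mineable supplementary files contain citations, and how many
#' articles cite databases in both body and supplementary data —
#' each with the percentage against its denominator (total articles for
#' article-level counts, mineable files for the file-level count).
#'
#' @param docs List of document records (post-triage).
#' @param annotations Pooled annotation tibble for these documents.
#' @return One-row tibble of counts (`n_*`) and percentages (`pct_*`,
#'   rounded half-up to two decimals).
#' @export
corpus_breakdown <- function(docs, annotations) {
  n_total <- length(docs)
  mineable_per_doc <- vapply(docs, function(d) {
    sum(d$supp_manifest$triage == "mineable", na.rm = TRUE)
  }, integer(1))
  n_with_supp <- sum(mineable_per_doc > 0L)
  n_files_mineable <- sum(mineable_per_doc)

  if (nrow(annotations) > 0L) {
    body_articles <- unique(
      annotations$article_id[annotations$section == "BODY"]
    )
    supp_rows <- annotations[is_supp(annotations$section), , drop = FALSE]
    supp_articles <- unique(supp_rows$article_id)
    n_files_cited <- nrow(dplyr::distinct(
      supp_rows[, c("article_id", "section")]
    ))
    n_both <- length(intersect(body_articles, supp_articles))
    n_body_cited <- length(body_articles)
  } else {
    n_files_cited <- 0L
    n_both <- 0L
    n_body_cited <- 0L
  }
  pct <- function(num, den) {
    if (den > 0) round_half_up(100 * num / den) else NA_real_
  }
  tibble::tibble(
    n_articles_total = n_total,
    n_with_mineable_supp = n_with_supp,
    n_files_mineable = n_files_mineable,
    n_files_supp_cited = n_files_cited,
    n_body_cited = n_body_cited,
    n_both_body_and_supp = n_both,
    pct_with_mineable_supp = pct(n_with_supp, n_total),
    pct_files_supp_cited = pct(n_files_cited, n_files_mineable),
    pct_body_cited = pct(n_body_cited, n_total),
    pct_both_body_and_supp = pct(n_both, n_total)
  )
}

#' Published corpus summary counts
#'
#' Reference article/file counts from the open-access full-text corpus
#' analysis this package's statistics mirror, for recomputing the derived
#' percentages (e.g. articles with mineable supplementary data out of all
#' articles).
#'
#' @return Tibble with `quantity`, `count`, `denominator`.
#' @export
corpus_summary_counts <- function() {
  path <- system.file("extdata", "corpus_summary.tsv",
                      package = "accminer", mustWork = TRUE)
  readr::read_tsv(path, col_types = "cii", progress = FALSE)
}

#' Published per-database citation counts
#'
#' Reference supplementary/body/shared citation counts per database from
#' the same corpus analysis; [derive_citation_stats()] recomputes the
#' ratio and shared-percentage columns from them.
#'
#' @return Tibble with `db`, `supp_count`, `body_count`, `shared_count`.
#' @export
citation_counts <- function() {
  path <- system.file("extdata", "citation_counts.tsv",
                      package = "accminer", mustWork = TRUE)
  readr::read_tsv(path, col_types = "ciii", progress = FALSE)
}

#' Yearly average citations per article
#'
#' Over articles that have at least one mineable supplementary file,
#' reports for each publication year the mean number of body mentions per
#' article and the mean number of supplementary mentions per article.
#' Databases can be excluded (e.g. to inspect a trend with and without the
#' dominant nucleotide archive).
#'
#' @param docs List of document records (post-triage, with `pub_year`).
#' @param annotations Pooled annotation tibble.
#' @param exclude_db Optional character vector of databases whose mentions
#'   are ignored; unknown identifiers are an error.
#' @return Tibble with `year`, `n_articles`, `mean_body`, `mean_supp`.
#' @export
yearly_averages <- function(docs, annotations, exclude_db = NULL) {
  if (!is.null(exclude_db)) {
    unknown <- setdiff(exclude_db, db_registry()$db)
    if (length(unknown) > 0L) {
      stop("unknown database: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    annotations <- annotations[!annotations$db %in% exclude_db, ,
                               drop = FALSE]
  }
  info <- tibble::tibble(
    article_id = vapply(docs, `[[`, character(1), "article_id"),
    year = vapply(docs, function(d) as.integer(d$pub_year %||% NA),
                  integer(1)),
    has_mineable = vapply(docs, function(d) {
      any(d$supp_manifest$triage == "mineable", na.rm = TRUE)
    }, logical(1))
  )
  info <- info[info$has_mineable & !is.na(info$year), , drop = FALSE]
  if (nrow(info) == 0L) {
    return(tibble::tibble(year = integer(), n_articles = integer(),
                          mean_body = double(), mean_supp = double()))
  }
  per_article <- annotations |>
    dplyr::filter(.data$article_id %in% info$article_id) |>
    dplyr::group_by(.data$article_id) |>
    dplyr::summarise(
      body = sum(.data$section == "BODY"),
      supp = sum(is_supp(.data$section)),
      .groups = "drop"
    )
  info |>
    dplyr::left_join(per_article, by = "article_id") |>
    dplyr::mutate(dplyr::across(c("body", "supp"),
                                ~ tidyr::replace_na(.x, 0L))) |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(
      n_articles = dplyr::n(),
      mean_body = mean(.data$body),
      mean_supp = mean(.data$supp),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$year)
}

#' Write a citation-distribution report TSV
#'
#' @param stats Output of [citation_distribution()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_citation_report <- function(stats, path) {
  out <- stats[, c("db", "supp_count", "body_count", "ratio",
                   "shared_count", "shared_pct")]
  readr::write_tsv(out, path, na = "")
  invisible(path)
}

#' Write a top-fraction concentration report TSV
#'
#' @param annotations Pooled annotation tibble.
#' @param path Output path.
#' @param fraction Top fraction (default 0.05).
#' @return The report tibble, invisibly.
#' @export
write_concentration_report <- function(annotations, path, fraction = 0.05) {
  dbs <- sort(unique(
    annotations$db[is_supp(annotations$section)]
  ))
  rows <- lapply(dbs, function(db) {
    top_fraction_concentration(annotations, db, fraction)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(db = character(), n_articles = integer(),
                          fraction = double(), pct_in_top = double())
  }
  out$pct_in_top <- round_half_up(out$pct_in_top)
  readr::write_tsv(out, path, na = "")
  invisible(out)
}
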