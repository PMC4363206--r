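# Scoring predicted annotations against gold standards.
#
# Granularity is the unique (db, normalized accession) pair per article:
# publisher-supplied gold annotations are identifier-level, not span-level.
# Metrics are percentages; the reported values are rounded half-up to two
# decimals while unrounded values are retained for derived quantities.

#' Read a gold-standard table
#'
#' @param path TSV with columns `article_id`, `db`, `accession`.
#' @param registry Registry used to warn about accessions that are not
#'   pattern-conformant for their database (they are kept).
#' @return Tibble of unique `(article_id, db, accession)` rows with
#'   accessions upper-case normalized.
#' @export
read_gold <- function(path, registry = db_registry()) {
  gold <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  stopifnot(all(c("article_id", "db", "accession") %in% names(gold)))
  as_gold(gold, registry)
}

#' Coerce a data frame to a gold standard
#'
#' @param gold Data frame with `article_id`, `db`, `accession`.
#' @inheritParams read_gold
#' @return Normalized, de-duplicated gold tibble.
#' @export
as_gold <- function(gold, registry = db_registry()) {
  out <- tibble::tibble(
    article_id = as.character(gold$article_id),
    db = as.character(gold$db),
    normalized_accession = vapply(
      seq_len(nrow(gold)),
      function(i) normalize_accession(gold$db[i],
                                      as.character(gold$accession[i])),
      character(1)
    )
  )
  for (db in unique(out$db)) {
    idx <- out$db == db
    bad <- !acc_conforms(db, out$normalized_accession[idx], registry)
    if (any(bad)) {
      warning(sum(bad), " gold accession(s) for ", db,
              " are not pattern-conformant (kept)", call. = FALSE)
    }
  }
  dplyr::distinct(out)
}

#' Confusion counts from predictions and gold
#'
#' Compares unique `(db, normalized_accession)` pairs per article:
#' `tp = |pred ∩ gold|`, `fp = |pred \\ gold|`, `fn = |gold \\ pred|`,
#' summed over articles. Articles present in the predictions but absent
#' from the gold standard are scored against an empty gold set, with a
#' warning.
#'
#' @param predicted Tibble of unique pairs with columns `article_id`,
#'   `db`, `normalized_accession` (e.g. `supp_pairs`/`body_pairs` from
#'   [annotate_document()], or any annotation tibble — it is de-duplicated).
#' @param gold Gold tibble from [read_gold()]/[as_gold()].
#' @return List of class `confusion_counts` with `tp`, `fp`, `fn`.
#' @export
align_to_gold <- function(predicted, gold) {
  cols <- c("article_id", "db", "normalized_accession")
  stopifnot(all(cols %in% names(predicted)), all(cols %in% names(gold)))
  pred <- dplyr::distinct(predicted[, cols])
  gold <- dplyr::distinct(gold[, cols])
  extra <- setdiff(unique(pred$article_id), unique(gold$article_id))
  if (length(extra) > 0L) {
    warning(length(extra), " predicted article(s) absent from gold; ",
            "scored against an empty gold set", call. = FALSE)
  }
  key <- function(x) paste(x$article_id, x$db, x$normalized_accession,
                           sep = "\t")
  pk <- key(pred)
  gk <- key(gold)
  confusion_counts(
    tp = sum(pk %in% gk),
    fp = sum(!pk %in% gk),
    fn = sum(!gk %in% pk)
  )
}

#' Construct confusion counts
#'
#' @param tp,fp,fn Non-negative integer counts of true positives, false
#'   positives and false negatives.
#' @return List of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn)),
            class = "confusion_counts")
}

#' Reclassify false positives as true positives after manual review
#'
#' Manual inspection of automatic false positives can show that the
#' article's own (gold) annotation was incomplete and the prediction was
#' in fact correct; each reviewed item then moves from `fp` to `tp`.
#'
#' @param counts `confusion_counts`.
#' @param n_reassign Number of reviewed false positives to reclassify.
#' @return Updated `confusion_counts`.
#' @export
apply_manual_overrides <- function(counts, n_reassign) {
  stopifnot(inherits(counts, "confusion_counts"),
            n_reassign >= 0)
  if (n_reassign > counts$fp) {
    stop("cannot reassign ", n_reassign, " items: only ", counts$fp,
         " false positives", call. = FALSE)
  }
  confusion_counts(counts$tp + n_reassign, counts$fp - n_reassign,
                   counts$fn)
}

round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Precision, recall and F-score from confusion counts
#'
#' `precision = 100 tp / (tp + fp)`, `recall = 100 tp / (tp + fn)`, and
#' the F-score is the harmonic mean `2PR/(P + R)` (0 when both are 0).
#' All three are percentages; reported values are rounded half-up to two
#' decimals, with the unrounded values kept alongside.
#'
#' @param counts `confusion_counts` with `tp + fp > 0` or `tp + fn > 0`.
#' @return Tibble with one row: `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f_score` (rounded) and `precision_raw`, `recall_raw`, `f_score_raw`.
#' @examples
#' score(confusion_counts(tp = 276, fp = 10, fn = 170))
#' @export
score <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  if (tp + fp == 0L && tp + fn == 0L) {
    stop("undefined metrics: tp, fp and fn are all zero", call. = FALSE)
  }
  p <- if (tp + fp > 0L) 100 * tp / (tp + fp) else 0
  r <- if (tp + fn > 0L) 100 * tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  tibble::tibble(
    tp = tp, fp = fp, fn = fn,
    precision = round_half_up(p), recall = round_half_up(r),
    f_score = round_half_up(f),
    precision_raw = p, recall_raw = r, f_score_raw = f
  )
}

#' Bundled benchmark confusion counts
#'
#' Published true/false positive and false negative counts for the ENA,
#' UniProt and PDBe gold-standard evaluations of the accession annotator,
#' for the new and old tool settings under both the automatic protocol
#' (publisher-supplied annotations taken as gold) and the manual protocol
#' (false positives reviewed and reclassified). [score()] recomputes the
#' corresponding precision/recall/F table from these counts.
#'
#' @return Tibble with columns `db`, `evaluation` (`automatic`/`manual`),
#'   `version` (`new`/`old`), `tp`, `fp`, `fn`.
#' @export
benchmark_counts <- function() {
  path <- system.file("extdata", "benchmark_counts.tsv",
                      package = "accminer", mustWork = TRUE)
  readr::read_tsv(path, col_types = "ccciii", progress = FALSE)
}

#' Score a table of confusion counts
#'
#' @param counts_table Tibble with `tp`, `fp`, `fn` columns plus any
#'   identifying columns, e.g. [benchmark_counts()].
#' @return The identifying columns joined with the [score()] metrics,
#'   one row per input row.
#' @export
score_table <- function(counts_table) {
  metrics <- lapply(seq_len(nrow(counts_table)), function(i) {
    score(confusion_counts(counts_table$tp[i], counts_table$fp[i],
                           counts_table$fn[i]))
  })
  id_cols <- setdiff(names(counts_table), c("tp", "fp", "fn"))
  dplyr::bind_cols(counts_table[, id_cols, drop = FALSE],
                   dplyr::bind_rows(metrics))
}
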