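# Ground-truthed synthetic corpus generator.
#
# Emits JATS-style article XML plus sibling supplementary files whose
# planted accession mentions (with or without licensing cues), decoy
# tokens and non-mineable files exercise exactly the mechanisms the
# annotator implements: pattern matching, cue gating within a window,
# triage. Planted mentions live in their own text block; blocks are
# separated by a cue-free filler longer than the default cue window, so a
# cue can only ever license the mention it was planted with.

FILLER_SENTENCE <- paste(
  "the measured values were consistent across replicates and the",
  "observed trends agreed with earlier reports from independent",
  "laboratories under comparable experimental conditions ."
)

# > default cue window (300), contains no cue words and no
# pattern-conformant tokens (lower case, no digits)
filler_block <- function() {
  paste(rep(FILLER_SENTENCE, 2L), collapse = " ")
}

#' Synthetic corpus configuration
#'
#' Defines the generated study conditions: per-database expected mention
#' counts per article (Poisson), cue placement probability, decoy rate,
#' the supplementary format mix (including non-mineable media and
#' source-code files), the probability that a body citation is repeated in
#' a supplementary file, and an optional heavy tail that concentrates
#' supplementary citations in occasional data-dump articles.
#'
#' @param n_articles Number of articles.
#' @param year_range Inclusive publication-year range.
#' @param body_rate,supp_rate Expected mentions per article per database;
#'   scalar or named per-database vector.
#' @param cue_prob Probability a planted mention has a licensing cue in
#'   its block.
#' @param decoy_rate Expected pattern-conformant decoy tokens (no cue) per
#'   article per database, split evenly between body and supplementary
#'   text.
#' @param format_mix Named fractions over `txt`, `tsv`, `html`, `media`,
#'   `source_code` for supplementary files beyond the first (which is
#'   always mineable); must sum to 1.
#' @param shared_prob Probability each unique body citation is repeated in
#'   a supplementary file.
#' @param heavy_tail_every Every k-th article is a data dump
#'   (supplementary counts scaled by `heavy_tail_factor`); 0 disables.
#' @param heavy_tail_factor Scale factor for data-dump articles.
#' @param seed Integer seed; fixed seed gives byte-identical corpora.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(n_articles = 100,
                         year_range = c(1995, 2014),
                         body_rate = 0.5,
                         supp_rate = 2,
                         cue_prob = 1,
                         decoy_rate = 0.2,
                         format_mix = c(txt = 0.35, tsv = 0.25,
                                        html = 0.15, media = 0.15,
                                        source_code = 0.10),
                         shared_prob = 0.1,
                         heavy_tail_every = 0,
                         heavy_tail_factor = 50,
                         seed = 1) {
  dbs <- db_registry()$db
  expand_rate <- function(rate, what) {
    if (length(rate) == 1L && is.null(names(rate))) {
      rate <- setNames(rep(rate, length(dbs)), dbs)
    }
    if (!all(dbs %in% names(rate))) {
      stop(what, " must be a scalar or name every database", call. = FALSE)
    }
    rate <- rate[dbs]
    if (any(rate < 0)) stop(what, " must be >= 0", call. = FALSE)
    rate
  }
  if (n_articles < 0) stop("n_articles must be >= 0", call. = FALSE)
  if (cue_prob < 0 || cue_prob > 1) {
    stop("cue_prob must be in [0, 1]", call. = FALSE)
  }
  if (shared_prob < 0 || shared_prob > 1) {
    stop("shared_prob must be in [0, 1]", call. = FALSE)
  }
  if (any(decoy_rate < 0)) stop("decoy_rate must be >= 0", call. = FALSE)
  if (!setequal(names(format_mix),
                c("txt", "tsv", "html", "media", "source_code")) ||
      abs(sum(format_mix) - 1) > 1e-8 || any(format_mix < 0)) {
    stop("format_mix must be non-negative fractions over ",
         "txt/tsv/html/media/source_code summing to 1", call. = FALSE)
  }
  structure(
    list(
      n_articles = as.integer(n_articles),
      year_range = as.integer(year_range),
      body_rate = expand_rate(body_rate, "body_rate"),
      supp_rate = expand_rate(supp_rate, "supp_rate"),
      cue_prob = cue_prob,
      decoy_rate = expand_rate(decoy_rate, "decoy_rate"),
      format_mix = format_mix[c("txt", "tsv", "html", "media",
                                "source_code")],
      shared_prob = shared_prob,
      heavy_tail_every = as.integer(heavy_tail_every),
      heavy_tail_factor = heavy_tail_factor,
      seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

rand_digits <- function(n) {
  paste(sample(0:9, n, replace = TRUE), collapse = "")
}

rand_letters <- function(n, pool = LETTERS) {
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

#' Sample an accession from a database's pattern language
#'
#' Draws a string uniformly at random from one of the database's
#' extraction patterns; the result always passes [acc_conforms()].
#'
#' @param db_id Database identifier.
#' @return A single accession string.
#' @export
sample_accession <- function(db_id) {
  alnum <- c(LETTERS, 0:9)
  switch(
    db_id,
    ENA = {
      k <- sample.int(5, 1)
      switch(k,
        paste0(rand_letters(1), rand_digits(5)),
        paste0(rand_letters(2), rand_digits(6)),
        paste0(rand_letters(3), rand_digits(5)),
        paste0(rand_letters(4), rand_digits(sample(8:10, 1))),
        paste0(rand_letters(5), rand_digits(7))
      )
    },
    UniProt = {
      if (sample.int(2, 1) == 1L) {
        paste0(rand_letters(1, setdiff(LETTERS, c("O", "P", "Q"))),
               rand_digits(1), rand_letters(1), rand_letters(2, alnum),
               rand_digits(1))
      } else {
        paste0(rand_letters(1, c("O", "P", "Q")), rand_digits(1),
               rand_letters(3, alnum), rand_digits(1))
      }
    },
    PDBe = paste0(rand_digits(1), rand_letters(3, alnum)),
    InterPro = paste0("IPR", rand_digits(6)),
    Pfam = paste0("PF", if (sample.int(2, 1) == 1L) "AM" else "",
                  rand_digits(5)),
    ArrayExpress = paste0("E-", rand_letters(4), "-",
                          rand_digits(sample(1:6, 1))),
    OMIM = rand_digits(6),
    Ensembl = paste0("ENS", rand_letters(sample(0:3, 1)), "G",
                     rand_digits(11)),
    RefSeq = {
      prefix <- sample(c("AC", "AP", "NC", "NG", "NM", "NP", "NR", "NT",
                         "NW", "NZ", "XM", "XP", "XR", "YP", "ZP", "NS"), 1)
      version <- if (sample.int(10, 1) <= 3L) {
        paste0(".", sample(1:9, 1))
      } else {
        ""
      }
      paste0(prefix, "_", rand_digits(sample(6:9, 1)), version)
    },
    RefSNP = paste0("RS", rand_digits(sample(5:9, 1))),
    stop("unknown database: ", db_id, call. = FALSE)
  )
}

cue_for <- function(registry, db_id) {
  cues <- db_entry(registry, db_id)$cues[[1]]
  cues[sample.int(length(cues), 1)]
}

mention_block <- function(db_id, accession, has_cue, registry) {
  if (has_cue) {
    paste("records retrieved from", cue_for(registry, db_id),
          "include the entry", accession, "in this collection .")
  } else {
    paste("the identifier", accession,
          "appears here without any nearby context .")
  }
}

decoy_block <- function(accession) {
  paste("an incidental token", accession,
        "occurs in running text with no context .")
}

# Draw planted mentions for one article section.
draw_mentions <- function(rates, cue_prob, registry) {
  rows <- list()
  for (db in names(rates)) {
    n <- rpois(1, rates[[db]])
    if (n == 0L) next
    for (k in seq_len(n)) {
      rows[[length(rows) + 1L]] <- list(
        db = db, accession = sample_accession(db),
        has_cue = runif(1) < cue_prob
      )
    }
  }
  rows
}

draw_decoys <- function(rates) {
  rows <- list()
  for (db in names(rates)) {
    n <- rpois(1, rates[[db]])
    if (n == 0L) next
    for (k in seq_len(n)) {
      rows[[length(rows) + 1L]] <- list(db = db,
                                        accession = sample_accession(db))
    }
  }
  rows
}

render_supp_file <- function(blocks, format) {
  sep <- filler_block()
  switch(
    format,
    txt = paste(c(rbind(blocks, sep)), collapse = "\n"),
    tsv = paste(c("label\tvalue",
                  c(rbind(gsub(" ", "\t", blocks, fixed = TRUE),
                          gsub(" ", "\t", sep, fixed = TRUE)))),
                collapse = "\n"),
    html = paste0("<html><body>",
                  paste0("<p>", c(rbind(blocks, sep)), "</p>",
                         collapse = ""),
                  "</body></html>"),
    stop("unrenderable format: ", format, call. = FALSE)
  )
}

supp_file_meta <- function(format, article_id, index) {
  base <- paste0(article_id, "_S", index)
  switch(
    format,
    txt = list(filename = paste0(base, ".txt"), mime = "text",
               subtype = "plain"),
    tsv = list(filename = paste0(base, ".tsv"), mime = "text",
               subtype = "tab-separated-values"),
    html = list(filename = paste0(base, ".html"), mime = "text",
                subtype = "html"),
    media = list(filename = paste0(base, ".png"), mime = "image",
                 subtype = "png"),
    source_code = list(filename = paste0(base, ".py"), mime = "text",
                       subtype = "x-python")
  )
}

article_xml <- function(article_id, year, body_text, supp_meta) {
  supp_elems <- vapply(supp_meta, function(m) {
    sprintf(
      paste0('<supplementary-material href="%s" mimetype="%s" ',
             'mime-subtype="%s"/>'),
      m$filename, m$mime, m$subtype
    )
  }, character(1))
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    "<article>\n<front>\n",
    '<article-id pub-id-type="pmcid">', article_id, "</article-id>\n",
    "<pub-date><year>", year, "</year></pub-date>\n",
    "</front>\n<body>\n<p>", body_text, "</p>\n",
    paste(supp_elems, collapse = "\n"),
    "\n</body>\n</article>\n"
  )
}

#' Generate a synthetic corpus with ground truth
#'
#' Writes one JATS-style XML file per article into `dir` and the
#' supplementary files into `dir/supp/`, and returns (and writes as
#' `ground_truth.tsv`) the table of planted mentions. Decoy tokens and
#' non-mineable files are emitted but never appear in the ground truth
#' with `has_cue = TRUE`. Deterministic for a fixed `config$seed`.
#'
#' @param config [synth_config()].
#' @param dir Output directory (created if needed).
#' @return List with `dir`, `truth` (tibble `article_id`, `section`, `db`,
#'   `accession`, `has_cue`) and `config`, invisibly classed
#'   `synth_corpus`.
#' @export
generate_corpus <- function(config = synth_config(), dir = tempfile()) {
  stopifnot(inherits(config, "synth_config"))
  registry <- db_registry()
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  supp_dir <- file.path(dir, "supp")
  dir.create(supp_dir, showWarnings = FALSE)
  set.seed(config$seed)
  truth <- list()
  formats <- names(config$format_mix)

  for (i in seq_len(config$n_articles)) {
    article_id <- sprintf("PMC%07d", i)
    year <- if (config$year_range[1] == config$year_range[2]) {
      config$year_range[1]
    } else {
      sample(config$year_range[1]:config$year_range[2], 1)
    }

    supp_scale <- if (config$heavy_tail_every > 0L &&
                        i %% config$heavy_tail_every == 0L) {
      config$heavy_tail_factor
    } else {
      1
    }

    # ---- body ----
    body_mentions <- draw_mentions(config$body_rate, config$cue_prob,
                                   registry)
    body_decoys <- draw_decoys(config$decoy_rate / 2)
    body_blocks <- character(0)
    for (m in body_mentions) {
      body_blocks <- c(body_blocks,
                       mention_block(m$db, m$accession, m$has_cue, registry))
      truth[[length(truth) + 1L]] <- list(
        article_id = article_id, section = "BODY", db = m$db,
        accession = m$accession, has_cue = m$has_cue
      )
    }
    for (d in body_decoys) {
      body_blocks <- c(body_blocks, decoy_block(d$accession))
    }
    body_text <- paste(c(rbind(c(body_blocks, ""), filler_block())),
                       collapse = " ")

    # ---- supplementary files ----
    n_files <- 1L + rpois(1, 1)
    file_formats <- c(
      sample(c("txt", "tsv", "html"), 1,
             prob = pmax(config$format_mix[c("txt", "tsv", "html")],
                         1e-9)),
      if (n_files > 1L) {
        sample(formats, n_files - 1L, replace = TRUE,
               prob = pmax(config$format_mix, 1e-9))
      }
    )
    mineable_idx <- which(file_formats %in% c("txt", "tsv", "html"))
    metas <- lapply(seq_along(file_formats), function(j) {
      supp_file_meta(file_formats[j], article_id, j)
    })
    file_blocks <- vector("list", length(file_formats))

    supp_mentions <- draw_mentions(config$supp_rate * supp_scale,
                                   config$cue_prob, registry)
    supp_decoys <- draw_decoys(config$decoy_rate / 2)
    # body citations repeated in supplementary data (shared citations)
    if (config$shared_prob > 0 && length(body_mentions) > 0L) {
      seen <- character(0)
      for (m in body_mentions) {
        key <- paste(m$db, m$accession)
        if (key %in% seen) next
        seen <- c(seen, key)
        if (runif(1) < config$shared_prob) {
          supp_mentions[[length(supp_mentions) + 1L]] <-
            list(db = m$db, accession = m$accession,
                 has_cue = runif(1) < config$cue_prob)
        }
      }
    }

    for (m in supp_mentions) {
      j <- mineable_idx[sample.int(length(mineable_idx), 1)]
      file_blocks[[j]] <- c(file_blocks[[j]],
                            mention_block(m$db, m$accession, m$has_cue,
                                          registry))
      truth[[length(truth) + 1L]] <- list(
        article_id = article_id,
        section = paste0("SUPP:", metas[[j]]$filename),
        db = m$db, accession = m$accession, has_cue = m$has_cue
      )
    }
    for (d in supp_decoys) {
      j <- mineable_idx[sample.int(length(mineable_idx), 1)]
      file_blocks[[j]] <- c(file_blocks[[j]], decoy_block(d$accession))
    }

    for (j in seq_along(file_formats)) {
      path <- file.path(supp_dir, metas[[j]]$filename)
      content <- switch(
        file_formats[j],
        media = "not a text file",
        source_code = paste("def main():", "    return None", sep = "\n"),
        render_supp_file(file_blocks[[j]] %||% character(0),
                         file_formats[j])
      )
      if (length(file_blocks[[j]]) == 0L &&
          file_formats[j] %in% c("txt", "tsv", "html")) {
        content <- render_supp_file(filler_block(), file_formats[j])
      }
      writeLines(content, path, useBytes = TRUE)
    }

    writeLines(article_xml(article_id, year, body_text, metas),
               file.path(dir, paste0(article_id, ".xml")),
               useBytes = TRUE)
  }

  truth <- if (length(truth) > 0L) {
    dplyr::bind_rows(truth)
  } else {
    tibble::tibble(article_id = character(), section = character(),
                   db = character(), accession = character(),
                   has_cue = logical())
  }
  readr::write_tsv(truth, file.path(dir, "ground_truth.tsv"))
  invisible(structure(list(dir = dir, truth = truth, config = config),
                      class = "synth_corpus"))
}

#' Ground truth as a gold standard
#'
#' Restricts the generator's ground truth to cue-licensed mentions (the
#' mentions the annotator is expected to accept) and converts it to the
#' unique-pair gold format used by [align_to_gold()].
#'
#' @param truth Ground-truth tibble from [generate_corpus()].
#' @param section Optional filter: `"BODY"`, `"SUPP"` (any supplementary
#'   section) or `NULL` for all sections.
#' @return Gold tibble of unique `(article_id, db, normalized_accession)`.
#' @export
truth_as_gold <- function(truth, section = NULL) {
  keep <- truth$has_cue
  if (!is.null(section)) {
    keep <- keep & if (section == "SUPP") {
      is_supp(truth$section)
    } else {
      truth$section == section
    }
  }
  t <- truth[keep, , drop = FALSE]
  tibble::tibble(
    article_id = t$article_id,
    db = t$db,
    normalized_accession = vapply(
      seq_len(nrow(t)),
      function(i) normalize_accession(t$db[i], t$accession[i]),
      character(1)
    )
  ) |> dplyr::distinct()
}
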