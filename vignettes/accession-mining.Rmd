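---
title: "Mining database accession numbers from articles and supplementary data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining database accession numbers from articles and supplementary data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accminer)
```

## The problem

Biomolecular databases assign stable accession numbers to their records —
`P09372` is a UniProt protein, `IPR000001` an InterPro domain family,
`rs12345` a RefSNP variant. When an article cites such a record, the
accession number in its text is the most reliable machine-actionable link
between the literature and the data. Publishers tag only a fraction of
these citations structurally, and supplementary data files — where authors
park complete result tables — are not indexed at all, so rule-based text
mining remains the practical way to recover the links at corpus scale.

`accminer` implements such a pipeline for ten databases: the submission
archives ENA, ArrayExpress and PDBe, and the added-value resources
UniProt, Pfam, RefSeq, RefSNP, Ensembl, OMIM and InterPro. It annotates
article bodies and supplementary files, evaluates the annotations against
gold standards, and computes corpus-level statistics on where data
citations live.

## The recognition model

Recognition is a two-stage rule system.

**Patterns.** Each database has one or more anchored regular expressions
describing its accession syntax (`db_registry()`). A candidate is a
maximal, word-bounded match: the characters flanking the span must not be
alphanumeric, so `IPR000001` matches inside punctuation but not inside
`xIPR000001`. Offsets are 0-based and half-open, computed on
whitespace-normalized text, so spans are reproducible across readers.

**Contextual cues.** Accession syntax is weak evidence on its own — an
OMIM identifier is any six-digit number, and a PDBe code is any
digit-plus-three-alphanumerics token. A candidate is therefore accepted
only if one of its database's cue words (`genbank`, `swissprot`, `pdb`,
`omim`, ...) occurs nearby. Two scopes are provided:

* `window` (default): the cue must lie within `cue_window` characters
  (default 300, each side) of the candidate span;
* `section`: the cue may occur anywhere in the same text section.

The window default mimics "contextual" licensing; section mode mimics
document-level presence. Neither is claimed to be the scope of the
original production system, which is not documented; both are exposed so
users can measure the difference. Cue matching is case-insensitive and
word-bounded, and a cue occurrence inside the candidate's own span never
licenses it (otherwise `E-PFAM-12345` would self-license via `pfam`).

**Overlap resolution.** Patterns of different databases collide —
`P09372` is simultaneously UniProt-shaped and ENA-shaped, and the digit
run inside `NM_123456` is OMIM-shaped. Overlapping candidates are resolved
deterministically: smallest cue distance first, then longest span, then a
fixed registry priority that ranks the most specific prefixes (Ensembl,
ArrayExpress, InterPro, Pfam, RefSeq, RefSNP) above the collision-prone
generic patterns (UniProt, ENA, OMIM, PDBe). Remaining ties break on
offset and database name, so `annotate_text()` is a pure function of its
input.

**Case policy.** The published patterns are upper-case. Prefix-keyed
identifiers are commonly written in lower case in running text
(`rs12345`, `pf00001`), so RefSNP, RefSeq, Ensembl, InterPro, Pfam and
ArrayExpress match case-insensitively and are normalized to upper case;
ENA, UniProt, PDBe and OMIM stay strictly upper-case to limit false
positives in prose. The Ensembl pattern is stored as
`ENS[A-Z]*G[0-9]{11}`; the published rendering carries a trailing `+`
that reads as a possessive quantifier, which is equivalent under
whole-token boundary anchoring. RefSeq accessions keep their version
suffix in the surface form but are normalized version-stripped, since
databases key on the versionless accession.

## Documents and triage

`parse_article_xml()` reads JATS-style XML: the body narrative (figure
and table text included, the reference list excluded — citation lists are
full of identifier-like tokens that are not data citations) and one
manifest entry per `<supplementary-material>` link with its declared MIME
type. Triage labels every entry exactly once:

1. `excluded_media` — MIME class image/audio/video;
2. `excluded_source_code` — extension in a configurable list
   (default `.c .cpp .h .py .pl .java .r .m .sh .js`); the rule is
   published, the list is not, so it is a config knob;
3. `mineable` — MIME class `text`, or a text-convertible extension
   (txt, csv, tsv, xml, html, pdf, doc, xls and variants);
4. `excluded_unconvertible` — everything else.

MIME is trusted over the extension when both are present and conflict,
because triage in the original pipeline was driven by the MIME attributes
on the file link. Built-in extractors cover TXT/CSV/TSV/HTML/XML; binary
formats route through user-registered adapter functions, and any failure
downgrades the file to `extraction_failed` instead of aborting the run.

## Validation

The original system validated candidate accessions against live database
search services. The core here is offline by design: a validator is any
function `(db, accession) -> valid/invalid/unknown`, with two built-ins —
a syntactic pass-through and a table-backed lookup against user-supplied
per-database accession lists. Validation happens after annotation (the
ordering in the original is undocumented), `unknown` maps to
`unvalidated`, and invalid annotations are dropped from downstream counts
by default. A failing backend leaves everything unvalidated with a
warning; a run never fails on validation.

## Evaluation

Scoring granularity is the unique (database, normalized accession) pair
per article — publisher-supplied gold annotations are identifier-level,
not span-level, and the published evaluation counts are far smaller than
mention counts. From `tp`, `fp`, `fn`:

$$P = 100\,\frac{tp}{tp+fp}, \qquad R = 100\,\frac{tp}{tp+fn}, \qquad
F = \frac{2PR}{P+R}$$

Reported values are rounded half-up to two decimals (matching the
published tables); unrounded values are kept alongside. The manual
protocol — reviewed false positives reclassified as true positives — is
`apply_manual_overrides()`, which refuses to reassign more items than
there are false positives.

## Corpus statistics

`citation_distribution()` counts **mentions** (every accepted span) per
database for bodies and supplementary files. Mention counting is this
package's declared convention: the published magnitudes (millions of
supplementary citations against thousands of contributing articles) are
only consistent with mentions, not unique accessions. Shared citations
are the exception — a shared citation is a unique pair present in both
the body and the supplementary data of the same article, because a string
cannot be "shared" twice — and the shared percentage is taken against the
supplementary count (verified against the published derived columns:
2,805/197,850 = 1.42%, 53/2,377 = 2.23%). A zero body count yields an
undefined ratio, not infinity.

`top_fraction_concentration()` ranks the articles that have at least one
supplementary citation of a database by their supplementary mention count
(ties broken by article identifier for determinism), takes the top
`ceiling(fraction * n)`, and reports the percentage of citations they
hold. `corpus_breakdown()` and `yearly_averages()` compute the
corpus-summary percentages and the per-year mean mentions per article,
the latter restricted to articles that have mineable supplementary data.

## The synthetic corpus

Real corpus numbers require hundreds of thousands of articles; the
generator (`synth_config()`, `generate_corpus()`) exists so that every
mechanism is testable at desk scale with known ground truth. It emulates:
per-database Poisson mention counts in body and supplementary text (the
defaults, 0.5 body and 2 supplementary mentions per database per article,
keep the supplementary-heavy asymmetry the corpus statistics are about);
cue licensing with probability `cue_prob`; pattern-conformant decoy
tokens planted in cue-free blocks; a mixed file manifest including
non-mineable media and source-code files; body citations re-planted in
supplementary files with probability `shared_prob`; and an optional
heavy-tail switch that turns every k-th article into a data dump to
emulate the observed concentration of citations in few articles.

Each planted mention lives in its own text block and blocks are separated
by a cue-free filler longer than the default cue window, so a cue can
only license the mention it was planted with. That makes ground truth
exact — and it is also what the generator deliberately does **not**
emulate about real prose: real cues sit at sentence distance from several
candidates at once, real decoys co-occur with unrelated cues, and real
supplementary tables put thousands of accessions under one header. A
perfect-recovery result on this generator therefore certifies the
machinery (patterns, gating, resolution, triage, counting), not the
field precision/recall of the rules, which only the published
gold-standard counts speak to.

Accession strings are sampled uniformly from each pattern language;
sampling is driven by R's RNG, and a fixed seed makes the emitted corpus
byte-identical across runs.

## Numerical and design choices

* Rounding is half-up at two decimals for all reported percentages,
  matching the published tables' convention (one published F-score cell,
  ENA manual/new, prints 77.10 where the harmonic mean of its own
  precision and recall gives 77.09; the package reports the computed
  value).
* Character classes printed with commas and spaces (`[A-Z, 0-9]`,
  `[A-N,R-Z]`) are read as plain classes; the punctuation is typography.
* Degenerate inputs: empty text gives an empty annotation set; all-zero
  confusion counts are an error ("undefined metrics"); a database with no
  supplementary citations is an error for concentration (there is no
  top slice of nothing); articles missing from the gold standard score
  against an empty gold set with a warning.
* Problem sizes in the test suite and acceptance script — 500-article
  corpora for recovery and rate checks, 10,000 fuzzed tokens per database
  for pattern-oracle equivalence — were chosen as the smallest sizes at
  which binomial/Poisson standard errors make the checks sharp (3
  standard errors on a 500-article corpus bounds a rate of 0.5 within
  ±0.095).

## Limitations

The extraction rules are the published ten-database set; no attempt is
made to extend coverage, to validate checksums (none are defined for
these identifier systems), or to disambiguate statistically. Sentence
structure is ignored — the cue window is a character window, not a
syntactic neighbourhood. PDF/DOC/XLS extraction is an adapter seam, not a
bundled capability. Corpus statistics reproduce the published *derived*
columns from the published counts; the absolute counts themselves require
the original open-access corpus and are out of scope.
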