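#' Locate gene mentions in segmented documents
#'
#' Exact, synonym-expanded dictionary matching. A match must be delimited by
#' token boundaries: the characters immediately before and after it may not
#' be ASCII letters, digits, or Greek letters (internal hyphens and dots in
#' dictionary terms match literally). Overlapping candidates are resolved by
#' the leftmost-longest rule; candidates sharing the exact same span (an
#' ambiguous term mapping to several genes) all survive, one mention per
#' gene.
#'
#' @param segments A `cooc_segments` tibble from [segment_corpus()].
#' @param index A `synonym_index` from [build_synonym_index()].
#' @return Tibble of mentions sorted by (`doc_id`, `paragraph`, `sentence`,
#'   `start`): columns `doc_id`, `paragraph`, `sentence`, `gene_id`,
#'   `surface`, `start`, `end` (1-based, end-exclusive, within the sentence).
#' @export
find_mentions <- function(segments, index) {
  stopifnot(inherits(index, "synonym_index"))
  empty <- tibble::tibble(doc_id = character(0), paragraph = integer(0),
                          sentence = integer(0), gene_id = character(0),
                          surface = character(0), start = integer(0),
                          end = integer(0))
  if (nrow(segments) == 0 || nrow(index) == 0) return(empty)
  case_sensitive <- attr(index, "case_sensitive")
  texts <- segments$text

  candidates <- purrr::imap(index$term, function(term, t_idx) {
    loc <- if (case_sensitive) {
      stringi::stri_locate_all_fixed(texts, term, omit_no_match = TRUE)
    } else {
      stringi::stri_locate_all_fixed(
        texts, term, omit_no_match = TRUE,
        opts_fixed = stringi::stri_opts_fixed(case_insensitive = TRUE))
    }
    hits <- purrr::imap(loc, function(m, row) {
      if (nrow(m) == 0) return(NULL)
      tibble::tibble(row = row, start = m[, 1], last = m[, 2])
    })
    hits <- dplyr::bind_rows(hits)
    if (nrow(hits) == 0) return(NULL)
    hits$term_idx <- t_idx
    hits
  })
  candidates <- dplyr::bind_rows(candidates)
  if (nrow(candidates) == 0) return(empty)

  # token-boundary filter
  boundary_ok <- function(text, pos) {
    ch <- stringr::str_sub(text, pos, pos)
    !stringr::str_detect(ch, "[A-Za-z0-9\\p{Greek}]")
  }
  txt <- texts[candidates$row]
  before_ok <- candidates$start == 1L | boundary_ok(txt, candidates$start - 1L)
  after_ok <- candidates$last == stringr::str_length(txt) |
    boundary_ok(txt, candidates$last + 1L)
  candidates <- candidates[before_ok & after_ok, , drop = FALSE]
  if (nrow(candidates) == 0) return(empty)

  # leftmost-longest resolution per sentence over distinct spans
  spans <- candidates |>
    dplyr::distinct(.data$row, .data$start, .data$last) |>
    dplyr::arrange(.data$row, .data$start, dplyr::desc(.data$last))
  keep <- logical(nrow(spans))
  cur_row <- -1L
  cur_end <- 0L
  for (i in seq_len(nrow(spans))) {
    if (spans$row[i] != cur_row) {
      cur_row <- spans$row[i]
      cur_end <- 0L
    }
    if (spans$start[i] > cur_end) {
      keep[i] <- TRUE
      cur_end <- spans$last[i]
    }
  }
  kept_spans <- spans[keep, , drop = FALSE]
  candidates <- dplyr::semi_join(candidates, kept_spans,
                                 by = c("row", "start", "last"))

  mentions <- candidates |>
    dplyr::mutate(gene_ids = index$gene_ids[.data$term_idx]) |>
    tidyr::unnest_longer("gene_ids", values_to = "gene_id") |>
    dplyr::mutate(
      doc_id = segments$doc_id[.data$row],
      paragraph = segments$paragraph[.data$row],
      sentence = segments$sentence[.data$row],
      surface = stringr::str_sub(texts[.data$row], .data$start, .data$last),
      end = as.integer(.data$last + 1L),
      start = as.integer(.data$start)
    ) |>
    dplyr::select("doc_id", "paragraph", "sentence", "gene_id", "surface",
                  "start", "end") |>
    dplyr::distinct() |>
    dplyr::arrange(.data$doc_id, .data$paragraph, .data$sentence,
                   .data$start, .data$gene_id)
  mentions
}

#' Genes found per document
#'
#' @param mentions Mention tibble from [find_mentions()].
#' @return Tibble (`doc_id`, `gene_id`), one row per distinct pair, sorted;
#'   only documents with at least one mention appear.
#' @export
genes_per_document <- function(mentions) {
  mentions |>
    dplyr::distinct(.data$doc_id, .data$gene_id) |>
    dplyr::arrange(.data$doc_id, .data$gene_id)
}

#' Write a mention dump as TSV
#'
#' @param mentions Mention tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mentions_tsv <- function(mentions, path) {
  readr::write_tsv(mentions[, c("doc_id", "paragraph", "sentence", "gene_id",
                                "surface", "start", "end")], path)
  invisible(path)
}
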