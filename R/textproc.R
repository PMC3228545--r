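#' Default protected-abbreviation list for sentence splitting
#'
#' Periods ending these tokens never split a sentence even when followed by
#' whitespace and a capital. Shipped as a plain-text config file in
#' `inst/extdata/abbreviations.txt`; one abbreviation per line.
#'
#' @return Character vector of abbreviations, each ending in a period.
#' @export
default_abbreviations <- function() {
  path <- system.file("extdata", "abbreviations.txt", package = "litcooc")
  if (nzchar(path)) {
    abb <- readr::read_lines(path)
    abb[nzchar(abb) & !stringr::str_starts(abb, "#")]
  } else {
    c("e.g.", "i.e.", "et al.", "al.", "cf.", "ca.", "vs.", "sp.", "spp.",
      "fig.", "figs.", "eq.", "ref.", "no.", "dr.", "prof.", "st.", "approx.")
  }
}

# sentence-terminal punctuation optionally followed by closing quotes/brackets
TERMINAL_RE <- "[.!?][\"')\\]]*"

#' Extract paragraph texts from HTML markup
#'
#' Parses the markup leniently, removes script and style content, and
#' returns the text of block-level elements (`p`, leaf `div`, `li`, `td`,
#' `th`, headings, `blockquote`) in document order, entities decoded,
#' whitespace squashed, empty blocks dropped. Nested block elements are
#' resolved to the innermost one so no text is reported twice.
#'
#' @param html A length-1 character of raw markup.
#' @return Character vector of paragraph texts (possibly empty).
#' @export
html_to_paragraphs <- function(html) {
  doc <- tryCatch(xml2::read_html(html), error = function(e) NULL)
  if (is.null(doc)) return(character(0))
  for (node in xml2::xml_find_all(doc, "//script | //style")) xml2::xml_remove(node)
  block_xpath <- paste0("//", c("p", "div", "li", "td", "th", "h1", "h2", "h3",
                                "h4", "h5", "h6", "blockquote"), collapse = " | ")
  blocks <- xml2::xml_find_all(doc, block_xpath)
  if (length(blocks) > 0) {
    inner <- paste0("./descendant::", c("p", "div", "li", "td", "th", "h1",
                                        "h2", "h3", "h4", "h5", "h6",
                                        "blockquote"), collapse = " | ")
    is_leaf <- purrr::map_lgl(blocks, function(b) {
      length(xml2::xml_find_all(b, inner)) == 0
    })
    texts <- purrr::map_chr(blocks[is_leaf], xml2::xml_text)
  } else {
    texts <- xml2::xml_text(doc)
  }
  texts <- stringr::str_squish(stringi::stri_trans_nfc(texts))
  texts[nzchar(texts)]
}

#' Split plain text into paragraphs
#'
#' A paragraph boundary occurs where sentence-terminal punctuation is
#' immediately followed by a line break, and at blank lines. Line breaks not
#' preceded by terminal punctuation are soft wraps and are joined with a
#' space.
#'
#' @param text Length-1 character of plain text.
#' @return Character vector of paragraph texts.
#' @export
text_to_paragraphs <- function(text) {
  text <- stringi::stri_trans_nfc(text)
  lines <- stringr::str_split_1(text, "\r?\n")
  paras <- character(0)
  buf <- character(0)
  flush <- function() {
    if (length(buf)) {
      p <- stringr::str_squish(paste(buf, collapse = " "))
      if (nzchar(p)) paras[[length(paras) + 1L]] <<- p
    }
    buf <<- character(0)
  }
  for (line in lines) {
    trimmed <- stringr::str_trim(line)
    if (!nzchar(trimmed)) {
      flush()
    } else {
      buf[[length(buf) + 1L]] <- trimmed
      if (stringr::str_detect(trimmed, paste0(TERMINAL_RE, "$"))) flush()
    }
  }
  flush()
  paras
}

# Does text ending at (and including) position `dot_pos` end with a protected
# abbreviation, with a non-alphanumeric character (or start of string) before
# the abbreviation?
ends_with_abbreviation <- function(text, dot_pos, abbreviations) {
  prefix <- stringi::stri_trans_tolower(
    stringr::str_sub(text, max(1L, dot_pos - 15L), dot_pos))
  for (ab in abbreviations) {
    if (stringr::str_ends(prefix, stringr::fixed(ab))) {
      before <- dot_pos - stringr::str_length(ab)
      if (before < 1L) return(TRUE)
      ch <- stringr::str_sub(text, before, before)
      if (!stringr::str_detect(ch, "[A-Za-z0-9]")) return(TRUE)
    }
  }
  FALSE
}

#' Split a paragraph into sentences with character offsets
#'
#' Splits at sentence-terminal punctuation (`.` `!` `?`, with optional
#' closing quotes or brackets) followed by whitespace and an uppercase
#' letter or digit. Periods inside decimal numbers, e-mail addresses and
#' URLs are never followed by whitespace, so they cannot split; periods
#' ending a protected abbreviation (see [default_abbreviations()]) are
#' explicitly exempted.
#'
#' @param paragraph Length-1 character.
#' @param abbreviations Protected abbreviation list.
#' @return Tibble with columns `text`, `start`, `end` (1-based, end-exclusive
#'   offsets into `paragraph`), in ascending order.
#' @export
split_sentences <- function(paragraph, abbreviations = default_abbreviations()) {
  abbreviations <- stringi::stri_trans_tolower(abbreviations)
  empty <- tibble::tibble(text = character(0), start = integer(0), end = integer(0))
  if (is.na(paragraph) || !nzchar(stringr::str_trim(paragraph))) return(empty)
  cand <- stringr::str_locate_all(
    paragraph, paste0("(", TERMINAL_RE, ")\\s+(?=[A-Z0-9])"))[[1]]
  boundaries <- integer(0)   # position of the last char of each sentence
  starts_next <- integer(0)  # position where the next sentence starts
  if (nrow(cand) > 0) {
    for (i in seq_len(nrow(cand))) {
      seg <- stringr::str_sub(paragraph, cand[i, 1], cand[i, 2])
      punct_len <- stringr::str_length(stringr::str_extract(seg, paste0("^", TERMINAL_RE)))
      punct_char <- stringr::str_sub(paragraph, cand[i, 1], cand[i, 1])
      if (punct_char == "." &&
          ends_with_abbreviation(paragraph, cand[i, 1], abbreviations)) next
      boundaries <- c(boundaries, cand[i, 1] + punct_len - 1L)
      starts_next <- c(starts_next, cand[i, 2] + 1L)
    }
  }
  span_start <- c(1L, starts_next)
  span_end <- c(boundaries, stringr::str_length(paragraph))
  out <- purrr::map2(span_start, span_end, function(s, e) {
    raw <- stringr::str_sub(paragraph, s, e)
    lead <- stringr::str_length(stringr::str_extract(raw, "^\\s*"))
    trail <- stringr::str_length(stringr::str_extract(raw, "\\s*$"))
    s2 <- s + lead
    e2 <- e - trail
    if (e2 < s2) return(NULL)
    tibble::tibble(text = stringr::str_sub(paragraph, s2, e2),
                   start = as.integer(s2), end = as.integer(e2 + 1L))
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) empty else out
}

#' Segment a whole corpus into paragraphs and sentences
#'
#' HTML documents go through [html_to_paragraphs()], plain text through
#' [text_to_paragraphs()]; every paragraph is then split into sentences.
#' Abstract-only documents (`full_text_available == FALSE`) are forced to a
#' single paragraph containing all their sentences.
#'
#' @param docs Document tibble (see [read_corpus_manifest()]).
#' @param abbreviations Protected abbreviation list for sentence splitting.
#' @return A tibble of class `cooc_segments` with one row per sentence:
#'   `doc_id`, `paragraph` (0-based), `sentence` (0-based within paragraph),
#'   `text`, `start`, `end` (offsets into the paragraph text). Attributes:
#'   `paragraphs` (tibble `doc_id`, `paragraph`, `text`) and `doc_ids` (all
#'   segmented documents, including any with no extractable text).
#' @export
segment_corpus <- function(docs, abbreviations = default_abbreviations()) {
  docs <- complete_documents(docs)
  validate_documents(docs)
  per_doc <- purrr::pmap(
    list(docs$doc_id, docs$content, docs$content_kind, docs$full_text_available),
    function(doc_id, content, kind, full_text) {
      paras <- if (identical(kind, "html")) html_to_paragraphs(content)
               else text_to_paragraphs(content)
      if (!isTRUE(full_text) && length(paras) > 1) {
        paras <- stringr::str_squish(paste(paras, collapse = " "))
      }
      if (length(paras) == 0) {
        message("document '", doc_id, "' yielded no extractable text")
        return(list(paragraphs = NULL, sentences = NULL))
      }
      sent <- purrr::imap(paras, function(p, i) {
        s <- split_sentences(p, abbreviations)
        if (nrow(s) == 0) return(NULL)
        s$doc_id <- doc_id
        s$paragraph <- i - 1L
        s$sentence <- seq_len(nrow(s)) - 1L
        s
      })
      list(
        paragraphs = tibble::tibble(doc_id = doc_id,
                                    paragraph = seq_along(paras) - 1L,
                                    text = paras),
        sentences = dplyr::bind_rows(sent)
      )
    })
  sentences <- dplyr::bind_rows(purrr::map(per_doc, "sentences"))
  if (nrow(sentences) == 0) {
    sentences <- tibble::tibble(text = character(0), start = integer(0),
                                end = integer(0), doc_id = character(0),
                                paragraph = integer(0), sentence = integer(0))
  }
  sentences <- sentences[, c("doc_id", "paragraph", "sentence", "text", "start", "end")]
  structure(sentences,
            class = c("cooc_segments", class(sentences)),
            paragraphs = dplyr::bind_rows(purrr::map(per_doc, "paragraphs")),
            doc_ids = docs$doc_id)
}

#' Paragraph texts of a segmented corpus
#'
#' @param segments A `cooc_segments` tibble.
#' @return Tibble (`doc_id`, `paragraph`, `text`).
#' @export
segment_paragraphs <- function(segments) {
  stopifnot(inherits(segments, "cooc_segments"))
  attr(segments, "paragraphs")
}

#' Write a segmentation dump as JSON lines
#'
#' One JSON object per sentence with doc id, paragraph and sentence indices,
#' offsets and text; useful for debugging the splitter.
#'
#' @param segments A `cooc_segments` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments_jsonl <- function(segments, path) {
  lines <- purrr::pmap_chr(
    segments[, c("doc_id", "paragraph", "sentence", "start", "end", "text")],
    function(doc_id, paragraph, sentence, start, end, text) {
      jsonlite::toJSON(list(doc_id = doc_id, paragraph = paragraph,
                            sentence = sentence, start = start, end = end,
                            text = text), auto_unbox = TRUE)
    })
  readr::write_lines(lines, path)
  invisible(path)
}
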