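# In-code fixtures shared across tests.

make_dict <- function(...) {
  entries <- list(...)
  tibble::tibble(
    gene_id = vapply(entries, `[[`, character(1), 1),
    organism = "test",
    primary_name = vapply(entries, `[[`, character(1), 2),
    synonyms = lapply(entries, function(e) unique(e[-1])))
}

write_dict_file <- function(lines) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(lines, tf)
  tf
}

make_docs <- function(contents, kind = "plain_text", full_text = TRUE,
                      url = NA_character_, doi = NA_character_) {
  n <- length(contents)
  tibble::tibble(
    doc_id = sprintf("doc%02d", seq_len(n)),
    source_name = "test", url = rep_len(url, n), doi = rep_len(doi, n),
    title = NA_character_, full_text_available = rep_len(full_text, n),
    content_kind = rep_len(kind, n), content = contents)
}

# A cooc_segments object built directly (structure-only corpora for stats
# tests, where sentence text is irrelevant).
make_segments <- function(sent_units, doc_ids = unique(sent_units$doc_id)) {
  paragraphs <- dplyr::distinct(tibble::as_tibble(sent_units), doc_id, paragraph)
  paragraphs$text <- rep("x", nrow(paragraphs))
  sentences <- tibble::as_tibble(sent_units)
  sentences$text <- rep("x", nrow(sentences))
  sentences$start <- rep(1L, nrow(sentences))
  sentences$end <- rep(2L, nrow(sentences))
  sentences <- sentences[, c("doc_id", "paragraph", "sentence",
                             "text", "start", "end")]
  structure(sentences,
            class = c("cooc_segments", class(sentences)),
            paragraphs = tibble::as_tibble(paragraphs),
            doc_ids = doc_ids)
}

# Random structure-only corpus: documents, paragraphs, sentences, and a
# random mention set over a small gene universe.
random_structure <- function(max_docs = 20, max_genes = 10,
                             mention_rate = 0.15) {
  n_docs <- sample(2:max_docs, 1)
  n_genes <- sample(2:max_genes, 1)
  genes <- sprintf("g%02d", seq_len(n_genes))
  units <- do.call(rbind, lapply(seq_len(n_docs), function(d) {
    n_par <- sample(1:3, 1)
    do.call(rbind, lapply(seq_len(n_par) - 1L, function(p) {
      n_sent <- sample(1:4, 1)
      data.frame(doc_id = sprintf("d%03d", d), paragraph = p,
                 sentence = seq_len(n_sent) - 1L)
    }))
  }))
  segments <- make_segments(units)
  pick <- matrix(stats::runif(nrow(units) * n_genes) < mention_rate,
                 nrow(units), n_genes)
  idx <- which(pick, arr.ind = TRUE)
  mentions <- tibble::tibble(
    doc_id = units$doc_id[idx[, 1]], paragraph = units$paragraph[idx[, 1]],
    sentence = units$sentence[idx[, 1]], gene_id = genes[idx[, 2]],
    surface = genes[idx[, 2]], start = 1L,
    end = nchar(genes[idx[, 2]]) + 1L)
  list(segments = segments, mentions = mentions, genes = genes)
}

# Random natural-language-like sentence for segmentation property tests:
# starts with a capitalized word, ends with terminal punctuation, and may
# carry a protected token (decimal / e-mail / URL) mid-sentence.
random_protected_sentence <- function(protected = TRUE) {
  words <- c("the", "kinase", "pathway", "response", "cells", "medium",
             "during", "growth", "was", "activated", "strongly", "under")
  n <- sample(3:6, 1)
  toks <- sample(words, n, replace = TRUE)
  substr(toks[1], 1, 1) <- toupper(substr(toks[1], 1, 1))
  if (protected) {
    prot <- sample(c("3.5", "0.25", "12.7", "a@b.org", "lab@example.org",
                     "http://x.y/z", "https://db.example.net/e?id=3"), 1)
    toks <- append(toks, prot, after = sample(n - 1, 1))
  }
  paste0(paste(toks, collapse = " "), sample(c(".", "!", "?"), 1))
}

# Minimal two-sentence corpus: "g1 g2" then "g1" in one paragraph.
two_sentence_corpus <- function() {
  units <- data.frame(doc_id = "d1", paragraph = 0L, sentence = 0:1)
  segments <- make_segments(units)
  mentions <- tibble::tibble(
    doc_id = "d1", paragraph = 0L, sentence = c(0L, 0L, 1L),
    gene_id = c("g1", "g2", "g1"), surface = "x", start = 1L, end = 2L)
  list(segments = segments, mentions = mentions)
}
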