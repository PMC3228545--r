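# filler vocabulary: common lowercase words guaranteed never to collide with
# generated gene names (which all carry digits)
FILLER_WORDS <- c(
  "the", "enzyme", "activity", "was", "measured", "under", "growth",
  "conditions", "cells", "were", "grown", "in", "medium", "and", "protein",
  "levels", "increased", "during", "exponential", "phase", "expression",
  "of", "this", "operon", "is", "regulated", "by", "carbon", "source",
  "availability", "we", "observed", "a", "strong", "response", "to",
  "glucose", "limitation", "samples", "collected", "at", "intervals")

PROTECTED_DECIMALS <- c("3.5", "0.25", "12.7", "1.05", "99.9")
PROTECTED_EMAILS <- c("lab@example.org", "info@genomics.net", "a@b.org")
PROTECTED_URLS <- c("http://example.org/data", "https://db.example.net/entry?id=7",
                    "http://x.y/z")

#' Describe a synthetic corpus with known co-occurrence structure
#'
#' The model fixes, per gene, the probability that any given sentence
#' mentions it; planted pairs additionally receive an excess joint sentence
#' probability over the product of their marginals, realized through a
#' shared Bernoulli component. All randomness flows from `seed`: the same
#' model generates byte-identical corpora.
#'
#' @param genes Named numeric vector: per-gene sentence occurrence
#'   probability (names become gene ids), or an integer to create that many
#'   genes with probability `p_default`.
#' @param planted_pairs Tibble/data.frame with columns `gene_i`, `gene_j`,
#'   `excess` (excess joint sentence probability). A gene may appear in at
#'   most one planted pair.
#' @param n_documents,paragraphs_per_document,sentences_per_paragraph Corpus
#'   dimensions.
#' @param p_default Occurrence probability used when `genes` is an integer.
#' @param abstract_only_rate Fraction of documents flagged abstract-only
#'   (generated with a single paragraph).
#' @param html_rate Fraction of documents emitted as HTML.
#' @param protected_token_rate Per-sentence rate of injected decimals,
#'   e-mail addresses and URLs (segmentation stress tokens).
#' @param n_synonyms Synonyms per gene in the emitted dictionary.
#' @param seed Integer seed.
#' @return An object of class `corpus_model`.
#' @export
corpus_model <- function(genes = 6, planted_pairs = NULL, n_documents = 20,
                         paragraphs_per_document = 2,
                         sentences_per_paragraph = 4, p_default = 0.1,
                         abstract_only_rate = 0.1, html_rate = 0.2,
                         protected_token_rate = 0, n_synonyms = 2,
                         seed = 1L) {
  if (is.numeric(genes) && length(genes) == 1 && is.null(names(genes))) {
    ids <- sprintf("g%02d", seq_len(genes))
    genes <- stats::setNames(rep(p_default, length(ids)), ids)
  }
  stopifnot(is.numeric(genes), !is.null(names(genes)) || length(genes) == 0,
            all(genes >= 0 & genes <= 1),
            n_documents >= 1, paragraphs_per_document >= 1,
            sentences_per_paragraph >= 1,
            abstract_only_rate >= 0, abstract_only_rate <= 1,
            html_rate >= 0, html_rate <= 1,
            protected_token_rate >= 0, protected_token_rate <= 1,
            n_synonyms >= 1)
  if (is.null(planted_pairs)) {
    planted_pairs <- tibble::tibble(gene_i = character(0),
                                    gene_j = character(0), excess = double(0))
  }
  planted_pairs <- tibble::as_tibble(planted_pairs)
  if (nrow(planted_pairs) > 0) {
    involved <- c(planted_pairs$gene_i, planted_pairs$gene_j)
    stopifnot(all(involved %in% names(genes)), !anyDuplicated(involved))
    for (r in seq_len(nrow(planted_pairs))) {
      p_i <- genes[[planted_pairs$gene_i[r]]]
      p_j <- genes[[planted_pairs$gene_j[r]]]
      e <- planted_pairs$excess[r]
      if (e < 0 || p_i * p_j + e > min(p_i, p_j)) {
        rlang::abort("inconsistent probabilities: planted joint exceeds min marginal")
      }
      # check the shared-component construction can reach this excess
      tryCatch(solve_shared_component(p_i, p_j, e),
               error = function(err) rlang::abort(paste0(
                 "planted excess not attainable for pair ",
                 planted_pairs$gene_i[r], "-", planted_pairs$gene_j[r])))
    }
  }
  structure(list(genes = genes, planted_pairs = planted_pairs,
                 n_documents = as.integer(n_documents),
                 paragraphs_per_document = as.integer(paragraphs_per_document),
                 sentences_per_paragraph = as.integer(sentences_per_paragraph),
                 abstract_only_rate = abstract_only_rate,
                 html_rate = html_rate,
                 protected_token_rate = protected_token_rate,
                 n_synonyms = as.integer(n_synonyms),
                 seed = as.integer(seed)),
            class = "corpus_model")
}

# Planted dependence: X_i = U | A_i with U ~ Bern(alpha), A ~ Bern(beta_i).
# Then p_ij - p_i p_j = alpha (1-alpha) (1-beta_i)(1-beta_j); solve for alpha.
solve_shared_component <- function(p_i, p_j, excess) {
  if (excess == 0) return(list(alpha = 0, beta_i = p_i, beta_j = p_j))
  f <- function(alpha) {
    beta_i <- (p_i - alpha) / (1 - alpha)
    beta_j <- (p_j - alpha) / (1 - alpha)
    alpha * (1 - alpha) * (1 - beta_i) * (1 - beta_j) - excess
  }
  upper <- min(p_i, p_j)
  root <- stats::uniroot(f, c(1e-12, upper), tol = 1e-14)$root
  list(alpha = root,
       beta_i = (p_i - root) / (1 - root),
       beta_j = (p_j - root) / (1 - root))
}

synth_dictionary <- function(model) {
  ids <- names(model$genes)
  tibble::tibble(
    gene_id = ids,
    organism = "synthetic",
    primary_name = paste0(ids, "A"),
    synonyms = purrr::map(ids, function(id) {
      paste0(id, LETTERS[seq_len(model$n_synonyms)])
    }))
}

#' Generate a synthetic corpus with ground truth
#'
#' Emits a dictionary, a document set (optionally written to disk in the
#' exact formats the rest of the pipeline consumes) and the ground-truth
#' indicator records of which genes were planted in which sentence. Mentions
#' are standalone tokens separated by filler words; the synonym used for
#' each mention is chosen uniformly. Every sentence starts with a
#' capitalized filler word and ends with a period, so sentence boundaries
#' are recoverable by construction; injected protected tokens (decimals,
#' e-mails, URLs) appear mid-sentence only.
#'
#' @param model A [corpus_model()].
#' @param dir Optional directory; when given, writes `dictionary.tsv`,
#'   `manifest.tsv`, `docs/` and `truth.json` there.
#' @return List of class `synth_corpus`: `dictionary` (tibble), `docs`
#'   (document tibble with content), `truth` (class `cooc_truth`: list with
#'   `indicators` tibble (`doc_id`, `paragraph`, `sentence`, `gene_id`) and
#'   `units` tibble (`doc_id`, `paragraph`, `n_sentences`)), and `paths`
#'   when `dir` was given.
#' @export
generate_corpus <- function(model, dir = NULL) {
  stopifnot(inherits(model, "corpus_model"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(model$seed, kind = "Mersenne-Twister")

  dict <- synth_dictionary(model)
  ids <- names(model$genes)
  n_docs <- model$n_documents

  abstract_only <- stats::runif(n_docs) < model$abstract_only_rate
  is_html <- stats::runif(n_docs) < model$html_rate
  n_paras <- ifelse(abstract_only, 1L, model$paragraphs_per_document)
  units <- tibble::tibble(
    doc_id = rep(sprintf("d%03d", seq_len(n_docs)), n_paras),
    paragraph = unlist(purrr::map(n_paras, ~ seq_len(.x) - 1L)),
    n_sentences = model$sentences_per_paragraph)
  sent_units <- units |>
    tidyr::uncount(.data$n_sentences, .id = "sentence") |>
    dplyr::mutate(sentence = .data$sentence - 1L)
  S <- nrow(sent_units)

  # presence indicators; planted pairs share a Bernoulli OR-component
  planted_genes <- c(model$planted_pairs$gene_i, model$planted_pairs$gene_j)
  presence <- matrix(FALSE, nrow = S, ncol = length(ids),
                     dimnames = list(NULL, ids))
  for (id in setdiff(ids, planted_genes)) {
    presence[, id] <- stats::runif(S) < model$genes[[id]]
  }
  if (nrow(model$planted_pairs) > 0) {
    for (r in seq_len(nrow(model$planted_pairs))) {
      gi <- model$planted_pairs$gene_i[r]
      gj <- model$planted_pairs$gene_j[r]
      sol <- solve_shared_component(model$genes[[gi]], model$genes[[gj]],
                                    model$planted_pairs$excess[r])
      u <- stats::runif(S) < sol$alpha
      presence[, gi] <- u | (stats::runif(S) < sol$beta_i)
      presence[, gj] <- u | (stats::runif(S) < sol$beta_j)
    }
  }

  sentences <- character(S)
  for (s in seq_len(S)) {
    present <- ids[presence[s, ]]
    n_fill <- sample(2:4, 1)
    words <- sample(FILLER_WORDS, n_fill, replace = TRUE)
    words[1] <- stringr::str_to_title(words[1])
    tokens <- words[1]
    rest <- words[-1]
    for (g in present) {
      syns <- dict$synonyms[[match(g, dict$gene_id)]]
      tokens <- c(tokens, sample(syns, 1),
                  if (length(rest)) rest[1] else sample(FILLER_WORDS, 1))
      rest <- rest[-1]
    }
    tokens <- c(tokens, rest)
    if (stats::runif(1) < model$protected_token_rate) {
      prot <- switch(sample(3, 1),
                     sample(PROTECTED_DECIMALS, 1),
                     sample(PROTECTED_EMAILS, 1),
                     sample(PROTECTED_URLS, 1))
      # mid-sentence insertion, never the final token
      at <- sample(seq_len(length(tokens) - 1), 1)
      tokens <- append(tokens, prot, after = at)
    }
    sentences[s] <- paste0(paste(tokens, collapse = " "), ".")
  }

  para_text <- sent_units |>
    dplyr::mutate(text = sentences) |>
    dplyr::group_by(.data$doc_id, .data$paragraph) |>
    dplyr::summarise(text = paste(.data$text, collapse = " "), .groups = "drop")
  doc_text <- para_text |>
    dplyr::group_by(.data$doc_id) |>
    dplyr::summarise(plain = paste(.data$text, collapse = "\n\n"),
                     html = paste0("<html><body>",
                                   paste0("<p>", .data$text, "</p>",
                                          collapse = ""),
                                   "</body></html>"),
                     .groups = "drop")
  docs <- tibble::tibble(
    doc_id = doc_text$doc_id,
    source_name = "synthetic",
    url = paste0("https://corpus.example.org/", doc_text$doc_id),
    doi = NA_character_,
    title = paste("Synthetic document", doc_text$doc_id),
    full_text_available = !abstract_only,
    content_kind = ifelse(is_html, "html", "plain_text"),
    content = ifelse(is_html, doc_text$html, doc_text$plain))

  ind <- which(presence, arr.ind = TRUE)
  indicators <- tibble::tibble(
    doc_id = sent_units$doc_id[ind[, 1]],
    paragraph = sent_units$paragraph[ind[, 1]],
    sentence = sent_units$sentence[ind[, 1]],
    gene_id = ids[ind[, 2]]) |>
    dplyr::arrange(.data$doc_id, .data$paragraph, .data$sentence, .data$gene_id)
  truth <- structure(list(indicators = indicators, units = units,
                          doc_ids = docs$doc_id), class = "cooc_truth")

  out <- structure(list(dictionary = dict, docs = docs, truth = truth),
                   class = "synth_corpus")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    dict_path <- file.path(dir, "dictionary.tsv")
    write_gene_dictionary(dict, dict_path)
    manifest_path <- write_corpus(docs, dir)
    truth_path <- file.path(dir, "truth.json")
    jsonlite::write_json(
      list(indicators = indicators, units = units, doc_ids = docs$doc_id),
      truth_path, dataframe = "columns")
    out$paths <- c(dictionary = dict_path, manifest = manifest_path,
                   truth = truth_path)
  }
  out
}

#' Read ground truth back from its JSON file
#'
#' @param path Path to `truth.json` from [generate_corpus()].
#' @return A `cooc_truth` object.
#' @export
read_truth_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(indicators = tibble::as_tibble(raw$indicators),
                 units = tibble::as_tibble(raw$units),
                 doc_ids = raw$doc_ids), class = "cooc_truth")
}

#' Ground-truth co-occurrence counts
#'
#' Computes `n`, `a` and `b` at any granularity directly from the recorded
#' indicator records, independently of the text pipeline; used as the oracle
#' for end-to-end count checks.
#'
#' @param truth A `cooc_truth` from [generate_corpus()].
#' @param level One of `"sentence"`, `"paragraph"`, `"document"`.
#' @return A `cooc_counts` object.
#' @export
truth_counts <- function(truth, level = c("sentence", "paragraph", "document")) {
  level <- rlang::arg_match(level)
  stopifnot(inherits(truth, "cooc_truth"))
  n <- switch(level,
    sentence = sum(truth$units$n_sentences),
    paragraph = nrow(truth$units),
    document = length(truth$doc_ids))
  unit_cols <- switch(level,
    sentence = c("doc_id", "paragraph", "sentence"),
    paragraph = c("doc_id", "paragraph"),
    document = "doc_id")
  pres <- truth$indicators |>
    dplyr::distinct(dplyr::pick(dplyr::all_of(c(unit_cols, "gene_id"))))
  a <- pres |> dplyr::count(.data$gene_id, name = "a") |>
    dplyr::arrange(.data$gene_id)
  pairs <- dplyr::inner_join(pres, pres, by = unit_cols,
                             relationship = "many-to-many",
                             suffix = c("_i", "_j")) |>
    dplyr::filter(.data$gene_id_i < .data$gene_id_j)
  b <- pairs |>
    dplyr::count(gene_i = .data$gene_id_i, gene_j = .data$gene_id_j,
                 name = "b") |>
    dplyr::arrange(.data$gene_i, .data$gene_j)
  pair_docs <- pairs |>
    dplyr::distinct(gene_i = .data$gene_id_i, gene_j = .data$gene_id_j,
                    .data$doc_id) |>
    dplyr::count(.data$gene_i, .data$gene_j, name = "d") |>
    dplyr::arrange(.data$gene_i, .data$gene_j)
  structure(list(level = level, n = as.integer(n), a = a, b = b,
                 pair_docs = pair_docs),
            class = "cooc_counts")
}
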