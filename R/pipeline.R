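#' Run configuration for the co-occurrence pipeline
#'
#' @param dictionaries Character vector of one or more dictionary TSV paths;
#'   multiple dictionaries are merged (on `gene_id`) before indexing.
#' @param corpus Corpus manifest TSV path.
#' @param out Output directory.
#' @param organism Organism label.
#' @param case_sensitive Matching case mode.
#' @param min_term_length Minimum synonym length indexed.
#' @param ambiguity Ambiguity policy (`"all"`, `"drop"`, `"first"`).
#' @param adjust_p Benjamini-Hochberg adjusted p-values on/off.
#' @param query_genes Optional character vector of gene ids used to select
#'   the reported subnetwork (all pairs are still computed).
#' @param seed Seed recorded in the config (used by synthetic generation).
#' @param log_level `"quiet"` or `"info"`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(dictionaries, corpus, out, organism = "unknown",
                       case_sensitive = TRUE, min_term_length = 2,
                       ambiguity = c("all", "drop", "first"),
                       adjust_p = FALSE, query_genes = NULL, seed = 1L,
                       log_level = c("info", "quiet")) {
  ambiguity <- rlang::arg_match(ambiguity)
  log_level <- rlang::arg_match(log_level)
  structure(list(dictionaries = dictionaries, corpus = corpus, out = out,
                 organism = organism, case_sensitive = case_sensitive,
                 min_term_length = as.integer(min_term_length),
                 ambiguity = ambiguity, adjust_p = adjust_p,
                 query_genes = query_genes, seed = as.integer(seed),
                 log_level = log_level),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' The flat key-value file round-trips losslessly through
#' [write_run_config()] and [read_run_config()].
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' @param config A `run_config`.
#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  vals <- unclass(config)
  vals <- vals[!vapply(vals, is.null, logical(1))]
  yaml::write_yaml(vals, path)
  invisible(path)
}

log_info <- function(config, ...) {
  if (identical(config$log_level, "info")) message(...)
}

#' Analyze a corpus for gene co-occurrence (in memory)
#'
#' The core analysis chain: de-duplicate documents, segment into paragraphs
#' and sentences, find dictionary mentions, compute the per-pair statistics
#' at all three granularities and build the two co-occurrence networks.
#'
#' @param docs Document tibble (see [read_corpus_manifest()]).
#' @param dictionary Dictionary tibble (see [read_gene_dictionary()]).
#' @param case_sensitive,min_term_length,ambiguity Index/matching options,
#'   see [build_synonym_index()].
#' @param adjust_p Benjamini-Hochberg adjustment flag, see [pair_table()].
#' @param abbreviations Sentence-splitting abbreviation list.
#' @return An object of class `cooc_result`: list with `docs` (survivors),
#'   `dedup` (drop report), `segments`, `mentions`, `genes_per_document`,
#'   `pair_table`, `networks` (named list: `sentence`,
#'   `paragraph_document`), `counts_document`.
#' @export
analyze_cooccurrence <- function(docs, dictionary, case_sensitive = TRUE,
                                 min_term_length = 2,
                                 ambiguity = c("all", "drop", "first"),
                                 adjust_p = FALSE,
                                 abbreviations = default_abbreviations()) {
  ambiguity <- rlang::arg_match(ambiguity)
  index <- build_synonym_index(dictionary, policy = ambiguity,
                               min_length = min_term_length,
                               case_sensitive = case_sensitive)
  docs <- deduplicate_documents(docs)
  if (nrow(docs) == 0) rlang::abort("empty corpus after de-duplication")
  segments <- segment_corpus(docs, abbreviations)
  mentions <- find_mentions(segments, index)
  pairs <- pair_table(segments, mentions, adjust_p = adjust_p)
  gpd <- genes_per_document(mentions)
  counts_doc <- count_occurrences(segments, mentions, "document")
  nets <- list(
    sentence = build_network(pairs, "sentence", gene_counts = counts_doc,
                             gpd = gpd),
    paragraph_document = build_network(pairs, "paragraph_document",
                                       gene_counts = counts_doc, gpd = gpd))
  structure(list(docs = docs, dedup = dedup_report(docs),
                 segments = segments, mentions = mentions,
                 genes_per_document = gpd, pair_table = pairs,
                 networks = nets, counts_document = counts_doc),
            class = "cooc_result")
}

#' Run the full pipeline from files to exported results
#'
#' Reads dictionaries and corpus, runs [analyze_cooccurrence()] and exports
#' the results XML, GraphML networks and pair-table TSV to the output
#' directory. Per-stage counts are logged.
#'
#' @param config A [run_config()].
#' @return A `cooc_result`, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  missing <- config$dictionaries[!file.exists(config$dictionaries)]
  if (!file.exists(config$corpus)) missing <- c(missing, config$corpus)
  if (length(missing)) {
    rlang::abort(paste0("missing input file(s): ", paste(missing, collapse = ", ")))
  }
  dicts <- purrr::map(config$dictionaries, read_gene_dictionary,
                      organism = config$organism)
  dictionary <- purrr::reduce(dicts, merge_dictionaries,
                              case_sensitive = config$case_sensitive)
  docs <- read_corpus_manifest(config$corpus)
  log_info(config, "corpus: ", nrow(docs), " document(s) read")
  result <- analyze_cooccurrence(
    docs, dictionary, case_sensitive = config$case_sensitive,
    min_term_length = config$min_term_length, ambiguity = config$ambiguity,
    adjust_p = config$adjust_p)
  log_info(config, "after de-duplication: ", nrow(result$docs),
           " document(s), ", nrow(result$dedup), " dropped")
  log_info(config, "genes found: ",
           dplyr::n_distinct(result$mentions$gene_id),
           "; mentions: ", nrow(result$mentions))
  log_info(config, "co-occurring pairs (document level): ",
           sum(result$pair_table$level == "document"))
  nets <- result$networks
  if (!is.null(config$query_genes)) {
    nets <- purrr::map(nets, function(net) {
      keep <- igraph::V(net$graph)$name %in% config$query_genes
      nb <- unlist(igraph::adjacent_vertices(net$graph, which(keep)))
      sub <- igraph::induced_subgraph(net$graph,
                                      union(which(keep), as.integer(nb)))
      net$graph <- sub
      net
    })
  }
  export_results(nets, result$pair_table, result$docs,
                 result$genes_per_document, config$out)
  log_info(config, "results exported to ", config$out)
  invisible(result)
}

#' @export
print.cooc_result <- function(x, ...) {
  cat("<cooc_result>\n",
      "  documents: ", nrow(x$docs), "\n",
      "  sentences: ", nrow(x$segments), "\n",
      "  mentions:  ", nrow(x$mentions), " (",
      dplyr::n_distinct(x$mentions$gene_id), " genes)\n",
      "  pairs:     ", sum(x$pair_table$level == "document"),
      " co-occurring at document level\n", sep = "")
  invisible(x)
}

#' Tidy the pair statistics of a co-occurrence analysis
#'
#' @param x A `cooc_result`.
#' @param level Optional filter: `"sentence"`, `"paragraph"` or
#'   `"document"`.
#' @param ... Unused.
#' @return The pair-statistics tibble (see [pair_table()]).
#' @method tidy cooc_result
#' @export
tidy.cooc_result <- function(x, level = NULL, ...) {
  out <- x$pair_table
  if (!is.null(level)) out <- out[out$level == level, , drop = FALSE]
  out
}

#' One-row summary of a co-occurrence analysis
#'
#' @param x A `cooc_result`.
#' @param ... Unused.
#' @return One-row tibble: documents, paragraphs, sentences, genes found,
#'   mentions, document-level co-occurring pairs, smallest raw p-value.
#' @method glance cooc_result
#' @export
glance.cooc_result <- function(x, ...) {
  doc_pairs <- x$pair_table[x$pair_table$level == "document", , drop = FALSE]
  tibble::tibble(
    n_documents = nrow(x$docs),
    n_paragraphs = nrow(segment_paragraphs(x$segments)),
    n_sentences = nrow(x$segments),
    n_genes = dplyr::n_distinct(x$mentions$gene_id),
    n_mentions = nrow(x$mentions),
    n_pairs = nrow(doc_pairs),
    min_p_value = if (nrow(doc_pairs)) min(doc_pairs$p_value) else NA_real_)
}
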