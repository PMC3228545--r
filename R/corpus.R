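#' Normalize a URL for duplicate detection
#'
#' Lower-cases the scheme and host, strips the URL fragment and any trailing
#' slash. Query strings are retained because they distinguish articles on
#' many publisher platforms.
#'
#' @param url Character vector (may contain `NA`).
#' @return Normalized character vector.
#' @export
normalize_url <- function(url) {
  out <- stringr::str_trim(url)
  out <- stringr::str_remove(out, "#.*$")
  m <- stringr::str_match(out, "^([A-Za-z][A-Za-z0-9+.-]*://)([^/?]*)(.*)$")
  parsed <- !is.na(m[, 1])
  out[parsed] <- paste0(stringi::stri_trans_tolower(m[parsed, 2]),
                        stringi::stri_trans_tolower(m[parsed, 3]),
                        m[parsed, 4])
  out <- stringr::str_remove(out, "/$")
  out[!nzchar(out) | is.na(url)] <- NA_character_
  out
}

#' Normalize a DOI for duplicate detection
#'
#' Case-insensitive; strips `doi:` and resolver-URL prefixes.
#'
#' @param doi Character vector (may contain `NA`).
#' @return Normalized character vector.
#' @export
normalize_doi <- function(doi) {
  out <- stringr::str_trim(doi)
  out <- stringr::str_remove(out, stringr::regex(
    "^(doi:\\s*|https?://(dx\\.)?doi\\.org/)", ignore_case = TRUE))
  out <- stringi::stri_trans_tolower(out)
  out[!nzchar(out) | is.na(doi)] <- NA_character_
  out
}

validate_documents <- function(docs) {
  stopifnot(is.data.frame(docs))
  required <- c("doc_id", "content")
  missing <- setdiff(required, names(docs))
  if (length(missing)) {
    rlang::abort(paste0("document table is missing columns: ",
                        paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(docs$doc_id)) rlang::abort("doc_id must be unique within a corpus")
  if (any(is.na(docs$content) | !nzchar(docs$content))) {
    rlang::abort("every document must have non-empty content")
  }
  invisible(docs)
}

# Fill optional metadata columns with defaults so downstream code can rely
# on them.
complete_documents <- function(docs) {
  defaults <- list(source_name = NA_character_, url = NA_character_,
                   doi = NA_character_, title = NA_character_,
                   full_text_available = TRUE, content_kind = "plain_text")
  for (nm in names(defaults)) {
    if (!nm %in% names(docs)) docs[[nm]] <- defaults[[nm]]
  }
  stopifnot(all(docs$content_kind %in% c("plain_text", "html")))
  tibble::as_tibble(docs)
}

#' Read a corpus manifest and its document contents
#'
#' The manifest is one TSV row per document with columns `doc_id`, `path`,
#' and optionally `source_name`, `url`, `doi`, `title`,
#' `full_text_available`, `content_kind`. Paths are resolved relative to the
#' manifest's directory. Content is read from each file as UTF-8.
#'
#' @param path Manifest TSV path.
#' @return Tibble of document records including a `content` column.
#' @export
read_corpus_manifest <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("manifest not found: ", path))
  manifest <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()))
  if ("full_text_available" %in% names(manifest)) {
    manifest$full_text_available <- as.logical(manifest$full_text_available)
  }
  if (!all(c("doc_id", "path") %in% names(manifest))) {
    rlang::abort("manifest needs at least doc_id and path columns")
  }
  base <- dirname(path)
  files <- ifelse(stringr::str_starts(manifest$path, "/"),
                  manifest$path, file.path(base, manifest$path))
  missing <- files[!file.exists(files)]
  if (length(missing)) {
    rlang::abort(paste0("manifest references missing file(s): ",
                        paste(missing, collapse = ", ")))
  }
  manifest$content <- purrr::map_chr(files, function(f) {
    paste(readr::read_lines(f), collapse = "\n")
  })
  docs <- complete_documents(manifest[setdiff(names(manifest), "path")])
  validate_documents(docs)
  docs
}

#' De-duplicate corpus documents by URL then DOI
#'
#' Two passes, in order: (1) drop exact duplicates by normalized URL;
#' (2) among the survivors, drop duplicates by normalized DOI. The first
#' occurrence in input order wins. Records with neither URL nor DOI are
#' always retained. The drop report is attached as an attribute and
#' retrievable with [dedup_report()].
#'
#' @param docs Document tibble.
#' @return Surviving documents in input order, with a `dedup_report`
#'   attribute: a tibble of (`dropped_doc_id`, `reason`, `retained_doc_id`).
#' @export
deduplicate_documents <- function(docs) {
  docs <- complete_documents(docs)
  validate_documents(docs)
  url_key <- normalize_url(docs$url)
  doi_key <- normalize_doi(docs$doi)
  drop_url <- !is.na(url_key) & duplicated(url_key, incomparables = NA)
  retained_for <- function(key, dropped) {
    vapply(which(dropped), function(i) {
      docs$doc_id[which(key == key[i])[1]]
    }, character(1))
  }
  report <- tibble::tibble(
    dropped_doc_id = docs$doc_id[drop_url],
    reason = rep("url_dup", sum(drop_url)),
    retained_doc_id = retained_for(url_key, drop_url))
  survivors <- docs[!drop_url, , drop = FALSE]
  doi_s <- doi_key[!drop_url]
  drop_doi <- !is.na(doi_s) & duplicated(doi_s, incomparables = NA)
  report <- dplyr::bind_rows(report, tibble::tibble(
    dropped_doc_id = survivors$doc_id[drop_doi],
    reason = rep("doi_dup", sum(drop_doi)),
    retained_doc_id = vapply(which(drop_doi), function(i) {
      survivors$doc_id[which(doi_s == doi_s[i])[1]]
    }, character(1))))
  out <- survivors[!drop_doi, , drop = FALSE]
  attr(out, "dedup_report") <- report
  out
}

#' Drop report from the last de-duplication
#'
#' @param docs Result of [deduplicate_documents()].
#' @return Tibble (`dropped_doc_id`, `reason`, `retained_doc_id`).
#' @export
dedup_report <- function(docs) {
  rep <- attr(docs, "dedup_report")
  if (is.null(rep)) {
    rep <- tibble::tibble(dropped_doc_id = character(0),
                          reason = character(0),
                          retained_doc_id = character(0))
  }
  rep
}

#' Write a corpus (documents plus manifest) to a directory
#'
#' The inverse of [read_corpus_manifest()]: content goes to one file per
#' document under `dir/docs/`, metadata to `dir/manifest.tsv`.
#'
#' @param docs Document tibble with `content`.
#' @param dir Output directory (created if needed).
#' @return Path of the manifest, invisibly.
#' @export
write_corpus <- function(docs, dir) {
  docs <- complete_documents(docs)
  validate_documents(docs)
  doc_dir <- file.path(dir, "docs")
  dir.create(doc_dir, recursive = TRUE, showWarnings = FALSE)
  ext <- ifelse(docs$content_kind == "html", ".html", ".txt")
  rel <- file.path("docs", paste0(docs$doc_id, ext))
  purrr::walk2(docs$content, file.path(dir, rel), readr::write_lines)
  manifest <- docs |>
    dplyr::mutate(path = rel) |>
    dplyr::select("doc_id", "path", "source_name", "url", "doi", "title",
                  "full_text_available", "content_kind")
  out <- file.path(dir, "manifest.tsv")
  readr::write_tsv(manifest, out)
  invisible(out)
}
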