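#' Normalize a gene-name term for redundancy removal and lookup
#'
#' Applies Unicode NFC normalization and whitespace trimming; optionally folds
#' case. Gene symbols are case-meaningful in some organisms, so the default
#' throughout the package is case-sensitive.
#'
#' @param x Character vector of terms.
#' @param case_sensitive Logical; if `FALSE`, terms are lower-cased.
#' @return Character vector of normalized terms.
#' @export
normalize_term <- function(x, case_sensitive = TRUE) {
  out <- stringr::str_trim(stringi::stri_trans_nfc(x))
  if (!case_sensitive) out <- stringi::stri_trans_tolower(out)
  out
}

# Deduplicate synonyms by normalized form, keeping the first-seen spelling.
dedup_synonyms <- function(syns, case_sensitive = TRUE) {
  syns <- stringr::str_trim(stringi::stri_trans_nfc(syns))
  syns <- syns[nzchar(syns)]
  syns[!duplicated(normalize_term(syns, case_sensitive))]
}

validate_gene_dictionary <- function(dict) {
  stopifnot(is.data.frame(dict))
  required <- c("gene_id", "organism", "primary_name", "synonyms")
  missing <- setdiff(required, names(dict))
  if (length(missing)) {
    rlang::abort(paste0("dictionary is missing columns: ",
                        paste(missing, collapse = ", ")))
  }
  if (any(!nzchar(dict$gene_id))) rlang::abort("empty gene_id in dictionary")
  dup <- dict$gene_id[duplicated(dict$gene_id)]
  if (length(dup)) {
    rlang::abort(paste0("duplicate gene_id in dictionary: ",
                        paste(unique(dup), collapse = ", ")))
  }
  bad <- purrr::map2_lgl(dict$primary_name, dict$synonyms,
                         function(p, s) !(p %in% s))
  if (any(bad)) rlang::abort("primary_name must be a member of synonyms")
  invisible(dict)
}

#' Read a gene-synonym dictionary from a TSV file
#'
#' One gene per line: `gene_id <TAB> primary_name <TAB> synonym ...`.
#' Blank lines and lines starting with `#` are skipped. The primary name is
#' itself a searchable term and is injected into the synonym set.
#'
#' @param path Path to a UTF-8, tab-separated dictionary file.
#' @param organism Organism label attached to every entry.
#' @return A tibble with columns `gene_id`, `organism`, `primary_name` and a
#'   `synonyms` list-column of character vectors.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("b2388\tglk\tglucokinase", "b1854\tpykA"), tf)
#' read_gene_dictionary(tf, organism = "eco")
#' @export
read_gene_dictionary <- function(path, organism = "unknown") {
  if (!file.exists(path)) rlang::abort(paste0("dictionary file not found: ", path))
  lines <- readr::read_lines(path)
  keep <- which(nzchar(stringr::str_trim(lines)) &
                  !stringr::str_starts(stringr::str_trim(lines), stringr::fixed("#")))
  fields <- stringr::str_split(lines[keep], "\t")
  bad <- which(purrr::map_int(fields, ~ sum(nzchar(stringr::str_trim(.x)))) < 2)
  if (length(bad)) {
    rlang::abort(paste0("malformed dictionary line ", keep[bad[1]],
                        ": need at least gene_id and primary_name"))
  }
  entries <- purrr::map(fields, function(f) {
    f <- stringr::str_trim(f)
    f <- f[nzchar(f)]
    tibble::tibble(gene_id = f[1], primary_name = f[2],
                   synonyms = list(dedup_synonyms(f[-1])))
  })
  dict <- dplyr::bind_rows(entries)
  dict$organism <- organism
  dict <- dict[, c("gene_id", "organism", "primary_name", "synonyms")]
  dup_at <- which(duplicated(dict$gene_id))
  if (length(dup_at)) {
    rlang::abort(paste0("duplicate gene_id '", dict$gene_id[dup_at[1]],
                        "' at line ", keep[dup_at[1]]))
  }
  validate_gene_dictionary(dict)
  dict
}

#' Write a gene dictionary back to the TSV dialect
#'
#' @param dict Dictionary tibble as returned by [read_gene_dictionary()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_dictionary <- function(dict, path) {
  validate_gene_dictionary(dict)
  lines <- purrr::pmap_chr(dict, function(gene_id, organism, primary_name, synonyms, ...) {
    extra <- setdiff(synonyms, primary_name)
    paste(c(gene_id, primary_name, extra), collapse = "\t")
  })
  readr::write_lines(lines, path)
  invisible(path)
}

#' Merge two gene dictionaries with redundancy removal
#'
#' Entries matched on the chosen key have their synonym sets unioned;
#' synonyms that are duplicates under the normalization are removed, keeping
#' one canonical spelling per normalized form (first seen, with `a` taking
#' precedence over `b`). Unmatched entries from both inputs are retained
#' unchanged. Output is sorted by `gene_id`.
#'
#' @param a,b Dictionary tibbles.
#' @param match_on Matching key: `"gene_id"` or `"primary_name"`.
#' @param case_sensitive Normalization mode for redundancy removal.
#' @return Merged dictionary tibble.
#' @export
merge_dictionaries <- function(a, b, match_on = c("gene_id", "primary_name"),
                               case_sensitive = TRUE) {
  match_on <- rlang::arg_match(match_on)
  validate_gene_dictionary(a)
  validate_gene_dictionary(b)
  both <- dplyr::bind_rows(a, b)
  key <- if (match_on == "gene_id") both$gene_id else
    normalize_term(both$primary_name, case_sensitive)
  merged <- both |>
    dplyr::mutate(.key = key) |>
    dplyr::group_by(.data$.key) |>
    dplyr::summarise(
      gene_id = .data$gene_id[1],
      organism = .data$organism[1],
      primary_name = .data$primary_name[1],
      synonyms = list(dedup_synonyms(unlist(.data$synonyms), case_sensitive)),
      .groups = "drop"
    ) |>
    dplyr::select(-".key") |>
    dplyr::arrange(.data$gene_id)
  validate_gene_dictionary(merged)
  merged
}

#' Build a searchable synonym index
#'
#' Every synonym of length at least `min_length` becomes a searchable term.
#' Terms shared by more than one gene are handled per the ambiguity policy:
#' `"all"` maps the term to every gene, `"drop"` removes it, `"first"` keeps
#' the lowest `gene_id`. The ambiguity report is attached as an attribute and
#' retrievable with [ambiguity_report()].
#'
#' @param dict Dictionary tibble.
#' @param policy Ambiguity policy; default `"all"` (every synonym of every
#'   gene is searched for).
#' @param min_length Minimum term length in characters; default 2, which
#'   suppresses one-letter symbols that would match ubiquitously.
#' @param case_sensitive Whether term matching distinguishes case.
#' @return An object of class `synonym_index`: a tibble with columns `term`
#'   (normalized) and `gene_ids` (list-column), with matching options and the
#'   ambiguity report as attributes.
#' @export
build_synonym_index <- function(dict, policy = c("all", "drop", "first"),
                                min_length = 2, case_sensitive = TRUE) {
  policy <- rlang::arg_match(policy)
  validate_gene_dictionary(dict)
  if (nrow(dict) == 0) rlang::abort("cannot index an empty dictionary")
  stopifnot(min_length >= 1)
  long <- dict |>
    dplyr::select("gene_id", "synonyms") |>
    tidyr::unnest_longer("synonyms", values_to = "surface") |>
    dplyr::mutate(term = normalize_term(.data$surface, case_sensitive)) |>
    dplyr::filter(stringr::str_length(.data$term) >= min_length) |>
    dplyr::distinct(.data$term, .data$gene_id)
  grouped <- long |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(gene_ids = list(sort(unique(.data$gene_id))), .groups = "drop")
  ambiguous <- grouped |> dplyr::filter(lengths(.data$gene_ids) > 1)
  report <- tibble::tibble(
    term = ambiguous$term,
    gene_ids = purrr::map_chr(ambiguous$gene_ids, paste, collapse = ","),
    action = switch(policy, all = "kept_all", drop = "dropped", first = "kept_first")
  )
  terms <- switch(policy,
    all = grouped,
    drop = grouped |> dplyr::filter(lengths(.data$gene_ids) == 1),
    first = grouped |> dplyr::mutate(gene_ids = purrr::map(.data$gene_ids, ~ .x[1]))
  )
  if (nrow(report) > 0 && policy == "drop") {
    message(nrow(report), " ambiguous term(s) dropped from index: ",
            paste(utils::head(report$term, 5), collapse = ", "),
            if (nrow(report) > 5) ", ..." else "")
  }
  structure(terms,
            class = c("synonym_index", class(terms)),
            policy = policy,
            min_length = min_length,
            case_sensitive = case_sensitive,
            ambiguity = report)
}

#' Ambiguity report of a synonym index
#'
#' @param index A `synonym_index`.
#' @return Tibble with columns `term`, `gene_ids`, `action`.
#' @export
ambiguity_report <- function(index) {
  stopifnot(inherits(index, "synonym_index"))
  attr(index, "ambiguity")
}

#' Look up a term in a synonym index
#'
#' @param index A `synonym_index`.
#' @param term Character vector of surface terms.
#' @return List of character vectors of gene ids (empty when absent).
#' @export
index_lookup <- function(index, term) {
  stopifnot(inherits(index, "synonym_index"))
  key <- normalize_term(term, attr(index, "case_sensitive"))
  idx <- match(key, index$term)
  purrr::map(idx, ~ if (is.na(.x)) character(0) else index$gene_ids[[.x]])
}

#' @export
print.synonym_index <- function(x, ...) {
  cat("<synonym_index> ", nrow(x), " terms, policy=", attr(x, "policy"),
      ", case_sensitive=", attr(x, "case_sensitive"),
      ", ", nrow(attr(x, "ambiguity")), " ambiguous term(s)\n", sep = "")
  NextMethod()
}
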