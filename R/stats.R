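#' Occurrence and co-occurrence counts at one granularity
#'
#' Units are pooled across the whole corpus: at sentence level a unit is one
#' sentence, at paragraph level one paragraph, at document level one
#' document. For each unit and gene the indicator y is 1 when the gene has
#' at least one mention inside the unit; multiple mentions in one unit count
#' once. `n` is the total number of units, `a[k]` the number of units
#' containing gene k, `b[{i,j}]` the number of units containing both genes of
#' an unordered pair (pairs with b = 0 are omitted).
#'
#' @param segments A `cooc_segments` tibble (defines the unit universe).
#' @param mentions Mention tibble from [find_mentions()] over `segments`.
#' @param level One of `"sentence"`, `"paragraph"`, `"document"`.
#' @return An object of class `cooc_counts`: a list with elements `level`,
#'   `n`, `a` (tibble `gene_id`, `a`), `b` (tibble `gene_i`, `gene_j`, `b`
#'   with `gene_i < gene_j`), and `pair_docs` (tibble `gene_i`, `gene_j`,
#'   `d`: number of documents holding at least one co-occurring unit of this
#'   level — used by the concentration odds ratio).
#' @export
count_occurrences <- function(segments, mentions,
                              level = c("sentence", "paragraph", "document")) {
  level <- rlang::arg_match(level)
  stopifnot(inherits(segments, "cooc_segments"))
  paragraphs <- segment_paragraphs(segments)
  doc_ids <- attr(segments, "doc_ids")
  n <- switch(level,
    sentence = nrow(segments),
    paragraph = if (is.null(paragraphs)) 0L else nrow(paragraphs),
    document = length(doc_ids))
  if (n == 0) rlang::abort("empty corpus: no units at this level")

  unit_cols <- switch(level,
    sentence = c("doc_id", "paragraph", "sentence"),
    paragraph = c("doc_id", "paragraph"),
    document = "doc_id")
  pres <- mentions |>
    dplyr::distinct(dplyr::pick(dplyr::all_of(c(unit_cols, "gene_id"))))

  a <- pres |>
    dplyr::count(.data$gene_id, name = "a") |>
    dplyr::arrange(.data$gene_id)

  pairs <- dplyr::inner_join(
    pres, pres,
    by = unit_cols, relationship = "many-to-many",
    suffix = c("_i", "_j")) |>
    dplyr::filter(.data$gene_id_i < .data$gene_id_j)
  b <- pairs |>
    dplyr::count(gene_i = .data$gene_id_i, gene_j = .data$gene_id_j, name = "b") |>
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

#' @export
print.cooc_counts <- function(x, ...) {
  cat("<cooc_counts> level=", x$level, ", n=", x$n, " units, ",
      nrow(x$a), " genes, ", nrow(x$b), " co-occurring pairs\n", sep = "")
  invisible(x)
}

#' Pointwise mutual information of a gene pair (nats)
#'
#' Computes `p_ij * ln(p_ij / (p_i * p_j))`, the single co-occurrence-cell
#' information term, in natural-log units. Zero joint probability returns 0
#' by the limit convention.
#'
#' @param p_i,p_j Marginal occurrence probabilities.
#' @param p_ij Joint occurrence probability; must satisfy
#'   `p_ij <= min(p_i, p_j)`.
#' @return Numeric vector of MI values (nats).
#' @export
mutual_information <- function(p_i, p_j, p_ij) {
  if (any(p_ij > pmin(p_i, p_j) + 1e-12) || any(c(p_i, p_j, p_ij) < 0) ||
      any(c(p_i, p_j, p_ij) > 1)) {
    rlang::abort("inconsistent probabilities: need 0 <= p_ij <= min(p_i, p_j) <= 1")
  }
  if (any(p_ij > 0 & (p_i == 0 | p_j == 0))) {
    rlang::abort("inconsistent probabilities: p_ij > 0 with a zero marginal")
  }
  ifelse(p_ij == 0, 0, p_ij * log(p_ij / (p_i * p_j)))
}

#' Concentration odds ratio of a pair at sentence or paragraph level
#'
#' Measures how concentrated a pair's joint mentions are: with
#' `q_l = d_level / n_docs` (fraction of documents in which the pair
#' co-occurs within at least one unit of the given level) and
#' `q_d = d_doc / n_docs` (fraction in which it co-occurs anywhere), returns
#' `[q_l / (1 - q_l)] / [q_d / (1 - q_d)]`. The value is 1 when every
#' document-level co-occurrence is concentrated inside a single sentence
#' (or paragraph); values near 0 mean the genes tend to appear in different
#' parts of the same document. When `q_l == q_d` (including the boundary
#' `q = 1`) the ratio is 1 by convention.
#'
#' @param counts_level `cooc_counts` at sentence or paragraph level.
#' @param counts_doc `cooc_counts` at document level over the same corpus.
#' @param pair Character vector of two gene ids.
#' @return A single numeric in `[0, 1]`.
#' @export
concentration_odds_ratio <- function(counts_level, counts_doc, pair) {
  stopifnot(inherits(counts_level, "cooc_counts"),
            inherits(counts_doc, "cooc_counts"),
            counts_level$level %in% c("sentence", "paragraph"),
            counts_doc$level == "document", length(pair) == 2)
  pair <- sort(pair)
  n_docs <- counts_doc$n
  d_doc <- lookup_pair(counts_doc$b, pair, "b")
  if (is.na(d_doc) || d_doc < 1) {
    rlang::abort("pair does not co-occur at document level")
  }
  d_level <- lookup_pair(counts_level$pair_docs, pair, "d")
  if (is.na(d_level)) d_level <- 0L
  odds_ratio_from_doc_counts(d_level, d_doc, n_docs)
}

# shared arithmetic for the concentration odds ratio
odds_ratio_from_doc_counts <- function(d_level, d_doc, n_docs) {
  q_l <- d_level / n_docs
  q_d <- d_doc / n_docs
  ifelse(q_l == q_d, 1,
         ifelse(q_d == 1, 0, (q_l / (1 - q_l)) / (q_d / (1 - q_d))))
}

lookup_pair <- function(tbl, pair, col) {
  hit <- tbl[tbl$gene_i == pair[1] & tbl$gene_j == pair[2], , drop = FALSE]
  if (nrow(hit) == 0) NA_integer_ else hit[[col]][1]
}

#' Two-cell Pearson chi-square test of co-occurrence independence
#'
#' Tests whether a pair co-occurs more often than expected under
#' independence, using the two-cell goodness-of-fit statistic over
#' {co-occur, not co-occur}: observed `n1 = b`, `n2 = n - b`; expected
#' `m1 = n * (a_i/n) * (a_j/n)`, `m2 = n - m1`;
#' `X2 = (n1-m1)^2/m1 + (n2-m2)^2/m2`, referred to a chi-square distribution
#' with one degree of freedom. The p-value uses the closed form
#' `erfc(sqrt(X2/2))`. Note this is deliberately not the conventional 2x2
#' contingency statistic; that variant is available via
#' `variant = "contingency"` for comparison.
#'
#' @param counts A `cooc_counts` object.
#' @param pair Character vector of two gene ids.
#' @param variant `"two_cell"` (default) or the conventional `"contingency"`
#'   2x2 statistic.
#' @return Named list with `chi2` and `p_value`; both `NA` (with a warning)
#'   when a marginal is zero so the expectation is degenerate.
#' @export
pearson_chi2 <- function(counts, pair, variant = c("two_cell", "contingency")) {
  variant <- rlang::arg_match(variant)
  stopifnot(inherits(counts, "cooc_counts"), length(pair) == 2)
  pair <- sort(pair)
  n <- counts$n
  a_i <- counts$a$a[match(pair[1], counts$a$gene_id)]
  a_j <- counts$a$a[match(pair[2], counts$a$gene_id)]
  if (is.na(a_i)) a_i <- 0L
  if (is.na(a_j)) a_j <- 0L
  b <- lookup_pair(counts$b, pair, "b")
  if (is.na(b)) b <- 0L
  res <- chi2_stat(n, a_i, a_j, b, variant)
  list(chi2 = res$chi2, p_value = res$p_value)
}

# vectorized statistic + p-value; NA when not computable (zero marginal)
chi2_stat <- function(n, a_i, a_j, b, variant = "two_cell") {
  m1 <- as.numeric(n) * (a_i / n) * (a_j / n)
  if (variant == "two_cell") {
    m2 <- n - m1
    # a saturated corpus (both marginals = n) empties the second cell:
    # observed and expected are both 0 there, and the term vanishes in the
    # limit; an empty first cell (zero marginal) stays not-computable
    term2 <- ifelse(m2 == 0, ifelse(n - b == 0, 0, NA_real_),
                    ((n - b) - m2)^2 / m2)
    chi2 <- ifelse(m1 == 0, NA_real_, (b - m1)^2 / m1 + term2)
  } else {
    # conventional 2x2 contingency statistic (not the default reported one)
    e11 <- a_i * a_j / n
    e10 <- a_i * (n - a_j) / n
    e01 <- (n - a_i) * a_j / n
    e00 <- (n - a_i) * (n - a_j) / n
    chi2 <- ifelse(e11 == 0 | e10 == 0 | e01 == 0 | e00 == 0, NA_real_,
                   (b - e11)^2 / e11 +
                     ((a_i - b) - e10)^2 / e10 +
                     ((a_j - b) - e01)^2 / e01 +
                     ((n - a_i - a_j + b) - e00)^2 / e00)
  }
  bad <- is.na(chi2)
  if (any(bad)) warning("chi-square not computable for ", sum(bad),
                        " pair(s): a zero marginal makes the expectation degenerate")
  list(chi2 = chi2, p_value = chi2_pvalue(chi2))
}

#' Upper-tail p-value of the chi-square distribution with 1 df
#'
#' Closed form `Pr(chi2_1 > x) = erfc(sqrt(x/2)) = 2 * pnorm(-sqrt(x))`.
#'
#' @param x Chi-square statistic (vectorized).
#' @return Numeric vector of p-values in `(0, 1]`.
#' @export
chi2_pvalue <- function(x) {
  2 * stats::pnorm(-sqrt(x))
}

#' Per-pair statistics table at all three granularities
#'
#' For every gene pair co-occurring in at least one document, emits one row
#' per level (sentence, paragraph, document) at which the pair co-occurs,
#' carrying counts, probabilities, mutual information, the concentration
#' odds ratio (sentence and paragraph rows; `NA` at document level), the
#' two-cell chi-square statistic and its p-value. Optionally adds
#' Benjamini-Hochberg adjusted p-values across all pairs within each level.
#'
#' @param segments A `cooc_segments` tibble.
#' @param mentions Mention tibble from [find_mentions()].
#' @param adjust_p Add BH-adjusted p-values? Default `FALSE` (raw p-values
#'   are reported).
#' @return Tibble with columns `gene_i`, `gene_j`, `level`, `n`, `a_i`,
#'   `a_j`, `b`, `p_i`, `p_j`, `p_ij`, `mi`, `odds_ratio`, `chi2`,
#'   `p_value`, `adjusted_p`.
#' @export
pair_table <- function(segments, mentions, adjust_p = FALSE) {
  counts <- list(sentence = count_occurrences(segments, mentions, "sentence"),
                 paragraph = count_occurrences(segments, mentions, "paragraph"),
                 document = count_occurrences(segments, mentions, "document"))
  doc_pairs <- counts$document$b[, c("gene_i", "gene_j")]
  n_docs <- counts$document$n
  d_doc <- counts$document$b$b

  rows <- purrr::imap(counts, function(cts, lvl) {
    tbl <- dplyr::inner_join(doc_pairs, cts$b, by = c("gene_i", "gene_j"))
    if (nrow(tbl) == 0) return(NULL)
    tbl$level <- lvl
    tbl$n <- cts$n
    tbl$a_i <- cts$a$a[match(tbl$gene_i, cts$a$gene_id)]
    tbl$a_j <- cts$a$a[match(tbl$gene_j, cts$a$gene_id)]
    if (lvl %in% c("sentence", "paragraph")) {
      key <- paste(tbl$gene_i, tbl$gene_j, sep = "\r")
      dl_tbl <- cts$pair_docs
      d_level <- dl_tbl$d[match(key, paste(dl_tbl$gene_i, dl_tbl$gene_j, sep = "\r"))]
      d_level[is.na(d_level)] <- 0L
      dd <- d_doc[match(key, paste(doc_pairs$gene_i, doc_pairs$gene_j, sep = "\r"))]
      tbl$odds_ratio <- odds_ratio_from_doc_counts(d_level, dd, n_docs)
    } else {
      tbl$odds_ratio <- NA_real_
    }
    tbl
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(gene_i = character(0), gene_j = character(0),
                          level = character(0), n = integer(0),
                          a_i = integer(0), a_j = integer(0), b = integer(0),
                          p_i = double(0), p_j = double(0), p_ij = double(0),
                          mi = double(0), odds_ratio = double(0),
                          chi2 = double(0), p_value = double(0),
                          adjusted_p = double(0)))
  }
  out <- out |>
    dplyr::mutate(
      p_i = .data$a_i / .data$n,
      p_j = .data$a_j / .data$n,
      p_ij = .data$b / .data$n,
      mi = mutual_information(.data$p_i, .data$p_j, .data$p_ij))
  stat <- chi2_stat(out$n, out$a_i, out$a_j, out$b)
  out$chi2 <- stat$chi2
  out$p_value <- stat$p_value
  out <- out |>
    dplyr::group_by(.data$level) |>
    dplyr::mutate(adjusted_p = if (adjust_p)
      stats::p.adjust(.data$p_value, method = "BH") else NA_real_) |>
    dplyr::ungroup() |>
    dplyr::mutate(level = factor(.data$level,
                                 levels = c("sentence", "paragraph", "document"))) |>
    dplyr::arrange(.data$gene_i, .data$gene_j, .data$level) |>
    dplyr::mutate(level = as.character(.data$level)) |>
    dplyr::select("gene_i", "gene_j", "level", "n", "a_i", "a_j", "b",
                  "p_i", "p_j", "p_ij", "mi", "odds_ratio", "chi2",
                  "p_value", "adjusted_p")
  out
}

#' Write the pair statistics table as TSV
#'
#' @param pairs Pair table from [pair_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pair_table_tsv <- function(pairs, path) {
  readr::write_tsv(pairs, path)
  invisible(path)
}
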