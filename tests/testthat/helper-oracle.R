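# Independent brute-force oracles. These deliberately avoid the package's
# own counting/matching code paths: plain loops over a dense indicator
# matrix and direct evaluation of the defining formulas.

# Materialize the full unit x gene indicator matrix for one level and
# derive n / a / b / d by exhaustive looping.
oracle_counts <- function(segments, mentions, level) {
  paragraphs <- attr(segments, "paragraphs")
  doc_ids <- attr(segments, "doc_ids")
  units <- switch(level,
    sentence = unique(paste(segments$doc_id, segments$paragraph,
                            segments$sentence, sep = "\r")),
    paragraph = unique(paste(paragraphs$doc_id, paragraphs$paragraph, sep = "\r")),
    document = doc_ids)
  genes <- sort(unique(mentions$gene_id))
  y <- matrix(0L, nrow = length(units), ncol = length(genes),
              dimnames = list(units, genes))
  if (nrow(mentions) > 0) {
    munit <- switch(level,
      sentence = paste(mentions$doc_id, mentions$paragraph,
                       mentions$sentence, sep = "\r"),
      paragraph = paste(mentions$doc_id, mentions$paragraph, sep = "\r"),
      document = mentions$doc_id)
    for (k in seq_len(nrow(mentions))) {
      y[munit[k], mentions$gene_id[k]] <- 1L
    }
  }
  n <- length(units)
  a <- if (length(genes)) colSums(y) else integer(0)
  b <- list()
  d <- list()
  unit_doc <- vapply(strsplit(units, "\r"), `[`, character(1), 1)
  if (length(genes) >= 2) {
    for (i in seq_len(length(genes) - 1)) {
      for (j in (i + 1):length(genes)) {
        phi <- y[, i] * y[, j]
        if (sum(phi) > 0) {
          key <- paste(genes[i], genes[j], sep = "\r")
          b[[key]] <- sum(phi)
          d[[key]] <- length(unique(unit_doc[phi == 1]))
        }
      }
    }
  }
  list(n = n, a = a, b = b, d = d, y = y, genes = genes)
}

# Direct evaluation of the printed formulas from counts.
oracle_mi <- function(n, a_i, a_j, b) {
  p_i <- a_i / n; p_j <- a_j / n; p_ij <- b / n
  if (p_ij == 0) return(0)
  p_ij * log(p_ij / (p_i * p_j))
}

oracle_chi2 <- function(n, a_i, a_j, b) {
  p_phi <- b / n
  n1 <- n * p_phi
  n2 <- (1 - p_phi) * n
  m1 <- n * (a_i / n) * (a_j / n)
  m2 <- n * (1 - (a_i / n) * (a_j / n))
  term2 <- if (m2 == 0) { if (n2 == 0) 0 else NA_real_ } else (n2 - m2)^2 / m2
  x2 <- (n1 - m1)^2 / m1 + term2
  list(chi2 = x2, p_value = stats::pchisq(x2, df = 1, lower.tail = FALSE))
}

oracle_odds_ratio <- function(d_level, d_doc, n_docs) {
  q_l <- d_level / n_docs
  q_d <- d_doc / n_docs
  if (q_l == q_d) return(1)
  if (q_d == 1) return(0)
  (q_l / (1 - q_l)) / (q_d / (1 - q_d))
}

# Brute-force exact matcher: tests every (term, position) pair with
# boundary checks, then resolves overlaps by repeatedly taking the
# leftmost (ties: longest) remaining candidate.
oracle_find_mentions <- function(segments, index) {
  case_sensitive <- attr(index, "case_sensitive")
  out <- list()
  for (r in seq_len(nrow(segments))) {
    text <- segments$text[r]
    cmp_text <- if (case_sensitive) text else tolower(text)
    nc <- nchar(text)
    cand <- list()
    for (t in seq_len(nrow(index))) {
      term <- index$term[[t]]
      lt <- nchar(term)
      if (lt > nc) next
      for (pos in seq_len(nc - lt + 1)) {
        if (substr(cmp_text, pos, pos + lt - 1) == term) {
          before <- if (pos == 1) "" else substr(text, pos - 1, pos - 1)
          after <- if (pos + lt - 1 == nc) "" else substr(text, pos + lt, pos + lt)
          bad <- function(ch) nzchar(ch) && grepl("[A-Za-z0-9Ͱ-Ͽ]", ch)
          if (!bad(before) && !bad(after)) {
            cand[[length(cand) + 1]] <- list(start = pos, last = pos + lt - 1, t = t)
          }
        }
      }
    }
    # leftmost-longest selection; candidates sharing the picked span (an
    # ambiguous term) are kept, all other overlaps are discarded
    taken <- list()
    while (length(cand) > 0) {
      starts <- vapply(cand, `[[`, numeric(1), "start")
      lens <- vapply(cand, function(x) x$last - x$start, numeric(1))
      best <- order(starts, -lens)[1]
      pick <- cand[[best]]
      same_span <- Filter(function(x) x$start == pick$start && x$last == pick$last, cand)
      taken <- c(taken, same_span)
      cand <- Filter(function(x) x$start > pick$last || x$last < pick$start, cand)
    }
    for (pick in taken) {
      for (gid in index$gene_ids[[pick$t]]) {
        out[[length(out) + 1]] <- tibble::tibble(
          doc_id = segments$doc_id[r], paragraph = segments$paragraph[r],
          sentence = segments$sentence[r], gene_id = gid,
          surface = substr(text, pick$start, pick$last),
          start = as.integer(pick$start), end = as.integer(pick$last + 1L))
      }
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble::tibble(doc_id = character(0), paragraph = integer(0),
                          sentence = integer(0), gene_id = character(0),
                          surface = character(0), start = integer(0),
                          end = integer(0)))
  }
  dplyr::arrange(dplyr::distinct(res), doc_id, paragraph, sentence, start, gene_id)
}
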