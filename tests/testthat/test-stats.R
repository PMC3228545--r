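counts_of <- function(n, a, b_tbl = NULL, level = "document") {
  structure(list(
    level = level, n = as.integer(n),
    a = tibble::tibble(gene_id = names(a), a = as.integer(unname(a))),
    b = if (is.null(b_tbl)) tibble::tibble(gene_i = character(0),
                                           gene_j = character(0),
                                           b = integer(0)) else b_tbl,
    pair_docs = tibble::tibble(gene_i = character(0), gene_j = character(0),
                               d = integer(0))),
    class = "cooc_counts")
}

test_that("counting uses indicator semantics at each granularity", {
  cp <- two_sentence_corpus()
  cs <- count_occurrences(cp$segments, cp$mentions, "sentence")
  expect_equal(cs$n, 2L)
  expect_equal(cs$a$a[match(c("g1", "g2"), cs$a$gene_id)], c(2L, 1L))
  expect_equal(cs$b$b, 1L)

  cd <- count_occurrences(cp$segments, cp$mentions, "document")
  expect_equal(cd$n, 1L)
  expect_equal(cd$a$a, c(1L, 1L))
  expect_equal(cd$b$b, 1L)

  # repeated mentions in one sentence count that sentence once
  rep_m <- dplyr::bind_rows(cp$mentions,
                            tibble::tibble(doc_id = "d1", paragraph = 0L,
                                           sentence = 0L, gene_id = "g1",
                                           surface = "x", start = 5L, end = 6L))
  cs2 <- count_occurrences(cp$segments, rep_m, "sentence")
  expect_equal(cs2$a$a[cs2$a$gene_id == "g1"], 2L)

  expect_error(count_occurrences(make_segments(data.frame(
    doc_id = character(0), paragraph = integer(0), sentence = integer(0)),
    doc_ids = character(0)), cp$mentions, "document"), "empty corpus")
})

test_that("mutual information follows the single-cell nats formula with its limit convention", {
  expect_equal(mutual_information(0.5, 0.5, 0.25), 0)
  expect_equal(mutual_information(0.5, 0.5, 0.5), 0.5 * log(2))
  expect_equal(mutual_information(0.3, 0.2, 0), 0)
  expect_error(mutual_information(0.2, 0.2, 0.3), "inconsistent")
  expect_error(mutual_information(0, 0.5, 0.1), "inconsistent")
})

test_that("MI is positive above independence and negative below", {
  set.seed(41)
  for (rep in 1:200) {
    p_i <- runif(1, 0.05, 0.95)
    p_j <- runif(1, 0.05, 0.95)
    p_ij <- runif(1, 0, min(p_i, p_j))
    mi <- mutual_information(p_i, p_j, p_ij)
    if (p_ij == 0) {
      expect_equal(mi, 0)
    } else {
      expect_equal(sign(mi), sign(p_ij - p_i * p_j))
    }
  }
})

test_that("concentration odds ratio matches its defining formula and conventions", {
  # hand evaluation: d_level=1, d_doc=2, n_docs=10
  cl <- counts_of(100, c(g1 = 10, g2 = 10), level = "sentence")
  cl$pair_docs <- tibble::tibble(gene_i = "g1", gene_j = "g2", d = 1L)
  cd <- counts_of(10, c(g1 = 5, g2 = 5),
                  tibble::tibble(gene_i = "g1", gene_j = "g2", b = 2L))
  expect_equal(concentration_odds_ratio(cl, cd, c("g1", "g2")),
               (0.1 / 0.9) / (0.2 / 0.8))

  # every document-level co-occurrence concentrated in one sentence
  cl$pair_docs$d <- 2L
  expect_equal(concentration_odds_ratio(cl, cd, c("g1", "g2")), 1)

  # co-occur only across different sentences
  cl$pair_docs$d <- 0L
  expect_equal(concentration_odds_ratio(cl, cd, c("g2", "g1")), 0)

  # boundary q = 1 convention
  cd2 <- counts_of(2, c(g1 = 2, g2 = 2),
                   tibble::tibble(gene_i = "g1", gene_j = "g2", b = 2L))
  cl2 <- counts_of(10, c(g1 = 4, g2 = 4), level = "sentence")
  cl2$pair_docs <- tibble::tibble(gene_i = "g1", gene_j = "g2", d = 2L)
  expect_equal(concentration_odds_ratio(cl2, cd2, c("g1", "g2")), 1)

  # pair absent at document level is an error
  expect_error(concentration_odds_ratio(cl, counts_of(10, c(g1 = 5, g2 = 5)),
                                        c("g1", "g2")), "document level")
})

test_that("the two-cell chi-square statistic matches hand evaluation", {
  ind <- counts_of(100, c(g1 = 50, g2 = 50),
                   tibble::tibble(gene_i = "g1", gene_j = "g2", b = 25L))
  r <- pearson_chi2(ind, c("g1", "g2"))
  expect_equal(r$chi2, 0)
  expect_equal(r$p_value, 1)

  dep <- counts_of(100, c(g1 = 50, g2 = 50),
                   tibble::tibble(gene_i = "g1", gene_j = "g2", b = 50L))
  r2 <- pearson_chi2(dep, c("g1", "g2"))
  expect_equal(r2$chi2, 25^2 / 25 + 25^2 / 75)
  expect_equal(r2$chi2, 100 / 3, tolerance = 1e-12)
  expect_equal(r2$p_value, pchisq(100 / 3, 1, lower.tail = FALSE))
  expect_equal(r2$p_value, 7.76e-9, tolerance = 1e-3)

  sat <- counts_of(10, c(g1 = 10, g2 = 10),
                   tibble::tibble(gene_i = "g1", gene_j = "g2", b = 10L))
  r3 <- pearson_chi2(sat, c("g1", "g2"))
  expect_equal(r3$chi2, 0)
  expect_equal(r3$p_value, 1)

  # zero marginal: flagged as not computable, not a number
  zero <- counts_of(10, c(g1 = 0, g2 = 5))
  expect_warning(r4 <- pearson_chi2(zero, c("g1", "g2")), "not computable")
  expect_true(is.na(r4$chi2))
})

test_that("the closed-form chi-square tail matches numerical integration of the density", {
  dens <- function(t) exp(-t / 2) / sqrt(2 * pi * t)
  for (x in c(0.01, 0.5, 1, 2, 5, 10, 20, 35, 50)) {
    num <- stats::integrate(dens, x, Inf, rel.tol = 1e-12)$value
    expect_equal(chi2_pvalue(x), num, tolerance = 1e-8)
  }
  expect_equal(chi2_pvalue(0), 1)
})

test_that("the conventional 2x2 contingency variant differs from the reported two-cell statistic", {
  cts <- counts_of(100, c(g1 = 50, g2 = 50),
                   tibble::tibble(gene_i = "g1", gene_j = "g2", b = 40L))
  two_cell <- pearson_chi2(cts, c("g1", "g2"))
  contingency <- pearson_chi2(cts, c("g1", "g2"), variant = "contingency")
  # cross-check the 2x2 variant against stats::chisq.test without continuity
  # correction
  tab <- matrix(c(40, 10, 10, 40), 2)
  ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  expect_equal(contingency$chi2, unname(ref$statistic))
  expect_false(isTRUE(all.equal(two_cell$chi2, contingency$chi2)))
})

test_that("pair_table emits rows only at levels of co-occurrence, with coherent columns", {
  cp <- two_sentence_corpus()
  tbl <- pair_table(cp$segments, cp$mentions)
  expect_setequal(tbl$level, c("sentence", "paragraph", "document"))
  expect_true(all(tbl$gene_i == "g1" & tbl$gene_j == "g2"))
  expect_true(all(tbl$p_ij <= pmin(tbl$p_i, tbl$p_j) + 1e-15))
  expect_true(all(tbl$b <= pmin(tbl$a_i, tbl$a_j)))
  expect_true(all(tbl$p_value > 0 & tbl$p_value <= 1))
  expect_true(is.na(tbl$odds_ratio[tbl$level == "document"]))

  # pair co-occurring in a document but never inside one sentence
  units <- data.frame(doc_id = "d1", paragraph = c(0L, 1L), sentence = 0L)
  segs <- make_segments(units)
  mns <- tibble::tibble(doc_id = "d1", paragraph = c(0L, 1L), sentence = 0L,
                        gene_id = c("g1", "g2"), surface = "x",
                        start = 1L, end = 2L)
  tbl2 <- pair_table(segs, mns)
  expect_false("sentence" %in% tbl2$level)
  expect_true("document" %in% tbl2$level)
})

test_that("BH adjustment is monotone above raw p-values within each level", {
  set.seed(43)
  rs <- random_structure()
  tbl <- pair_table(rs$segments, rs$mentions, adjust_p = TRUE)
  if (nrow(tbl) > 0) {
    expect_true(all(tbl$adjusted_p >= tbl$p_value - 1e-15))
    expect_true(all(tbl$adjusted_p <= 1))
    for (lvl in unique(tbl$level)) {
      sub <- tbl[tbl$level == lvl, ]
      expect_equal(sub$adjusted_p, stats::p.adjust(sub$p_value, "BH"))
    }
  }
})

test_that("counts and statistics agree with the brute-force indicator-matrix oracle", {
  set.seed(44)
  for (rep in 1:30) {
    rs <- random_structure()
    lvl <- sample(c("sentence", "paragraph", "document"), 1)
    got <- count_occurrences(rs$segments, rs$mentions, lvl)
    want <- oracle_counts(rs$segments, rs$mentions, lvl)
    expect_equal(got$n, want$n)
    expect_equal(got$a$a, as.integer(unname(want$a[got$a$gene_id])))
    for (k in seq_len(nrow(got$b))) {
      key <- paste(got$b$gene_i[k], got$b$gene_j[k], sep = "\r")
      expect_equal(got$b$b[k], as.integer(want$b[[key]]))
      a_i <- want$a[[got$b$gene_i[k]]]
      a_j <- want$a[[got$b$gene_j[k]]]
      expect_equal(
        mutual_information(a_i / got$n, a_j / got$n, got$b$b[k] / got$n),
        oracle_mi(want$n, a_i, a_j, want$b[[key]]), tolerance = 1e-12)
      ref <- oracle_chi2(want$n, a_i, a_j, want$b[[key]])
      r <- pearson_chi2(got, c(got$b$gene_i[k], got$b$gene_j[k]))
      expect_equal(r$chi2, ref$chi2, tolerance = 1e-12)
      expect_equal(r$p_value, ref$p_value, tolerance = 1e-8)
    }
    expect_equal(length(want$b), nrow(got$b))
  }
})

test_that("co-occurrence counts are monotone across granularities", {
  set.seed(45)
  for (rep in 1:10) {
    rs <- random_structure()
    cs <- count_occurrences(rs$segments, rs$mentions, "sentence")
    cp <- count_occurrences(rs$segments, rs$mentions, "paragraph")
    cd <- count_occurrences(rs$segments, rs$mentions, "document")
    key <- function(x) paste(x$gene_i, x$gene_j, sep = "\r")
    for (k in seq_len(nrow(cs$b))) {
      bp <- cp$b$b[match(key(cs$b)[k], key(cp$b))]
      expect_true(!is.na(bp) && cs$b$b[k] <= bp)
    }
    for (k in seq_len(nrow(cp$b))) {
      bd <- cd$b$b[match(key(cp$b)[k], key(cd$b))]
      expect_true(!is.na(bd) && bd >= 1)
    }
    expect_true(all(cd$b$b <= pmin(
      cd$a$a[match(cd$b$gene_i, cd$a$gene_id)],
      cd$a$a[match(cd$b$gene_j, cd$a$gene_id)])))
    expect_true(all(cd$a$a <= cd$n))
  }
})
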