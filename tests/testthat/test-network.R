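analysis_fixture <- function(seed = 5) {
  model <- corpus_model(genes = 6, planted_pairs = data.frame(
    gene_i = "g01", gene_j = "g02", excess = 0.05),
    n_documents = 12, p_default = 0.15, protected_token_rate = 0.1,
    seed = seed)
  sc <- generate_corpus(model)
  analyze_cooccurrence(sc$docs, sc$dictionary)
}

test_that("networks are built per level with the documented membership rules", {
  res <- analysis_fixture()
  pairs <- res$pair_table
  net_s <- build_network(pairs, "sentence")
  net_pd <- build_network(pairs, "paragraph_document")

  edge_keys <- function(net) {
    if (igraph::ecount(net$graph) == 0) return(character(0))
    el <- igraph::as_edgelist(net$graph)
    paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  }
  # sentence edges are exactly the sentence-level rows
  sent_rows <- pairs[pairs$level == "sentence", ]
  expect_setequal(edge_keys(net_s), paste(sent_rows$gene_i, sent_rows$gene_j))
  # subset invariant
  expect_true(all(edge_keys(net_s) %in% edge_keys(net_pd)))
  # no self loops, endpoints exist
  expect_false(any(igraph::which_loop(net_pd$graph)))
  expect_true(all(unique(c(sent_rows$gene_i, sent_rows$gene_j)) %in%
                    igraph::V(net_s$graph)$name))

  # paragraph-level statistics preferred over document-level on shared edges
  lvls <- igraph::E(net_pd$graph)$stat_level
  expect_true(all(lvls %in% c("paragraph", "document")))
  both <- pairs[pairs$level == "paragraph", c("gene_i", "gene_j")]
  if (nrow(both) > 0) {
    el <- igraph::as_edgelist(net_pd$graph)
    on_par <- paste(el[, 1], el[, 2]) %in% paste(both$gene_i, both$gene_j)
    expect_true(all(lvls[on_par] == "paragraph"))
  }
})

test_that("single-pair and empty inputs give the degenerate networks", {
  cp <- two_sentence_corpus()
  tbl <- pair_table(cp$segments, cp$mentions)
  ns <- build_network(tbl, "sentence")
  npd <- build_network(tbl, "paragraph_document")
  expect_equal(igraph::ecount(ns$graph), 1)
  expect_equal(igraph::ecount(npd$graph), 1)

  # document-only pair appears only in the combined network
  units <- data.frame(doc_id = "d1", paragraph = c(0L, 1L), sentence = 0L)
  segs <- make_segments(units)
  mns <- tibble::tibble(doc_id = "d1", paragraph = c(0L, 1L), sentence = 0L,
                        gene_id = c("g1", "g2"), surface = "x",
                        start = 1L, end = 2L)
  tbl2 <- pair_table(segs, mns)
  expect_equal(igraph::ecount(build_network(tbl2, "sentence")$graph), 0)
  expect_equal(igraph::ecount(build_network(tbl2, "paragraph_document")$graph), 1)

  empty <- tbl[0, ]
  expect_equal(igraph::vcount(build_network(empty, "sentence")$graph), 0)
})

test_that("edge styling maps MI to thickness and p-value to a red-green ramp, monotonically", {
  tbl <- tibble::tibble(
    gene_i = c("a", "a", "b", "c"), gene_j = c("b", "c", "c", "d"),
    level = "sentence", n = 100L, a_i = 10L, a_j = 10L, b = c(1L, 4L, 8L, 4L),
    p_i = 0.1, p_j = 0.1, p_ij = c(.01, .04, .08, .04),
    mi = c(0, 0.05, 0.2, 0.05), odds_ratio = 1, chi2 = c(0, 10, 50, 10),
    p_value = c(1, 1e-3, 1e-12, 1e-3), adjusted_p = NA_real_)
  net <- style_edges(build_network(tbl, "sentence"))
  e <- igraph::E(net$graph)
  expect_equal(e$color[e$p_value == 1], "#FF0000")
  expect_equal(e$color[e$p_value <= 1e-10], "#00FF00")
  # equal MI, equal thickness; higher MI, thicker
  th <- e$thickness[order(e$mi)]
  expect_true(all(diff(th) >= 0))
  expect_equal(e$thickness[e$mi == 0.05][1], e$thickness[e$mi == 0.05][2])
  # greener with smaller p
  green <- function(col) grDevices::col2rgb(col)["green", ]
  expect_true(all(diff(green(e$color)[order(-e$p_value)]) >= 0))

  # constant MI degenerates to the mid thickness
  tbl_const <- tbl[1:2, ]
  tbl_const$mi <- 0.1
  net2 <- style_edges(build_network(tbl_const, "sentence"),
                      thickness_range = c(1, 3))
  expect_true(all(igraph::E(net2$graph)$thickness == 2))
})

test_that("exports round-trip: XML reproduces the pair table, GraphML the topology", {
  res <- analysis_fixture()
  dir <- tempfile()
  paths <- export_results(res$networks, res$pair_table, res$docs,
                          res$genes_per_document, dir)
  expect_true(all(file.exists(
    file.path(dir, c("results.xml", "network_sentence.graphml",
                     "network_paragraph_document.graphml", "pair_table.tsv")))))

  back <- read_results_xml(file.path(dir, "results.xml"))
  expect_equal(as.data.frame(back), as.data.frame(res$pair_table))

  for (nm in names(res$networks)) {
    g <- igraph::read_graph(file.path(dir, paste0("network_", nm, ".graphml")),
                            format = "graphml")
    expect_equal(igraph::vcount(g), igraph::vcount(res$networks[[nm]]$graph))
    expect_equal(igraph::ecount(g), igraph::ecount(res$networks[[nm]]$graph))
    expect_true(all(c("mi", "p_value", "b") %in% igraph::edge_attr_names(g)))
  }
})

test_that("the results XML validates against the shipped schema, including empty runs", {
  xsd <- xml2::read_xml(system.file("extdata", "results.xsd", package = "litcooc"))
  res <- analysis_fixture()
  dir <- tempfile()
  export_results(res$networks, res$pair_table, res$docs,
                 res$genes_per_document, dir)
  expect_true(xml2::xml_validate(xml2::read_xml(file.path(dir, "results.xml")), xsd))

  # empty run still produces a valid document with empty sections
  dir2 <- tempfile()
  empty_net <- build_network(res$pair_table[0, ], "sentence")
  export_results(list(sentence = empty_net), res$pair_table[0, ],
                 res$docs[0, ], res$genes_per_document[0, ], dir2)
  doc <- xml2::read_xml(file.path(dir2, "results.xml"))
  expect_true(xml2::xml_validate(doc, xsd))
  expect_length(xml2::xml_find_all(doc, "//pair"), 0)
})

test_that("an unwritable export path is an error", {
  blocker <- tempfile()
  writeLines("x", blocker)
  res <- analysis_fixture()
  expect_error(export_results(res$networks, res$pair_table, res$docs,
                              res$genes_per_document,
                              file.path(blocker, "sub")))
})

test_that("autoplot returns a ggplot with one segment layer per network edge", {
  res <- analysis_fixture()
  p <- ggplot2::autoplot(res$networks$paragraph_document)
  expect_s3_class(p, "ggplot")
  expect_no_error(ggplot2::ggplot_build(p))
})
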