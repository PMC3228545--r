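#' Build a co-occurrence network from pair statistics
#'
#' Two graphs summarize a run: the sentence-level network contains pairs
#' co-occurring in at least one sentence; the combined paragraph/document
#' network contains pairs co-occurring in at least one paragraph or
#' document, with the paragraph-level statistics preferred for display when
#' present (falling back to document level). Nodes are all genes incident to
#' at least one edge, plus optionally a set of isolated query genes.
#'
#' @param pairs Pair table from [pair_table()].
#' @param level_tag `"sentence"` or `"paragraph_document"`.
#' @param gene_counts Optional document-level `cooc_counts` whose `a` table
#'   provides node occurrence counts.
#' @param gpd Optional [genes_per_document()] tibble; per-node document
#'   lists are attached as a node attribute.
#' @param include_genes Optional character vector of genes to include even
#'   when isolated.
#' @return An object of class `cooc_network`: a list with `graph` (an
#'   [igraph::igraph] with edge attributes `mi`, `p_value`, `b`,
#'   `odds_ratio`, `stat_level`) and `level_tag`.
#' @export
build_network <- function(pairs, level_tag = c("sentence", "paragraph_document"),
                          gene_counts = NULL, gpd = NULL,
                          include_genes = character(0)) {
  level_tag <- rlang::arg_match(level_tag)
  edges <- if (level_tag == "sentence") {
    pairs |> dplyr::filter(.data$level == "sentence")
  } else {
    pairs |>
      dplyr::filter(.data$level %in% c("paragraph", "document")) |>
      dplyr::group_by(.data$gene_i, .data$gene_j) |>
      dplyr::arrange(factor(.data$level, levels = c("paragraph", "document")),
                     .by_group = TRUE) |>
      dplyr::slice(1) |>
      dplyr::ungroup()
  }
  nodes <- sort(unique(c(edges$gene_i, edges$gene_j, include_genes)))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (nrow(edges) > 0) {
    g <- igraph::add_edges(
      g, rbind(match(edges$gene_i, nodes), match(edges$gene_j, nodes)),
      mi = edges$mi, p_value = edges$p_value, b = edges$b,
      odds_ratio = edges$odds_ratio, stat_level = edges$level)
  }
  if (!is.null(gene_counts)) {
    stopifnot(inherits(gene_counts, "cooc_counts"))
    a <- gene_counts$a$a[match(nodes, gene_counts$a$gene_id)]
    igraph::V(g)$a <- ifelse(is.na(a), 0L, a)
  }
  if (!is.null(gpd) && length(nodes) > 0) {
    doc_lists <- gpd |>
      dplyr::filter(.data$gene_id %in% nodes) |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::summarise(docs = paste(sort(.data$doc_id), collapse = ";"),
                       .groups = "drop")
    igraph::V(g)$documents <- doc_lists$docs[match(nodes, doc_lists$gene_id)]
  }
  structure(list(graph = g, level_tag = level_tag), class = "cooc_network")
}

#' @export
print.cooc_network <- function(x, ...) {
  cat("<cooc_network> ", x$level_tag, ": ",
      igraph::vcount(x$graph), " genes, ",
      igraph::ecount(x$graph), " edges\n", sep = "")
  invisible(x)
}

#' Attach display styling to network edges
#'
#' Edge thickness is an affine map of mutual information onto
#' `thickness_range` (all edges get the mid thickness when MI is constant).
#' Edge colour interpolates continuously from red (non-significant, p = 1)
#' to green (significant), on `-log10(p)` clamped to `[0, 10]`. Topology is
#' unchanged.
#'
#' @param net A `cooc_network`.
#' @param mi_range MI values mapped to the thickness extremes; defaults to
#'   the observed MI range.
#' @param thickness_range Numeric length-2, output thickness range.
#' @param logp_max Clamp anchor for `-log10(p)`; default 10.
#' @return The network with `thickness` and `color` edge attributes added.
#' @export
style_edges <- function(net, mi_range = NULL, thickness_range = c(0.5, 4),
                        logp_max = 10) {
  stopifnot(inherits(net, "cooc_network"))
  g <- net$graph
  if (igraph::ecount(g) > 0) {
    mi <- igraph::E(g)$mi
    if (is.null(mi_range)) mi_range <- range(mi)
    if (diff(mi_range) <= 0) {
      thick <- rep(mean(thickness_range), length(mi))
    } else {
      frac <- pmin(1, pmax(0, (mi - mi_range[1]) / diff(mi_range)))
      thick <- thickness_range[1] + frac * diff(thickness_range)
    }
    logp <- pmin(logp_max, pmax(0, -log10(igraph::E(g)$p_value))) / logp_max
    ramp <- grDevices::colorRamp(c("#FF0000", "#00FF00"))
    rgbm <- ramp(logp)
    igraph::E(g)$thickness <- thick
    igraph::E(g)$color <- grDevices::rgb(rgbm[, 1], rgbm[, 2], rgbm[, 3],
                                         maxColorValue = 255)
  }
  net$graph <- g
  net
}

#' Write a network as GraphML
#'
#' Edge attributes `mi`, `p_value`, `b`, `odds_ratio` (and any styling) are
#' carried in the file.
#'
#' @param net A `cooc_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  stopifnot(inherits(net, "cooc_network"))
  g <- net$graph
  # igraph's GraphML writer rejects NA in numeric attributes
  for (attrname in igraph::edge_attr_names(g)) {
    v <- igraph::edge_attr(g, attrname)
    if (is.numeric(v)) igraph::edge_attr(g, attrname) <- ifelse(is.na(v), -1, v)
    if (is.character(v)) igraph::edge_attr(g, attrname) <- ifelse(is.na(v), "", v)
  }
  for (attrname in igraph::vertex_attr_names(g)) {
    v <- igraph::vertex_attr(g, attrname)
    if (is.character(v)) igraph::vertex_attr(g, attrname) <- ifelse(is.na(v), "", v)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

num_attr <- function(x) {
  # full-precision decimal serialization so the XML round-trips exactly
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

#' Export all results of a run
#'
#' Writes (1) `results.xml` with `<documents>`, `<genes>`, `<pairs>` and
#' `<networks>` sections (schema shipped as `extdata/results.xsd`); (2) each
#' network as GraphML; (3) the pair table as TSV. Re-reading the XML with
#' [read_results_xml()] reproduces the pair table exactly. On any write
#' error, partially written files are removed.
#'
#' @param nets Named list of `cooc_network` objects (names used in
#'   filenames).
#' @param pairs Pair table from [pair_table()].
#' @param documents Document tibble of the analyzed corpus.
#' @param gpd [genes_per_document()] tibble.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
export_results <- function(nets, pairs, documents, gpd, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) rlang::abort(paste0("cannot create output directory: ", dir))
  written <- character(0)
  on_fail <- function(e) {
    file.remove(written[file.exists(written)])
    rlang::abort(paste0("export failed, partial outputs removed: ",
                        conditionMessage(e)))
  }
  tryCatch({
    xml_path <- file.path(dir, "results.xml")
    root <- xml2::xml_new_root("cooccurrence_results")

    docs_node <- xml2::xml_add_child(root, "documents")
    if (nrow(documents) > 0) {
      purrr::pwalk(list(documents$doc_id,
                        documents$source_name %||% NA,
                        documents$url %||% NA,
                        documents$doi %||% NA,
                        documents$title %||% NA,
                        documents$full_text_available %||% TRUE),
        function(doc_id, source_name, url, doi, title, fta) {
          d <- xml2::xml_add_child(docs_node, "document", id = doc_id,
                                   full_text = tolower(as.character(fta)))
          if (!is.na(source_name)) xml2::xml_set_attr(d, "source", source_name)
          if (!is.na(url)) xml2::xml_set_attr(d, "url", url)
          if (!is.na(doi)) xml2::xml_set_attr(d, "doi", doi)
          if (!is.na(title)) xml2::xml_set_attr(d, "title", title)
        })
    }

    genes_node <- xml2::xml_add_child(root, "genes")
    if (nrow(gpd) > 0) {
      gene_docs <- gpd |>
        dplyr::group_by(.data$gene_id) |>
        dplyr::summarise(docs = list(sort(.data$doc_id)), .groups = "drop")
      purrr::pwalk(gene_docs, function(gene_id, docs) {
        gnode <- xml2::xml_add_child(genes_node, "gene", id = gene_id)
        purrr::walk(docs, ~ xml2::xml_add_child(gnode, "in_document", ref = .x))
      })
    }

    pairs_node <- xml2::xml_add_child(root, "pairs")
    if (nrow(pairs) > 0) {
      purrr::pwalk(pairs, function(gene_i, gene_j, level, n, a_i, a_j, b,
                                   p_i, p_j, p_ij, mi, odds_ratio, chi2,
                                   p_value, adjusted_p) {
        xml2::xml_add_child(pairs_node, "pair",
          gene_i = gene_i, gene_j = gene_j, level = level,
          n = as.character(n), a_i = as.character(a_i),
          a_j = as.character(a_j), b = as.character(b),
          p_i = num_attr(p_i), p_j = num_attr(p_j), p_ij = num_attr(p_ij),
          mi = num_attr(mi), odds_ratio = num_attr(odds_ratio),
          chi2 = num_attr(chi2), p_value = num_attr(p_value),
          adjusted_p = num_attr(adjusted_p))
      })
    }

    nets_node <- xml2::xml_add_child(root, "networks")
    purrr::iwalk(nets, function(net, nm) {
      nnode <- xml2::xml_add_child(nets_node, "network",
                                   level_tag = net$level_tag,
                                   nodes = as.character(igraph::vcount(net$graph)),
                                   edges = as.character(igraph::ecount(net$graph)),
                                   graphml = paste0("network_", nm, ".graphml"))
    })

    xml2::write_xml(root, xml_path)
    written <- c(written, xml_path)

    for (nm in names(nets)) {
      gpath <- file.path(dir, paste0("network_", nm, ".graphml"))
      write_network_graphml(nets[[nm]], gpath)
      written <- c(written, gpath)
    }

    tsv_path <- file.path(dir, "pair_table.tsv")
    write_pair_table_tsv(pairs, tsv_path)
    written <- c(written, tsv_path)
  }, error = on_fail)
  invisible(written)
}

#' Read the pair statistics back from a results XML file
#'
#' @param path Path to a `results.xml` written by [export_results()].
#' @return Pair table tibble identical to the one that was exported.
#' @export
read_results_xml <- function(path) {
  doc <- xml2::read_xml(path)
  nodes <- xml2::xml_find_all(doc, "/cooccurrence_results/pairs/pair")
  at <- function(nm) xml2::xml_attr(nodes, nm)
  num <- function(nm) {
    v <- at(nm)
    out <- suppressWarnings(as.numeric(v))
    out[v == "NA"] <- NA_real_
    out
  }
  tibble::tibble(
    gene_i = at("gene_i"), gene_j = at("gene_j"), level = at("level"),
    n = as.integer(at("n")), a_i = as.integer(at("a_i")),
    a_j = as.integer(at("a_j")), b = as.integer(at("b")),
    p_i = num("p_i"), p_j = num("p_j"), p_ij = num("p_ij"),
    mi = num("mi"), odds_ratio = num("odds_ratio"), chi2 = num("chi2"),
    p_value = num("p_value"), adjusted_p = num("adjusted_p"))
}

#' Plot a co-occurrence network with ggplot2
#'
#' Edge width is proportional to mutual information, edge colour to the
#' p-value (red = non-significant, green = significant), matching
#' [style_edges()].
#'
#' @param object A `cooc_network`.
#' @param seed Layout seed (Fruchterman-Reingold).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cooc_network
#' @export
autoplot.cooc_network <- function(object, seed = 42L, ...) {
  net <- style_edges(object)
  g <- net$graph
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  lay <- igraph::layout_with_fr(g)
  nodes <- tibble::tibble(name = igraph::V(g)$name,
                          x = lay[, 1], y = lay[, 2])
  p <- ggplot2::ggplot()
  if (igraph::ecount(g) > 0) {
    el <- igraph::as_edgelist(g)
    edges <- tibble::tibble(
      x = nodes$x[match(el[, 1], nodes$name)],
      y = nodes$y[match(el[, 1], nodes$name)],
      xend = nodes$x[match(el[, 2], nodes$name)],
      yend = nodes$y[match(el[, 2], nodes$name)],
      thickness = igraph::E(g)$thickness,
      color = igraph::E(g)$color)
    p <- p + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend),
      linewidth = edges$thickness, colour = edges$color, alpha = 0.8)
  }
  p +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y), size = 3) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$name),
                       vjust = -1, size = 3) +
    ggplot2::theme_void() +
    ggplot2::ggtitle(paste0("Co-occurrence network (", net$level_tag, ")"))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
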