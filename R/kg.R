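#' Assemble the TF/pathway knowledge graph
#'
#' Builds a directed multigraph with two node kinds. TF nodes carry the list
#' of `(cascade_id, level)` memberships of the cascades they appear in;
#' pathway nodes carry the pathway description. TF -> TF edges are added for
#' every consecutive pair in every cascade with weight 1 each, so a pair
#' shared by several cascades gets parallel edges. For each cascade whose
#' enrichment contains a pathway with `p_adjusted <= alpha`, an edge is
#' added from that cascade's terminal TF to the pathway node, attributed
#' with `p`, `z` and `combined` and weighted `1 - p_adjusted` (clipped to
#' \[0, 1\]; a convention monotone in significance — the weight itself is
#' not defined by any external standard). Pathway nodes never have outgoing
#' edges to TFs.
#'
#' @param cascades List of chains from [enumerate_cascades()].
#' @param enrichment_results Data frame of [enrich_cascades()] `results`
#'   rows (must carry `cascade_id`).
#' @param alpha Significance filter on `p_adjusted`, default 0.05.
#' @return An igraph directed multigraph with vertex attributes `kind`
#'   ("TF"/"pathway"), `cascade_memberships` (JSON string on TF nodes),
#'   `description` (pathway nodes); edge attributes `kind`
#'   ("regulates"/"enriched_in"), `weight`, `p`, `z`, `combined`,
#'   `cascade_id`.
#' @export
assemble_kg <- function(cascades, enrichment_results, alpha = 0.05) {
  n_cas <- length(cascades)
  if (nrow(enrichment_results)) {
    bad <- setdiff(unique(enrichment_results$cascade_id), seq_len(n_cas))
    bad <- bad[!is.na(bad)]
    if (length(bad)) {
      stop("enrichment results cite unknown cascade id(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  tf_nodes <- sort(unique(unlist(cascades)))
  memberships <- lapply(tf_nodes, function(tf) {
    hits <- which(vapply(cascades, function(ch) tf %in% ch, logical(1)))
    data.frame(cascade_id = hits,
               level = vapply(cascades[hits], function(ch)
                 length(ch) - 1L, integer(1)))
  })
  sig <- enrichment_results[!is.na(enrichment_results$p_adjusted) &
                              enrichment_results$p_adjusted <= alpha, ,
                            drop = FALSE]
  pw_nodes <- sort(unique(sig$pathway))

  edges <- list()
  for (i in seq_along(cascades)) {
    ch <- cascades[[i]]
    if (length(ch) < 2L) next
    for (k in seq_len(length(ch) - 1L)) {
      edges[[length(edges) + 1L]] <- data.frame(
        from = ch[k], to = ch[k + 1L], kind = "regulates", weight = 1,
        p = NA_real_, z = NA_real_, combined = NA_real_, cascade_id = i,
        stringsAsFactors = FALSE)
    }
  }
  if (nrow(sig)) {
    for (r in seq_len(nrow(sig))) {
      cid <- sig$cascade_id[r]
      terminal <- cascades[[cid]][length(cascades[[cid]])]
      edges[[length(edges) + 1L]] <- data.frame(
        from = terminal, to = sig$pathway[r], kind = "enriched_in",
        weight = min(max(1 - sig$p_adjusted[r], 0), 1),
        p = sig$p[r], z = sig$z[r], combined = sig$combined[r],
        cascade_id = cid, stringsAsFactors = FALSE)
    }
  }
  vertices <- data.frame(
    name = c(tf_nodes, pw_nodes),
    kind = c(rep("TF", length(tf_nodes)), rep("pathway", length(pw_nodes))),
    cascade_memberships = c(
      vapply(memberships, function(m)
        as.character(jsonlite::toJSON(m, dataframe = "columns")),
        character(1)),
      rep(NA_character_, length(pw_nodes))),
    description = c(rep(NA_character_, length(tf_nodes)),
                    rep("pathway", length(pw_nodes))),
    stringsAsFactors = FALSE
  )
  edf <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(), to = character(), kind = character(),
               weight = numeric(), p = numeric(), z = numeric(),
               combined = numeric(), cascade_id = integer(),
               stringsAsFactors = FALSE)
  if (!nrow(vertices)) return(igraph::make_empty_graph(directed = TRUE))
  igraph::graph_from_data_frame(edf, directed = TRUE, vertices = vertices)
}

#' Summarize a knowledge graph
#'
#' Counts nodes and edges by kind and summarizes the TF -> pathway edge
#' weights (min, max, mean, sd).
#'
#' @param kg Knowledge graph from [assemble_kg()].
#' @return List with `nodes` (named counts by kind, plus total), `edges`
#'   (named counts by kind, plus total) and `pathway_edge_weights`
#'   (min/max/mean/sd, all `NA` when there are no TF -> pathway edges).
#' @export
kg_summary <- function(kg) {
  vkind <- if (igraph::vcount(kg)) igraph::V(kg)$kind else character()
  ekind <- if (igraph::ecount(kg)) igraph::E(kg)$kind else character()
  nodes <- c(TF = sum(vkind == "TF"), pathway = sum(vkind == "pathway"),
             total = length(vkind))
  edges <- c(tf_tf = sum(ekind == "regulates"),
             tf_pathway = sum(ekind == "enriched_in"),
             total = length(ekind))
  w <- if (any(ekind == "enriched_in")) {
    igraph::E(kg)$weight[ekind == "enriched_in"]
  } else numeric()
  weights <- if (length(w)) {
    c(min = min(w), max = max(w), mean = mean(w),
      sd = if (length(w) > 1) stats::sd(w) else NA_real_)
  } else c(min = NA_real_, max = NA_real_, mean = NA_real_, sd = NA_real_)
  list(nodes = nodes, edges = edges, pathway_edge_weights = weights)
}

#' Export a knowledge graph to GraphML, JSON node-link, or an edge list
#'
#' GraphML and JSON round-trip losslessly through [import_kg()] (nodes,
#' edges and attributes); the TSV edge list keeps only endpoints, kind and
#' weight and is documented as lossy.
#'
#' @param kg Knowledge graph from [assemble_kg()].
#' @param path Output file path.
#' @param format One of "graphml", "json", "edgelist".
#' @return Invisibly, `path`.
#' @export
export_kg <- function(kg, path, format = c("graphml", "json", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(kg, path, format = "graphml")
  } else if (format == "json") {
    vs <- igraph::as_data_frame(kg, what = "vertices")
    es <- igraph::as_data_frame(kg, what = "edges")
    jsonlite::write_json(list(nodes = vs, links = es), path, digits = NA,
                         na = "null")
  } else {
    es <- igraph::as_data_frame(kg, what = "edges")
    utils::write.table(es[, c("from", "to", "kind", "weight")], path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Import a knowledge graph written by [export_kg()]
#'
#' @param path File path.
#' @param format "graphml" or "json" (the edge list is lossy and cannot be
#'   re-imported as a full knowledge graph).
#' @return An igraph graph.
#' @export
import_kg <- function(path, format = c("graphml", "json")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    # igraph stores vertex names in "name"; drop its internal "id" attr
    if ("id" %in% igraph::vertex_attr_names(g)) {
      g <- igraph::delete_vertex_attr(g, "id")
    }
    return(g)
  }
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  vs <- as.data.frame(obj$nodes, stringsAsFactors = FALSE)
  es <- as.data.frame(obj$links, stringsAsFactors = FALSE)
  if (!nrow(vs)) return(igraph::make_empty_graph(directed = TRUE))
  if (!nrow(es) || !all(c("from", "to") %in% names(es))) {
    es <- data.frame(from = character(), to = character(),
                     stringsAsFactors = FALSE)
  }
  igraph::graph_from_data_frame(es, directed = TRUE, vertices = vs)
}
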