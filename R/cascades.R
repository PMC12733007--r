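#' Build the directed TF graph from a deduplicated edge table
#'
#' Constructs an [igraph][igraph::graph_from_data_frame] directed graph over
#' the TFs appearing in at least one edge (isolated TFs are excluded by
#' construction). Edges must already be deduplicated per orientation;
#' duplicates or self-loops are rejected.
#'
#' @param edges Data frame with columns `regulator`, `target` and optionally
#'   `mode`, `score` (kept as edge attributes).
#' @return An igraph directed graph.
#' @export
build_graph <- function(edges) {
  if (!nrow(edges)) {
    return(igraph::make_empty_graph(directed = TRUE))
  }
  if (any(edges$regulator == edges$target)) {
    stop("self-loops are not allowed in the TF graph")
  }
  if (anyDuplicated(edges[, c("regulator", "target")])) {
    stop("edges must be deduplicated per (regulator, target) orientation")
  }
  g <- igraph::graph_from_data_frame(edges, directed = TRUE)
  message(sprintf("TF graph: %d nodes, %d edges",
                  igraph::vcount(g), igraph::ecount(g)))
  g
}

#' Source TFs of the regulatory graph
#'
#' Cascades are rooted at source nodes: TFs that no other TF in the graph
#' regulates (in-degree zero).
#'
#' @param graph Directed igraph graph.
#' @return Lexicographically sorted character vector of source TF symbols.
#' @export
find_sources <- function(graph) {
  if (igraph::vcount(graph) == 0) return(character())
  deg_in <- igraph::degree(graph, mode = "in")
  sort(names(deg_in)[deg_in == 0])
}

#' Enumerate simple directed TF cascades
#'
#' Performs a depth-first search from every source node (in-degree 0),
#' pruning cycles with a visited set along the current path, and emits
#' maximal simple directed paths: a path is emitted when no out-neighbour of
#' its last node can extend it without revisiting a node. With
#' `include_prefixes = TRUE`, every prefix of length >= 2 is also emitted.
#' Duplicate node sequences are removed and the output is sorted
#' lexicographically by chain, so results are deterministic across runs.
#'
#' Graphs in which every node lies on a cycle have no sources; the result is
#' then empty, with a warning rather than an error.
#'
#' @param graph Directed igraph graph without self-loops.
#' @param max_length Safety cap on chain length (number of TFs); enumeration
#'   beyond it is truncated with a warning. Default 64.
#' @param max_cascades Safety cap on the number of cascades; default 1e6.
#' @param include_prefixes Emit non-maximal prefixes as separate cascades.
#' @return A list of cascades, each a character vector of TF symbols in
#'   regulatory order (class `tf_cascades`). Attribute `truncated` flags a
#'   hit cap.
#' @export
enumerate_cascades <- function(graph, max_length = 64L, max_cascades = 1e6,
                               include_prefixes = FALSE) {
  if (any(igraph::which_loop(graph))) {
    stop("graph must not contain self-loops")
  }
  sources <- find_sources(graph)
  if (igraph::vcount(graph) > 0 && !length(sources)) {
    warning("graph has no in-degree-0 source node (every node lies on a ",
            "cycle); no cascades enumerated")
  }
  # adjacency as sorted neighbour lists for deterministic DFS order
  nodes <- igraph::V(graph)$name
  adj <- lapply(igraph::adjacent_vertices(graph, nodes, mode = "out"),
                function(v) sort(v$name))
  names(adj) <- nodes

  out <- new.env(parent = emptyenv())
  out$paths <- vector("list", 256L)
  out$n <- 0L
  out$truncated <- FALSE
  push <- function(chain) {
    if (out$n >= max_cascades) {
      out$truncated <- TRUE
      return(FALSE)
    }
    out$n <- out$n + 1L
    if (out$n > length(out$paths)) {
      length(out$paths) <- 2L * length(out$paths)
    }
    out$paths[[out$n]] <- chain
    TRUE
  }

  dfs <- function(path) {
    if (out$truncated && out$n >= max_cascades) return()
    last <- path[length(path)]
    extensions <- adj[[last]][!(adj[[last]] %in% path)]
    if (!length(extensions)) {
      if (length(path) >= 2L) push(path)
      return()
    }
    if (length(path) >= max_length) {
      out$truncated <- TRUE
      push(path)
      return()
    }
    if (include_prefixes && length(path) >= 2L) push(path)
    for (w in extensions) {
      dfs(c(path, w))
    }
  }
  for (s in sources) {
    dfs(s)
    if (out$truncated && out$n >= max_cascades) break
  }
  paths <- out$paths[seq_len(out$n)]
  if (out$truncated) {
    warning(sprintf(
      "cascade enumeration truncated (max_length = %d, max_cascades = %g); ",
      max_length, max_cascades), "results are incomplete")
  }
  # deduplicate exact node sequences, sort lexicographically by chain
  keys <- vapply(paths, paste, character(1), collapse = "\r")
  paths <- paths[!duplicated(keys)]
  paths <- paths[order(vapply(paths, paste, character(1), collapse = "\r"),
                       method = "radix")]
  reachable <- unique(unlist(paths))
  unreached <- setdiff(nodes, reachable)
  if (length(unreached) && length(sources)) {
    message(length(unreached),
            " node(s) unreachable from any source were never visited")
  }
  structure(paths, class = "tf_cascades", truncated = out$truncated,
            unreached = unreached)
}

#' Cascade level of a chain
#'
#' A chain of `n` TFs has cascade level `n - 1` (the number of regulatory
#' steps), reported with the label `L{n-1}`: a three-TF chain has length 3
#' and level label "L2".
#'
#' @param chain Character vector of TF symbols.
#' @return The level label, e.g. `"L2"`.
#' @export
cascade_level <- function(chain) {
  sprintf("L%d", length(chain) - 1L)
}

#' Convert cascades to the wide, level-indexed cascade table
#'
#' One row per cascade: sequential `cascade_id`, the level label (`"L2"` for
#' a 3-TF chain) and one `TF_i` column per position up to the longest chain.
#' Positions beyond a cascade's length are structurally missing (`NA`).
#'
#' @param cascades List of chains from [enumerate_cascades()].
#' @return Data frame with columns `cascade_id`, `level`, `TF_1` ...
#'   `TF_<maxlen>`.
#' @export
to_cascade_table <- function(cascades) {
  if (!length(cascades)) {
    return(data.frame(cascade_id = integer(), level = character(),
                      stringsAsFactors = FALSE))
  }
  maxlen <- max(lengths(cascades))
  mat <- t(vapply(cascades, function(ch) c(ch, rep(NA_character_,
                                                   maxlen - length(ch))),
                  character(maxlen)))
  tab <- data.frame(cascade_id = seq_along(cascades),
                    level = vapply(cascades, cascade_level, character(1)),
                    mat, stringsAsFactors = FALSE)
  names(tab) <- c("cascade_id", "level", paste0("TF_", seq_len(maxlen)))
  rownames(tab) <- NULL
  tab
}

#' Frequency of cascades per chain length
#'
#' @param table Cascade table from [to_cascade_table()].
#' @return Named integer vector mapping chain length to cascade count; the
#'   counts sum to the number of rows.
#' @export
level_histogram <- function(table) {
  if (!nrow(table)) return(stats::setNames(integer(), character()))
  lev <- as.integer(sub("^L", "", table$level))
  tab <- table(lev + 1L)  # chain length = level + 1
  stats::setNames(as.integer(tab), names(tab))
}

#' Univariate exploratory summary of the cascade table
#'
#' For each TF position: number of distinct symbols, the five most frequent
#' symbols with their counts, and the structurally-missing fraction (the
#' share of cascades shorter than that position). Globally: row count,
#' number of distinct levels and the five most frequent levels.
#'
#' @param table Cascade table from [to_cascade_table()].
#' @return List with elements `n_rows`, `n_distinct_levels`, `top_levels`
#'   (named counts) and `positions` (data frame keyed by position).
#' @export
eda_summary <- function(table) {
  tf_cols <- grep("^TF_", names(table), value = TRUE)
  top5 <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return("")
    tt <- sort(table(x), decreasing = TRUE)
    tt <- utils::head(tt, 5)
    paste(sprintf("%s(%d)", names(tt), as.integer(tt)), collapse = ";")
  }
  positions <- data.frame(
    position = seq_along(tf_cols),
    distinct = vapply(tf_cols, function(cn)
      length(unique(stats::na.omit(table[[cn]]))), integer(1)),
    missing_fraction = vapply(tf_cols, function(cn)
      if (nrow(table)) mean(is.na(table[[cn]])) else NA_real_, numeric(1)),
    top5 = vapply(tf_cols, function(cn) top5(table[[cn]]), character(1)),
    stringsAsFactors = FALSE
  )
  rownames(positions) <- NULL
  lev_tab <- sort(table(table$level), decreasing = TRUE)
  list(
    n_rows = nrow(table),
    n_distinct_levels = length(lev_tab),
    top_levels = stats::setNames(as.integer(utils::head(lev_tab, 5)),
                                 names(utils::head(lev_tab, 5))),
    positions = positions
  )
}
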