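#' Build the extraction graph by uniting all cascades
#'
#' Combines every cascade into a single simple directed graph: nodes are the
#' TFs appearing in at least one cascade; each consecutive pair in any
#' cascade contributes a directed edge, deduplicated with an
#' `occurrence_count` attribute recording in how many cascades the pair
#' appears consecutively.
#'
#' @param cascades List of chains from [enumerate_cascades()].
#' @return Directed igraph graph with edge attribute `occurrence_count`.
#' @export
build_extraction_graph <- function(cascades) {
  if (!length(cascades)) return(igraph::make_empty_graph(directed = TRUE))
  pairs <- do.call(rbind, lapply(cascades, function(ch) {
    if (length(ch) < 2L) return(NULL)
    cbind(ch[-length(ch)], ch[-1L])
  }))
  key <- paste(pairs[, 1], pairs[, 2], sep = "\r")
  cnt <- table(key)
  uniq <- !duplicated(key)
  df <- data.frame(from = pairs[uniq, 1], to = pairs[uniq, 2],
                   occurrence_count = as.integer(cnt[key[uniq]]),
                   stringsAsFactors = FALSE)
  df <- df[order(df$from, df$to), , drop = FALSE]
  singletons <- setdiff(unique(unlist(cascades)), c(df$from, df$to))
  g <- igraph::graph_from_data_frame(df, directed = TRUE,
                                     vertices = sort(unique(c(
                                       df$from, df$to, singletons))))
  message(sprintf("extraction graph: %d nodes, %d unique edges, %d total occurrences",
                  igraph::vcount(g), igraph::ecount(g),
                  sum(df$occurrence_count)))
  g
}

#' Fixed-iteration PageRank with uniform initial weights
#'
#' Runs the damped power-method update
#' `x'(v) = (1 - d) / N + d * sum_{u -> v} x(u) / outdeg(u)` for a fixed
#' number of iterations on the directed graph, with the mass of dangling
#' nodes (out-degree 0) redistributed uniformly. Every node starts at the
#' same initial weight (default 0.25, the cascade-connection convention);
#' because that start vector need not sum to one, the final vector is
#' L1-normalized for reporting so scores are comparable across graphs.
#'
#' @param graph Directed igraph graph.
#' @param damping Damping factor, default 0.85.
#' @param iterations Number of power iterations, default 10 (no convergence
#'   test; see `converge`).
#' @param init Initial weight assigned to every node, default 0.25.
#' @param converge If `TRUE`, iterate instead until the L1 change drops
#'   below `tol` (overrides `iterations`).
#' @param tol Convergence tolerance used when `converge = TRUE`.
#' @return Named numeric vector of PageRank scores summing to 1, sorted
#'   descending with lexicographic tie-break.
#' @export
pagerank <- function(graph, damping = 0.85, iterations = 10L, init = 0.25,
                     converge = FALSE, tol = 1e-10) {
  n <- igraph::vcount(graph)
  if (n == 0) stop("cannot compute PageRank on an empty graph")
  nodes <- igraph::V(graph)$name
  el <- igraph::as_edgelist(graph, names = FALSE)
  outdeg <- igraph::degree(graph, mode = "out")
  x <- rep(init, n)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    contrib <- x / pmax(outdeg, 1)
    dangling_mass <- sum(x[outdeg == 0])
    xn <- rep((1 - damping) / n + damping * dangling_mass / n, n)
    if (nrow(el)) {
      inc <- tapply(contrib[el[, 1]], el[, 2], sum)
      idx <- as.integer(names(inc))
      xn[idx] <- xn[idx] + damping * as.numeric(inc)
    }
    delta <- sum(abs(xn - x))
    x <- xn
    if (converge) {
      if (delta < tol || iter >= 1000L) break
    } else if (iter >= iterations) break
  }
  x <- x / sum(x)
  names(x) <- nodes
  x[order(-x, nodes, method = "radix")]
}

#' Classical centralities of the extraction graph
#'
#' Computes, per TF: total degree (in + out), betweenness on the directed
#' graph (normalized shortest-path betweenness), closeness and eigenvector
#' centrality. Closeness and eigenvector are computed on the undirected view
#' by default: on a near-acyclic directed graph, directed eigenvector
#' centrality collapses to zero on source nodes and directed closeness is
#' undefined for most pairs, which makes the undirected view the informative
#' one. Closeness uses the Wasserman-Faust correction so disconnected graphs
#' get component-size-weighted values; eigenvector centrality is scaled to
#' unit Euclidean norm and non-negative.
#'
#' @param graph Directed igraph graph.
#' @param directed_centrality If `TRUE`, compute closeness and eigenvector
#'   on the directed graph instead of the undirected view.
#' @return Data frame with columns `tf`, `degree`, `betweenness`,
#'   `closeness`, `eigenvector`, sorted by TF symbol.
#' @export
centralities <- function(graph, directed_centrality = FALSE) {
  n <- igraph::vcount(graph)
  if (n == 0) stop("cannot compute centralities on an empty graph")
  nodes <- igraph::V(graph)$name
  deg <- igraph::degree(graph, mode = "all")
  btw <- igraph::betweenness(graph, directed = TRUE,
                             normalized = TRUE, weights = NA)
  gview <- if (directed_centrality) graph else
    igraph::as_undirected(graph, mode = "collapse")
  clo <- closeness_wf(gview, directed = directed_centrality)
  # leading eigenvector via a dense solver: deterministic across runs,
  # unlike ARPACK with a random start vector
  eig <- if (n == 1) stats::setNames(1, nodes) else {
    A <- igraph::as_adjacency_matrix(gview, sparse = FALSE)
    A <- 1 * (A > 0)
    ev <- if (directed_centrality) {
      e <- eigen(A)
      Re(e$vectors[, which.max(Re(e$values))])
    } else {
      e <- eigen(A, symmetric = TRUE)
      e$vectors[, which.max(e$values)]
    }
    v <- abs(ev)
    v <- if (sum(v^2) > 0) v / sqrt(sum(v^2)) else v
    stats::setNames(v, rownames(A))
  }
  out <- data.frame(tf = nodes, degree = as.integer(deg),
                    betweenness = as.numeric(btw),
                    closeness = as.numeric(clo[nodes]),
                    eigenvector = as.numeric(eig[nodes]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$tf), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Wasserman-Faust closeness: ((r-1)/(n-1)) * ((r-1)/sum of distances to the
# r-1 reachable nodes); 0 for isolated nodes. igraph's closeness has no
# component-size correction, so the correction is applied here from the
# distance matrix.
closeness_wf <- function(graph, directed = FALSE) {
  n <- igraph::vcount(graph)
  nodes <- igraph::V(graph)$name
  d <- igraph::distances(graph, mode = if (directed) "out" else "all",
                         weights = NA)
  vals <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    finite <- di[is.finite(di)]
    r1 <- length(finite)  # reachable nodes excluding self
    if (r1 == 0 || n == 1) return(0)
    (r1 / (n - 1)) * (r1 / sum(finite))
  }, numeric(1))
  stats::setNames(vals, nodes)
}

#' Full per-TF rank table
#'
#' Joins PageRank, the four centralities and per-TF cascade membership
#' counts into one table, the shape used for top-k reporting.
#'
#' @param graph Extraction graph from [build_extraction_graph()].
#' @param cascades The cascades the graph was built from (for per-TF
#'   cascade membership counts).
#' @param ... Passed to [pagerank()].
#' @return Data frame with columns `tf`, `degree`, `pagerank`,
#'   `betweenness`, `closeness`, `eigenvector`, `cascade_count`, sorted by
#'   descending PageRank.
#' @export
rank_table <- function(graph, cascades = NULL, ...) {
  pr <- pagerank(graph, ...)
  cen <- centralities(graph)
  cen$pagerank <- as.numeric(pr[cen$tf])
  counts <- if (is.null(cascades)) {
    stats::setNames(rep(NA_integer_, nrow(cen)), cen$tf)
  } else {
    tab <- table(unlist(lapply(cascades, unique)))
    stats::setNames(as.integer(tab)[match(cen$tf, names(tab))], cen$tf)
  }
  cen$cascade_count <- as.integer(counts[cen$tf])
  cen$cascade_count[is.na(cen$cascade_count)] <- 0L
  cen <- cen[order(-cen$pagerank, cen$tf, method = "radix"),
             c("tf", "degree", "pagerank", "betweenness", "closeness",
               "eigenvector", "cascade_count")]
  rownames(cen) <- NULL
  cen
}

#' Prioritize TFs by centrality, cascade membership and alteration evidence
#'
#' A TF is prioritized when it satisfies all three criteria: (i) it ranks in
#' the top decile (>= 90th percentile, ties included) of at least two of the
#' four measures PageRank, eigenvector, closeness and betweenness; (ii) it
#' appears in at least `min_cascades` cascades; and (iii) it has a non-zero
#' alteration frequency in at least `min_cohorts` cohorts.
#'
#' @param rank_table Data frame from [rank_table()].
#' @param alteration_table Data frame with a `gene` column and `freq_*`
#'   cohort columns.
#' @param min_cascades Cascade-membership threshold, default 1000 (scale to
#'   the data: synthetic runs use a smaller value).
#' @param min_cohorts Minimum cohorts with non-zero alteration ("multiple
#'   cohorts"), default 2.
#' @return `rank_table` augmented with logical columns `crit_centrality`,
#'   `crit_cascades`, `crit_alteration` and `prioritized`.
#' @export
prioritize_tfs <- function(rank_table, alteration_table,
                           min_cascades = 1000L, min_cohorts = 2L) {
  measures <- c("pagerank", "eigenvector", "closeness", "betweenness")
  in_top_decile <- matrix(unlist(lapply(measures, function(m) {
    v <- rank_table[[m]]
    v >= stats::quantile(v, 0.9, type = 1)
  })), ncol = length(measures))
  n_top <- rowSums(in_top_decile)
  freq_cols <- grep("^freq_", names(alteration_table), value = TRUE)
  idx <- match(rank_table$tf, alteration_table$gene)
  n_altered <- rowSums(
    as.matrix(alteration_table[, freq_cols, drop = FALSE]) > 0
  )[idx]
  n_altered[is.na(n_altered)] <- 0
  out <- rank_table
  out$crit_centrality <- n_top >= 2L
  out$crit_cascades <- out$cascade_count >= min_cascades
  out$crit_alteration <- n_altered >= min_cohorts
  out$prioritized <- out$crit_centrality & out$crit_cascades &
    out$crit_alteration
  out
}
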